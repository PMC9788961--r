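# Ridge-regression BLUP genomic prediction on signed PAV markers, the
# present-allele sweep, and replicated k-fold cross-validation.

#' Fit RR-BLUP: y = 1 beta + Z g + e with g ~ N(0, sigma_g^2 I)
#'
#' The ridge parameter lambda = sigma_e^2 / sigma_g^2 is estimated by REML
#' through the spectral decomposition of Z Z' (an n x n problem regardless of
#' marker count), reusing the single-ratio REML engine. Marker effects are
#' recovered in dual form, g = Z' (Z Z' + lambda I)^-1 (y - 1 beta), with
#' beta the GLS intercept.
#'
#' @param y numeric trait vector; z-scored internally when `standardize`
#'   (the default), matching the convention of fitting all traits on a
#'   common scale.
#' @param Z numeric matrix, samples x markers, signed coding (-1 absent,
#'   +1 present).
#' @param standardize z-score `y` before fitting (default TRUE).
#' @return list of class `rrblup_model`: beta, g (named marker effects),
#'   sigma_g2, sigma_e2, lambda, h2 (marker-variance share on the n x n
#'   scale), marker_ids, sample_ids, y_center, y_scale.
#' @export
fit_rrblup <- function(y, Z, standardize = TRUE) {
  Z <- as.matrix(Z)
  n <- length(y)
  assert_that(nrow(Z) == n, "y and Z must have matching samples")
  assert_that(n >= 10 && ncol(Z) >= 1, "need n >= 10 samples and >= 1 marker")
  if (var(y) == 0) stop2("zero-variance trait")
  y_center <- if (standardize) mean(y) else 0
  y_scale <- if (standardize) sd(y) else 1
  ys <- (y - y_center) / y_scale

  K <- tcrossprod(Z)
  X <- matrix(1, n, 1)
  null <- fit_null_mixed_model(ys, X, K)
  lambda <- null$delta

  U <- null$eigen_K$vectors
  lam <- pmax(null$eigen_K$values, 0)
  hinv <- 1 / (lam + lambda)      # (ZZ' + lambda I)^-1 in the eigenbasis
  Uy <- drop(crossprod(U, ys))
  U1 <- drop(crossprod(U, X))
  beta <- sum(U1 * hinv * Uy) / sum(U1 * hinv * U1)
  resid_rot <- hinv * (Uy - U1 * beta)
  g <- drop(crossprod(Z, U %*% resid_rot))
  names(g) <- colnames(Z) %||% sprintf("m%06d", seq_len(ncol(Z)))

  # marker-variance share on the trait scale: sigma_g2 is per-marker, and
  # the genetic variance per sample is sigma_g2 * diag(ZZ') (= m for signed
  # coding)
  kdiag <- mean(diag(K))
  structure(
    list(beta = beta, g = g,
         sigma_g2 = null$sigma_g2, sigma_e2 = null$sigma_e2,
         lambda = lambda,
         h2 = null$sigma_g2 * kdiag / (null$sigma_g2 * kdiag + null$sigma_e2),
         marker_ids = names(g),
         sample_ids = rownames(Z) %||% as.character(seq_len(n)),
         y_center = y_center, y_scale = y_scale),
    class = "rrblup_model"
  )
}

#' Predict phenotypes from an RR-BLUP model
#'
#' @param object an `rrblup_model`.
#' @param Znew samples x markers signed genotype matrix (marker order must
#'   match the training matrix).
#' @param ... unused.
#' @return numeric vector of predictions on the (standardized) trait scale.
#' @export
predict.rrblup_model <- function(object, Znew, ...) {
  Znew <- as.matrix(Znew)
  assert_that(ncol(Znew) == length(object$g), "marker count mismatch")
  drop(object$beta + Znew %*% object$g)
}

#' Sweep the fraction of present alleles and regress prediction on it
#'
#' For each percentage p on a 0..100 grid (101 points at the default 1-pct
#' step; both endpoints are kept and are deterministic: all-absent at 0,
#' all-present at 100), a genotype vector is drawn with each locus
#' independently present with probability p/100, the fitted model predicts
#' its phenotype, and an ordinary least squares line predicted ~ percentage
#' is fitted. A positive slope means presence alleles tend to increase the
#' trait.
#'
#' @param model an `rrblup_model`.
#' @param step_pct grid step in percent (default 1).
#' @param n_draws_per_point genotype draws averaged per grid point
#'   (default 1, one prediction per interval).
#' @param seed RNG seed.
#' @return list of class `sweep_result`: grid (data.frame pct, prediction),
#'   slope, intercept, slope_se, slope_ci (95%), seed.
#' @export
sweep_present_fraction <- function(model, step_pct = 1, n_draws_per_point = 1L,
                                   seed = 1L) {
  assert_that(inherits(model, "rrblup_model"), "fitted rrblup_model required")
  m <- length(model$g)
  pct <- seq(0, 100, by = step_pct)
  set.seed(seed)
  pred <- vapply(pct, function(p) {
    mean(vapply(seq_len(n_draws_per_point), function(d) {
      z <- ifelse(runif(m) < p / 100, 1, -1)
      model$beta + sum(z * model$g)
    }, 0))
  }, 0)
  fit <- lm(pred ~ pct)
  ci <- stats::confint(fit)["pct", ]
  structure(
    list(grid = data.frame(pct = pct, prediction = pred),
         slope = unname(coef(fit)["pct"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         slope_se = summary(fit)$coefficients["pct", "Std. Error"],
         slope_ci = unname(ci), seed = seed),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("present-allele sweep: slope %.4g per pct (95%% CI [%.4g, %.4g])\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Replicated k-fold cross-validation of RR-BLUP prediction
#'
#' For each k and each repeat, unique sample identifiers are randomly
#' assigned to k bins (duplicated identifiers are co-assigned, so repeated
#' measurements of one line never leak across the train/validation split);
#' each bin is predicted once from a model trained on the remaining bins.
#' Accuracy per run is the Pearson correlation between predicted and
#' observed values in the validation bin; R^2 comes from the linear model
#' observed ~ predicted.
#'
#' @param y trait vector.
#' @param Z samples x markers signed genotype matrix.
#' @param k_values folds to evaluate (default c(2, 5, 10)).
#' @param n_repeats repeats per k (default 20, giving k x 20 runs).
#' @param seed RNG seed.
#' @param standardize passed to [fit_rrblup()].
#' @return list of class `cv_result`: `runs` data.frame (k, repeat, fold, r,
#'   r2) and `summary` (per-k mean and SD of r and R^2 across runs).
#' @export
cross_validate <- function(y, Z, k_values = c(2L, 5L, 10L), n_repeats = 20L,
                           seed = 1L, standardize = TRUE) {
  Z <- as.matrix(Z)
  n <- length(y)
  assert_that(n >= max(k_values), "need at least max(k) samples")
  ids <- rownames(Z) %||% as.character(seq_len(n))
  uid <- unique(ids)
  set.seed(seed)
  rows <- list()
  for (k in k_values) {
    for (rep_i in seq_len(n_repeats)) {
      bin_of <- setNames(sample(rep_len(seq_len(k), length(uid))), uid)
      fold <- bin_of[ids]
      for (f in seq_len(k)) {
        test <- fold == f
        if (sum(!test) < 10 || sum(test) < 2) next
        model <- fit_rrblup(y[!test], Z[!test, , drop = FALSE],
                            standardize = standardize)
        pred <- predict(model, Z[test, , drop = FALSE])
        obs <- (y[test] - model$y_center) / model$y_scale
        r <- if (var(obs) > 0 && var(pred) > 0) cor(obs, pred) else NA_real_
        r2 <- if (!is.na(r)) summary(lm(obs ~ pred))$r.squared else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, rep = rep_i, fold = f, r = r, r2 = r2
        )
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$k), function(d) {
    data.frame(k = d$k[1], n_runs = nrow(d),
               mean_r = mean(d$r, na.rm = TRUE), sd_r = sd(d$r, na.rm = TRUE),
               mean_r2 = mean(d$r2, na.rm = TRUE), sd_r2 = sd(d$r2, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg, seed = seed), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("replicated k-fold cross-validation:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
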