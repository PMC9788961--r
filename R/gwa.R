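# Mixed-model association on PAV (or stop-codon) markers and the
# direction-of-effect proportion statistic with block-bootstrap confidence
# intervals.

#' Greedy LD pruning of markers
#'
#' Left-to-right greedy retention within each chromosome: a marker is kept
#' unless its squared Pearson correlation with an already-retained marker
#' within `window_bp` exceeds `r2_max`. Defaults reproduce the common
#' "LD < 0.2 in 500 kb windows" rule.
#'
#' @param geno numeric matrix, markers x samples.
#' @param positions data.frame with `chrom` and `pos` (bp) per marker, same
#'   order as `geno` rows.
#' @param r2_max maximum allowed squared correlation (default 0.2).
#' @param window_bp window width in bp (default 500000).
#' @return logical vector of retained markers.
#' @export
ld_prune <- function(geno, positions, r2_max = 0.2, window_bp = 500000L) {
  n <- nrow(geno)
  keep <- logical(n)
  for (chr in unique(positions$chrom)) {
    idx <- which(positions$chrom == chr)
    idx <- idx[order(positions$pos[idx])]
    retained <- integer(0)
    for (j in idx) {
      near <- retained[positions$pos[retained] > positions$pos[j] - window_bp]
      ok <- TRUE
      for (r in near) {
        r2 <- suppressWarnings(cor(geno[j, ], geno[r, ]))^2
        if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) {
        keep[j] <- TRUE
        retained <- c(retained, j)
      }
    }
  }
  keep
}

#' Principal components and identity-by-state kinship from markers
#'
#' PCs come from the singular value decomposition of the centered
#' sample-by-marker matrix; kinship is the pairwise identity-by-state
#' proportion (1 minus the mean absolute allelic difference after rescaling
#' genotypes to [0, 1]).
#'
#' @param geno numeric matrix, markers x samples.
#' @param n_pcs number of PCs to return (default 10, capped by rank).
#' @param method "ibs" (default) for the identity-by-state proportion or
#'   "grm" for the centered-and-scaled genomic relationship matrix
#'   X X' / m on standardized genotypes (diagonal near 1, off-diagonal near
#'   0 for unrelated samples, so the variance ratio is directly
#'   interpretable as heritability).
#' @return list: `scores` (samples x PCs), `varprop` (variance share per PC),
#'   `kinship` (samples x samples matrix).
#' @export
compute_pca_kinship <- function(geno, n_pcs = 10L, method = c("ibs", "grm")) {
  method <- match.arg(method)
  assert_that(ncol(geno) >= 3, "at least 3 samples required")
  const <- apply(geno, 1, function(r) var(r) == 0 || all(is.na(r)))
  if (any(const)) {
    warning("dropping ", sum(const), " constant marker(s)")
    geno <- geno[!const, , drop = FALSE]
  }
  x <- t(geno)
  if (method == "ibs") {
    rng <- range(geno)
    xs <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x
    k <- 1 - as.matrix(dist(xs, method = "manhattan")) / ncol(xs)
  } else {
    xs <- scale(x)
    k <- tcrossprod(xs) / ncol(xs)
  }
  dimnames(k) <- list(rownames(x), rownames(x))

  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  list(
    scores = pc$x[, seq_len(n_pcs), drop = FALSE],
    varprop = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)],
    kinship = k
  )
}

# Restricted log-likelihood of the single-ratio model at delta = sigma_e^2 /
# sigma_g^2, in terms of the eigenvalues xi of the kinship projected off X
# and the rotated residuals eta.
reml_loglik <- function(delta, xi, eta2) {
  q <- length(xi)
  s <- sum(eta2 / (xi + delta))
  0.5 * (q * log(q / (2 * pi)) - q - q * log(s) - sum(log(xi + delta)))
}

#' Fit the null mixed model y ~ N(Xb, sigma_g^2 K + sigma_e^2 I) by REML
#'
#' Single-ratio REML via the spectral decomposition of the kinship matrix
#' projected off the covariates: the variance ratio delta = sigma_e^2 /
#' sigma_g^2 maximizing the restricted likelihood is located on a log-spaced
#' grid (1e-5 to 1e5) and refined by golden-section search in the bracketing
#' interval. The full eigendecomposition of K is cached so that per-marker
#' generalized least squares can be run with the variance components fixed
#' (the EMMAX approximation).
#'
#' @param y numeric trait vector.
#' @param X covariate matrix including the intercept (samples x covariates).
#' @param K kinship matrix (symmetric positive semi-definite).
#' @param grid_points number of log-grid points for the delta search.
#' @return list of class `null_mixed_model`: delta, sigma_g2, sigma_e2, h2,
#'   identifiable flag, loglik, plus the cached rotation (eigen of K) and X.
#' @export
fit_null_mixed_model <- function(y, X, K, grid_points = 100L) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  assert_that(n > p + 1, "more samples than covariates + 1 required")
  assert_that(nrow(X) == n && all(dim(K) == n), "dimension mismatch")
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(abs(eK$values))) {
    stop2("kinship matrix is not positive semi-definite")
  }

  # projection off X, restricted spectrum
  qrX <- qr(X)
  Q <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  eR <- eigen(crossprod(Q, K %*% Q), symmetric = TRUE)
  xi <- pmax(eR$values, 0)
  eta <- crossprod(eR$vectors, crossprod(Q, y))
  eta2 <- drop(eta)^2

  grid <- 10^seq(-5, 5, length.out = grid_points)
  ll <- vapply(grid, reml_loglik, 0, xi = xi, eta2 = eta2)
  i <- which.max(ll)
  identifiable <- diff(range(ll)) > 1e-6
  if (!identifiable) {
    warning("restricted likelihood is flat in delta; variance ratio unidentifiable (K ~ I or h2 ~ 0)")
  }
  if (i == 1L || i == grid_points) {
    warning("delta at grid boundary; h2 estimate is at the edge of the search range")
    delta <- grid[i]
  } else {
    opt <- optimize(reml_loglik, interval = c(grid[i - 1L], grid[i + 1L]),
                    xi = xi, eta2 = eta2, maximum = TRUE, tol = 1e-10)
    delta <- opt$maximum
    if (reml_loglik(delta, xi, eta2) < ll[i]) delta <- grid[i]
  }
  sigma_g2 <- sum(eta2 / (xi + delta)) / length(xi)
  sigma_e2 <- delta * sigma_g2
  structure(
    list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         h2 = sigma_g2 / (sigma_g2 + sigma_e2),
         identifiable = identifiable,
         loglik = reml_loglik(delta, xi, eta2),
         grid = grid, grid_loglik = ll,
         eigen_K = eK, X = X, y = y),
    class = "null_mixed_model"
  )
}

#' Score markers by generalized least squares with fixed variance components
#'
#' EMMAX approximation: the variance components from the null fit rotate the
#' model into independent observations; each marker is then tested by
#' weighted least squares against the covariate-residualized trait. Two-sided
#' p-values use the t distribution with n - rank(X) - 1 degrees of freedom.
#'
#' @param geno numeric matrix, markers x samples, signed coding
#'   (-1 absent / +1 present) for PAVs or any numeric dosage.
#' @param null a `null_mixed_model` from [fit_null_mixed_model()].
#' @param positions optional data.frame (chrom, pos) per marker, carried into
#'   the result for block assignment.
#' @return data.frame of class `association_result`: marker, chrom, pos,
#'   beta, se, t, p, direction. Monomorphic or collinear markers are skipped.
#' @export
score_markers <- function(geno, null, positions = NULL) {
  assert_that(inherits(null, "null_mixed_model"), "null model fit required")
  U <- null$eigen_K$vectors
  lam <- pmax(null$eigen_K$values, 0)
  w <- 1 / (null$sigma_g2 * lam + null$sigma_e2)
  sw <- sqrt(w)
  n <- length(null$y)
  p <- ncol(null$X)

  ys <- sw * drop(crossprod(U, null$y))
  Xs <- sw * crossprod(U, null$X)
  Zs <- sw * crossprod(U, t(geno))      # n x m
  XtXi <- solve(crossprod(Xs))
  resid_y <- ys - Xs %*% (XtXi %*% crossprod(Xs, ys))
  resid_Z <- Zs - Xs %*% (XtXi %*% crossprod(Xs, Zs))

  ztz <- colSums(resid_Z^2)
  zty <- drop(crossprod(resid_Z, resid_y))
  yty <- sum(resid_y^2)
  df <- n - p - 1L

  mono <- apply(geno, 1, function(r) var(r) == 0)
  usable <- !mono & ztz > 1e-10 * max(ztz)
  if (any(!usable)) {
    message("skipping ", sum(!usable), " monomorphic/collinear marker(s)")
  }
  beta <- zty / ztz
  rss <- pmax(yty - beta^2 * ztz, 0)
  se <- sqrt(rss / df / ztz)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)

  out <- data.frame(
    marker = rownames(geno) %||% sprintf("m%06d", seq_len(nrow(geno))),
    chrom = if (!is.null(positions)) positions$chrom else NA_character_,
    pos = if (!is.null(positions)) positions$pos else NA_integer_,
    beta = beta, se = se, t = tval, p = pval,
    direction = ifelse(beta > 0, "positive", ifelse(beta < 0, "negative", "zero")),
    stringsAsFactors = FALSE
  )[usable, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_result", class(out))
  out
}

#' Direction-of-effect proportion with block-bootstrap confidence interval
#'
#' Among markers significant at `p < alpha`, computes the proportion whose
#' presence allele has a positive effect, then resamples 1-Mb genomic blocks
#' of those markers with replacement (as many draws as observed blocks) to
#' form a percentile 95% confidence interval. The proportion differs from
#' the 0.5 random expectation when the CI excludes 0.5; an exact binomial
#' test against 0.5 is reported alongside for reference. Markers with a beta
#' of exactly zero are excluded from both numerator and denominator.
#'
#' @param results an `association_result` data.frame with positions.
#' @param alpha significance threshold for selecting markers (default 0.05).
#' @param block_bp block width in bp (default 1e6).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `direction_summary`: n_selected, n_blocks,
#'   prop_positive, ci (lo, hi), excludes_half, binom_p, alpha, block_bp,
#'   n_boot, seed.
#' @export
direction_summary <- function(results, alpha = 0.05, block_bp = 1e6,
                              n_boot = 2000L, seed = 1L) {
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  sel <- results[results$p < alpha & results$direction != "zero", , drop = FALSE]
  if (!nrow(sel)) {
    return(structure(list(n_selected = 0L, n_blocks = 0L,
                          prop_positive = NA_real_, ci = c(NA_real_, NA_real_),
                          excludes_half = NA, binom_p = NA_real_,
                          alpha = alpha, block_bp = block_bp,
                          n_boot = n_boot, seed = seed),
                     class = "direction_summary"))
  }
  assert_that(!any(is.na(sel$pos)), "marker positions required for block bootstrap")
  pos_flag <- sel$direction == "positive"
  prop <- mean(pos_flag)
  block <- paste0(sel$chrom, ":", floor(sel$pos / block_bp))
  blocks <- split(pos_flag, block)
  b <- length(blocks)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    draw <- sample.int(b, b, replace = TRUE)
    mean(unlist(blocks[draw], use.names = FALSE))
  }, 0)
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(
    list(n_selected = nrow(sel), n_blocks = b, prop_positive = prop,
         ci = ci, excludes_half = ci[1] > 0.5 || ci[2] < 0.5,
         binom_p = stats::binom.test(sum(pos_flag), length(pos_flag), 0.5)$p.value,
         alpha = alpha, block_bp = block_bp, n_boot = n_boot, seed = seed),
    class = "direction_summary"
  )
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("direction summary: %d significant markers in %d blocks\n",
              x$n_selected, x$n_blocks))
  if (x$n_selected > 0) {
    cat(sprintf("  prop(presence effect > 0) = %.3f, 95%% CI [%.3f, %.3f]%s\n",
                x$prop_positive, x$ci[1], x$ci[2],
                if (isTRUE(x$excludes_half)) " (differs from 0.5)" else ""))
  }
  invisible(x)
}

#' Run the association + direction chain on one marker set
#'
#' Convenience wrapper used both for PAV windows and for stop-codon
#' genotypes: fits the null mixed model once, scores every marker, and
#' summarizes the direction of significant effects.
#'
#' @param geno markers x samples numeric matrix.
#' @param y trait vector aligned with columns of `geno`.
#' @param X covariate matrix (with intercept).
#' @param K kinship matrix.
#' @param positions data.frame (chrom, pos) per marker.
#' @param alpha,block_bp,n_boot,seed passed to [direction_summary()].
#' @return list: `null` fit, `results`, `direction`.
#' @export
run_direction_gwa <- function(geno, y, X, K, positions,
                              alpha = 0.05, block_bp = 1e6,
                              n_boot = 2000L, seed = 1L) {
  null <- fit_null_mixed_model(y, X, K)
  res <- score_markers(geno, null, positions)
  list(null = null, results = res,
       direction = direction_summary(res, alpha = alpha, block_bp = block_bp,
                                     n_boot = n_boot, seed = seed))
}
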