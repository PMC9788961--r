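# Sparse partial least squares between an expression block and a splicing
# block: iterative power method on the cross-covariance with rank-calibrated
# soft-thresholding, deflation between components.

soft_threshold_keep <- function(v, keep) {
  if (keep >= length(v)) return(v)
  thr <- sort(abs(v), decreasing = TRUE)[keep + 1L]
  sign(v) * pmax(abs(v) - thr, 0)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

#' Fit a two-block sparse partial least squares model
#'
#' Per component, loading vectors (u, v) maximize u' X' Y v subject to
#' sparsity: each power-method update is soft-thresholded so that at most
#' `keepX` / `keepY` loadings stay nonzero (the threshold is the magnitude
#' of the (keep+1)-th largest entry, making the sparsity deterministic),
#' then renormalized to unit length. With `keepX`/`keepY` equal to the full
#' column counts the solution coincides with the leading singular vectors of
#' X'Y (classical two-block PLS). Components are deflated before the next
#' one is extracted: both blocks on their own scores in canonical mode, Y on
#' the X score in regression mode.
#'
#' @param X samples x features matrix (e.g. log-CPM of the top
#'   differentially expressed genes).
#' @param Y samples x features matrix (e.g. PSI of the top differentially
#'   spliced events); same rows as `X`.
#' @param n_components number of components (default 2).
#' @param keepX,keepY maximum nonzero loadings per component (default 50).
#' @param scale unit-variance scale the columns (default TRUE); columns are
#'   always centered.
#' @param mode "canonical" (default) or "regression".
#' @param max_iter,tol power-iteration controls.
#' @return list of class `spls_model`: loadings_x, loadings_y (features x
#'   components), scores_x, scores_y (samples x components), n_components,
#'   keepX, keepY, mode.
#' @export
fit_spls <- function(X, Y, n_components = 2L, keepX = 50L, keepY = 50L,
                     scale = TRUE, mode = c("canonical", "regression"),
                     max_iter = 500L, tol = 1e-6) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y must share sample rows")
  assert_that(keepX >= 1 && keepY >= 1, "keepX/keepY must be >= 1")
  cscale <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    if (scale) {
      s <- apply(M, 2, sd)
      s[s == 0] <- 1
      M <- sweep(M, 2, s, `/`)
    }
    M
  }
  Xc <- cscale(X); Yc <- cscale(Y)
  p <- ncol(Xc); q <- ncol(Yc)
  keepX <- min(keepX, p); keepY <- min(keepY, q)

  U <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  Tx <- matrix(0, nrow(X), n_components, dimnames = list(rownames(X), NULL))
  Ty <- matrix(0, nrow(X), n_components, dimnames = list(rownames(X), NULL))

  for (h in seq_len(n_components)) {
    M <- crossprod(Xc, Yc)
    sv <- svd(M, nu = 1, nv = 1)
    u <- drop(sv$u); v <- drop(sv$v)
    for (it in seq_len(max_iter)) {
      u_new <- unit(soft_threshold_keep(drop(M %*% v), keepX))
      v_new <- unit(soft_threshold_keep(drop(crossprod(M, u_new)), keepY))
      delta <- max(sum((u_new - u)^2), sum((v_new - v)^2))
      u <- u_new; v <- v_new
      if (delta < tol^2) break
    }
    # resolve the sign indeterminacy: largest-|loading| X entry positive
    s <- sign(u[which.max(abs(u))])
    if (s < 0) { u <- -u; v <- -v }
    xi <- drop(Xc %*% u)
    om <- drop(Yc %*% v)
    U[, h] <- u; V[, h] <- v; Tx[, h] <- xi; Ty[, h] <- om

    if (h < n_components) {
      Xc <- Xc - xi %*% crossprod(xi, Xc) / sum(xi^2)
      if (mode == "canonical") {
        Yc <- Yc - om %*% crossprod(om, Yc) / sum(om^2)
      } else {
        Yc <- Yc - xi %*% crossprod(xi, Yc) / sum(xi^2)
      }
    }
  }
  structure(
    list(loadings_x = U, loadings_y = V, scores_x = Tx, scores_y = Ty,
         n_components = n_components, keepX = keepX, keepY = keepY, mode = mode),
    class = "spls_model"
  )
}

#' Correlation summary of a fitted sPLS model
#'
#' Reports the Pearson correlation between the X and Y sample scores per
#' component, every pairwise correlation between the selected (nonzero
#' loading, any component) X and Y features on the original data, and the
#' fraction of those pairwise correlations that are negative.
#'
#' @param model a fitted `spls_model`.
#' @param X,Y the data matrices the model was fitted on.
#' @return list of class `spls_correlation`: component_r, pair_cor (matrix
#'   selected-X x selected-Y), negative_fraction, n_pairs.
#' @export
correlation_summary <- function(model, X, Y) {
  comp_r <- vapply(seq_len(model$n_components), function(h) {
    cor(model$scores_x[, h], model$scores_y[, h])
  }, 0)
  sel_x <- rownames(model$loadings_x)[rowSums(model$loadings_x != 0) > 0]
  sel_y <- rownames(model$loadings_y)[rowSums(model$loadings_y != 0) > 0]
  Xs <- as.matrix(X)[, sel_x, drop = FALSE]
  Ys <- as.matrix(Y)[, sel_y, drop = FALSE]
  okx <- apply(Xs, 2, sd) > 0
  oky <- apply(Ys, 2, sd) > 0
  if (any(!okx) || any(!oky)) {
    message("skipping ", sum(!okx) + sum(!oky), " zero-variance feature(s)")
  }
  pc <- cor(Xs[, okx, drop = FALSE], Ys[, oky, drop = FALSE])
  structure(
    list(component_r = comp_r, pair_cor = pc,
         negative_fraction = mean(pc < 0), n_pairs = length(pc)),
    class = "spls_correlation"
  )
}

#' @export
print.spls_correlation <- function(x, ...) {
  cat(sprintf("sPLS: component score correlations %s; %.0f%% of %d feature pairs negative\n",
              paste(sprintf("%.2f", x$component_r), collapse = ", "),
              100 * x$negative_fraction, x$n_pairs))
  invisible(x)
}

#' Select the top features by FDR rank for sPLS input
#'
#' Mirrors the "top N by significance" pre-selection used upstream of sPLS:
#' features are ordered by adjusted p-value and the first `n` kept.
#'
#' @param result a `deg_result` or `das_result` data.frame with an `fdr`
#'   column and a feature identifier in the first column.
#' @param n number of features to keep (default 500).
#' @return character vector of feature ids.
#' @export
top_features <- function(result, n = 500L) {
  ord <- order(result$fdr, result$p)
  head(result[[1]][ord], n)
}
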