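# Expression quantification and negative-binomial differential expression.
# The NB GLM engine (log link, library-size offsets, TMM normalization,
# likelihood-ratio tests, tagwise dispersion shrunk toward a common value)
# is implemented here; vectorized Newton updates across genes keep the
# per-gene fits fast.

#' Transcripts per million
#'
#' TPM divides each count by gene length in kb and rescales every sample to
#' sum to one million.
#'
#' @param counts gene x sample count matrix.
#' @param lengths named vector of gene lengths in bp (must cover all genes,
#'   all positive).
#' @return TPM matrix; all-zero samples stay all-zero and are reported.
#' @export
compute_tpm <- function(counts, lengths) {
  lengths <- lengths[rownames(counts)]
  assert_that(!anyNA(lengths), "lengths must cover all genes")
  if (any(lengths <= 0)) stop2("zero or negative gene length")
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    message("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, `/`) * 1e6
}

#' Remove weakly expressed genes by a counts-per-million rule
#'
#' Retains genes with CPM >= `min_cpm` in at least `min_samples` samples.
#'
#' @param counts gene x sample count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples passing (default 3).
#' @return filtered count matrix; attribute `n_removed`.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 3L) {
  assert_that(min_cpm >= 0 && min_samples >= 0, "thresholds must be >= 0")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Standard TMM: relative to a reference sample (the one whose upper
#' quartile is closest to the mean upper quartile), log ratios (M) are
#' trimmed by 30% and abundances (A) by 5%, and the factor is the
#' inverse-variance-weighted mean of the remaining M values. Factors are
#' rescaled to a geometric mean of one.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of normalization factors per sample.
#' @export
tmm_factors <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    y <- counts[, j]; r <- counts[, ref]
    ok <- y > 0 & r > 0
    y <- y[ok]; r <- r[ok]
    if (!length(y)) return(1)
    m <- log2((y / lib[j]) / (r / lib[ref]))
    a <- 0.5 * log2((y / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - r) / (lib[ref] * r)
    keep <- m >= quantile(m, 0.30) & m <= quantile(m, 0.70) &
      a >= quantile(a, 0.05) & a <= quantile(a, 0.95)
    if (!any(keep)) return(1)
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  f / exp(mean(log(f)))
}

# --- internal NB GLM machinery -------------------------------------------

nb_ll <- function(Y, mu, phi) {
  size <- 1 / pmax(phi, 1e-8)
  rowSums(dnbinom(Y, mu = pmax(mu, 1e-10), size = size, log = TRUE))
}

# Per-group NB means with offsets (separable one-parameter Newton updates,
# vectorized across genes). Returns log-mean matrix B (genes x groups),
# fitted mu, and per-gene log-likelihood.
nb_fit_groupmeans <- function(Y, offsets, group, phi) {
  groups <- unique(group)
  G <- nrow(Y)
  B <- matrix(0, G, length(groups), dimnames = list(rownames(Y), groups))
  mu <- Y * 0
  for (gi in seq_along(groups)) {
    cols <- which(group == groups[gi])
    yg <- Y[, cols, drop = FALSE]
    og <- offsets[cols]
    b <- log((rowSums(yg) + 0.1) / sum(exp(og)))
    for (it in 1:50) {
      mug <- exp(outer(b, og, `+`))
      score <- rowSums((yg - mug) / (1 + phi * mug))
      info <- rowSums(mug / (1 + phi * mug))
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b <- pmin(pmax(b + step, -30), 30)
      if (max(abs(step)) < 1e-10) break
    }
    B[, gi] <- b
    mu[, cols] <- exp(outer(b, og, `+`))
  }
  list(B = B, mu = mu, ll = nb_ll(Y, mu, phi))
}

# Two-parameter NB GLM with arbitrary design rows (used for the mid-parent
# contrast); Fisher scoring vectorized across genes.
nb_fit_design2 <- function(Y, offsets, X, phi) {
  G <- nrow(Y)
  b1 <- log((rowSums(Y) + 0.1) / sum(exp(offsets))) ; b2 <- b1
  for (it in 1:80) {
    eta <- b1 %o% X[, 1] + b2 %o% X[, 2] + matrix(offsets, G, length(offsets), byrow = TRUE)
    mu <- exp(pmin(eta, 30))
    r <- (Y - mu) / (1 + phi * mu)
    w <- mu / (1 + phi * mu)
    s1 <- r %*% X[, 1]; s2 <- r %*% X[, 2]
    i11 <- w %*% (X[, 1]^2); i22 <- w %*% (X[, 2]^2); i12 <- w %*% (X[, 1] * X[, 2])
    det <- pmax(i11 * i22 - i12^2, 1e-12)
    d1 <- (i22 * s1 - i12 * s2) / det
    d2 <- (i11 * s2 - i12 * s1) / det
    d1 <- pmin(pmax(d1, -5), 5); d2 <- pmin(pmax(d2, -5), 5)
    b1 <- pmin(pmax(b1 + drop(d1), -30), 30)
    b2 <- pmin(pmax(b2 + drop(d2), -30), 30)
    if (max(abs(c(d1, d2))) < 1e-10) break
  }
  eta <- b1 %o% X[, 1] + b2 %o% X[, 2] + matrix(offsets, G, length(offsets), byrow = TRUE)
  mu <- exp(pmin(eta, 30))
  list(b1 = b1, b2 = b2, mu = mu, ll = nb_ll(Y, mu, phi))
}

#' Estimate a common NB dispersion by profile likelihood
#'
#' Maximizes the sum over genes of the NB log-likelihood at the group-wise
#' mean MLEs over a log-spaced dispersion grid refined by golden-section
#' search.
#'
#' @param Y gene x sample count matrix.
#' @param offsets log effective library sizes.
#' @param group grouping factor/vector per sample.
#' @return scalar dispersion phi (variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(Y, offsets, group) {
  prof <- function(lphi) sum(nb_fit_groupmeans(Y, offsets, group, exp(lphi))$ll)
  grid <- log(10^seq(-4, 0.6, length.out = 12))
  vals <- vapply(grid, prof, 0)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  exp(optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum)
}

#' Tagwise dispersions shrunk toward the common value
#'
#' Each gene's dispersion maximizes its own profile likelihood plus
#' `prior_weight` times the average profile likelihood of all genes (a
#' weighted-likelihood shrinkage with a fixed prior weight in pseudo-genes),
#' evaluated on a grid around the common dispersion.
#'
#' @param Y gene x sample count matrix.
#' @param offsets log effective library sizes.
#' @param group grouping vector per sample.
#' @param common common dispersion (estimated if NULL).
#' @param prior_weight weight of the shared likelihood, in pseudo-genes
#'   (default 10).
#' @return numeric vector of per-gene dispersions.
#' @export
estimate_tagwise_dispersion <- function(Y, offsets, group, common = NULL,
                                        prior_weight = 10) {
  if (is.null(common)) common <- estimate_common_dispersion(Y, offsets, group)
  grid <- common * 4^seq(-3, 3, length.out = 15)
  llmat <- vapply(grid, function(phi) nb_fit_groupmeans(Y, offsets, group, phi)$ll,
                  numeric(nrow(Y)))
  shared <- colMeans(llmat)
  obj <- llmat + matrix(prior_weight * shared, nrow(Y), length(grid), byrow = TRUE)
  grid[max.col(obj, ties.method = "first")]
}

#' Negative-binomial differential expression between two groups
#'
#' Per gene, an NB GLM with log link and log effective-library-size offsets
#' (TMM-normalized) is fitted with a free mean per group and compared with a
#' single-mean null by likelihood-ratio test (chi-squared, 1 df).
#' Dispersions are tagwise estimates shrunk toward the common dispersion;
#' supplying `dispersion` skips estimation (the documented fallback for
#' designs without replication, flagged in the result).
#'
#' @param counts gene x sample count matrix.
#' @param metadata data.frame with a `sample` column matching the count
#'   columns plus the contrast variable.
#' @param contrast character(3): variable name, test level, reference level;
#'   log2FC is test relative to reference.
#' @param fdr_cutoff,lfc_cutoff call thresholds (defaults 0.01 and 1).
#' @param dispersion optional fixed dispersion (scalar or per-gene).
#' @param prior_weight shrinkage weight for tagwise dispersion (default 10).
#' @param normalize apply TMM factors (default TRUE).
#' @return data.frame of class `deg_result`: gene, log2fc, p, fdr, call
#'   (up/down/ns); attributes `common_dispersion` and `fixed_dispersion`.
#' @export
test_differential_expression <- function(counts, metadata, contrast,
                                         fdr_cutoff = 0.01, lfc_cutoff = 1,
                                         dispersion = NULL, prior_weight = 10,
                                         normalize = TRUE) {
  assert_that(length(contrast) == 3, "contrast must be c(variable, test, reference)")
  var <- contrast[1]
  assert_that(var %in% colnames(metadata), paste0("contrast variable '", var, "' not in metadata"))
  assert_that(all(contrast[2:3] %in% metadata[[var]]),
    "contrast levels absent from metadata")
  meta <- metadata[metadata[[var]] %in% contrast[2:3], , drop = FALSE]
  assert_that(all(meta$sample %in% colnames(counts)), "metadata samples missing from counts")
  Y <- as.matrix(counts[, meta$sample, drop = FALSE])
  group <- ifelse(meta[[var]] == contrast[2], "test", "ref")
  if (is.null(dispersion)) {
    assert_that(min(table(group)) >= 2,
      "need >= 2 replicates per group (or supply a fixed dispersion)")
  }

  lib <- colSums(Y)
  nf <- if (normalize) tmm_factors(Y) else rep(1, ncol(Y))
  offsets <- log(lib * nf)

  nonzero <- rowSums(Y) > 0
  Yn <- Y[nonzero, , drop = FALSE]

  common <- NA_real_
  if (is.null(dispersion)) {
    common <- estimate_common_dispersion(Yn, offsets, group)
    phi <- estimate_tagwise_dispersion(Yn, offsets, group, common, prior_weight)
  } else {
    phi <- rep_len(dispersion, nrow(Yn))
  }

  full <- nb_fit_groupmeans(Yn, offsets, group, phi)
  null <- nb_fit_groupmeans(Yn, offsets, rep("all", ncol(Yn)), phi)
  lrt <- pmax(2 * (full$ll - null$ll), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  log2fc <- (full$B[, "test"] - full$B[, "ref"]) / log(2)

  out <- data.frame(gene = rownames(Y), log2fc = 0, p = 1, fdr = 1,
                    stringsAsFactors = FALSE)
  out$log2fc[nonzero] <- log2fc
  out$p[nonzero] <- p
  out$fdr <- p.adjust(out$p, method = "BH")
  out$call <- ifelse(out$fdr < fdr_cutoff & out$log2fc > lfc_cutoff, "up",
               ifelse(out$fdr < fdr_cutoff & out$log2fc < -lfc_cutoff, "down", "ns"))
  attr(out, "common_dispersion") <- common
  attr(out, "fixed_dispersion") <- !is.null(dispersion)
  class(out) <- c("deg_result", class(out))
  out
}
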