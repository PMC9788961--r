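#' Call presence/absence genotypes from windowed read depth
#'
#' A window is scored present in a sample when its read depth is greater than
#' zero and absent when the depth is exactly zero, treating each line as a
#' haploid genotype for the window. Windows absent in every sample (or
#' present in every sample) are invariant; all-absent windows are dropped
#' here since they carry no marker information, while monomorphic present
#' windows are retained until [filter_maf()] so that the unfiltered table
#' mirrors the raw window grid.
#'
#' @param depths numeric matrix, windows x samples, rownames `chrom:start-end`
#'   (0-based half-open), or the list returned by [simulate_depth_windows()].
#' @param mask optional data.frame (chrom, start, end; 0-based half-open) of
#'   regions to exclude, e.g. repeats; overlapping windows are removed.
#' @param min_sample_mean_depth optional per-sample mean-depth floor; samples
#'   below it are dropped with a message (default off).
#' @return object of class `pav_matrix`: list with `geno` (windows x samples
#'   matrix, 1 = present, 0 = absent), `windows` (coordinates), `maf`
#'   (per-window minor allele frequency on the haploid coding), and
#'   `n_input_windows`.
#' @export
call_pav <- function(depths, mask = NULL, min_sample_mean_depth = NULL) {
  if (is.list(depths) && !is.null(depths$depth)) depths <- depths$depth
  assert_that(is.matrix(depths) && !is.null(rownames(depths)),
    "depth matrix with window rownames required")
  if (any(depths < 0)) stop2("data error: negative read depth encountered")

  if (!is.null(min_sample_mean_depth)) {
    keep_s <- colMeans(depths) >= min_sample_mean_depth
    if (!all(keep_s)) {
      message("dropping ", sum(!keep_s), " sample(s) below the mean-depth floor")
      depths <- depths[, keep_s, drop = FALSE]
    }
  }

  windows <- parse_window_id(rownames(depths))
  if (!is.null(mask) && nrow(mask) > 0) {
    masked <- rep(FALSE, nrow(windows))
    for (i in seq_len(nrow(mask))) {
      masked <- masked | (windows$chrom == mask$chrom[i] &
                          windows$start < mask$end[i] &
                          windows$end > mask$start[i])
    }
    depths <- depths[!masked, , drop = FALSE]
    windows <- windows[!masked, , drop = FALSE]
  }

  geno <- (depths > 0) * 1L
  all_absent_sample <- colSums(geno) == 0
  if (any(all_absent_sample)) {
    message("sample(s) absent at every window: ",
            paste(colnames(geno)[all_absent_sample], collapse = ", "))
  }

  n_input <- nrow(geno)
  keep <- rowSums(geno) > 0  # windows absent in ALL samples are invariant
  geno <- geno[keep, , drop = FALSE]
  windows <- windows[keep, , drop = FALSE]
  rownames(windows) <- NULL

  structure(
    list(geno = geno, windows = windows, maf = pav_maf(geno),
         n_input_windows = n_input),
    class = "pav_matrix"
  )
}

pav_maf <- function(geno) {
  f_absent <- rowMeans(geno == 0)
  pmin(f_absent, 1 - f_absent)
}

#' Filter PAV windows on minor allele frequency
#'
#' Retains windows whose minor allele frequency (haploid coding) is at least
#' `min_maf`; the boundary is inclusive, so with 100 samples and
#' `min_maf = 0.05`, 5 absent calls retain the window and 4 drop it.
#'
#' @param pav a `pav_matrix` from [call_pav()].
#' @param min_maf minimum minor allele frequency in [0, 0.5].
#' @return filtered `pav_matrix`, window order preserved; attribute
#'   `n_before`/`n_after` record the filtering.
#' @export
filter_maf <- function(pav, min_maf = 0.05) {
  assert_that(inherits(pav, "pav_matrix"), "pav_matrix required")
  assert_that(min_maf >= 0 && min_maf <= 0.5, "min_maf must lie in [0, 0.5]")
  keep <- pav$maf >= min_maf
  out <- pav
  out$geno <- pav$geno[keep, , drop = FALSE]
  out$windows <- pav$windows[keep, , drop = FALSE]
  rownames(out$windows) <- NULL
  out$maf <- pav$maf[keep]
  attr(out, "n_before") <- nrow(pav$geno)
  attr(out, "n_after") <- sum(keep)
  out
}

#' Re-encode a PAV genotype matrix
#'
#' The three encodings are bijective images of one another:
#' haploid `{0, 1}` (absent/present), diploid homozygote `{0, 2}` as used in
#' mixed-model association, and signed `{-1, +1}` as used by RR-BLUP.
#'
#' @param pav a `pav_matrix`.
#' @param encoding one of "haploid", "diploid", "signed".
#' @return numeric matrix, windows x samples.
#' @export
pav_encode <- function(pav, encoding = c("haploid", "diploid", "signed")) {
  encoding <- match.arg(encoding)
  g <- pav$geno
  switch(encoding,
    haploid = g,
    diploid = 2 * g,
    signed = 2 * g - 1
  )
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat("pav_matrix:", nrow(x$geno), "windows x", ncol(x$geno), "samples; MAF range [",
      if (nrow(x$geno)) sprintf("%.3f, %.3f", min(x$maf), max(x$maf)) else "-", "]\n")
  invisible(x)
}

#' Summarize a PAV matrix
#'
#' @param object a `pav_matrix`.
#' @param ... unused.
#' @return list: windows before/after invariant-window removal, per-sample
#'   present fraction.
#' @export
summary.pav_matrix <- function(object, ...) {
  list(
    n_input_windows = object$n_input_windows,
    n_windows = nrow(object$geno),
    present_fraction = colMeans(object$geno)
  )
}
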