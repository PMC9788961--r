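#' Simulate windowed read depth with planted absence alleles
#'
#' Emulates the depth-of-coverage signal PAV genotyping works from: the genome
#' is tiled in non-overlapping fixed-width windows and each sample's depth per
#' window is drawn from a negative binomial around a sample-specific mean
#' coverage. At planted PAV loci a random subset of samples carries the
#' absence allele (the window is deleted from their genome) and their depth is
#' exactly zero. A small dropout process additionally zeroes truly present
#' windows, mimicking regions missed by chance at modest coverage.
#'
#' @param config a [sim_config()] object.
#' @return list with
#'   \item{depth}{integer matrix, windows x samples, rownames `chrom:start-end`
#'     (0-based half-open), colnames sample ids;}
#'   \item{windows}{data.frame of window coordinates;}
#'   \item{sample_mean_depth}{named vector of the per-sample mean coverage
#'     used (the depth covariate downstream);}
#'   \item{truth}{list: `pav_loci` data.frame (window_id, absent_freq,
#'     n_carriers) and `absent` logical matrix loci x samples (TRUE = absence
#'     allele carried).}
#' @export
simulate_depth_windows <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_win_per_chrom <- config$chrom_length_bp %/% config$window_bp
  n_windows <- n_win_per_chrom * config$n_chromosomes
  assert_that(n_windows > 0 && config$n_samples > 0,
    "configuration error: need at least one window and one sample")
  assert_that(config$n_pav_loci <= n_windows,
    "configuration error: more PAV loci than windows")

  chrom <- rep(sprintf("chr%02d", seq_len(config$n_chromosomes)), each = n_win_per_chrom)
  start <- rep.int(seq(0L, config$chrom_length_bp - config$window_bp, by = config$window_bp),
                   config$n_chromosomes)
  windows <- data.frame(chrom = chrom, start = start, end = start + config$window_bp,
                        stringsAsFactors = FALSE)
  wid <- window_id(windows$chrom, windows$start, windows$end)
  samples <- sprintf("S%03d", seq_len(config$n_samples))

  mean_depth <- runif(config$n_samples, config$mean_depth_range[1], config$mean_depth_range[2])
  names(mean_depth) <- samples

  # NB with phi parameterization: size = 1/phi; phi -> 0 recovers Poisson.
  mu <- matrix(rep(mean_depth, each = n_windows), nrow = n_windows)
  depth <- if (config$depth_dispersion > 0) {
    matrix(rnbinom(n_windows * config$n_samples, mu = mu, size = 1 / config$depth_dispersion),
           nrow = n_windows)
  } else {
    matrix(rpois(n_windows * config$n_samples, lambda = mu), nrow = n_windows)
  }
  dimnames(depth) <- list(wid, samples)

  pav_idx <- sort(sample.int(n_windows, config$n_pav_loci))
  absent_freq <- runif(config$n_pav_loci, config$pav_absent_freq_range[1],
                       config$pav_absent_freq_range[2])
  absent <- matrix(FALSE, config$n_pav_loci, config$n_samples,
                   dimnames = list(wid[pav_idx], samples))
  for (i in seq_len(config$n_pav_loci)) {
    absent[i, ] <- runif(config$n_samples) < absent_freq[i]
    depth[pav_idx[i], absent[i, ]] <- 0L
  }

  if (config$dropout > 0) {
    present <- depth > 0
    drop <- present & matrix(runif(length(depth)) < config$dropout, nrow = n_windows)
    depth[drop] <- 0L
  }

  list(
    depth = depth,
    windows = windows,
    sample_mean_depth = mean_depth,
    truth = list(
      pav_loci = data.frame(
        window_id = wid[pav_idx],
        absent_freq = absent_freq,
        n_carriers = rowSums(absent),
        stringsAsFactors = FALSE
      ),
      absent = absent
    )
  )
}
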