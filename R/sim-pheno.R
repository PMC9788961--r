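#' Simulate phenotypes driven by presence/absence alleles
#'
#' Plants the directional architecture the association stage is designed to
#' detect: a subset of PAV loci is causal, the presence allele (coded +1, the
#' absence allele -1) carries a signed effect, and the trait is the sum of
#' genetic values plus Gaussian noise scaled to hit a target heritability.
#' Two traits are emitted: `heterotic`, where the fraction of causal loci
#' whose presence allele increases the trait is `config$frac_presence_positive`,
#' and `neutral`, where that fraction is 0.5 (the random expectation).
#'
#' @param pav a `pav_matrix` (see [call_pav()]) covering the planted loci, or
#'   the list returned by [simulate_depth_windows()] (its truth is used
#'   directly).
#' @param truth truth list from [simulate_depth_windows()]; ignored when
#'   `pav` is the simulation output itself.
#' @param config a [sim_config()] object.
#' @return list with
#'   \item{phenotypes}{data.frame: sample, heterotic, neutral;}
#'   \item{truth}{data.frame of causal loci (window_id, trait, effect) plus
#'     attribute `realized_h2` (named vector per trait).}
#' @export
simulate_phenotypes <- function(pav, truth = NULL, config) {
  validate_sim_config(config)
  assert_that(config$heritability >= 0 && config$heritability < 1,
    "configuration error: heritability must lie in [0, 1)")
  if (is.null(truth) && !is.null(pav$truth)) truth <- pav$truth
  assert_that(!is.null(truth$absent), "truth set with carrier matrix required")

  # Signed coding from the planted carrier state: presence +1, absence -1.
  z <- 1 - 2 * t(truth$absent) # samples x loci
  samples <- rownames(z)
  n_loci <- ncol(z)
  assert_that(config$n_causal_pavs <= n_loci,
    "configuration error: more causal PAVs than planted loci")

  set.seed(config$seed + 1L)
  traits <- c(heterotic = config$frac_presence_positive, neutral = 0.5)
  pheno <- data.frame(sample = samples, stringsAsFactors = FALSE)
  causal <- list()
  realized_h2 <- numeric(0)
  for (tr in names(traits)) {
    idx <- sort(sample.int(n_loci, config$n_causal_pavs))
    sign_pos <- rbinom(config$n_causal_pavs, 1, traits[[tr]]) == 1
    eff <- abs(rnorm(config$n_causal_pavs, 0, config$effect_size_sd)) * ifelse(sign_pos, 1, -1)
    g <- drop(z[, idx, drop = FALSE] %*% eff)
    var_g <- var(g)
    h2 <- config$heritability
    noise_sd <- if (h2 > 0 && var_g > 0) sqrt(var_g * (1 - h2) / h2) else 1
    e <- rnorm(length(g), 0, noise_sd)
    y <- if (h2 > 0) g + e else e
    pheno[[tr]] <- y
    causal[[tr]] <- data.frame(
      window_id = colnames(z)[idx], trait = tr, effect = eff,
      stringsAsFactors = FALSE
    )
    realized_h2[tr] <- if (h2 > 0) var(g) / var(y) else 0
  }
  truth_df <- do.call(rbind, causal)
  rownames(truth_df) <- NULL
  attr(truth_df, "realized_h2") <- realized_h2
  list(phenotypes = pheno, truth = truth_df)
}
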