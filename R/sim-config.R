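#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data generators.
#' Defaults emulate the study design the pipeline targets: a diversity panel
#' of 288 cultivated sunflower lines resequenced at 5-25x depth and genotyped
#' for presence/absence variation in 100-bp windows, plus a parent/hybrid
#' transcriptome experiment (two parents and their F1, two watering
#' conditions, three replicates each) with negative-binomial counts.
#'
#' @param seed integer seed recorded in the config; generators call
#'   `set.seed(seed)` so the same config yields bit-identical data.
#' @param n_samples number of lines in the diversity panel.
#' @param n_chromosomes,chrom_length_bp genome shape for the window grid.
#' @param window_bp window width in bp (100, matching depth-based PAV calling).
#' @param n_pav_loci number of windows carrying a planted absence allele.
#' @param pav_absent_freq_range range the per-locus absence-allele frequency
#'   is drawn from (uniform).
#' @param n_causal_pavs number of PAV loci given a phenotypic effect.
#' @param frac_presence_positive fraction of causal loci whose presence allele
#'   increases the trait; near 1 for a heterosis-like trait, 0.5 for a
#'   direction-neutral trait.
#' @param effect_size_sd standard deviation of causal effect magnitudes
#'   (trait units per allele unit).
#' @param heritability narrow-sense heritability targeted by the phenotype
#'   generator, in [0, 1).
#' @param mean_depth_range per-sample mean sequencing depth range (uniform).
#' @param depth_dispersion negative-binomial dispersion (phi, so variance =
#'   mu + phi mu^2) of window depths; overdispersed coverage stresses the
#'   depth-covariate correction downstream.
#' @param dropout fraction of truly present windows zeroed at random, the
#'   "missed by chance" genotyping noise.
#' @param n_genes number of genes in the transcriptome simulation.
#' @param n_replicates_per_group RNA-seq replicates per genotype x condition.
#' @param nb_dispersion negative-binomial dispersion of counts (default
#'   0.02, a biological CV of ~14%, typical of replicated inbred lines
#'   under controlled conditions).
#' @param n_complementation_genes genes planted as true PAV complementation
#'   (present and expressed in one parent and the hybrid, missing from the
#'   other genome), split evenly between the two parental genomes.
#' @param n_spe_silent genes expressed in a single parent and the hybrid but
#'   present in both genomes (expression-only SPE); these must be rejected by
#'   homology confirmation.
#' @param n_overdominant,n_underdominant,n_dominant genes planted in each
#'   non-additive inheritance class.
#' @param dominance_fold fold-change used when planting inheritance classes
#'   (hybrid above/below the parental range, or parents 2x apart).
#' @param n_deg_genes,deg_log2fc genes differentially expressed between
#'   conditions and their log2 fold change.
#' @param n_as_events number of alternative-splicing events with per-sample
#'   alt/constitutive read counts.
#' @param psi_base_range range of baseline percent-spliced-index values.
#' @param n_das_events events whose PSI shifts between conditions.
#' @param das_log2fc log2 fold change of PSI planted at DAS events.
#' @param as_mean_reads mean total (alt + constitutive) reads per event and
#'   sample.
#'
#' @return a list of class `sim_config` with validated fields.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 288L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 100000L,
                       window_bp = 100L,
                       n_pav_loci = 200L,
                       pav_absent_freq_range = c(0.05, 0.5),
                       n_causal_pavs = 50L,
                       frac_presence_positive = 0.7,
                       effect_size_sd = 1,
                       heritability = 0.5,
                       mean_depth_range = c(5, 25),
                       depth_dispersion = 0.2,
                       dropout = 0.005,
                       n_genes = 2000L,
                       n_replicates_per_group = 3L,
                       nb_dispersion = 0.02,
                       n_complementation_genes = 40L,
                       n_spe_silent = 10L,
                       n_overdominant = 30L,
                       n_underdominant = 30L,
                       n_dominant = 30L,
                       dominance_fold = 2,
                       n_deg_genes = 200L,
                       deg_log2fc = 2,
                       n_as_events = 500L,
                       psi_base_range = c(0.05, 0.5),
                       n_das_events = 50L,
                       das_log2fc = 1,
                       as_mean_reads = 100) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    window_bp = as.integer(window_bp),
    n_pav_loci = as.integer(n_pav_loci),
    pav_absent_freq_range = as.numeric(pav_absent_freq_range),
    n_causal_pavs = as.integer(n_causal_pavs),
    frac_presence_positive = frac_presence_positive,
    effect_size_sd = effect_size_sd,
    heritability = heritability,
    mean_depth_range = as.numeric(mean_depth_range),
    depth_dispersion = depth_dispersion,
    dropout = dropout,
    n_genes = as.integer(n_genes),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    nb_dispersion = nb_dispersion,
    n_complementation_genes = as.integer(n_complementation_genes),
    n_spe_silent = as.integer(n_spe_silent),
    n_overdominant = as.integer(n_overdominant),
    n_underdominant = as.integer(n_underdominant),
    n_dominant = as.integer(n_dominant),
    dominance_fold = dominance_fold,
    n_deg_genes = as.integer(n_deg_genes),
    deg_log2fc = deg_log2fc,
    n_as_events = as.integer(n_as_events),
    psi_base_range = as.numeric(psi_base_range),
    n_das_events = as.integer(n_das_events),
    das_log2fc = das_log2fc,
    as_mean_reads = as_mean_reads
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(
    "n_samples", "n_chromosomes", "n_pav_loci", "n_causal_pavs", "n_genes",
    "n_replicates_per_group", "n_complementation_genes", "n_spe_silent",
    "n_overdominant", "n_underdominant", "n_dominant", "n_deg_genes",
    "n_as_events", "n_das_events"
  )
  for (f in counts) {
    assert_that(cfg[[f]] >= 0L, paste0("configuration error: ", f, " must be >= 0"))
  }
  assert_that(cfg$n_samples >= 1L, "configuration error: n_samples must be >= 1")
  assert_that(cfg$n_chromosomes >= 1L && cfg$chrom_length_bp >= cfg$window_bp,
    "configuration error: genome must contain at least one window")
  assert_that(cfg$chrom_length_bp %% cfg$window_bp == 0L,
    "configuration error: window_bp must divide chrom_length_bp")
  props <- list(
    cfg$pav_absent_freq_range, cfg$frac_presence_positive,
    cfg$heritability, cfg$dropout, cfg$psi_base_range
  )
  for (p in props) {
    assert_that(all(p >= 0 & p <= 1), "configuration error: proportions must lie in [0, 1]")
  }
  assert_that(cfg$heritability < 1, "configuration error: heritability must be < 1")
  assert_that(all(cfg$mean_depth_range > 0), "configuration error: mean depth must be positive")
  assert_that(cfg$nb_dispersion >= 0 && cfg$depth_dispersion >= 0,
    "configuration error: dispersions must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,",
      x$n_chromosomes, "chromosome(s) x", x$chrom_length_bp, "bp,",
      x$n_pav_loci, "PAV loci,", x$n_genes, "genes\n")
  invisible(x)
}
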