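#' Simulate parent/hybrid RNA-seq counts and splicing with planted truth
#'
#' Generates the transcriptome side of the study design: three genotype
#' groups (parentA, parentB and their F1 hybrid) under two watering
#' conditions (control, FTSW 1.0; drought, FTSW 0.1) with
#' `n_replicates_per_group` replicates each. Gene counts are negative
#' binomial around group-by-condition means; splicing events receive
#' alt/constitutive read pairs binomially split at a planted percent spliced
#' index (PSI).
#'
#' Planted structure (disjoint gene sets, recorded in the truth set):
#' \itemize{
#'   \item complementation genes hosted by one parental genome: expressed in
#'     the host parent and the hybrid, physically missing from the other
#'     genome, so their counts on the host annotation are zero for the other
#'     parent;
#'   \item expression-only single-parent-expressed genes: the same expression
#'     pattern but the gene is present in both genomes (these must be
#'     rejected by homology confirmation);
#'   \item over-/under-dominant genes: hybrid mean above/below both parents
#'     by `dominance_fold`; dominant genes: parents `dominance_fold` apart
#'     with the hybrid at one parent's level;
#'   \item differentially expressed genes: condition effect of
#'     `deg_log2fc` log2 units, half up- and half down-regulated;
#'   \item differentially spliced events: PSI scaled by `2^das_log2fc` under
#'     drought.
#' }
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts_a`, `counts_b` (gene x sample count
#'   matrices on the two parental annotations), `gene_lengths_a`,
#'   `gene_lengths_b` (bp), `metadata` (sample, genotype_group, condition,
#'   FTSW, replicate), `as_counts` (event_id, sample, alt_count,
#'   const_count), and `truth` (complementation, inheritance, deg, das).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  assert_that(config$n_replicates_per_group >= 1L,
    "configuration error: n_replicates_per_group must be >= 1")
  set.seed(config$seed + 2L)

  groups <- c("parentA", "parentB", "hybrid")
  conditions <- c(control = 1.0, drought = 0.1)
  meta <- expand.grid(
    replicate = seq_len(config$n_replicates_per_group),
    condition = names(conditions),
    genotype_group = groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  meta$FTSW <- conditions[meta$condition]
  meta$sample <- sprintf("%s_%s_r%d", meta$genotype_group, meta$condition, meta$replicate)
  meta <- meta[, c("sample", "genotype_group", "condition", "FTSW", "replicate")]
  n_s <- nrow(meta)

  n_comp_a <- config$n_complementation_genes %/% 2L
  n_comp_b <- config$n_complementation_genes - n_comp_a
  n_spe_a <- config$n_spe_silent %/% 2L
  n_spe_b <- config$n_spe_silent - n_spe_a
  n_shared <- config$n_genes - n_comp_a - n_spe_a
  n_planted <- config$n_overdominant + config$n_underdominant + config$n_dominant +
    config$n_deg_genes
  assert_that(n_shared > n_planted,
    "configuration error: n_genes too small for the planted classes")

  shared_ids <- sprintf("gene%05d", seq_len(n_shared))
  comp_a_ids <- sprintf("geneA_pav%03d", seq_len(n_comp_a))
  comp_b_ids <- sprintf("geneB_pav%03d", seq_len(n_comp_b))
  spe_a_ids <- if (n_spe_a > 0) sprintf("geneA_spe%03d", seq_len(n_spe_a)) else character(0)
  spe_b_ids <- if (n_spe_b > 0) sprintf("geneB_spe%03d", seq_len(n_spe_b)) else character(0)

  pick <- sample.int(n_shared, n_planted)
  splits <- rep(c("over", "under", "dom", "deg"),
                c(config$n_overdominant, config$n_underdominant, config$n_dominant,
                  config$n_deg_genes))
  over_ids <- shared_ids[pick[splits == "over"]]
  under_ids <- shared_ids[pick[splits == "under"]]
  dom_ids <- shared_ids[pick[splits == "dom"]]
  deg_ids <- shared_ids[pick[splits == "deg"]]

  base_mean <- stats::rlnorm(n_shared, meanlog = log(50), sdlog = 1)
  names(base_mean) <- shared_ids
  base_mean[c(over_ids, under_ids, dom_ids, deg_ids)] <- 100

  fold <- config$dominance_fold
  # group x condition mean per gene, genome A annotation
  mean_for <- function(gene, group, condition) {
    mu <- base_mean[gene]
    if (gene %in% over_ids && group == "hybrid") mu <- mu * fold
    if (gene %in% under_ids && group == "hybrid") mu <- mu / fold
    if (gene %in% dom_ids) {
      # stable per-gene choice of high parent; hybrid matches the high parent
      high <- if (dom_high_parent[gene]) "parentA" else "parentB"
      if (group == high || group == "hybrid") mu <- mu * fold
    }
    if (gene %in% deg_ids && condition == "drought") {
      mu <- mu * 2^(deg_sign[gene] * config$deg_log2fc)
    }
    mu
  }
  dom_high_parent <- setNames(sample(c(TRUE, FALSE), length(dom_ids), TRUE), dom_ids)
  deg_sign <- setNames(rep_len(c(1, -1), length(deg_ids)), deg_ids)

  draw_counts <- function(gene_ids, mu_matrix) {
    if (!length(gene_ids)) {
      return(matrix(0L, 0L, n_s, dimnames = list(character(0), meta$sample)))
    }
    lib_factor <- runif(n_s, 0.8, 1.25)
    mu <- sweep(mu_matrix, 2, lib_factor, `*`)
    draws <- if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(length(mu), lambda = mu)
    }
    matrix(draws, nrow = nrow(mu), ncol = n_s,
           dimnames = list(gene_ids, meta$sample))
  }

  build_mu <- function(gene_ids, host = NULL) {
    mu <- matrix(0, length(gene_ids), n_s, dimnames = list(gene_ids, meta$sample))
    for (j in seq_len(n_s)) {
      grp <- meta$genotype_group[j]
      cond <- meta$condition[j]
      for (g in gene_ids) {
        if (!is.null(host)) {
          # single-parent-expressed: silent in the non-host parent
          other <- if (host == "A") "parentB" else "parentA"
          mu[g, j] <- if (grp == other) 0 else 100
        } else {
          mu[g, j] <- mean_for(g, grp, cond)
        }
      }
    }
    mu
  }

  mu_shared <- build_mu(shared_ids)
  counts_a <- rbind(
    draw_counts(shared_ids, mu_shared),
    draw_counts(comp_a_ids, build_mu(comp_a_ids, host = "A")),
    draw_counts(spe_a_ids, build_mu(spe_a_ids, host = "A"))
  )
  counts_b <- rbind(
    draw_counts(shared_ids, mu_shared),
    draw_counts(comp_b_ids, build_mu(comp_b_ids, host = "B")),
    draw_counts(spe_b_ids, build_mu(spe_b_ids, host = "B"))
  )

  gene_lengths_a <- setNames(sample(500:3000, nrow(counts_a), TRUE), rownames(counts_a))
  gene_lengths_b <- setNames(sample(500:3000, nrow(counts_b), TRUE), rownames(counts_b))

  # splicing events
  ev_ids <- sprintf("event%04d", seq_len(config$n_as_events))
  psi_base <- runif(config$n_as_events, config$psi_base_range[1], config$psi_base_range[2])
  names(psi_base) <- ev_ids
  das_ids <- if (config$n_das_events > 0) {
    sample(ev_ids, min(config$n_das_events, config$n_as_events))
  } else character(0)
  psi_drought <- psi_base
  psi_drought[das_ids] <- pmin(0.95, psi_base[das_ids] * 2^config$das_log2fc)

  as_counts <- expand.grid(event_id = ev_ids, sample = meta$sample,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cond_of <- setNames(meta$condition, meta$sample)
  psi_use <- ifelse(cond_of[as_counts$sample] == "drought",
                    psi_drought[as_counts$event_id], psi_base[as_counts$event_id])
  total <- rpois(nrow(as_counts), config$as_mean_reads)
  alt <- rbinom(nrow(as_counts), total, psi_use)
  as_counts$alt_count <- alt
  as_counts$const_count <- total - alt

  truth <- list(
    complementation = data.frame(
      gene_id = c(comp_a_ids, spe_a_ids, comp_b_ids, spe_b_ids),
      host_genome = c(rep("A", n_comp_a + n_spe_a), rep("B", n_comp_b + n_spe_b)),
      class = c(rep("pav_complementation", n_comp_a), rep("expression_only", n_spe_a),
                rep("pav_complementation", n_comp_b), rep("expression_only", n_spe_b)),
      stringsAsFactors = FALSE
    ),
    inheritance = data.frame(
      gene_id = c(over_ids, under_ids, dom_ids),
      category = c(rep("over_dominant", length(over_ids)),
                   rep("under_dominant", length(under_ids)),
                   ifelse(dom_high_parent[dom_ids], "dominant_high", "dominant_high")),
      high_parent = c(rep(NA, length(over_ids) + length(under_ids)),
                      ifelse(dom_high_parent[dom_ids], "parentA", "parentB")),
      stringsAsFactors = FALSE
    ),
    deg = data.frame(gene_id = deg_ids,
                     direction = ifelse(deg_sign[deg_ids] > 0, "up", "down"),
                     stringsAsFactors = FALSE),
    das = data.frame(event_id = das_ids,
                     direction = rep(if (config$das_log2fc >= 0) "up" else "down",
                                     length(das_ids)),
                     psi_control = unname(psi_base[das_ids]),
                     psi_drought = unname(psi_drought[das_ids]),
                     stringsAsFactors = FALSE)
  )

  list(counts_a = counts_a, counts_b = counts_b,
       gene_lengths_a = gene_lengths_a, gene_lengths_b = gene_lengths_b,
       metadata = meta, as_counts = as_counts, truth = truth)
}
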