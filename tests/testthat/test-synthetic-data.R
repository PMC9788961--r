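test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(chrom_length_bp = 1050, window_bp = 100), "divide")
  expect_error(sim_config(heritability = 1), "heritability")
  expect_error(sim_config(pav_absent_freq_range = c(-0.1, 0.5)), "proportions")
  expect_error(simulate_counts(sim_config(n_replicates_per_group = 0)),
               "n_replicates_per_group")
})

test_that("same seed gives bit-identical outputs", {
  cfg <- sim_config(seed = 42, n_samples = 30, chrom_length_bp = 5000,
                    n_pav_loci = 20, n_causal_pavs = 10, n_genes = 60, n_complementation_genes = 4,
                    n_spe_silent = 2, n_overdominant = 2, n_underdominant = 2,
                    n_dominant = 2, n_deg_genes = 5, n_as_events = 20,
                    n_das_events = 4)
  d1 <- simulate_depth_windows(cfg); d2 <- simulate_depth_windows(cfg)
  expect_identical(d1, d2)
  p1 <- simulate_phenotypes(d1, config = cfg)
  p2 <- simulate_phenotypes(d2, config = cfg)
  expect_identical(p1, p2)
  c1 <- simulate_counts(cfg); c2 <- simulate_counts(cfg)
  expect_identical(c1, c2)
})

test_that("planted truth ids exist in the emitted data", {
  cfg <- sim_config(seed = 3, n_samples = 40, chrom_length_bp = 10000,
                    n_pav_loci = 40, n_causal_pavs = 15, n_genes = 120,
                    n_complementation_genes = 8, n_spe_silent = 4,
                    n_overdominant = 5, n_underdominant = 5, n_dominant = 5,
                    n_deg_genes = 10, n_as_events = 40, n_das_events = 8)
  d <- simulate_depth_windows(cfg)
  expect_true(all(d$truth$pav_loci$window_id %in% rownames(d$depth)))
  ph <- simulate_phenotypes(d, config = cfg)
  expect_true(all(ph$truth$window_id %in% d$truth$pav_loci$window_id))
  expect_true(all(ph$truth$effect != 0))
  cs <- simulate_counts(cfg)
  ids <- union(rownames(cs$counts_a), rownames(cs$counts_b))
  expect_true(all(cs$truth$complementation$gene_id %in% ids))
  expect_true(all(cs$truth$inheritance$gene_id %in% rownames(cs$counts_a)))
  expect_true(all(cs$truth$deg$gene_id %in% rownames(cs$counts_a)))
  expect_true(all(cs$truth$das$event_id %in% cs$as_counts$event_id))
})

test_that("depth generator plants absence alleles at the requested frequencies", {
  cfg <- sim_config(seed = 9, n_samples = 200, chrom_length_bp = 20000,
                    n_pav_loci = 60, dropout = 0)
  d <- simulate_depth_windows(cfg)
  # carriers have depth exactly zero
  for (i in seq_len(10)) {
    wid <- d$truth$pav_loci$window_id[i]
    expect_true(all(d$depth[wid, d$truth$absent[wid, ]] == 0))
  }
  # marginal frequencies within 3 binomial SE of the requested values
  freq <- d$truth$pav_loci$absent_freq
  obs <- rowMeans(d$truth$absent)
  se <- sqrt(freq * (1 - freq) / cfg$n_samples)
  expect_true(all(abs(obs - freq) <= 3 * se + 1e-12))
  # no planted loci, no dropout -> every window variable only by chance zeros
  cfg0 <- sim_config(seed = 10, n_samples = 20, chrom_length_bp = 5000,
                     n_pav_loci = 0, dropout = 0, mean_depth_range = c(30, 40))
  d0 <- simulate_depth_windows(cfg0)
  expect_true(mean(d0$depth > 0) > 0.999)
  # window width default is 100 bp
  w <- parse_window_id(rownames(d$depth))
  expect_true(all(w$end - w$start == 100L))
})

test_that("phenotypes hit the target heritability and direction fractions", {
  cfg <- sim_config(seed = 21, n_samples = 300, chrom_length_bp = 30000,
                    n_pav_loci = 120, n_causal_pavs = 50, heritability = 0.6,
                    dropout = 0)
  d <- simulate_depth_windows(cfg)
  ph <- simulate_phenotypes(d, config = cfg)
  h2 <- attr(ph$truth, "realized_h2")
  expect_true(all(abs(h2 - 0.6) < 0.1))
  # neutral trait plants positive directions at ~0.5
  neu <- ph$truth[ph$truth$trait == "neutral", ]
  expect_gt(mean(neu$effect > 0), 0.3)
  expect_lt(mean(neu$effect > 0), 0.7)
  # h2 = 0 -> trait independent of genotype
  cfg0 <- sim_config(seed = 22, n_samples = 200, chrom_length_bp = 20000,
                     n_pav_loci = 60, n_causal_pavs = 30, heritability = 0)
  d0 <- simulate_depth_windows(cfg0)
  ph0 <- simulate_phenotypes(d0, config = cfg0)
  z <- 1 - 2 * t(d0$truth$absent)
  cors <- abs(cor(ph0$phenotypes$heterotic, z))
  expect_lt(mean(cors), 3 / sqrt(cfg0$n_samples))
})

test_that("count generator plants complementation, DAS shift, and Poisson limit", {
  cfg <- sim_config(seed = 31, n_genes = 200, n_complementation_genes = 10,
                    n_spe_silent = 4, n_overdominant = 5, n_underdominant = 5,
                    n_dominant = 5, n_deg_genes = 10, n_as_events = 100,
                    n_das_events = 20)
  cs <- simulate_counts(cfg)
  # complementation genes hosted on A have ~zero TPM in parentB
  tpm <- compute_tpm(cs$counts_a, cs$gene_lengths_a)
  comp_a <- with(cs$truth$complementation, gene_id[host_genome == "A" &
                                                    class == "pav_complementation"])
  pb <- cs$metadata$sample[cs$metadata$genotype_group == "parentB"]
  expect_true(all(tpm[comp_a, pb] < 0.1))
  # planted DAS events shift empirical PSI by ~ the planted amount
  das <- cs$truth$das
  d <- cs$as_counts
  cond <- setNames(cs$metadata$condition, cs$metadata$sample)
  for (ev in das$event_id[1:5]) {
    sub <- d[d$event_id == ev, ]
    p_c <- with(sub[cond[sub$sample] == "control", ], sum(alt_count) / sum(alt_count + const_count))
    p_d <- with(sub[cond[sub$sample] == "drought", ], sum(alt_count) / sum(alt_count + const_count))
    truth_shift <- das$psi_drought[das$event_id == ev] - das$psi_control[das$event_id == ev]
    expect_lt(abs((p_d - p_c) - truth_shift), 0.15)
  }
  # Monte-Carlo check of the binomial PSI machinery at the stated precision:
  # 200 replicate pairs at PSI 0.2 vs 0.4, 100 reads each
  set.seed(1)
  d1 <- rbinom(200, 100, 0.2) / 100
  d2 <- rbinom(200, 100, 0.4) / 100
  expect_lt(abs(mean(d2 - d1) - 0.2), 0.02)
  # dispersion -> 0 gives Poisson-like variance/mean near 1
  cfg_p <- sim_config(seed = 32, n_genes = 300, nb_dispersion = 0,
                      n_complementation_genes = 0, n_spe_silent = 0,
                      n_overdominant = 0, n_underdominant = 0, n_dominant = 0,
                      n_deg_genes = 0, n_as_events = 10, n_das_events = 0)
  cs_p <- simulate_counts(cfg_p)
  grp <- cs_p$metadata$sample[cs_p$metadata$genotype_group == "parentA" &
                              cs_p$metadata$condition == "control"]
  # remove the per-sample library factor before checking the Poisson ratio
  y <- cs_p$counts_a[, grp]
  sf <- colSums(y) / mean(colSums(y))
  yn <- sweep(y, 2, sf, `/`)
  vm <- apply(yn, 1, var) / pmax(rowMeans(yn), 1)
  expect_lt(median(vm), 1.5)
  # with NB dispersion the same ratio is clearly overdispersed at high means
  y2 <- cs$counts_a[, grp]
  hi <- rowMeans(y2) > 200
  sf2 <- colSums(y2) / mean(colSums(y2))
  yn2 <- sweep(y2, 2, sf2, `/`)
  vm2 <- apply(yn2, 1, var) / pmax(rowMeans(yn2), 1)
  expect_gt(median(vm2[hi]), median(vm))
})
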