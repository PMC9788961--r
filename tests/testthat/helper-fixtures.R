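# Shared fixture builders (all data generated in code).

exdf <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

tx <- function(exons, strand = "+", gene = "g1") {
  list(gene_id = gene, strand = strand, exons = exons)
}

# signed marker matrix with local LD blocks (adjacent windows of one
# deletion are near-identical), samples x markers
block_markers <- function(n, blocks, per_block, discordance = 0.05) {
  B <- matrix(sample(c(-1, 1), n * blocks, TRUE), n, blocks)
  Z <- B[, rep(seq_len(blocks), each = per_block)]
  flip <- matrix(runif(length(Z)) < discordance, nrow = n)
  Z[flip] <- -Z[flip]
  colnames(Z) <- sprintf("w%04d", seq_len(ncol(Z)))
  Z
}

# trait with exact heritability partition from a signed marker matrix
trait_from_markers <- function(Z, h2, n_causal = ncol(Z)) {
  idx <- sample.int(ncol(Z), n_causal)
  g <- rnorm(n_causal)
  gv <- drop(Z[, idx, drop = FALSE] %*% g)
  if (h2 == 0) return(rnorm(nrow(Z)))
  gv <- gv / sd(gv) * sqrt(h2)
  gv + rnorm(nrow(Z), 0, sqrt(1 - h2))
}

# two-condition count matrix with planted fold changes
counts_two_groups <- function(n_genes, n_de, lfc, n_rep = 3, mean_count = 100,
                              dispersion = 0.1) {
  mu <- matrix(mean_count, n_genes, 2 * n_rep)
  lvec <- rep(0, n_genes)
  if (n_de > 0) lvec[seq_len(n_de)] <- rep_len(c(lfc, -lfc), n_de)
  mu[, n_rep + seq_len(n_rep)] <- mu[, n_rep + seq_len(n_rep)] * 2^lvec
  Y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_genes)
  rownames(Y) <- sprintf("g%05d", seq_len(n_genes))
  colnames(Y) <- sprintf("s%d", seq_len(ncol(Y)))
  meta <- data.frame(sample = colnames(Y),
                     condition = rep(c("control", "drought"), each = n_rep))
  list(counts = Y, meta = meta, lfc = lvec)
}

# long-format alt/const count table for two conditions
psi_sim <- function(n_events, n_shift, psi1, psi2, n_rep = 3, reads = 100) {
  ev <- sprintf("e%04d", seq_len(n_events))
  samples <- paste0(rep(c("c", "d"), each = n_rep), seq_len(n_rep))
  d <- expand.grid(event_id = ev, sample = samples,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cond <- ifelse(grepl("^c", d$sample), "control", "drought")
  psi <- ifelse(d$event_id %in% ev[seq_len(n_shift)] & cond == "drought", psi2, psi1)
  tot <- rpois(nrow(d), reads)
  d$alt_count <- rbinom(nrow(d), tot, psi)
  d$const_count <- tot - d$alt_count
  meta <- data.frame(sample = samples,
                     condition = ifelse(grepl("^c", samples), "control", "drought"))
  list(psi = d, meta = meta, shifted = ev[seq_len(n_shift)])
}

# parent/parent/hybrid trio counts with planted non-additive genes
trio_counts <- function(n_genes, n_over, n_under, fold = 2, n_rep = 3,
                        mean_count = 100, dispersion = 0.02) {
  groups <- rep(c("parentA", "parentB", "hybrid"), each = n_rep)
  mu <- matrix(mean_count, n_genes, 3 * n_rep)
  hy <- groups == "hybrid"
  if (n_over > 0) mu[seq_len(n_over), hy] <- mean_count * fold
  if (n_under > 0) mu[n_over + seq_len(n_under), hy] <- mean_count / fold
  Y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_genes)
  rownames(Y) <- sprintf("g%04d", seq_len(n_genes))
  colnames(Y) <- paste0(groups, "_r", rep(seq_len(n_rep), 3))
  meta <- data.frame(sample = colnames(Y), genotype_group = groups,
                     condition = "control")
  list(counts = Y, meta = meta,
       over = rownames(Y)[seq_len(n_over)],
       under = rownames(Y)[n_over + seq_len(n_under)])
}

# brute-force NB LRT oracle: 1-D golden-section maximization of each group
# mean (profile likelihood), independent of the package's Newton fits
nb_lrt_oracle <- function(y, group, offsets, phi) {
  prof <- function(y, o) {
    f <- function(lmu) -sum(dnbinom(y, mu = exp(lmu + o), size = 1 / phi, log = TRUE))
    opt <- optimize(f, c(-30, 15))
    -opt$objective
  }
  ll_full <- sum(vapply(unique(group), function(g) {
    prof(y[group == g], offsets[group == g])
  }, 0))
  ll_null <- prof(y, offsets)
  2 * (ll_full - ll_null)
}

# brute-force binomial logistic LRT oracle via grid-refined 1-D likelihood
binom_lrt_oracle <- function(alt, tot, group) {
  llp <- function(a, n, p) sum(dbinom(a, n, p, log = TRUE))
  prof <- function(a, n) {
    f <- function(p) -llp(a, n, p)
    optimize(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$objective * -1
  }
  ll_full <- sum(vapply(unique(group), function(g) {
    prof(alt[group == g], tot[group == g])
  }, 0))
  ll_null <- prof(alt, tot)
  2 * (ll_full - ll_null)
}

# brute-force stop-effect oracle: rebuild and translate the full mutant CDS
stop_oracle <- function(snps, models, genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  count_stop <- function(s) sum(strsplit(s, "")[[1]] == "*")
  res <- list()
  for (m in models) {
    sp <- heteropav:::splice_cds(m$exons, m$strand, genome[[m$chrom]])
    ref_aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(sp$seq), if.fuzzy.codon = "X")))
    for (k in seq_len(nrow(snps))) {
      if (snps$chrom[k] != m$chrom) next
      idx <- match(snps$pos[k] - 1L, sp$pos)
      if (is.na(idx)) next
      mut <- sp$seq
      base <- if (m$strand == "-") comp[[snps$alt[k]]] else snps$alt[k]
      substr(mut, idx, idx) <- base
      mut_aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(mut), if.fuzzy.codon = "X")))
      d <- count_stop(mut_aa) - count_stop(ref_aa)
      if (d != 0) {
        res[[length(res) + 1L]] <- data.frame(
          pos = snps$pos[k], gene = m$gene_id,
          effect = if (d > 0) "stop_gained" else "stop_lost",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(data.frame(pos = integer(0), gene = character(0),
                                      effect = character(0)))
  do.call(rbind, res)
}

# two coupled data blocks driven by one latent factor (coupling = -1 plants
# the anti-correlated relationship between the blocks)
spls_instance <- function(n = 30, p = 40, q = 35, coupling = 1, noise = 0.5,
                          n_signal_x = 20, n_signal_y = 20) {
  n_signal_x <- min(n_signal_x, p)
  n_signal_y <- min(n_signal_y, q)
  f <- rnorm(n)
  X <- matrix(rnorm(n * p, 0, noise), n, p)
  Y <- matrix(rnorm(n * q, 0, noise), n, q)
  X[, seq_len(n_signal_x)] <- X[, seq_len(n_signal_x)] +
    outer(f, runif(n_signal_x, 0.5, 1.5))
  Y[, seq_len(n_signal_y)] <- Y[, seq_len(n_signal_y)] +
    outer(coupling * f, runif(n_signal_y, 0.5, 1.5))
  colnames(X) <- paste0("x", seq_len(p))
  colnames(Y) <- paste0("y", seq_len(q))
  list(X = X, Y = Y)
}
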