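test_that("planted non-additive genes are recovered and categories partition", {
  set.seed(61)
  sim <- trio_counts(300, n_over = 25, n_under = 25, fold = 2)
  ic <- classify_inheritance(sim$counts, sim$meta, "expression")
  cats <- setNames(ic$category, ic$feature)
  expect_gt(mean(cats[sim$over] == "over_dominant"), 0.9)
  expect_gt(mean(cats[sim$under] == "under_dominant"), 0.9)
  null_genes <- setdiff(ic$feature, c(sim$over, sim$under))
  expect_lt(mean(cats[null_genes] != "additive"), 0.05)
  # exhaustive, exclusive partition
  expect_true(all(ic$category %in% c("additive", "dominant_high", "dominant_low",
                                     "over_dominant", "under_dominant",
                                     "unclassified")))
})

test_that("dominance is called at the matching parent's level", {
  set.seed(62)
  n_rep <- 3
  groups <- rep(c("parentA", "parentB", "hybrid"), each = n_rep)
  mu <- matrix(100, 60, 9)
  mu[1:20, groups == "parentA"] <- 200
  mu[1:20, groups == "hybrid"] <- 200   # hybrid tracks the high parent (A)
  mu[21:40, groups == "parentB"] <- 200 # high parent is B, hybrid stays low
  Y <- matrix(rnbinom(length(mu), mu = mu, size = 50), nrow(mu))
  rownames(Y) <- sprintf("g%02d", seq_len(nrow(Y)))
  colnames(Y) <- paste0(groups, "_", rep(1:n_rep, 3))
  meta <- data.frame(sample = colnames(Y), genotype_group = groups,
                     condition = "control")
  ic <- classify_inheritance(Y, meta, "expression")
  cats <- setNames(ic$category, ic$feature)
  expect_gte(mean(cats[sprintf("g%02d", 1:20)] == "dominant_high"), 0.75)
  expect_gte(mean(cats[sprintf("g%02d", 21:40)] == "dominant_low"), 0.75)
  # no calls on the wrong side of the parental range
  expect_false(any(cats[sprintf("g%02d", 1:20)] %in%
                   c("dominant_low", "under_dominant")))
  expect_false(any(cats[sprintf("g%02d", 21:40)] %in%
                   c("dominant_high", "over_dominant")))
})

test_that("swapping parent labels leaves every call unchanged", {
  set.seed(63)
  sim <- trio_counts(120, n_over = 10, n_under = 10, fold = 2)
  ic1 <- classify_inheritance(sim$counts, sim$meta, "expression")
  meta_sw <- sim$meta
  meta_sw$genotype_group <- c(parentA = "parentB", parentB = "parentA",
                              hybrid = "hybrid")[sim$meta$genotype_group]
  ic2 <- classify_inheritance(sim$counts, meta_sw, "expression")
  expect_equal(setNames(ic2$category, ic2$feature)[ic1$feature],
               setNames(ic1$category, ic1$feature))
})

test_that("splicing inheritance recovers planted hybrid PSI shifts", {
  set.seed(64)
  n_rep <- 3
  groups <- rep(c("parentA", "parentB", "hybrid"), each = n_rep)
  samples <- paste0(groups, "_", rep(1:n_rep, 3))
  ev <- sprintf("e%03d", 1:60)
  d <- expand.grid(event_id = ev, sample = samples,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grp <- setNames(groups, samples)[d$sample]
  psi <- rep(0.3, nrow(d))
  psi[d$event_id %in% ev[1:15] & grp == "hybrid"] <- 0.6   # above both parents
  psi[d$event_id %in% ev[16:30] & grp == "hybrid"] <- 0.1  # below both parents
  tot <- rpois(nrow(d), 150)
  d$alt_count <- rbinom(nrow(d), tot, psi)
  d$const_count <- tot - d$alt_count
  meta <- data.frame(sample = samples, genotype_group = groups,
                     condition = "control")
  ic <- classify_inheritance(d, meta, "splicing")
  cats <- setNames(ic$category, ic$feature)
  expect_gt(mean(cats[ev[1:15]] == "over_dominant"), 0.85)
  expect_gt(mean(cats[ev[16:30]] == "under_dominant"), 0.85)
  expect_lt(mean(cats[ev[31:60]] != "additive"), 0.1)
})

test_that("exact rank-sum p-values match independent enumeration", {
  # oracle: enumerate assignments, compute the Mann-Whitney U from direct
  # value comparisons (not ranks)
  u_oracle <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x); n <- length(pooled)
    u_of <- function(idx) {
      a <- pooled[idx]; b <- pooled[-idx]
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    u_obs <- u_of(seq_len(n1))
    us <- apply(combn(n, n1), 2, u_of)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(65)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, TRUE)   # ties likely
    y <- sample(1:6, n2, TRUE)
    expect_equal(heteropav:::rank_sum_exact_p(x, y), u_oracle(x, y),
                 tolerance = 1e-12, info = paste("case", i))
  }
  # tie-free agreement with the textbook exact test
  for (i in 1:6) {
    x <- sample(1:100, 5); y <- sample(101:200, 6)
    expect_equal(heteropav:::rank_sum_exact_p(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("phenotypic heterosis statistics follow their definitions", {
  # 3 vs 3 fully separated: the minimum exact two-sided p is 0.1
  wh <- wilcoxon_heterosis(c(10, 11, 12), c(1, 2, 3), c(2, 3, 4), alpha = 0.15)
  expect_equal(wh$p_vs_parentA, 0.1)
  expect_true(wh$heterotic_above_best)
  # hybrid identical to a parent: p = 1 against it
  wh2 <- wilcoxon_heterosis(c(5, 5, 5), c(5, 5, 5), c(1, 2, 3))
  expect_equal(wh2$p_vs_parentA, 1)
  # mid-parent heterosis arithmetic: F1 12, parents 8 and 10 -> 1/3
  wh3 <- wilcoxon_heterosis(c(12, 12), c(8, 8), c(10, 10))
  expect_equal(wh3$mph, 1 / 3)
  expect_error(wilcoxon_heterosis(1, c(1, 2), c(1, 2)), "replicates")
})
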