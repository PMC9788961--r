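test_that("LD pruning drops correlated neighbours and matches brute force", {
  set.seed(11)
  g1 <- rbinom(60, 1, 0.5)
  geno <- rbind(m1 = g1, m2 = g1, m3 = rbinom(60, 1, 0.5))
  pos <- data.frame(chrom = "c1", pos = c(100, 200, 300))
  keep <- ld_prune(geno, pos, r2_max = 0.2, window_bp = 500000)
  expect_identical(keep, c(TRUE, FALSE, TRUE))  # perfect duplicate dropped
  # independent markers: retained set has no pair above the threshold, and
  # nearly everything survives (checked against exhaustive pairwise r^2)
  m <- 120
  geno2 <- matrix(rbinom(m * 80, 1, 0.4), m, 80)
  pos2 <- data.frame(chrom = "c1", pos = seq_len(m) * 1000)
  keep2 <- ld_prune(geno2, pos2, r2_max = 0.2, window_bp = 500000)
  r2 <- suppressWarnings(cor(t(geno2[keep2, ])))^2
  diag(r2) <- 0
  expect_true(all(r2 <= 0.2 + 1e-12))
  expect_gt(mean(keep2), 0.8)
  # a marker outside the window is never compared
  far <- rbind(m1 = g1, m2 = g1)
  posf <- data.frame(chrom = "c1", pos = c(0, 600000))
  expect_identical(ld_prune(far, posf, 0.2, 500000), c(TRUE, TRUE))
})

test_that("PCA matches a dense eigendecomposition and kinship is IBS", {
  set.seed(12)
  geno <- matrix(rbinom(500 * 50, 1, 0.5), 500, 50,
                 dimnames = list(NULL, sprintf("s%02d", 1:50)))
  pk <- compute_pca_kinship(geno)
  # identical samples have IBS 1 with themselves
  expect_equal(unname(diag(pk$kinship)), rep(1, 50))
  geno_dup <- cbind(geno, s_dup = geno[, 1])
  pk2 <- compute_pca_kinship(geno_dup)
  expect_equal(unname(pk2$kinship["s01", "s_dup"]), 1)
  # PC variance shares equal eigenvalue/trace from a dense eigen oracle
  xc <- scale(t(geno), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)$values
  expect_equal(pk$varprop[1], ev[1] / sum(ev), tolerance = 1e-10)
  # planted subpopulations separate on PC1
  p1 <- matrix(rbinom(300 * 25, 1, 0.9), 300, 25)
  p2 <- matrix(rbinom(300 * 25, 1, 0.1), 300, 25)
  pk3 <- compute_pca_kinship(cbind(p1, p2))
  lab <- rep(c(1, 2), each = 25)
  expect_true(abs(mean(pk3$scores[lab == 1, 1]) - mean(pk3$scores[lab == 2, 1])) >
              2 * (sd(pk3$scores[lab == 1, 1]) + sd(pk3$scores[lab == 2, 1])))
  expect_warning(compute_pca_kinship(rbind(geno, rep(1, 50))), "constant")
})

test_that("REML delta maximizes the restricted likelihood over the grid", {
  set.seed(13)
  n <- 80
  G <- matrix(rbinom(n * 300, 1, 0.3), 300, n)
  pk <- compute_pca_kinship(G, method = "grm")
  L <- t(chol(pk$kinship + diag(1e-6, n)))
  y <- drop(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
  fit <- fit_null_mixed_model(y, matrix(1, n, 1), pk$kinship)
  expect_true(all(fit$loglik >= fit$grid_loglik - 1e-9))
  expect_true(fit$sigma_g2 >= 0 && fit$sigma_e2 >= 0)
  # identity kinship: ridge is flat, flagged unidentifiable
  expect_warning(fit_null_mixed_model(rnorm(n), matrix(1, n, 1), diag(n)),
                 "unidentifiable|boundary")
  expect_error(fit_null_mixed_model(rnorm(n), matrix(1, n, 1), -diag(n)),
               "positive semi-definite")
})

test_that("GLS with identity kinship reproduces plain OLS", {
  set.seed(14)
  n <- 60; m <- 40
  geno <- matrix(sample(c(-1, 1), m * n, TRUE), m, n,
                 dimnames = list(sprintf("w%03d", 1:m), NULL))
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  null <- suppressWarnings(fit_null_mixed_model(y, X, diag(n)))
  res <- score_markers(geno, null)
  for (j in c(1, 10, 25)) {
    ols <- summary(lm(y ~ 0 + X + geno[j, ]))$coefficients
    expect_equal(res$beta[j], ols[3, 1], tolerance = 1e-8)
    expect_equal(res$se[j], ols[3, 2], tolerance = 1e-8)
    expect_equal(res$p[j], ols[3, 4], tolerance = 1e-8)
  }
  # collinear marker (equal to a covariate) is skipped
  geno2 <- rbind(geno, dup = X[, 2])
  expect_message(res2 <- score_markers(geno2, null), "collinear")
  expect_false("dup" %in% res2$marker)
})

test_that("null traits give nominal type-I error", {
  set.seed(15)
  n <- 120; m <- 400
  geno <- matrix(rbinom(m * n, 1, 0.4) * 2 - 1, m, n)
  pk <- compute_pca_kinship(geno)
  y <- rnorm(n)
  null <- suppressWarnings(fit_null_mixed_model(y, matrix(1, n, 1), pk$kinship))
  res <- score_markers(geno, null)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("direction summary handles edge cases and is seed-reproducible", {
  res <- data.frame(marker = sprintf("m%02d", 1:20), chrom = "c1",
                    pos = seq(0, 19) * 2e5,
                    beta = abs(rnorm(20)), se = 1, t = 1,
                    p = c(rep(0.01, 10), rep(0.5, 10)),
                    direction = "positive", stringsAsFactors = FALSE)
  ds <- direction_summary(res, alpha = 0.05, block_bp = 1e6, n_boot = 200, seed = 1)
  expect_equal(ds$prop_positive, 1)
  expect_equal(ds$ci[2], 1)        # all positive: upper CI bound is 1
  expect_true(ds$excludes_half)
  # single block degenerates to the observed proportion in every replicate
  res$pos <- 10
  ds1 <- direction_summary(res, block_bp = 1e9, n_boot = 50, seed = 2)
  expect_equal(ds1$ci, c(1, 1))
  # empty selection is explicit
  res$p <- 0.9
  ds0 <- direction_summary(res)
  expect_equal(ds0$n_selected, 0L)
  expect_true(is.na(ds0$prop_positive))
  # same seed, same CI
  res$p <- runif(20)
  res$direction <- sample(c("positive", "negative"), 20, TRUE)
  res$beta <- ifelse(res$direction == "positive", 1, -1)
  a <- direction_summary(res, n_boot = 300, seed = 7)
  b <- direction_summary(res, n_boot = 300, seed = 7)
  expect_identical(a$ci, b$ci)
})

test_that("bootstrap CI width shrinks with the number of blocks", {
  set.seed(16)
  mk <- function(nblocks) {
    data.frame(marker = seq_len(nblocks), chrom = "c1",
               pos = (seq_len(nblocks) - 1) * 1e6 + 1,
               beta = sample(c(-1, 1), nblocks, TRUE, prob = c(0.3, 0.7)),
               se = 1, t = 1, p = 0.01,
               direction = NA, stringsAsFactors = FALSE) |>
      transform(direction = ifelse(beta > 0, "positive", "negative"))
  }
  w <- vapply(c(25, 400), function(nb) {
    ds <- direction_summary(mk(nb), n_boot = 400, seed = 3)
    diff(ds$ci)
  }, 0)
  expect_lt(w[2], w[1] / 2)  # ~ 1/sqrt(16) narrower
})
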