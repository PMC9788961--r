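test_that("all seven event types are labelled on enumerated structures", {
  con <- tx(exdf(0, 100, 200, 300, 400, 500))
  cases <- list(
    IR = tx(exdf(0, 300, 400, 500)),
    SKIP = tx(exdf(0, 100, 400, 500)),
    ALTA = tx(exdf(0, 100, 250, 300, 400, 500)),  # donor 100 shared, acceptor moves
    ALTD = tx(exdf(0, 90, 200, 300, 400, 500)),   # acceptor 200 shared, donor moves
    ALTP = tx(exdf(0, 90, 250, 300, 400, 500)),
    CRIN = tx(exdf(0, 40, 60, 100, 200, 300, 400, 500)),
    CREX = tx(exdf(0, 100, 140, 160, 200, 300, 400, 500))
  )
  for (type in names(cases)) {
    ev <- classify_events(con, cases[[type]])
    expect_equal(ev$type, type, info = type)
  }
  # minus-strand mirrors: identical coordinates, donor/acceptor roles swap
  con_m <- tx(exdf(0, 100, 200, 300, 400, 500), strand = "-")
  expect_equal(classify_events(con_m, tx(cases$ALTA$exons, strand = "-"))$type, "ALTD")
  expect_equal(classify_events(con_m, tx(cases$ALTD$exons, strand = "-"))$type, "ALTA")
  for (type in c("IR", "SKIP", "ALTP", "CRIN", "CREX")) {
    expect_equal(classify_events(con_m, tx(cases[[type]]$exons, strand = "-"))$type,
                 type, info = paste("minus", type))
  }
  expect_error(classify_events(con, tx(exdf(0, 100), strand = "-")), "strand")
  # identical forms produce no events
  expect_equal(nrow(classify_events(con, con)), 0L)
})

test_that("classification is invariant under coordinate translation", {
  con <- tx(exdf(0, 100, 200, 300, 400, 500))
  alt <- tx(exdf(0, 100, 250, 300, 400, 500))
  shift <- function(t, k) { t$exons <- t$exons + k; t }
  a <- classify_events(con, alt)
  b <- classify_events(shift(con, 10000), shift(alt, 10000))
  expect_equal(b$type, a$type)
  expect_equal(b$start, a$start + 10000)
  expect_equal(b$end, a$end + 10000)
})

test_that("junction support counts constructed reads correctly", {
  con <- tx(exdf(0, 100, 200, 300))
  alt <- tx(exdf(0, 300))
  ev <- classify_events(con, alt)   # IR of intron [100,200)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:5), sample = "s1", chrom = "chr1",
    block_starts = c("50,200",  # gap exactly [100,200): constitutive
                     "80",      # continuous across 100 with 20/30 overhang: alt
                     "260",     # spans neither junction
                     "95",      # only 5 bp overhang: below the default 8
                     "120,205"),# gap [150,205)? no: blocks 120-150,205-230
    block_ends = c("100,250", "130", "290", "102", "150,230"))
  ps <- count_junction_support(reads, ev, chrom = "chr1")
  expect_equal(ps$const_count, 1L)
  expect_equal(ps$alt_count, 1L)
  expect_equal(ps$psi, 0.5)
  # reads on another chromosome are ignored
  reads$chrom <- "chr2"
  ps2 <- count_junction_support(reads, ev, chrom = "chr1")
  expect_equal(ps2$alt_count + ps2$const_count, 0L)
})

test_that("the minimum-alternative-read filter applies per gene", {
  psi <- data.frame(event_id = rep(c("e1", "e2", "e3"), each = 2),
                    sample = rep(c("s1", "s2"), 3),
                    alt_count = c(1L, 1L, 2L, 0L, 3L, 4L),
                    const_count = 5L)
  gene_of <- c(e1 = "gA", e2 = "gA", e3 = "gB")
  out <- filter_min_alt_reads(psi, min_alt = 3, gene_of = gene_of)
  expect_setequal(unique(out$event_id), c("e1", "e2", "e3"))  # gA total = 4
  out5 <- filter_min_alt_reads(psi, min_alt = 5, gene_of = gene_of)
  expect_setequal(unique(out5$event_id), "e3")
  # per-event mode: e1 (2) drops, e2 (2) drops at min_alt = 3
  oute <- filter_min_alt_reads(psi, min_alt = 3, by = "event")
  expect_setequal(unique(oute$event_id), "e3")
  expect_equal(nrow(filter_min_alt_reads(psi, min_alt = 0, gene_of = gene_of)),
               nrow(psi))
})

test_that("logistic LRT deviance matches the brute-force likelihood oracle", {
  set.seed(51)
  x <- psi_sim(50, 25, 0.25, 0.45)
  das <- test_differential_splicing(x$psi, x$meta,
                                    c("condition", "drought", "control"))
  d <- merge(x$psi, x$meta, by = "sample")
  for (ev in sample(das$event_id, 20)) {
    sub <- d[d$event_id == ev, ]
    dev_oracle <- binom_lrt_oracle(sub$alt_count,
                                   sub$alt_count + sub$const_count,
                                   sub$condition)
    p_oracle <- pchisq(dev_oracle, 1, lower.tail = FALSE)
    expect_equal(das$p[das$event_id == ev], p_oracle, tolerance = 1e-6)
  }
})

test_that("swapping alt/const labels mirrors PSI and negates the effect", {
  set.seed(52)
  x <- psi_sim(30, 15, 0.2, 0.4)
  a <- test_differential_splicing(x$psi, x$meta,
                                  c("condition", "drought", "control"))
  swapped <- x$psi
  names(swapped)[names(swapped) == "alt_count"] <- "tmp"
  names(swapped)[names(swapped) == "const_count"] <- "alt_count"
  names(swapped)[names(swapped) == "tmp"] <- "const_count"
  b <- test_differential_splicing(swapped, x$meta,
                                  c("condition", "drought", "control"))
  expect_equal(b$psi_test, 1 - a$psi_test, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-9)     # LRT is label-symmetric
  expect_true(all(sign(b$log2fc[a$log2fc != 0]) == -sign(a$log2fc[a$log2fc != 0]) |
                  b$log2fc == 0))
})

test_that("differential splicing attains power and a quiet null", {
  set.seed(53)
  x <- psi_sim(300, 50, 0.2, 0.4)
  das <- test_differential_splicing(x$psi, x$meta,
                                    c("condition", "drought", "control"))
  shifted <- das$event_id %in% x$shifted
  expect_gt(mean(das$call[shifted] == "DASU"), 0.8)
  expect_lt(mean(das$call[!shifted] != "ns"), 0.03)
  # null-only data across a few simulations
  rates <- vapply(1:5, function(i) {
    x0 <- psi_sim(200, 0, 0.3, 0.3)
    d0 <- test_differential_splicing(x0$psi, x0$meta,
                                     c("condition", "drought", "control"))
    mean(d0$call != "ns")
  }, 0)
  expect_lt(mean(rates), 0.03)
})
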