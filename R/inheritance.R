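# Inheritance-mode classification of hybrid expression/splicing relative to
# the parents, and rank-sum tests of phenotypic heterosis.

# Pooled two-group binomial likelihood-ratio test (closed form).
binom_lrt_2group <- function(a1, n1, a2, n2) {
  if (n1 == 0 || n2 == 0) return(NA_real_)
  ll <- function(a, n, p) {
    if (p <= 0) return(if (a == 0) 0 else -Inf)
    if (p >= 1) return(if (a == n) 0 else -Inf)
    a * log(p) + (n - a) * log(1 - p)
  }
  p1 <- a1 / n1; p2 <- a2 / n2; p0 <- (a1 + a2) / (n1 + n2)
  dev <- 2 * (ll(a1, n1, p1) + ll(a2, n2, p2) - ll(a1, n1, p0) - ll(a2, n2, p0))
  pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
}

# Binomial LRT of the mid-parent constraint p_H = (p_A + p_B) / 2 against
# free group proportions, on pooled per-group counts.
binom_midparent_lrt <- function(aA, nA, aB, nB, aH, nH) {
  if (min(nA, nB, nH) == 0) return(NA_real_)
  llb <- function(a, n, p) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    a * log(p) + (n - a) * log(1 - p)
  }
  ll_full <- llb(aA, nA, aA / nA) + llb(aB, nB, aB / nB) + llb(aH, nH, aH / nH)
  nll0 <- function(theta) {
    pA <- stats::plogis(theta[1]); pB <- stats::plogis(theta[2])
    -(llb(aA, nA, pA) + llb(aB, nB, pB) + llb(aH, nH, (pA + pB) / 2))
  }
  init <- stats::qlogis(pmin(pmax(c((aA + 0.5) / (nA + 1), (aB + 0.5) / (nB + 1)), 1e-6), 1 - 1e-6))
  opt <- stats::optim(init, nll0, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  dev <- 2 * (ll_full + opt$value)
  pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
}

#' Classify inheritance mode of hybrid expression or splicing
#'
#' Implements the hierarchical additive/non-additive model: step 1 tests the
#' hybrid against the mid-parent value (NB GLM contrast on the log scale for
#' expression; binomial likelihood-ratio test with the mid-parent constraint
#' on the proportion scale for splicing), with BH adjustment across
#' features; features with adjusted p >= `alpha` are additive. Step 2, on
#' non-additive features only, tests the hybrid against the high parent and
#' the low parent (BH within each comparison family): significantly above
#' the high parent is over-dominant, significantly below the low parent
#' under-dominant, distinguishable from exactly one parent is dominance at
#' the other parent's level, distinguishable from neither is unclassified.
#' Parent roles are decided by fitted values, so swapping parent labels
#' leaves every call unchanged.
#'
#' @param x gene x sample count matrix (expression) or a `psi_table`
#'   data.frame (splicing).
#' @param metadata data.frame: sample, genotype_group (parentA / parentB /
#'   hybrid), condition.
#' @param modality "expression" or "splicing".
#' @param condition restrict to one condition (default: use all samples).
#' @param alpha FDR threshold for every step (default 0.05).
#' @param dispersion optional fixed NB dispersion (expression only).
#' @param prior_weight tagwise-dispersion shrinkage weight (expression).
#' @return data.frame of class `inheritance_call`: feature, modality,
#'   condition, value_parentA, value_parentB, value_hybrid, p_mid, p_high,
#'   p_low (FDR-adjusted), category.
#' @export
classify_inheritance <- function(x, metadata,
                                 modality = c("expression", "splicing"),
                                 condition = NULL, alpha = 0.05,
                                 dispersion = NULL, prior_weight = 10) {
  modality <- match.arg(modality)
  meta <- metadata
  if (!is.null(condition)) meta <- meta[meta$condition == condition, , drop = FALSE]
  groups <- c("parentA", "parentB", "hybrid")
  assert_that(all(groups %in% meta$genotype_group), "all three genotype groups required")

  if (modality == "expression") {
    res <- inherit_expression(x, meta, dispersion, prior_weight)
  } else {
    res <- inherit_splicing(x, meta)
  }
  res$fdr_mid <- p.adjust(res$p_mid, "BH")
  res$fdr_high <- p.adjust(res$p_high, "BH")
  res$fdr_low <- p.adjust(res$p_low, "BH")

  categorize <- function(r) {
    if (is.na(r[["fdr_mid"]])) return("unclassified")
    if (r[["fdr_mid"]] >= alpha) return("additive")
    hi <- max(r[["value_parentA"]], r[["value_parentB"]])
    lo <- min(r[["value_parentA"]], r[["value_parentB"]])
    sig_hi <- !is.na(r[["fdr_high"]]) && r[["fdr_high"]] < alpha
    sig_lo <- !is.na(r[["fdr_low"]]) && r[["fdr_low"]] < alpha
    v <- r[["value_hybrid"]]
    if (sig_hi && v > hi) "over_dominant"
    else if (sig_lo && v < lo) "under_dominant"
    else if (sig_lo && !sig_hi) "dominant_high"
    else if (sig_hi && !sig_lo) "dominant_low"
    else "unclassified"
  }
  res$category <- apply(res[, c("fdr_mid", "fdr_high", "fdr_low",
                                "value_parentA", "value_parentB", "value_hybrid")],
                        1, categorize)
  res$modality <- modality
  res$condition <- condition %||% NA_character_
  class(res) <- c("inheritance_call", class(res))
  res
}

inherit_expression <- function(counts, meta, dispersion, prior_weight) {
  Y <- as.matrix(counts[, meta$sample, drop = FALSE])
  group <- meta$genotype_group
  lib <- colSums(Y)
  offsets <- log(lib * tmm_factors(Y))
  nonzero <- rowSums(Y) > 0
  Yn <- Y[nonzero, , drop = FALSE]

  if (is.null(dispersion)) {
    common <- estimate_common_dispersion(Yn, offsets, group)
    phi <- estimate_tagwise_dispersion(Yn, offsets, group, common, prior_weight)
  } else {
    phi <- rep_len(dispersion, nrow(Yn))
  }

  full <- nb_fit_groupmeans(Yn, offsets, group, phi)
  # mid-parent constraint: log mu_H = (log mu_A + log mu_B) / 2
  X2 <- rbind(parentA = c(1, 0), parentB = c(0, 1), hybrid = c(0.5, 0.5))[group, ]
  red <- nb_fit_design2(Yn, offsets, X2, phi)
  p_mid <- pchisq(pmax(2 * (full$ll - red$ll), 0), df = 1, lower.tail = FALSE)

  pair_p <- function(g2) {
    cols <- group %in% c("hybrid", g2)
    sub <- Yn[, cols, drop = FALSE]
    g <- group[cols]
    f <- nb_fit_groupmeans(sub, offsets[cols], g, phi)
    n0 <- nb_fit_groupmeans(sub, offsets[cols], rep("all", sum(cols)), phi)
    pchisq(pmax(2 * (f$ll - n0$ll), 0), df = 1, lower.tail = FALSE)
  }
  pA <- pair_p("parentA")
  pB <- pair_p("parentB")
  vA <- full$B[, "parentA"]; vB <- full$B[, "parentB"]; vH <- full$B[, "hybrid"]
  a_high <- vA >= vB
  out <- data.frame(
    feature = rownames(Y)[nonzero],
    value_parentA = vA, value_parentB = vB, value_hybrid = vH,
    p_mid = p_mid,
    p_high = ifelse(a_high, pA, pB),
    p_low = ifelse(a_high, pB, pA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

inherit_splicing <- function(psi, meta) {
  d <- merge(psi, meta[, c("sample", "genotype_group")], by = "sample")
  rows <- list()
  for (ev in unique(d$event_id)) {
    sub <- d[d$event_id == ev, , drop = FALSE]
    a <- tapply(sub$alt_count, sub$genotype_group, sum)
    n <- tapply(sub$alt_count + sub$const_count, sub$genotype_group, sum)
    need <- c("parentA", "parentB", "hybrid")
    if (anyNA(a[need]) || any(n[need] == 0)) next
    p_mid <- binom_midparent_lrt(a[["parentA"]], n[["parentA"]],
                                 a[["parentB"]], n[["parentB"]],
                                 a[["hybrid"]], n[["hybrid"]])
    pA <- binom_lrt_2group(a[["hybrid"]], n[["hybrid"]], a[["parentA"]], n[["parentA"]])
    pB <- binom_lrt_2group(a[["hybrid"]], n[["hybrid"]], a[["parentB"]], n[["parentB"]])
    psiA <- a[["parentA"]] / n[["parentA"]]
    psiB <- a[["parentB"]] / n[["parentB"]]
    a_high <- psiA >= psiB
    rows[[ev]] <- data.frame(
      feature = ev,
      value_parentA = psiA, value_parentB = psiB,
      value_hybrid = a[["hybrid"]] / n[["hybrid"]],
      p_mid = p_mid,
      p_high = if (a_high) pA else pB,
      p_low = if (a_high) pB else pA,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact two-sided rank-sum p-value by enumeration of all C(n1+n2, n1)
# assignments of the pooled ranks (ties handled through midranks).
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  p <- 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9))
  min(p, 1)
}

#' Rank-sum tests of hybrid superiority and mid-parent heterosis
#'
#' Two-sided Mann-Whitney rank-sum tests of the hybrid against each parent
#' (exact enumeration for group sizes up to `exact_max`, normal
#' approximation with tie correction otherwise), mid-parent heterosis
#' `(F1 - MP) / MP` from group means, and a best-parent call: heterotic
#' above the best parent when the hybrid mean exceeds both parents with
#' p < alpha against both.
#'
#' @param hybrid,parentA,parentB numeric replicate values per group
#'   (>= 2 each).
#' @param alpha significance level (default 0.05).
#' @param exact_max maximum group size for exact enumeration (default 10).
#' @return list of class `heterosis_result`: means, mph, p_vs_parentA,
#'   p_vs_parentB, above_both, heterotic_above_best.
#' @export
wilcoxon_heterosis <- function(hybrid, parentA, parentB, alpha = 0.05,
                               exact_max = 10L) {
  assert_that(length(hybrid) >= 2 && length(parentA) >= 2 && length(parentB) >= 2,
    "at least 2 replicates per group required")
  test_vs <- function(par) {
    if (var(c(hybrid, par)) == 0) return(1)
    if (max(length(hybrid), length(par)) <= exact_max) {
      rank_sum_exact_p(hybrid, par)
    } else {
      suppressWarnings(wilcox.test(hybrid, par, exact = FALSE, correct = TRUE)$p.value)
    }
  }
  pA <- test_vs(parentA)
  pB <- test_vs(parentB)
  mh <- mean(hybrid); mA <- mean(parentA); mB <- mean(parentB)
  mp <- (mA + mB) / 2
  above_both <- mh > mA && mh > mB
  structure(
    list(mean_hybrid = mh, mean_parentA = mA, mean_parentB = mB,
         mid_parent = mp, mph = (mh - mp) / mp,
         p_vs_parentA = pA, p_vs_parentB = pB,
         above_both = above_both,
         heterotic_above_best = above_both && pA < alpha && pB < alpha),
    class = "heterosis_result"
  )
}

#' @export
print.heterosis_result <- function(x, ...) {
  cat(sprintf("mid-parent heterosis %.3f; p vs parents %.3g / %.3g%s\n",
              x$mph, x$p_vs_parentA, x$p_vs_parentB,
              if (x$heterotic_above_best) " (heterotic above best parent)" else ""))
  invisible(x)
}
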