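# Alternative-splicing event classification, alt/constitutive junction
# support counting, percent spliced index, and binomial logistic-regression
# differential splicing. All coordinates are 0-based half-open; exon lists
# are sorted by genomic position, and donor/acceptor roles follow the
# transcription direction (on the minus strand the donor is the genomic end
# of an intron).

introns_of <- function(exons) {
  if (nrow(exons) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1])
}

#' Classify alternative-splicing events between two transcript forms
#'
#' Compares the intron chains of a constitutive and an alternative transcript
#' of the same gene (same strand), producing one typed event per structural
#' difference:
#' \describe{
#'   \item{IR}{a constitutive intron retained, fully inside an alternative
#'     exon;}
#'   \item{SKIP}{a constitutive exon absent from the alternative form, its
#'     flanking introns fused;}
#'   \item{ALTD / ALTA}{intron pair sharing the acceptor with a shifted
#'     donor, or sharing the donor with a shifted acceptor (strand-aware);}
#'   \item{ALTP}{overlapping introns differing at both ends;}
#'   \item{CRIN}{a novel (cryptic) intron strictly inside a constitutive
#'     exon;}
#'   \item{CREX}{a novel (cryptic) exon strictly inside a constitutive
#'     intron;}
#'   \item{OTHER}{any remaining difference.}
#' }
#'
#' @param constitutive,alternative transcript models: lists with gene_id,
#'   strand, and `exons` (data.frame start/end, 0-based half-open, sorted).
#' @return data.frame: event_id, gene_id, type, strand, start, end (the
#'   defining interval), const_start, const_end, alt_start, alt_end (the
#'   defining junctions; NA where a form has no junction, as for IR).
#' @export
classify_events <- function(constitutive, alternative) {
  assert_that(constitutive$strand == alternative$strand,
    "strand mismatch between transcript forms")
  strand <- constitutive$strand
  gene <- constitutive$gene_id %||% "gene"
  c_ex <- constitutive$exons
  a_ex <- alternative$exons
  c_in <- introns_of(c_ex)
  a_in <- introns_of(a_ex)

  key <- function(d) if (nrow(d)) paste(d$start, d$end) else character(0)
  c_key <- key(c_in); a_key <- key(a_in)
  c_open <- !(c_key %in% a_key)
  a_open <- !(a_key %in% c_key)

  ev <- list()
  add <- function(type, start, end, cs = NA, ce = NA, as = NA, ae = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = gene, type = type, strand = strand,
      start = start, end = end,
      const_start = cs, const_end = ce, alt_start = as, alt_end = ae,
      stringsAsFactors = FALSE
    )
  }

  # SKIP: alternative intron fusing two consecutive constitutive introns
  for (i in which(a_open)) {
    j1 <- which(c_open & c_in$start == a_in$start[i])
    for (j in j1) {
      if (j < nrow(c_in) && c_open[j + 1L] && c_in$end[j + 1L] == a_in$end[i]) {
        add("SKIP", c_in$end[j], c_in$start[j + 1L],
            cs = c_in$start[j], ce = c_in$end[j + 1L],
            as = a_in$start[i], ae = a_in$end[i])
        a_open[i] <- FALSE
        c_open[j] <- c_open[j + 1L] <- FALSE
        break
      }
    }
  }

  # IR: constitutive intron fully inside an alternative exon
  for (j in which(c_open)) {
    inside <- any(a_ex$start <= c_in$start[j] & c_in$end[j] <= a_ex$end)
    if (inside) {
      add("IR", c_in$start[j], c_in$end[j], cs = c_in$start[j], ce = c_in$end[j])
      c_open[j] <- FALSE
    }
  }

  # CRIN: alternative intron strictly inside a constitutive exon
  for (i in which(a_open)) {
    inside <- any(c_ex$start <= a_in$start[i] & a_in$end[i] <= c_ex$end)
    if (inside) {
      add("CRIN", a_in$start[i], a_in$end[i], as = a_in$start[i], ae = a_in$end[i])
      a_open[i] <- FALSE
    }
  }

  # CREX: alternative exon strictly inside a constitutive intron; its two
  # flanking alternative junctions are part of the event
  for (e in seq_len(nrow(a_ex))) {
    j <- which(c_in$start < a_ex$start[e] & a_ex$end[e] < c_in$end)
    if (length(j) == 1L) {
      left <- which(a_in$start == c_in$start[j] & a_in$end == a_ex$start[e])
      right <- which(a_in$start == a_ex$end[e] & a_in$end == c_in$end[j])
      if (length(left) == 1L && length(right) == 1L && a_open[left] && a_open[right]) {
        add("CREX", a_ex$start[e], a_ex$end[e],
            cs = c_in$start[j], ce = c_in$end[j],
            as = a_in$start[left], ae = a_in$end[right])
        a_open[c(left, right)] <- FALSE
        c_open[j] <- FALSE
      }
    }
  }

  # ALTD / ALTA / ALTP: overlapping intron pairs
  for (i in which(a_open)) {
    ov <- which(c_open & c_in$start < a_in$end[i] & a_in$start[i] < c_in$end)
    if (!length(ov)) next
    j <- ov[which.max(pmin(c_in$end[ov], a_in$end[i]) - pmax(c_in$start[ov], a_in$start[i]))]
    same_start <- c_in$start[j] == a_in$start[i]
    same_end <- c_in$end[j] == a_in$end[i]
    type <- if (same_start && !same_end) {
      if (strand == "+") "ALTA" else "ALTD"   # genomic start shared = donor on +, acceptor on -
    } else if (same_end && !same_start) {
      if (strand == "+") "ALTD" else "ALTA"
    } else {
      "ALTP"
    }
    add(type, min(c_in$start[j], a_in$start[i]), max(c_in$end[j], a_in$end[i]),
        cs = c_in$start[j], ce = c_in$end[j],
        as = a_in$start[i], ae = a_in$end[i])
    a_open[i] <- FALSE
    c_open[j] <- FALSE
  }

  # anything still unexplained
  for (i in which(a_open)) {
    add("OTHER", a_in$start[i], a_in$end[i], as = a_in$start[i], ae = a_in$end[i])
  }
  for (j in which(c_open)) {
    add("OTHER", c_in$start[j], c_in$end[j], cs = c_in$start[j], ce = c_in$end[j])
  }

  if (!length(ev)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      const_start = integer(0), const_end = integer(0),
                      alt_start = integer(0), alt_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- cbind(event_id = sprintf("%s:%s:%d-%d", out$gene_id, out$type, out$start, out$end),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

parse_blocks <- function(starts, ends) {
  data.frame(start = as.integer(strsplit(starts, ",")[[1]]),
             end = as.integer(strsplit(ends, ",")[[1]]))
}

#' Count junction reads supporting the alternative vs constitutive form
#'
#' A read supports the constitutive form of an event when one of its block
#' gaps exactly matches the constitutive junction; it supports the
#' alternative form when a gap exactly matches the alternative junction or,
#' for intron retention, when one continuous block crosses an exon-intron
#' boundary of the retained intron with at least `overhang` bases on each
#' side. Each read counts at most once per event.
#'
#' @param reads data.frame: read_id, sample, chrom, block_starts, block_ends
#'   (comma-separated 0-based half-open block bounds).
#' @param events event catalog from [classify_events()], with an added
#'   `chrom` column (or all on one chromosome via `chrom =`).
#' @param chrom chromosome for events lacking a `chrom` column.
#' @param overhang minimum bases on each side of a retained boundary
#'   (default 8).
#' @return `psi_table` data.frame: event_id, sample, alt_count, const_count,
#'   psi.
#' @export
count_junction_support <- function(reads, events, chrom = NULL, overhang = 8L) {
  if (is.null(events$chrom)) {
    assert_that(!is.null(chrom), "supply chrom for the event catalog")
    events$chrom <- chrom
  }
  samples <- unique(reads$sample)
  alt <- matrix(0L, nrow(events), length(samples),
                dimnames = list(events$event_id, samples))
  const <- alt
  blocks <- Map(parse_blocks, reads$block_starts, reads$block_ends)
  for (r in seq_len(nrow(reads))) {
    bl <- blocks[[r]]
    gaps <- introns_of(bl)
    s <- reads$sample[r]
    on_chrom <- events$chrom == reads$chrom[r]
    for (e in which(on_chrom)) {
      hit_const <- !is.na(events$const_start[e]) && nrow(gaps) > 0 &&
        any(gaps$start == events$const_start[e] & gaps$end == events$const_end[e])
      hit_alt <- FALSE
      if (events$type[e] == "IR") {
        b1 <- events$const_start[e]; b2 <- events$const_end[e]
        hit_alt <- any((bl$start <= b1 - overhang & bl$end >= b1 + overhang) |
                       (bl$start <= b2 - overhang & bl$end >= b2 + overhang))
      } else if (!is.na(events$alt_start[e]) && nrow(gaps) > 0) {
        if (events$type[e] == "CREX") {
          hit_alt <- any(gaps$start == events$alt_start[e] & gaps$end == events$start[e]) ||
            any(gaps$start == events$end[e] & gaps$end == events$alt_end[e])
        } else {
          hit_alt <- any(gaps$start == events$alt_start[e] & gaps$end == events$alt_end[e])
        }
      }
      if (hit_alt) alt[e, s] <- alt[e, s] + 1L
      else if (hit_const) const[e, s] <- const[e, s] + 1L
    }
  }
  out <- expand.grid(event_id = events$event_id, sample = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$alt_count <- alt[cbind(out$event_id, out$sample)]
  out$const_count <- const[cbind(out$event_id, out$sample)]
  out$psi <- with(out, ifelse(alt_count + const_count > 0,
                              alt_count / (alt_count + const_count), NA_real_))
  out
}

#' Filter events on minimum alternative-isoform read support
#'
#' By default the rule is applied per gene: a gene whose total alternative
#' reads (summed over its events and all samples) fall below `min_alt` has
#' all its events removed. Per-event filtering is available via
#' `by = "event"`.
#'
#' @param psi `psi_table` data.frame (event_id, sample, alt_count,
#'   const_count).
#' @param min_alt minimum alternative read count (default 3).
#' @param gene_of named vector mapping event_id to gene_id (required for
#'   gene-level filtering; defaults to treating each event as its own gene).
#' @param by "gene" (default) or "event".
#' @return filtered `psi_table`.
#' @export
filter_min_alt_reads <- function(psi, min_alt = 3L, gene_of = NULL,
                                 by = c("gene", "event")) {
  by <- match.arg(by)
  assert_that(min_alt >= 0, "min_alt must be >= 0")
  if (by == "gene" && is.null(gene_of)) {
    gene_of <- setNames(unique(psi$event_id), unique(psi$event_id))
  }
  unit <- if (by == "gene") gene_of[psi$event_id] else psi$event_id
  tot <- tapply(psi$alt_count, unit, sum)
  keep_units <- names(tot)[tot >= min_alt]
  psi[unit %in% keep_units, , drop = FALSE]
}

#' Differential alternative splicing by binomial logistic regression
#'
#' Per event, the per-sample (alt, constitutive) read pairs are modelled by
#' a binomial logistic regression on the contrast variable and tested by
#' likelihood ratio against the intercept-only model. The log2 fold change
#' is computed on the group-pooled PSI with a pseudo-fraction:
#' `log2((PSI_test + eps) / (PSI_ref + eps))`. Calls: DASU when FDR and
#' log2FC pass upward, DASD downward.
#'
#' @param psi `psi_table` data.frame.
#' @param metadata data.frame with sample and the contrast variable.
#' @param contrast character(3): variable, test level, reference level.
#' @param fdr_cutoff,lfc_cutoff thresholds (defaults 0.01 and 0.25).
#' @param epsilon pseudo-fraction for the fold change (default 0.01).
#' @param quasi use quasi-binomial dispersion and an F test instead of the
#'   plain binomial LRT (default FALSE).
#' @return data.frame of class `das_result`: event_id, psi_test, psi_ref,
#'   log2fc, p, fdr, call (DASU/DASD/ns). Events with zero total reads in a
#'   group are skipped.
#' @export
test_differential_splicing <- function(psi, metadata, contrast,
                                       fdr_cutoff = 0.01, lfc_cutoff = 0.25,
                                       epsilon = 0.01, quasi = FALSE) {
  assert_that(length(contrast) == 3, "contrast must be c(variable, test, reference)")
  var <- contrast[1]
  meta <- metadata[metadata[[var]] %in% contrast[2:3], , drop = FALSE]
  d <- merge(psi, meta[, c("sample", var)], by = "sample")
  d$grp <- factor(ifelse(d[[var]] == contrast[2], "test", "ref"),
                  levels = c("ref", "test"))
  rows <- list()
  for (ev in unique(d$event_id)) {
    sub <- d[d$event_id == ev, , drop = FALSE]
    tot <- tapply(sub$alt_count + sub$const_count, sub$grp, sum)
    if (any(is.na(tot)) || any(tot == 0)) next
    fam <- if (quasi) stats::quasibinomial() else binomial()
    fit1 <- glm(cbind(alt_count, const_count) ~ grp, family = fam, data = sub)
    fit0 <- glm(cbind(alt_count, const_count) ~ 1, family = fam, data = sub)
    p <- if (quasi) {
      anova(fit0, fit1, test = "F")[2, "Pr(>F)"]
    } else {
      pchisq(fit0$deviance - fit1$deviance, df = 1, lower.tail = FALSE)
    }
    alt_g <- tapply(sub$alt_count, sub$grp, sum)
    psi_g <- alt_g / tot
    rows[[ev]] <- data.frame(
      event_id = ev,
      psi_test = unname(psi_g["test"]), psi_ref = unname(psi_g["ref"]),
      log2fc = log2((psi_g[["test"]] + epsilon) / (psi_g[["ref"]] + epsilon)),
      p = p, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p, method = "BH")
  out$call <- ifelse(out$fdr < fdr_cutoff & out$log2fc > lfc_cutoff, "DASU",
               ifelse(out$fdr < fdr_cutoff & out$log2fc < -lfc_cutoff, "DASD", "ns"))
  class(out) <- c("das_result", class(out))
  out
}
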