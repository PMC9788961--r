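# Cross-genome expression complementation: genes expressed in one parent and
# the hybrid but silent in the other parent, confirmed as physically missing
# from the silent parent's genome by homology search.

#' Classify expression-complementation candidates from TPM on one genome
#'
#' Per gene on the host annotation, each genotype group's state is taken
#' from its replicate-mean TPM: expressed when above `tpm_hi`, silent when
#' below `tpm_lo`, ambiguous in the gap. A gene is a candidate when it is
#' expressed in the host parent and the hybrid and silent in the other
#' parent. Candidates are evaluated separately per condition.
#'
#' @param tpm TPM matrix (genes x samples) quantified on one parental
#'   reference genome.
#' @param metadata data.frame: sample, genotype_group (parentA / parentB /
#'   hybrid), condition.
#' @param host_genome "A" or "B": which parent's annotation `tpm` is on.
#' @param tpm_hi expressed threshold (default 2).
#' @param tpm_lo silent threshold (default 0.1).
#' @param per_replicate if TRUE, require every replicate (rather than the
#'   group mean) to pass the state thresholds.
#' @return data.frame: gene, condition, state_parentA, state_parentB,
#'   state_hybrid, candidate (logical).
#' @export
classify_complementation <- function(tpm, metadata, host_genome = c("A", "B"),
                                     tpm_hi = 2, tpm_lo = 0.1,
                                     per_replicate = FALSE) {
  host_genome <- match.arg(host_genome)
  host_parent <- if (host_genome == "A") "parentA" else "parentB"
  other_parent <- if (host_genome == "A") "parentB" else "parentA"
  assert_that(all(c("sample", "genotype_group", "condition") %in% colnames(metadata)),
    "metadata needs sample, genotype_group, condition")
  groups <- c("parentA", "parentB", "hybrid")

  state_of <- function(vals) {
    if (per_replicate) {
      if (all(vals > tpm_hi)) "expressed" else if (all(vals < tpm_lo)) "silent" else "ambiguous"
    } else {
      m <- mean(vals)
      if (m > tpm_hi) "expressed" else if (m < tpm_lo) "silent" else "ambiguous"
    }
  }

  rows <- list()
  for (cond in unique(metadata$condition)) {
    sub <- metadata[metadata$condition == cond, , drop = FALSE]
    missing_groups <- setdiff(groups, unique(sub$genotype_group))
    if (length(missing_groups)) next  # condition unchecked without all groups
    cols <- lapply(groups, function(g) sub$sample[sub$genotype_group == g])
    st <- vapply(cols, function(s) apply(tpm[, s, drop = FALSE], 1, state_of),
                 character(nrow(tpm)))
    colnames(st) <- groups
    cand <- st[, host_parent] == "expressed" & st[, "hybrid"] == "expressed" &
      st[, other_parent] == "silent"
    rows[[cond]] <- data.frame(
      gene = rownames(tpm), condition = cond, host_genome = host_genome,
      state_parentA = st[, "parentA"], state_parentB = st[, "parentB"],
      state_hybrid = st[, "hybrid"], candidate = cand,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a tabular homology hit table (12-column BLAST outfmt-6 dialect)
#'
#' @param path TSV without header: qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore. Malformed rows are
#'   skipped with a warning.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop2("hit table must have 12 columns")
  colnames(df) <- cols
  num <- c("pident", "length", "evalue", "bitscore")
  for (cn in num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  bad <- !complete.cases(df[, num])
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed hit row(s)")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Confirm candidate complementation genes as truly missing
#'
#' A candidate survives as a confirmed presence/absence polymorphism only if
#' it has no qualifying homology hit against the silent parent's genome. A
#' qualifying hit has E-value < 1e-100, identity > 95%, alignment length
#' >= 200 bp and bit score >= 200 (hits shorter than 200 bp are skipped);
#' such a hit means the gene is present but unexpressed, and the candidate
#' is rejected.
#'
#' @param candidates character vector of candidate gene ids (or the
#'   data.frame from [classify_complementation()], from which
#'   candidate gene/condition rows are taken).
#' @param hits hit table (see [read_hit_table()]) of candidate genes
#'   searched against the silent parent's genome.
#' @param max_evalue,min_pident,min_length,min_bitscore qualifying-hit
#'   thresholds.
#' @return data.frame: gene (x condition if supplied), homology_status
#'   (hit_found / no_hit), class (confirmed_pav_complementation / rejected).
#' @export
confirm_absence <- function(candidates, hits,
                            max_evalue = 1e-100, min_pident = 95,
                            min_length = 200, min_bitscore = 200) {
  if (is.data.frame(candidates)) {
    cand_df <- candidates[candidates$candidate, c("gene", "condition"), drop = FALSE]
  } else {
    cand_df <- data.frame(gene = candidates, condition = NA_character_,
                          stringsAsFactors = FALSE)
  }
  qual <- hits[hits$evalue < max_evalue & hits$pident > min_pident &
                 hits$length >= min_length & hits$bitscore >= min_bitscore, ,
               drop = FALSE]
  found <- cand_df$gene %in% qual$qseqid
  out <- cand_df
  out$homology_status <- ifelse(found, "hit_found", "no_hit")
  out$class <- ifelse(found, "rejected", "confirmed_pav_complementation")
  rownames(out) <- NULL
  out
}

#' Exact k-mer homology matcher for synthetic genomes
#'
#' A self-contained substitute for an external nucleotide aligner on
#' synthetic data: every k-mer (default 31) of each query is looked up in
#' the subject genome (both strands), and maximal runs of consecutive
#' matching k-mers of total span >= `min_run_bp` are reported as hits with
#' 100% identity, E-value 0 and a bit score of twice the span, so they pass
#' (or fail) the same qualifying-hit thresholds as real alignments.
#'
#' @param queries named character vector of query sequences (genes).
#' @param genome named character vector of subject chromosome sequences.
#' @param k k-mer size (default 31).
#' @param min_run_bp minimum matched span to report (default 200).
#' @return hit table in the 12-column tabular dialect.
#' @export
kmer_hit_table <- function(queries, genome, k = 31L, min_run_bp = 200L) {
  subj <- paste(c(genome, vapply(genome, revcomp, "")), collapse = "N")
  subj_kmers <- new.env(hash = TRUE, parent = emptyenv())
  nk <- nchar(subj) - k + 1L
  if (nk > 0) {
    km <- substring(subj, seq_len(nk), seq_len(nk) + k - 1L)
    for (s in unique(km)) assign(s, TRUE, envir = subj_kmers)
  }
  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    nq <- nchar(q) - k + 1L
    if (nq < 1) next
    qk <- substring(q, seq_len(nq), seq_len(nq) + k - 1L)
    hit <- vapply(qk, function(s) exists(s, envir = subj_kmers, inherits = FALSE),
                  TRUE, USE.NAMES = FALSE)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      span <- r$lengths[i] + k - 1L
      if (span >= min_run_bp) {
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = qn, sseqid = names(genome)[1], pident = 100,
          length = span, mismatch = 0L, gapopen = 0L,
          qstart = starts[i], qend = starts[i] + span - 1L,
          sstart = 1L, send = span, evalue = 0, bitscore = 2 * span,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
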