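# Stop-codon annotation: identify stop_gained / stop_lost SNVs from gene
# models and genome sequence. Only these two effect classes are produced;
# the standard nuclear genetic code is assumed (stops TAA, TAG, TGA).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Filter gene models to the protein-coding set used for stop-codon scans
#'
#' Drops genes with an open reading frame shorter than `min_orf_aa` amino
#' acids (the threshold excludes ORFs strictly below it, so 75 aa is
#' retained at the default) and, optionally, intronless genes (a pseudogene
#' signature in this context). Genes whose CDS length is not a multiple of 3
#' are malformed and dropped with a warning.
#'
#' @param models list of gene models (see [read_gene_models()]).
#' @param min_orf_aa minimum ORF length in amino acids (default 75).
#' @param require_introns drop genes without introns (default TRUE).
#' @return filtered list of models; attributes `n_before` and `n_after`.
#' @export
filter_protein_genes <- function(models, min_orf_aa = 75L, require_introns = TRUE) {
  keep <- logical(length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    cds_len <- sum(m$exons$end - m$exons$start)
    if (cds_len %% 3L != 0L) {
      warning("gene ", m$gene_id, ": CDS length not a multiple of 3; dropped")
      next
    }
    orf_aa <- m$orf_aa %||% (cds_len %/% 3L - 1L)
    keep[i] <- orf_aa >= min_orf_aa && (!require_introns || (m$n_introns %||% (nrow(m$exons) - 1L)) >= 1L)
  }
  out <- models[keep]
  attr(out, "n_before") <- length(models)
  attr(out, "n_after") <- length(out)
  out
}

# Spliced CDS sequence and the genomic position of each transcript-order base.
splice_cds <- function(exons, strand, chrom_seq) {
  exons <- exons[order(exons$start), , drop = FALSE]
  seqs <- substring(chrom_seq, exons$start + 1L, exons$end)
  pos <- unlist(Map(function(s, e) seq(s, e - 1L), exons$start, exons$end))
  cds <- paste(seqs, collapse = "")
  if (strand == "-") {
    cds <- revcomp(cds)
    pos <- rev(pos)
  }
  list(seq = cds, pos = pos)
}

#' Annotate stop-gained and stop-lost SNVs
#'
#' For each bi-allelic SNV falling inside a coding exon, the CDS is spliced
#' (strand-aware: minus-strand transcripts are reverse-complemented), the
#' affected codon located, and the substitution classified as `stop_gained`
#' (non-stop codon mutated to TAA/TAG/TGA) or `stop_lost` (stop codon mutated
#' to a non-stop codon). SNVs with neither effect, or outside CDS, yield no
#' call. Multi-transcript genes are called if the effect occurs in any
#' transcript.
#'
#' @param snps data.frame: chrom, pos (1-based), ref, alt (single bases);
#'   an `id` column is carried through if present.
#' @param models list of gene models.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame: snp_id, chrom, pos, ref, alt, gene_id, transcript,
#'   effect, codon_ref, codon_alt.
#' @export
annotate_stops <- function(snps, models, genome) {
  assert_that(all(nchar(snps$ref) == 1L & nchar(snps$alt) == 1L),
    "bi-allelic single-nucleotide variants required")
  snp_id <- snps$id %||% sprintf("snp%05d", seq_len(nrow(snps)))

  calls <- list()
  for (m in models) {
    chrom_seq <- genome[[m$chrom]]
    if (is.null(chrom_seq)) stop2("data error: genome lacks chromosome ", m$chrom)
    txs <- m$transcripts %||% setNames(list(m$exons), paste0(m$gene_id, ".t1"))
    in_chrom <- which(snps$chrom == m$chrom)
    if (!length(in_chrom)) next
    for (tname in names(txs)) {
      sp <- splice_cds(txs[[tname]], m$strand, chrom_seq)
      idx <- match(snps$pos[in_chrom] - 1L, sp$pos)
      hit <- which(!is.na(idx))
      for (h in hit) {
        k <- in_chrom[h]
        tx_pos <- idx[h]
        genome_base <- substr(chrom_seq, snps$pos[k], snps$pos[k])
        if (genome_base != snps$ref[k]) {
          stop2("data error: reference base mismatch at ", snps$chrom[k], ":",
                snps$pos[k], " (genome ", genome_base, ", VCF ", snps$ref[k], ")")
        }
        codon_i <- (tx_pos - 1L) %/% 3L
        offset <- (tx_pos - 1L) %% 3L
        codon <- substr(sp$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
        alt_tx <- if (m$strand == "-") COMPLEMENT[[snps$alt[k]]] else snps$alt[k]
        codon_alt <- codon
        substr(codon_alt, offset + 1L, offset + 1L) <- alt_tx
        is_stop_ref <- codon %in% STOP_CODONS
        is_stop_alt <- codon_alt %in% STOP_CODONS
        effect <- if (!is_stop_ref && is_stop_alt) "stop_gained"
                  else if (is_stop_ref && !is_stop_alt) "stop_lost"
                  else NA_character_
        if (!is.na(effect)) {
          calls[[length(calls) + 1L]] <- data.frame(
            snp_id = snp_id[k], chrom = snps$chrom[k], pos = snps$pos[k],
            ref = snps$ref[k], alt = snps$alt[k], gene_id = m$gene_id,
            transcript = tname, effect = effect,
            codon_ref = codon, codon_alt = codon_alt,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), gene_id = character(0),
                      transcript = character(0), effect = character(0),
                      codon_ref = character(0), codon_alt = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  # one row per SNP x gene x effect (any-transcript rule)
  out[!duplicated(out[, c("snp_id", "gene_id", "effect")]), , drop = FALSE]
}

#' Filter stop-codon calls on minor allele frequency
#'
#' Retains calls with MAF strictly greater than `min_maf` (so MAF exactly at
#' the threshold is dropped). MAF is the allele-count frequency over called
#' genotypes (missing genotypes excluded from the denominator); under
#' residual heterozygosity a 0.5 dosage contributes half an alternate allele.
#'
#' @param calls data.frame from [annotate_stops()].
#' @param genotypes numeric matrix, variants x samples, alternate-allele
#'   dosage in [0, 1] with rownames matching `snp_id`; NA = missing.
#' @param min_maf strict lower bound (default 0.20).
#' @return filtered calls with an added `maf` column.
#' @export
filter_stop_maf <- function(calls, genotypes, min_maf = 0.20) {
  if (!nrow(calls)) return(cbind(calls, maf = numeric(0)))
  assert_that(all(calls$snp_id %in% rownames(genotypes)),
    "genotype matrix must cover all called SNPs")
  f_alt <- rowMeans(genotypes[calls$snp_id, , drop = FALSE], na.rm = TRUE)
  maf <- pmin(f_alt, 1 - f_alt)
  out <- calls
  out$maf <- maf
  out[maf > min_maf, , drop = FALSE]
}
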