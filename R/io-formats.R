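# Readers/writers for the standard interchange formats. Genomic coordinates
# are 0-based half-open internally; GFF3 and VCF are 1-based at the file
# boundary per their specifications.

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Export gene models as GFF3
#'
#' Writes gene/mRNA/exon/CDS features (one transcript per gene, CDS identical
#' to the exons as the models are UTR-less).
#'
#' @param models list of gene models as built by [simulate_gene_models()].
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(models, function(m) {
    gs <- min(m$exons$start) + 1L   # to 1-based inclusive
    ge <- max(m$exons$end)
    tx <- paste0(m$gene_id, ".t1")
    feat <- rbind(
      data.frame(type = "gene", start = gs, end = ge,
                 attr = sprintf("ID=%s", m$gene_id)),
      data.frame(type = "mRNA", start = gs, end = ge,
                 attr = sprintf("ID=%s;Parent=%s", tx, m$gene_id)),
      data.frame(type = "exon", start = m$exons$start + 1L, end = m$exons$end,
                 attr = sprintf("Parent=%s", tx)),
      data.frame(type = "CDS", start = m$exons$start + 1L, end = m$exons$end,
                 attr = sprintf("Parent=%s", tx))
    )
    data.frame(seqid = m$chrom, source = "heteropav", type = feat$type,
               start = feat$start, end = feat$end, score = ".",
               strand = m$strand, phase = ifelse(feat$type == "CDS", "0", "."),
               attributes = feat$attr, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features into the internal gene-model list (0-based
#' half-open exon coordinates, CDS taken as the exon set of each transcript).
#' Multi-transcript genes keep every transcript's CDS chain.
#'
#' @param path GFF3 file.
#' @return list of gene models: gene_id, chrom, strand, exons (data.frame of
#'   the first transcript's CDS intervals), transcripts (named list of CDS
#'   interval data.frames), orf_aa, n_introns.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  tx_parent <- setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], ""),
    as.character(mrna$ID)
  )
  cds$tx <- vapply(cds$Parent, function(p) as.character(p)[1], "")
  models <- list()
  for (g in unique(unname(tx_parent))) {
    txs <- names(tx_parent)[tx_parent == g]
    tx_list <- list()
    for (t in txs) {
      sub <- cds[cds$tx == t, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      tx_list[[t]] <- data.frame(start = sub$start - 1L, end = sub$end)
    }
    first <- tx_list[[1]]
    cds_len <- sum(first$end - first$start)
    models[[g]] <- list(
      gene_id = g,
      chrom = as.character(cds$seqnames[cds$tx == txs[1]][1]),
      strand = as.character(cds$strand[cds$tx == txs[1]][1]),
      exons = first,
      transcripts = tx_list,
      orf_aa = cds_len %/% 3L - 1L,
      n_introns = nrow(first) - 1L
    )
  }
  unname(models)
}

#' Write bi-allelic SNVs (with optional genotypes) as VCF
#'
#' @param snps data.frame with chrom, pos (1-based), ref, alt; row order kept.
#' @param path output file.
#' @param genotypes optional 0/1 haploid matrix (variants x samples), written
#'   as homozygous diploid GT fields (0/0 or 1/1).
#' @export
write_snp_vcf <- function(snps, path, genotypes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- data.frame(snps$chrom, snps$pos,
                     sprintf("snp%05d", seq_len(nrow(snps))),
                     snps$ref, snps$alt, ".", "PASS", ".",
                     stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    hdr <- c(hdr, "FORMAT", colnames(genotypes))
    gt <- matrix(ifelse(genotypes == 1, "1/1", "0/0"), nrow = nrow(genotypes))
    body <- cbind(body, "GT", as.data.frame(gt, stringsAsFactors = FALSE))
  }
  writeLines(paste(hdr, collapse = "\t"), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read bi-allelic SNVs from VCF
#'
#' @param path VCF file.
#' @return list: `snps` data.frame (chrom, pos, id, ref, alt) and `genotypes`
#'   haploid 0/1 matrix (NA for missing) or NULL when no samples present.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  keep <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L
  genotypes <- NULL
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v)
    genotypes <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    genotypes[gt %in% c("0/0", "0|0", "0")] <- 0
    genotypes[gt %in% c("1/1", "1|1", "1")] <- 1
    genotypes[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 0.5
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  list(snps = snps[keep, , drop = FALSE], genotypes = genotypes)
}

#' Write a truth set as JSON
#' @param truth list of truth fragments.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
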