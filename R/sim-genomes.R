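# Synthetic genomes, gene models and coding SNPs.
#
# Gene models use 0-based half-open genomic coordinates internally; GFF3
# export is 1-based inclusive per the format standard.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_orf <- function(orf_aa) {
  # ATG + (orf_aa - 1) random non-stop codons + one stop codon
  bases <- c("A", "C", "G", "T")
  codons <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
  codons <- apply(codons, 1, paste, collapse = "")
  non_stop <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(non_stop, orf_aa - 1, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate protein-coding gene models on a synthetic genome
#'
#' Builds genes with clean open reading frames (ATG start, no internal stop,
#' terminal stop codon), 1 to `max_exons` exons, and both strands. Minus
#' strand genes are reverse-complemented into the genome so that splicing the
#' genomic exons in transcription order recovers the ORF.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param orf_aa_range range of ORF lengths in amino acids (stop excluded).
#' @param max_exons maximum exons per gene.
#' @param intron_bp_range,intergenic_bp_range intron and spacer lengths.
#' @param chrom chromosome name for the emitted sequence.
#' @return list with `models` (list of gene models: gene_id, chrom, strand,
#'   exons data.frame with 0-based half-open genomic `start`/`end` sorted by
#'   position, orf_aa, n_introns) and `genome` (named character vector of
#'   chromosome sequence).
#' @export
simulate_gene_models <- function(n_genes = 50, seed = 1L,
                                 orf_aa_range = c(60L, 200L),
                                 max_exons = 5L,
                                 intron_bp_range = c(40L, 150L),
                                 intergenic_bp_range = c(80L, 200L),
                                 chrom = "chrS1") {
  set.seed(seed)
  models <- vector("list", n_genes)
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(n_genes)) {
    spacer <- random_dna(sample(intergenic_bp_range[1]:intergenic_bp_range[2], 1))
    pieces <- c(pieces, spacer)
    cursor <- cursor + nchar(spacer)

    orf_aa <- sample(orf_aa_range[1]:orf_aa_range[2], 1)
    cds <- random_orf(orf_aa)
    n_ex <- sample.int(max_exons, 1)
    # split CDS into n_ex contiguous pieces of >= 6 nt each
    len <- nchar(cds)
    if (n_ex > 1) {
      cuts <- sort(sample(seq(6L, len - 6L), n_ex - 1L))
      while (any(diff(c(0L, cuts, len)) < 6L)) {
        cuts <- sort(sample(seq(6L, len - 6L), n_ex - 1L))
      }
    } else {
      cuts <- integer(0)
    }
    bounds <- c(0L, cuts, len)
    exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    introns <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1L),
             function(k) random_dna(sample(intron_bp_range[1]:intron_bp_range[2], 1)),
             "")
    } else character(0)

    strand <- sample(c("+", "-"), 1)
    # gene sequence in transcription order, then orient onto the genome
    tx_pieces <- character(2L * n_ex - 1L)
    tx_pieces[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_seqs
    if (n_ex > 1) tx_pieces[seq(2L, 2L * n_ex - 2L, by = 2L)] <- introns
    gene_seq_tx <- paste(tx_pieces, collapse = "")
    gene_len <- nchar(gene_seq_tx)
    gene_start <- cursor

    # exon bounds within the transcription-order gene sequence
    piece_len <- nchar(tx_pieces)
    offs <- cumsum(c(0L, piece_len))[seq_along(tx_pieces)]
    ex_tx <- data.frame(start = offs[seq(1L, length(tx_pieces), by = 2L)],
                        end = offs[seq(1L, length(tx_pieces), by = 2L)] +
                          piece_len[seq(1L, length(tx_pieces), by = 2L)])
    if (strand == "+") {
      genome_seq <- gene_seq_tx
      exons <- data.frame(start = gene_start + ex_tx$start,
                          end = gene_start + ex_tx$end)
    } else {
      genome_seq <- revcomp(gene_seq_tx)
      exons <- data.frame(start = gene_start + gene_len - ex_tx$end,
                          end = gene_start + gene_len - ex_tx$start)
      exons <- exons[order(exons$start), , drop = FALSE]
      rownames(exons) <- NULL
    }
    pieces <- c(pieces, genome_seq)
    cursor <- cursor + gene_len

    models[[i]] <- list(
      gene_id = sprintf("g%04d", i),
      chrom = chrom,
      strand = strand,
      exons = exons,
      orf_aa = orf_aa,
      n_introns = n_ex - 1L
    )
  }
  tail_sp <- random_dna(100)
  genome <- setNames(paste(c(pieces, tail_sp), collapse = ""), chrom)
  list(models = models, genome = genome)
}

#' Draw random single-nucleotide variants inside coding sequence
#'
#' Picks random CDS positions across the supplied gene models and mutates the
#' reference base to a random different base. Used to exercise the
#' stop-gained/stop-lost annotator against a brute-force translator.
#'
#' @param models,genome output of [simulate_gene_models()].
#' @param n number of SNVs.
#' @param seed RNG seed.
#' @return data.frame: chrom, pos (1-based), ref, alt, gene_id.
#' @export
random_cds_snps <- function(models, genome, n = 100, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  genes <- sample(seq_along(models), n, replace = TRUE)
  for (k in seq_len(n)) {
    m <- models[[genes[k]]]
    ex <- m$exons
    cds_pos <- unlist(Map(function(s, e) seq(s, e - 1L), ex$start, ex$end))
    pos0 <- sample(cds_pos, 1)
    ref <- substr(genome[[m$chrom]], pos0 + 1L, pos0 + 1L)
    alt <- sample(setdiff(bases, ref), 1)
    rows[[k]] <- data.frame(chrom = m$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
                            gene_id = m$gene_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build the two parental genome sequences for complementation testing
#'
#' Each gene in the count matrices gets a random sequence of its annotated
#' length; shared genes get the same sequence in both genomes, while genes
#' hosted by only one genome (true PAV) appear only there. Genomes are the
#' concatenation of gene sequences and random spacers on one chromosome.
#'
#' @param sim output of [simulate_counts()].
#' @param seed RNG seed.
#' @return list: `genome_a`, `genome_b` (named character vectors),
#'   `gene_seqs_a`, `gene_seqs_b` (named character vectors of gene sequence).
#' @export
simulate_parent_genomes <- function(sim, seed = 1L) {
  set.seed(seed)
  truth <- sim$truth$complementation
  pav_a <- truth$gene_id[truth$host_genome == "A" & truth$class == "pav_complementation"]
  pav_b <- truth$gene_id[truth$host_genome == "B" & truth$class == "pav_complementation"]
  all_ids <- union(names(sim$gene_lengths_a), names(sim$gene_lengths_b))
  lens <- c(sim$gene_lengths_a, sim$gene_lengths_b)[all_ids]
  seqs <- setNames(vapply(lens, random_dna, ""), all_ids)

  # a genome carries every gene except the PAVs hosted by the other genome;
  # expression-only SPE genes are present in both genomes by construction
  ids_a <- setdiff(all_ids, pav_b)
  ids_b <- setdiff(all_ids, pav_a)
  glue <- function(ids) {
    spacers <- vapply(seq_along(ids), function(i) random_dna(50), "")
    paste(rbind(seqs[ids], spacers), collapse = "")
  }
  list(
    genome_a = setNames(glue(ids_a), "chrA"),
    genome_b = setNames(glue(ids_b), "chrB"),
    gene_seqs_a = seqs[names(sim$gene_lengths_a)],
    gene_seqs_b = seqs[names(sim$gene_lengths_b)]
  )
}
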