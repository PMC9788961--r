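test_that("protein-gene filters apply the ORF and intron rules at their boundaries", {
  mk <- function(id, orf_aa, n_exons) {
    list(gene_id = id, chrom = "c", strand = "+",
         exons = data.frame(start = 0, end = 3 * (orf_aa + 1)),
         orf_aa = orf_aa, n_introns = n_exons - 1L)
  }
  models <- list(mk("a", 74, 2), mk("b", 75, 2), mk("c", 200, 1))
  f <- filter_protein_genes(models, min_orf_aa = 75, require_introns = TRUE)
  expect_equal(vapply(f, `[[`, "", "gene_id"), "b")  # 74 aa and intronless drop
  expect_length(filter_protein_genes(list()), 0)
  bad <- list(list(gene_id = "m", chrom = "c", strand = "+",
                   exons = data.frame(start = 0, end = 100),
                   orf_aa = NULL, n_introns = 1L))
  expect_warning(filter_protein_genes(bad), "multiple of 3")
})

test_that("hand-constructed stop gains/losses are annotated on both strands", {
  # plus strand: ATG TAC TAA; C -> A at codon-2 position 3 makes TAA
  genome <- c(chrP = "ATGTACTAA", chrM = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGTACTAA"))))
  mP <- list(gene_id = "gP", chrom = "chrP", strand = "+",
             exons = data.frame(start = 0, end = 9), orf_aa = 2, n_introns = 0)
  mM <- list(gene_id = "gM", chrom = "chrM", strand = "-",
             exons = data.frame(start = 0, end = 9), orf_aa = 2, n_introns = 0)
  snpP <- data.frame(chrom = "chrP", pos = 6, ref = "C", alt = "A")
  out <- annotate_stops(snpP, list(mP), genome)
  expect_equal(out$effect, "stop_gained")
  expect_equal(out$codon_ref, "TAC")
  expect_equal(out$codon_alt, "TAA")
  # same substitution through the minus-strand gene: transcript TAC -> TAA.
  # chrM = TTAGTACAT; transcript codon 2 spans chrM positions 4-6 (TAC on
  # the transcript); genome G -> T at pos 4 is transcript C -> A
  snpM <- data.frame(chrom = "chrM", pos = 4, ref = "G", alt = "T")
  outM <- annotate_stops(snpM, list(mM), genome)
  expect_equal(outM$effect, "stop_gained")
  # stop retained: TAA -> TGA on the transcript is no call
  # plus strand codon 3 (TAA), A -> G at pos 8 gives TGA
  snp_ret <- data.frame(chrom = "chrP", pos = 8, ref = "A", alt = "G")
  expect_equal(nrow(annotate_stops(snp_ret, list(mP), genome)), 0L)
  # stop lost: TAA -> CAA
  snp_lost <- data.frame(chrom = "chrP", pos = 7, ref = "T", alt = "C")
  expect_equal(annotate_stops(snp_lost, list(mP), genome)$effect, "stop_lost")
  # intronic SNP: no call
  mI <- list(gene_id = "gI", chrom = "chrP", strand = "+",
             exons = data.frame(start = c(0, 6), end = c(3, 9)),
             orf_aa = 1, n_introns = 1)
  snpI <- data.frame(chrom = "chrP", pos = 5, ref = "C", alt = "G")
  expect_equal(nrow(annotate_stops(snpI, list(mI), genome)), 0L)
  # reference mismatch is a data error naming the position
  snp_bad <- data.frame(chrom = "chrP", pos = 6, ref = "G", alt = "A")
  expect_error(annotate_stops(snp_bad, list(mP), genome), "chrP:6")
})

test_that("every single-base change of a stop codon is classified correctly", {
  # enumerate all 9 substitutions of each stop codon in a minimal gene
  for (stop in c("TAA", "TAG", "TGA")) {
    genome <- setNames(paste0("ATGAAA", stop), "chr")
    model <- list(gene_id = "g", chrom = "chr", strand = "+",
                  exons = data.frame(start = 0, end = 9), orf_aa = 2, n_introns = 0)
    for (off in 1:3) {
      ref <- substr(stop, off, off)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        mutated <- stop
        substr(mutated, off, off) <- alt
        out <- annotate_stops(data.frame(chrom = "chr", pos = 6 + off,
                                         ref = ref, alt = alt),
                              list(model), genome)
        if (mutated %in% c("TAA", "TAG", "TGA")) {
          expect_equal(nrow(out), 0L)           # stop retained
        } else {
          expect_equal(out$effect, "stop_lost")
        }
      }
    }
  }
})

test_that("annotator agrees with a brute-force mutant-CDS translator", {
  gm <- simulate_gene_models(n_genes = 80, seed = 101)
  snps <- random_cds_snps(gm$models, gm$genome, n = 600, seed = 102)
  calls <- annotate_stops(snps, gm$models, gm$genome)
  oracle <- stop_oracle(snps, gm$models, gm$genome)
  expect_setequal(paste(calls$pos, calls$gene_id, calls$effect),
                  paste(oracle$pos, oracle$gene, oracle$effect))
  strands <- vapply(gm$models, `[[`, "", "strand")
  names(strands) <- vapply(gm$models, `[[`, "", "gene_id")
  expect_setequal(unique(strands[calls$gene_id]), c("+", "-"))
})

test_that("stop MAF filter is strictly greater-than", {
  calls <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "c", pos = 1:3,
                      ref = "A", alt = "T", gene_id = "g", transcript = "t",
                      effect = "stop_gained", codon_ref = "AAA", codon_alt = "TAA",
                      stringsAsFactors = FALSE)
  gt <- rbind(s1 = rep(c(0, 1), c(80, 20)),   # MAF exactly 0.20 -> dropped
              s2 = rep(c(0, 1), c(70, 30)),   # MAF 0.30 -> kept
              s3 = rep(c(0, 1), c(99, 1)))    # MAF 0.01 -> dropped
  out <- filter_stop_maf(calls, gt, min_maf = 0.20)
  expect_equal(out$snp_id, "s2")
  expect_equal(out$maf, 0.3)
  out0 <- filter_stop_maf(calls, gt, min_maf = 0)
  expect_equal(nrow(out0), 3L)  # all variable sites retained at 0
})
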