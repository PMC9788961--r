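Package: heteropav
Title: Gene Presence/Absence Variation and the Dominance Model of Heterosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking gene presence/absence variation (PAV)
    to hybrid vigour in crop populations. Calls presence/absence genotypes per
    100-bp window from aligned read depth, runs mixed-model association with a
    direction-of-effect proportion statistic and block-bootstrap confidence
    intervals, fits ridge-regression BLUP genomic prediction with a
    present-allele sweep and replicated k-fold cross-validation, annotates
    premature-stop SNPs from gene models, detects cross-genome expression
    complementation in hybrids, performs negative-binomial differential
    expression and binomial-logistic differential splicing on the percent
    spliced index, classifies inheritance mode (additive, dominant,
    over-/under-dominant), and integrates expression with splicing by sparse
    partial least squares. Includes a synthetic-data generator with planted
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
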