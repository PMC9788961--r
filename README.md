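# heteropav

Does losing whole chunks of the genome make crop inbreds worse — and does
getting them back explain why hybrids are better? `heteropav` is an R
package for testing the **dominance model of heterosis** through **gene
presence/absence variation (PAV)**: genomic segments carried by some lines
and entirely missing in others. It is aimed at quantitative and population
geneticists working with resequenced crop diversity panels (the motivating
system is cultivated sunflower) together with parent × F1-hybrid
transcriptome experiments.

## What it computes

**Genotyping and association**

- Presence/absence calls per 100-bp window from windowed read depth
  (present ⇔ depth > 0), haploid treatment, MAF ≥ 5% filter.
- Mixed-model association (single REML fit of
  `y ~ N(Xb, σ²g K + σ²e I)` via spectral decomposition, then per-marker
  GLS with fixed variance components), with SNP-PC, kinship and
  read-depth covariates.
- The **direction-of-effect statistic**: among markers with p < 0.05, the
  proportion whose *presence* allele increases the trait, with a 95% CI
  from 2000 bootstrap resamples of 1-Mb genomic blocks. Under the
  dominance model this proportion exceeds the random expectation of 0.5
  for heterosis-related traits.
- Stop-gained / stop-lost SNV annotation from GFF3 + FASTA (strand-aware
  codon reconstruction), ORF ≥ 75 aa and intron filters, MAF > 20%.

**Genomic prediction**

- RR-BLUP (`y = 1β + Zg + ε`, `Z ∈ {−1, +1}`) with REML-estimated ridge
  parameter and dual-form marker effects.
- A 0–100% **present-allele sweep**: predict synthetic genotypes with an
  increasing fraction of presence alleles and regress prediction on the
  percentage — a positive slope means presence alleles raise the trait.
- Replicated k-fold cross-validation (k = 2, 5, 10 × 20 repeats) scored
  by Pearson r and R² of observed ~ predicted.

**Transcriptomics of the parent/hybrid trio**

- TPM, CPM filtering, TMM normalization, and a negative-binomial GLM
  engine (tagwise dispersion shrunk toward the common value, LRT,
  FDR < 0.01 and |log2FC| > 1 calls).
- **Expression complementation**: genes expressed (TPM > 2) in one parent
  and the hybrid but silent (TPM < 0.1) in the other parent, confirmed
  truly missing by homology search (E < 1e-100, identity > 95%,
  length ≥ 200 bp, bit score ≥ 200) against the silent parent's genome.
- Alternative-splicing event classification (IR, ALTD, ALTA, ALTP, SKIP,
  CRIN, CREX), junction-support counting, PSI, and differential splicing
  by binomial logistic regression (FDR < 0.01, |log2FC| > 0.25).
- **Inheritance-mode classification** of hybrid expression and PSI:
  additive, dominant (high/low parent), over-dominant, under-dominant,
  via a mid-parent model contrast and per-parent tests; Wilcoxon
  rank-sum heterosis tests (exact by enumeration for small groups) for
  morpho-physiological traits.
- Sparse PLS integration of the expression and splicing blocks, with
  component-score correlations and the fraction of negative
  feature-pair correlations.

A first-class synthetic-data generator (`sim_config()`,
`simulate_depth_windows()`, `simulate_phenotypes()`, `simulate_counts()`,
`simulate_gene_models()`, `simulate_parent_genomes()`) plants all of this
structure with a truth set, so every stage is validated by parameter
recovery.

## Worked example

Simulate a 300-line panel with 300 causal PAV loci where 70% of presence
alleles increase a heterosis-like trait (h² = 0.8), genotype it from
depth, and run the association and prediction chain:

```r
library(heteropav)

cfg <- sim_config(seed = 1, n_samples = 300, n_chromosomes = 20,
                  chrom_length_bp = 50000, n_pav_loci = 300,
                  n_causal_pavs = 300, frac_presence_positive = 0.7,
                  heritability = 0.8)
depth <- simulate_depth_windows(cfg)
pheno <- simulate_phenotypes(depth, config = cfg)

pav <- filter_maf(call_pav(depth), min_maf = 0.05)
pav
#> pav_matrix: 297 windows x 300 samples; MAF range [ 0.053, 0.500 ]

# kinship and PCs from an independent SNP set, depth as covariate
set.seed(1001)
snps <- matrix(rbinom(500 * cfg$n_samples, 1, 0.4), 500)
colnames(snps) <- colnames(depth$depth)
pk <- compute_pca_kinship(snps)
X <- cbind(1, pk$scores[, 1:2], depth = colMeans(depth$depth))

gwa <- run_direction_gwa(pav_encode(pav, "signed"),
                         pheno$phenotypes$heterotic, X, pk$kinship,
                         data.frame(chrom = pav$windows$chrom,
                                    pos = pav$windows$start),
                         n_boot = 2000, seed = 1)
gwa$direction
#> direction summary: 50 significant markers in 20 blocks
#>   prop(presence effect > 0) = 0.620, 95% CI [0.500, 0.750]

Z <- t(pav_encode(pav, "signed"))
fit <- fit_rrblup(pheno$phenotypes$heterotic, Z)
sweep_present_fraction(fit, seed = 2)
#> present-allele sweep: slope 0.03033 per pct (95% CI [0.02673, 0.03393])

cross_validate(pheno$phenotypes$heterotic, Z, k_values = c(2, 5),
               n_repeats = 3, seed = 3)
#> replicated k-fold cross-validation:
#>  k n_runs    mean_r       sd_r   mean_r2      sd_r2
#>  2      6 0.5531912 0.05770283 0.3087951 0.06348568
#>  5     15 0.6317247 0.06261245 0.4027351 0.07872057
```

Reading the output: 62% of the significant PAVs have presence alleles that
increase the trait (planted: 70%; the CI reaches the 0.5 null boundary at
this marker count), the sweep slope is positive — synthetic genotypes
richer in presence alleles are predicted to score higher — and PAV markers
alone predict the trait with r ≈ 0.63 under 5-fold cross-validation.

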