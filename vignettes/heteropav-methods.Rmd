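---
title: "Methods: presence/absence variation and the dominance model of heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence variation and the dominance model of heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteropav)
```

# Scope and scientific background

`heteropav` tests a specific mechanistic account of hybrid vigour
(heterosis): the dominance model, in which heterosis arises because each
inbred parent carries deleterious alleles — here, wholesale *absences* of
genomic segments — that are masked in the F1 by the functional copy
inherited from the other parent. The package implements the full chain of
evidence for this account in a crop diversity panel and a parent/hybrid
trio:

1. **PAV genotyping**: presence/absence calls per 100-bp window from
   windowed read depth.
2. **Direction-of-effect association**: mixed-model GWA of PAV markers
   against traits, then the proportion of nominally significant markers
   whose *presence* allele increases the trait, with a genomic
   block-bootstrap CI against the 0.5 random expectation.
3. **Premature-stop annotation**: stop-gained/stop-lost SNVs as a second
   class of large-effect deleterious variants.
4. **Genomic prediction**: RR-BLUP on signed PAV markers, a 0–100%
   present-allele sweep whose regression slope summarizes the aggregate
   direction of PAV effects, and replicated k-fold cross-validation.
5. **Expression complementation**: genes expressed in one parent and the
   hybrid but silent in the other parent, confirmed missing from the
   silent parent's genome by homology search.
6. **Differential expression / splicing** and **inheritance-mode
   classification** (additive, dominant, over-/under-dominant) of hybrid
   expression and percent-spliced-index (PSI).
7. **Sparse PLS** integration of the expression and splicing blocks.

Every stage is exercisable on synthetic data with a machine-readable truth
set, so the package's claims are validated by parameter recovery rather
than by re-running the original field data.

# The synthetic-data generator

`sim_config()` fixes the study conditions once. Defaults emulate the
design the pipeline targets: a diversity panel of 288 lines resequenced at
5–25x (`mean_depth_range`), 100-bp windows, absence-allele frequencies
drawn from 0.05–0.5, and a transcriptome experiment with three genotype
groups (two parents, one hybrid) by two watering conditions (FTSW 1.0
control, 0.1 drought) with three replicates each.

Choices worth making explicit:

* **Depth distribution.** Window depth is negative binomial
  (`depth_dispersion` = 0.2) around a sample-specific mean; overdispersed
  coverage is what real short-read data look like and it stresses the
  depth covariate used in association. Windows deleted in a carrier are
  *exactly* zero; additionally a dropout process zeroes 0.5% of truly
  present windows, the "missed by chance" genotyping noise a depth rule
  must tolerate.
* **Count dispersion.** RNA-seq counts use NB dispersion 0.02 (biological
  CV ≈ 14%), the realistic scale for replicated inbred lines and their F1
  in controlled conditions; outbred or field material would be several
  times noisier, and the power statements in the test suite would not
  carry over to such data.
* **Hybrid PAV genotype** is the union of parental presence (presence
  dominant) — the premise of the complementation analysis.
* **Planted classes are disjoint** (complementation, expression-only
  single-parent expression, over-/under-dominant, dominant, condition-DE
  genes), so recovery can be scored without ambiguity.
* **Coordinates** are 0-based half-open internally (window ids
  `chrom:start-end`); GFF3 and VCF are 1-based at the file boundary.

What the generator does *not* emulate: mapping artefacts and repeat-driven
false absences, realistic linkage disequilibrium beyond block-level
correlation, GC/length biases in counts, and isoform-level read
assignment. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery, not robustness to every real
data pathology.

# PAV genotyping

A window is *present* when depth > 0 and *absent* when depth = 0; lines
are treated as haploid for this call. Windows absent in all samples are
uninformative and dropped; remaining windows are filtered on minor allele
frequency with an inclusive boundary (MAF ≥ 5% keeps a window with
exactly 5 absent calls in 100 samples). Three marker encodings are
provided: haploid {0,1}, diploid homozygote {0,2} (association), and
signed {−1,+1} (prediction).

# Mixed-model association and the direction statistic

The null model `y ~ N(Xb, σ²g K + σ²e I)` is fitted by REML through the
spectral decomposition of K projected off the covariates; the variance
ratio δ = σ²e/σ²g is located on a 100-point log grid spanning 1e-5–1e5 and
refined by golden-section search (tolerance 1e-10). Markers are then
scored by GLS with the variance components fixed from the null fit — the
single-eigendecomposition approximation that makes the scan O(nm) — with
two-sided p-values from the t distribution on n − rank(X) − 1 df.
Covariates follow the study design: intercept, the first two SNP-based
principal components, and per-sample mean read depth (absence calls are
depth-confounded, so depth must be in the model). Kinship defaults to the
identity-by-state proportion; a centered GRM (`method = "grm"`) is the
right choice when the variance ratio itself is to be interpreted as
heritability, and is what the recovery simulations use. Kinship should be
computed from an *independent*, LD-pruned SNP set, not from the tested PAV
markers — building K from the markers under test absorbs their own signal
(proximal contamination) and collapses power; the acceptance simulations
reproduce exactly this design decision.

The direction statistic selects markers at p < 0.05, computes the
proportion with a positive presence-allele effect, and bootstraps 1-Mb
blocks of selected markers (2000 replicates, percentile 95% CI) to respect
local linkage. Exact-zero effects are excluded from both numerator and
denominator (a measure-zero case, but explicit). "Differs from 0.5" means
the CI excludes 0.5; an exact binomial test is reported alongside for
reference. The bootstrap resamples *blocks of markers*; a sign-permutation
variant would be an alternative reading of "block bootstrap permutations"
and is intentionally not the default.

# RR-BLUP prediction, the present-allele sweep, and cross-validation

The model `y = 1β + Zg + ε` with i.i.d. marker effects is fitted on
z-scored traits; the ridge parameter λ = σ²e/σ²g is REML-estimated via the
spectral decomposition of ZZᵀ (an n×n problem however many markers), and
effects are recovered in dual form `g = Zᵀ(ZZᵀ + λI)⁻¹(y − 1β̂)`. The dual
and primal ridge solutions agree to 1e-8, which the test suite checks
explicitly.

The sweep predicts the phenotype of synthetic genotypes whose loci are
independently present with probability p for p = 0, 1, …, 100% (101 grid
points — both endpoints are kept and are deterministic: all-absent and
all-present) and reports the OLS slope of prediction on percentage. One
genotype draw per grid point is the default (`n_draws_per_point = 1`);
averaging reduces Monte-Carlo noise but was not part of the original
design. Note that the within-sweep CI of the slope reflects only draw
noise around Σĝ; with direction-balanced effects the slope is only zero
*in expectation across training replicates*, which is how the symmetric
case is tested.

Cross-validation assigns unique sample ids to k bins (duplicated ids are
co-assigned — a leakage guard for repeated measurements of one line),
trains on k−1 bins and scores the held-out bin by Pearson r and by R² of
observed ~ predicted, repeated 20 times by default. Under a null trait the
per-fold r values within one simulation are correlated (they share y), so
null calibration must be judged across independent simulations.

# Stop-codon annotation

Only the two effect classes used downstream are implemented: stop_gained
and stop_lost, under the standard nuclear code. The CDS is spliced
strand-aware (minus-strand transcripts reverse-complemented), the affected
codon is located and the substitution classified. Multi-transcript genes
are called if any retained transcript shows the effect (the most inclusive
reading). Gene filters: ORF ≥ 75 aa (strictly-below excluded) and, by
default, at least one intron. The marker-level MAF filter is strict
(> 20%), computed as allele-count frequency over called genotypes, with
0.5 dosages contributing half an allele — the panel's residual
heterozygosity makes homozygote/heterozygote distinction unreliable, so
no attempt is made to resolve it. The annotator is regression-tested for
exact agreement with a brute-force oracle that rebuilds and translates the
entire mutant CDS of every SNP on hundreds of random genes, both strands.

# Differential expression

The NB GLM engine uses log-link models with log effective-library-size
offsets (trimmed-mean-of-M normalization: 30% M-trim, 5% A-trim,
inverse-variance weights). Dispersion is estimated by profile likelihood
(common) and per-gene with shrinkage toward the common value through a
weighted likelihood with a fixed prior weight of 10 pseudo-genes — a
deterministic, reproducible stand-in for empirical-Bayes moderation. Tests
are likelihood-ratio chi-squared with 1 df; calls default to FDR < 0.01
and |log2FC| > 1. A fixed-dispersion mode supports designs without
replication (e.g. a one-sample-per-level stress gradient) and is flagged
in the output. Weak expression is removed by a transparent CPM rule
(≥ 1 CPM in ≥ 3 samples) rather than a data-driven similarity filter; the
rule is a documented parameter, not a tuned constant.

# Expression complementation

Quantified against *each* parental genome separately, a gene's group state
is expressed (mean TPM > 2), silent (mean TPM < 0.1), or ambiguous
(excluded from candidacy — the conservative treatment of the undefined
mid-zone). A candidate is expressed in the host parent and hybrid and
silent in the other parent, per condition. Candidates are confirmed as
true presence/absence polymorphisms only if a homology search of the gene
against the silent parent's genome yields *no* qualifying hit (E < 1e-100,
identity > 95%, length ≥ 200 bp, bit score ≥ 200); a qualifying hit means
the gene is present but unexpressed and the candidate is rejected. For
synthetic genomes the package ships an exact 31-mer matcher that reports
maximal runs ≥ 200 bp in the same tabular dialect as an external
aligner, so the confirm/reject contract is testable end to end; real data
would use BLASTN output in the standard 12-column format.

# Alternative splicing

Events are classified from strand-aware comparison of intron chains:
intron retention (IR), exon skipping (SKIP), alternative donor/acceptor
(ALTD/ALTA — donor and acceptor are defined in transcription direction,
so the genomic roles swap on the minus strand), alternative position
(ALTP, both ends shifted), cryptic intron/exon (CRIN/CREX), and OTHER.
Junction support requires an exact block-gap match to the event's
junction; IR retention support additionally demands ≥ 8 bp of continuous
alignment on each side of the exon–intron boundary (a junction-ambiguity
guard). PSI = alt/(alt + const) per sample. The ≥ 3 alternative reads
filter is applied per gene by default, as a gene-level rule, with a
per-event mode available.

Differential splicing is a per-event binomial logistic regression of
(alt, const) on condition with a likelihood-ratio test; the plain binomial
is the default (a quasi-binomial F-test option exists because replicate
overdispersion inflates significance). The reported log2FC is on pooled
PSI with a pseudo-fraction of 0.01 — the fold-change basis is genuinely
underdetermined (PSI, odds, or counts); pooled-PSI was chosen as the most
interpretable and is configurable. Calls: DASU/DASD at FDR < 0.01 and
|log2FC| > 0.25.

# Inheritance classification

The hierarchy: (1) hybrid vs mid-parent; non-significant (BH-adjusted
p ≥ 0.05) is additive. For expression the mid-parent null is a *model
constraint* — log µ_hybrid = (log µ_A + log µ_B)/2 in the NB GLM — rather
than construction of pseudo-mid-parent samples; the constraint is the
statistically clean reading, and the comparison is on the log scale. For
splicing the constraint is p_hybrid = (p_A + p_B)/2 on the proportion
scale, maximized numerically. (2) Non-additive features are tested against
the high and low parent (parent roles decided by fitted values, so calls
are invariant to parent labels): significantly above the high parent is
over-dominant, below the low parent under-dominant, distinguishable from
exactly one parent is dominance at the other's level, distinguishable
from neither is reported as unclassified rather than silently merged.

Phenotypic heterosis uses two-sided Mann–Whitney rank-sum tests of the
hybrid against each parent — exact by full enumeration of rank
assignments (ties via midranks) for group sizes ≤ 10, normal
approximation with tie correction above — plus mid-parent heterosis
(F1 − MP)/MP from group means.

# Sparse PLS

Per component, loadings maximize uᵀXᵀYv with sparsity imposed by
soft-thresholding at the magnitude of the (keep+1)-th largest entry, which
hits the requested nonzero count deterministically; iteration stops at a
relative change below 1e-6 or 500 iterations. With no thresholding the
solution equals the leading singular vectors of XᵀY. Canonical-mode
deflation (each block on its own scores) is the default, with regression
mode available; scaling is unit-variance by default. The sign
indeterminacy is resolved by making the largest-magnitude X loading
positive, and all reported summaries are invariant to simultaneous sign
flips. Upstream feature pre-selection mirrors the "top 500 by FDR"
convention (`top_features()`); defaults keepX = keepY = 50,
2 components.

# Problem sizes, numerics, and degenerate inputs

The validation suite runs at desk scale, chosen to exercise the asymptotic
regime of each method while completing quickly: REML recovery at n = 300
samples × 1000 markers over 20 seeds per heritability level;
direction-of-effect coverage on 20 replicate genomes of 20 chromosomes
with 300 planted causal loci; differential expression on 2000-gene
matrices (20 null simulations); splicing power at 100 reads/event with 3
replicates; 500 random genes for the annotation oracle. Degenerate inputs
are handled explicitly: all-zero samples are flagged, monomorphic and
collinear markers skipped with a message, flat REML likelihoods (K ≈ I)
warned as unidentifiable, zero-selected-marker direction summaries
returned as explicit empty results, and zero-read groups skipped per
event. The generator parameters above were fixed from the study design
before the validation bands were frozen and are not tuned to them.

# Known limitations

* The EMMAX-style single-variance-component approximation understates
  uncertainty for markers in strong LD with large-effect loci.
* The depth rule cannot distinguish true absence from alignment failure
  due to sequence divergence; in real data this is accepted as genotyping
  noise, and the dropout process models only its random component.
* The binomial DAS model ignores replicate overdispersion by default
  (matching the method it implements); use `quasi = TRUE` when replicates
  disagree more than binomially.
* Expression complementation depends on quantification against both
  parental references; cross-mapping bias between diverged genomes is not
  modelled by the generator.
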