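---
title: "Regional polygenic transmission, expression and chromatin contact with sptdt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional polygenic transmission, expression and chromatin contact with sptdt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptdt)
```

## The problem

Common polygenic variation is the largest genetic influence on many
neurodevelopmental traits, but a genome-wide polygenic score (PGS) says
nothing about *where* in the genome that influence is concentrated. sptdt
implements a family-based scan for regional excesses of polygenic signal:
the stratified polygenic transmission disequilibrium test (S-pTDT),
together with the regional statistics needed to follow such a signal into
gene composition, gene expression and chromatin contact.

## The transmission model

For one family with a scored child and two scored parents, the pTDT
deviation is

$$d_i \;=\; \frac{\mathrm{PGS}_{C,i} - \mathrm{PGS}_{MP,i}}
                {\widehat{\sigma}(\mathrm{PGS}_{MP})},
\qquad \mathrm{PGS}_{MP,i} = \tfrac12(\mathrm{PGS}_{M,i} + \mathrm{PGS}_{F,i}),$$

where the normalizer is the sample standard deviation (n − 1 denominator;
the choice of denominator is not forced by the definition, so we fix it
and keep it consistent everywhere) of the midparent scores over the
analyzed families. Under Mendelian transmission without ascertainment,
$E[d_i] = 0$ regardless of assortative mating or population
stratification, because each parent transmits either allele with equal
probability — this within-family property is what makes the test immune
to the confounders that plague population-level PGS associations.
Ascertaining children on the phenotype induces $E[d_i] > 0$
("over-transmission"). The cohort-level test is a one-sample two-sided
Student's t-test of the deviations against zero (`ptdt_test()`).

The stratified variant (S-pTDT) is the identical computation on a PGS
restricted to one genomic partition's SNPs, with the midparent normalizer
recomputed per partition. Because the linear score is additive, stratified
scores over any disjoint SNP cover sum exactly to the genome-wide score —
the package's core conservation invariant — and the normalization makes
deviations invariant to adding a constant to every score or rescaling all
weights by a positive factor.

## Partitioning the genome

Two partition families are supported:

* **SNP-count blocks** (`make_snp_count_partitions()`): consecutive
  disjoint blocks of exactly *k* scoring SNPs per chromosome, counted
  from either the chromosome start or end; a leftover run shorter than
  *k* at the non-anchored end is unassigned. Scanning several block sizes
  (2,000–6,000 SNPs) from both anchors surveys regional transmission at
  overlapping granularities.
* **Fixed-length windows** (`make_fixed_length_partitions()`): adjacent
  windows of a constant length (33 Mb in the worked analyses) from each
  chromosome start, the trailing remainder discarded. These provide
  length-matched controls for any single region of interest.

Coordinates are 0-based half-open for all intervals (BED convention) and
1-based for SNP positions (VCF convention); the SNP at position *p*
occupies the 0-based base *p* − 1. SNP-count partitions span the first
and last member SNP — the simplest reproducible bound, affecting only the
length covariate below.

**Gap capping.** Partition length enters the transmission model as a
covariate, but a partition spanning a SNP desert (for example a
centromere) is not really "long" in linkage-disequilibrium terms. The
effective length (`effective_length()`) therefore sums consecutive
inter-SNP gaps capped at 1 Mb (the default `gap_cap`, roughly the scale
beyond which LD has decayed); flanks outside the first and last member
SNP contribute nothing, and the raw span is retained for reporting.

## Residual z-scores

Bigger partitions carry more of the genome-wide signal, so raw S-pTDT
estimates are regressed (OLS with intercept) on SNP count and effective
length; for fixed-length windows, on SNP count alone (length is
constant). Residuals are standardized by their sample standard deviation,
giving each partition a **residual z-score**: how many s.d. more (or
less) transmission it shows than its composition predicts. Numerical
conventions: exactly collinear covariates are dropped with a warning; an
exact fit (zero residual spread) yields all-zero z rather than 0/0; rows
flagged by the scan (e.g. zero midparent variance in an empty partition)
are excluded from the fit and get `NA`.

Two follow-up statistics operate on residual z-scores. The **quadrant
enrichment** (`quadrant_enrichment()`) asks whether annotated partitions
(for instance those containing a GWAS locus) concentrate in the
positive-positive quadrant of two cohorts' z-scores; we use a one-sided
exact binomial test at the overall quadrant fraction, a deliberate design
choice since no standard test is canonical for this construction. The
**block-removal decay** (`block_removal_decay()`) measures how diffuse a
regional signal is: blocks are ranked once by their point estimate (ties
broken by genomic order — the curve plots estimates, so the estimate is
the natural ranking key) and the union is re-tested as the top remaining
block is removed one at a time.

## Regional composition and annotation

`segdup_fraction()` measures the fraction of partition bases covered by
the merged union of an interval set. `peak_density_z()` counts peaks per
partition by peak midpoint — "within the partition" is ambiguous for
boundary-spanning peaks, and the midpoint rule avoids double counting —
then standardizes across partitions and averages over replicates.
`density_residual_test()` regresses a gene-class count (e.g.
cortex-specific genes, the top decile of a specificity statistic with
deterministic id-ordered tie breaking) on total gene count and reports
two-sided normal-tail p-values from the residual z. `enrichment_chi2()`
is the 2×2 chi-square without continuity correction; expected cell counts
below 5 trigger a warning recommending an exact test.

## Regional PGS–expression association

Donor expression (genes × donors, normalized upstream) and per-partition
PGS are standardized **within cohort** before cohorts are concatenated,
so cohort-specific location and scale cannot masquerade as signal. The
per-gene model is

`expression ~ regional PGS + diagnosis + ancestry group + assay type`,

with the PGS coefficient and its t-statistic the quantities of interest;
the mean-region model fits the same covariates to the per-donor average
of the regional gene set. Cohort fixed effects beyond the listed binary
indicators are not added. Note that with only two cohorts a pair of
cohort-aligned indicators is complementary and the design becomes rank
deficient; the fit then fails loudly, naming the collinear column.

Significance of the mean regional effect uses a permutation null
(`permutation_mean_t()`): PGS-to-donor assignment is shuffled
independently within each cohort, leaving expression and covariates
fixed, which preserves the within-cohort PGS distribution exactly. The
one-sided empirical p-value uses the add-one convention
$p = (1 + \#\{\bar t^{null} \le \bar t^{obs}\})/(1 + B)$ — the standard
choice that keeps p-values positive and valid; the alternative without
the added one is anti-conservative.

The CNV contrast (`region_de_contrast()`) compares per-gene
differential-expression statistics of a regional set against all other
genes after dropping every gene whose body overlaps the CNV window
widened by ±100 kb (any-overlap rule) — the cis-regulatory neighborhood
of those genes may be perturbed by creating the deletion itself.

## Hi-C contact statistics

A `contact_matrix()` is one chromosome's symmetric bins × bins matrix at
a stated resolution; bin *b* covers `[(b−1)·res, b·res)`. Intervals snap
to the nearest bin boundary, never to an empty range. Within-region
contact is the mean over the square sub-matrix, either of the
off-diagonal elements (raw count matrices, where the diagonal is
self-ligation dominated) or of all elements (matrices whose diagonal was
zeroed upstream). Per-partition contact is residualized on gene count and
segmental-duplication coverage — both inflate raw contact through mapping
artifacts and genomic activity — with the same standardization machinery
as the transmission model.

The distal enrichment test (`distal_enrichment()`) compares the contacts
of a target rectangle (region A × region B) against **distance-matched
controls**: all same-chromosome bin pairs whose separation lies within
the rectangle's nearest-edge/farthest-edge distance band. Conventions,
fixed here because open/closed endpoints are genuinely ambiguous:
separations are measured between bin starts; the band is inclusive at
both ends; the control set excludes the rectangle itself. Zero entries
typically mark masked hard-to-map bins and are dropped from both sets by
default (`zero_policy = "exclude"`); including them is exposed as a
robustness re-run. The fold is mean(target)/mean(control), invariant to
global rescaling of the matrix, with a two-sided Welch t-test. Only
intra-chromosomal matrices are supported.

## The synthetic-data generator

Every analysis input can be generated under one seeded configuration
(`sim_config()`), so the full pipeline runs and is validated with no
protected data. What it emulates, and how:

* **Trios** (`simulate_trios()`): parent genotypes binomial(2, *f*) with
  frequencies uniform on [0.05, 0.5]; children by fair Mendelian draws.
  Proband status follows the **liability threshold model**:
  $L = \sqrt{h^2}\,Z + \sqrt{1-h^2}\,\varepsilon$ with $Z$ the child's
  PGS standardized by its theoretical moments
  ($\mu = \sum_j 2 f_j w_j$, $\sigma^2 = \sum_j 2 f_j (1-f_j) w_j^2$ —
  theoretical rather than empirical, so batching cannot shift the
  threshold), ascertained when $L$ exceeds a liability quantile.
  Over-transmission is therefore *emergent*, not injected: conditioning
  on $L > t$ gives
  $E[d] \approx \tfrac{1}{\sqrt 2}\sqrt{h^2}\,\lambda(t)$ in midparent
  s.d. units, where $\lambda$ is the truncated-normal mean. The defaults
  — a PGS share of 1.5% of liability variance at top-2% ascertainment
  ($\lambda \approx 2.42$) — imply $E[d] \approx 0.21$, the cohort-scale
  over-transmission magnitude typical of large ascertained autism trio
  collections; the default cohort size is 5,048 families. An
  unascertained sibling (an independent draw from the same parents) can
  be generated per family and is the natural negative control.
* **SNP map** (`simulate_snp_map()`): exponential inter-SNP gaps with
  occasional >1 Mb gaps (so gap capping is exercised); weights centered
  at zero, inflated ×4 inside a designated effect region, concentrating
  score variance there. The default genome is a desk-scale emulation:
  five 132-Mb background chromosomes plus one 90-Mb chromosome labelled
  "16" whose first 33 Mb is the effect region.
* **Expression** (`simulate_expression()`): region genes respond
  linearly (default β = −0.3 per s.d. of regional score) to the donors'
  within-cohort-standardized regional PGS; three cohorts (122
  single-cell, 229 bulk European-ancestry, 193 bulk African-ancestry
  donors) carry distinct mean offsets and noise scales so within-cohort
  standardization has real work to do, plus diagnosis/ancestry/assay
  covariate effects.
* **Hi-C** (`simulate_contact_matrix()`): power-law distance decay
  (default exponent 1) under multiplicative log-normal noise, with a
  boostable within-region block (default ×2 in the convergence scenario)
  and a boostable distal rectangle (default ×3 between a 0.7-Mb locus at
  29.5–30.2 Mb and the first 5.2 Mb — the geometry whose edge-distance
  band is 24.3–30.2 Mb).
* **Annotations** (`simulate_annotations()`): genes with a ×2 regional
  density multiplier and a regional specificity excess;
  segmental-duplication-like intervals; centromeres; a
  differential-expression table with a regional shift.

What it deliberately does **not** emulate: linkage disequilibrium between
sites (the transmission machinery never requires it; LD-block partitions
are exercised with arbitrary block files), population structure,
imputation error, genotyping batch effects, or realistic GWAS effect-size
architecture. Passing tests therefore demonstrate the *statistical
machinery* — calibration of the null, emergence and recovery of planted
regional structure, exactness of the bookkeeping — not robustness to
those real-data complications, which enter the analyses only through the
upstream QC this package assumes.

## Numerical choices

* Sample standard deviations (n − 1) everywhere a normalizer is needed;
  residual z-scores are consequently invariant to row order.
* Score conservation over disjoint covers is exact up to summation
  order; tests assert a 1e-12 relative tolerance.
* Missing dosages impute to 2 × the effect-allele frequency of the
  non-missing samples; a SNP missing everywhere is excluded with a
  warning. (Scoring-time missingness handling is not standardized in the
  field; upstream QC normally keeps missingness below 1%, making the
  choice numerically negligible.)
* Degenerate inputs fail loudly and early: zero midparent variance,
  constant deviations, rank-deficient designs, empty gene sets after
  exclusion, overlapping rectangle regions, empty control bands.
* Ties: top-decile specificity flags and decay-ranking ties break by
  id/genomic order, so every result is reproducible bit for bit.

## Problem sizes used in the shipped checks

The validation suite runs at desk scale, chosen so the full suite
completes in minutes on one CPU while every check retains clear power:
1,000 replicate cohorts of 200 unascertained trios for type-I error
calibration (the exact binomial 95% band at α = 0.05 is 3.7–6.5%);
liability shares {0, 0.15, 0.3} at top-2% ascertainment with deviations
pooled over five replicate cohorts of 300 families per grid point; 200
replicate expression studies with 99 permutations each for permutation
calibration (Kolmogorov–Smirnov screen); 100 replicate contact matrices
for the planted-block ranking; and a 600-family, 3,600-SNP, 22-partition
convergence scenario (`convergence_config()`) in which the effect region
is expected to top the transmission and contact rankings while its
regional score associates negatively with regional expression — the
qualitative three-way convergence, asserted as rankings and signs, never
as effect sizes.

## Limitations

* No weight estimation: SNP weights are an input (from any external
  GWAS + shrinkage pipeline); no genotype imputation, phasing or
  ancestry inference; autosomes only.
* No liftover: all coordinate inputs must share one genome build; and
  coordinates must stay below 2³¹, which every real chromosome does.
* The case/pseudocontrol transmission variant and count-level expression
  normalization (VST and relatives) are upstream of this package's
  inputs.
* The quadrant enrichment p-value is one defensible choice among
  several; compare like with like across analyses.
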