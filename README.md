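# sptdt: stratified polygenic transmission disequilibrium and regional genomic association

Genome-wide polygenic scores (PGS) capture a trait's common-variant
influence but say nothing about where in the genome that influence is
concentrated. **sptdt** is a toolkit for family-based regional polygenic
analysis: it locates genomic regions carrying an excess of a trait's
polygenic influence using parent–child trios, and follows such signals
into gene composition, gene expression and chromatin contact. It is
aimed at statistical geneticists working with ascertained trio cohorts
(e.g. autism family collections) and the brain expression and Hi-C
resources those analyses draw on.

## The statistic

For family *i*, with child score PGS<sub>C,i</sub> and midparent score
PGS<sub>MP,i</sub> = (PGS<sub>M,i</sub> + PGS<sub>F,i</sub>)/2, the pTDT
deviation is

&nbsp;&nbsp;&nbsp;&nbsp;d<sub>i</sub> = (PGS<sub>C,i</sub> − PGS<sub>MP,i</sub>) / sd(PGS<sub>MP</sub>)

Under Mendelian transmission E[d] = 0 irrespective of population
stratification or assortative mating; ascertaining children on the
phenotype makes E[d] > 0 ("over-transmission"). The cohort test is a
one-sample two-sided Student's t-test of the deviations. The
**stratified** test (S-pTDT) is the same computation on a PGS restricted
to one genomic partition's SNPs (SNP-count blocks or fixed-length
windows), with per-partition estimates residualized on SNP count and
gap-capped partition length and standardized into residual z-scores —
how much more transmission a region shows than its composition predicts.

Companion statistics: quadrant enrichment of annotated partitions across
two cohorts (exact binomial), signal decay under successive removal of
the most over-transmitted sub-blocks, segmental-duplication coverage and
peak-density annotation, regional PGS–expression association with a
within-cohort permutation null, a CNV regional differential-expression
contrast with a ±100 kb exclusion flank, and Hi-C within-region contact
z-scores plus a distal rectangle enrichment test against
distance-matched controls. A seeded synthetic-data generator (liability
threshold trio ascertainment, distance-decay contact matrices, planted
regional effects) produces every input class, so the full pipeline runs
without access-controlled data.

## Worked example

Simulate a complete study in which one region ("16", first 33 Mb)
concentrates score variance, trios are ascertained through a liability
threshold, regional expression responds negatively to the regional
score, and the region's chromatin contact block is elevated — then run
the three analysis arms:

```r
library(sptdt)

study <- simulate_study(convergence_config(seed = 7))

# genome-wide transmission in the ascertained probands
scores <- score_samples(study$trios$dosages, study$snps)
ptdt_test(ptdt_deviations(trio_scores(scores, study$trios$pedigree)))
#> pTDT: mean deviation 0.5509 (se 0.0394), t = 13.989, p = 1.11e-38, n = 600

# regional scan over 33-Mb partitions
scan <- residual_zscores(
  sptdt_scan(study$strat, study$trios$pedigree, study$partitions),
  covariates = "n_snps")
head(scan[order(-scan$residual_z),
          c("partition_id", "estimate", "se", "residual_z")], 3)
#>    partition_id  estimate         se residual_z
#> 21       16_w01 0.3611762 0.04260715  3.4182069
#> 16        4_w04 0.1525141 0.04177715  0.9757801
#> 11        3_w03 0.1361625 0.03986879  0.8830308

# all three analysis arms at once
res <- analyze_study(study)
#> region 16_w01: S-pTDT rank 1, expression beta -0.275 (p = 5.4e-148),
#>                contact rank 1
```

The genome-wide over-transmission (0.55 s.d. at this desk-scale
liability share) concentrates in the effect-region partition `16_w01`,
which tops the residual z ranking (z = 3.42) while the other partitions
sit near expectation; the same region's score associates negatively with
its genes' expression, and it tops the covariate-corrected contact
ranking — the three-way convergence the scenario plants.

A thin command-line front end wraps the same functions:

```sh
sptdt simulate --scenario convergence --seed 7 --out study/
sptdt scan --scores study/stratified_scores.tsv --ped study/pedigree.tsv \
           --partitions study/partitions.tsv --covars n_snps --out scan.tsv
sptdt hic-rect --matrix study/hic_16.coo.tsv --resolution 1000000 \
               --n-bins 90 --region-a 2000000-5000000 \
               --region-b 40000000-44000000 --out rect.json
```

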