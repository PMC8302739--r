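---
title: "Methods: C+T polygenic risk scores with APOE-aware models"
author: "ctprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C+T polygenic risk scores with APOE-aware models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctprs)
```

## Scope and data model

`ctprs` builds and evaluates clumping-and-thresholding (C+T) polygenic risk
scores for Alzheimer's disease, with the *APOE* locus treated as a
first-class modelling decision rather than just another variant. The central
containers are S4 classes: `SummaryStats` (a position-sorted table of
biallelic GWAS association records), `GenotypePanel` (a
`SummarizedExperiment` whose `dosage` assay holds effect-allele dosages,
variants × samples), `ScoreSet` (per-sample score values with an explicit
processing stage), and `TailTable` (the 2×2 case/control extreme-tail
counts).

## Allele harmonisation

Before any scoring, `harmonizePanel()` restricts panel and summary
statistics to shared variants and orients every dosage to count the
statistics' effect allele: swapped allele pairs map dosage d to 2 − d,
strand flips are resolved by base complement, and strand-ambiguous A/T and
C/G variants are removed outright. Ambiguous-variant removal is standard PRS
practice: for those pairs a strand flip is indistinguishable from an allele
swap, so no orientation can be trusted. The operation is idempotent, and all
removals are counted in a log attribute. Coordinates are 1-based with closed
intervals throughout (the VCF convention); the *APOE* region default,
chr19:44,400,000–46,500,000, is a configurable `GRanges` applied to whatever
genome build the inputs share, since the region is specified only at Mb
resolution.

## The C+T engine

`clumpVariants()` implements greedy clumping: candidates are sorted by
ascending p-value (ties broken deterministically by chromosome then
position), the best remaining variant becomes an index, and every remaining
variant on the same chromosome within ±1000 kb whose squared dosage
correlation with the index strictly exceeds 0.1 is removed. Both parameters
are configurable (`clumpSpec()`; r² thresholds of 0.01 and 0.001 are common
stricter settings). r² is the squared Pearson correlation over
pairwise-complete samples, defined as 0 for constant vectors; LD is
estimated on the analysis panel itself unless a dedicated reference panel is
supplied. `scorePanel()` then computes Σ βⱼ·Gᵢⱼ per sample, imputing missing
dosages as 2·eaf (the PLINK scoring default); a missing dosage without a
recorded frequency is an error rather than a silent drop.

## APOE coding and the five models

The ε2/ε4 allele counts are coded from unphased rs429358 and rs7412
genotypes: n(ε4) = #C at rs429358, n(ε2) = #T at rs7412. The ambiguous
CT/CT double heterozygote is resolved as ε2/ε4 — the standard unphased
convention; the rare ε1 haplotype is not modelled, and genotype combinations
implying more than two isoform alleles are rejected. `modelSpec()` fixes the
five named models: ORS.full and ORS.no.APOE at pT ≤ 1e-5, PRS.full and
PRS.no.APOE at pT ≤ 0.1, and PRS.AD = PRS.no.APOE + (−0.47)·n(ε2) +
1.12·n(ε4). The SNP component of PRS.AD enters unstandardised, on the raw
log-odds scale, so its units match the fixed APOE weights; the alternative
reading of PRS.AD as a *two-predictor regression* (PRS.no.APOE and the APOE
term as separate covariates with fitted coefficients) is supported
explicitly by `fitLogistic()`, which accepts any number of score predictors.
`buildModel()` wires the pipeline in the order region-exclusion → clump →
threshold → score, and reports the number of contributing SNPs (+2 for the
two APOE SNPs in PRS.AD).

## Standardisation

All scores are PC-adjusted and then z-scored. `genotypePCs()` decomposes the
per-variant centred, unit-variance dosage matrix (mean imputation for
missing values, constant variants dropped, deterministic sign convention);
the number of components defaults to k = 10 and is fully configurable, since
no single value is canonical — it is not even clear a priori whether PCs
should be recomputed per model, so the package simply exposes both choices.
`residualizeScores()` takes least-squares residuals, which are exactly
orthogonal to every component. Two standardisation modes exist:

* **in-sample** — z-scored by the sample's own mean and SD (n − 1
  denominator everywhere, the sample-statistics convention);
* **population-referenced** — the study panel is merged with a population
  panel over shared harmonised variants, the model score and PCs are
  computed on the merged data, and z-scores use the mean and SD of the
  population subsample only.

Because a case-control sample is a mixture of two shifted distributions, its
SD exceeds the population SD, so population referencing flags at least as
many |z| > 2 extremes — a property asserted across 20 seeded simulated
cohorts in the test suite. The population subsample itself standardises to
mean 0, SD 1 exactly. References are exportable as small JSON records so a
cohort can be standardised against a stored population reference.

## Tail statistics

`classifyExtremes()` uses strict inequalities ("exceeding ±2 SD"): z
exactly at the cutoff is not an extreme. The tail table's odds ratio is
(a·d)/(b·c) with a Woolf 95% CI on the log scale; whenever any cell is zero
the Haldane correction adds 0.5 to all four cells before both the OR and the
CI are computed — this convention reproduces the published tail odds ratios
(100, 124, 39, ...) exactly at printed precision. AUC is the rank-based
concordance probability (ties count one half), reported in percent;
pseudo-R² is Nagelkerke's, chosen as the field default for logistic fits
where only "variance explained" is specified. Complete separation in
logistic fits is detected and reported from a lightly ridge-penalised
fallback with a warning. `printedPrecision()` encodes the publication
rounding conventions (ORs ≥ 10 to integers, AUC to one decimal, R² to two).

## The simulation study

`simulateCohort()` draws independent per-SNP genotypes binomial(2, f) for
three subgroups of a 10,000-case / 10,000-control cohort:

* an **ε4-like SNP** (placed inside the *APOE* region) at f = 0.355 in
  labelled cases, 0.36 in *putative* controls and 0.142 in the remaining
  controls. The putative fraction, 28% of controls, is the Hardy–Weinberg
  penetrance mixture `hiddenCaseFraction(0.142, 0.91, 0.47, 0.20)` — the
  expected share of controls who will develop disease after the observation
  window. The anchor frequencies come from inverting the mixture system
  (whole-sample frequency 0.216, allelic OR 3.326, 34% cases) via
  `solveCaseControlFreqs()`, and the pooled frequency of labelled plus
  hidden cases recovers ≈ 0.356;
* **67 oligogenic SNPs** with supplied (frequency, β) pairs; case
  frequencies are shifted from control frequencies on the odds scale by β.
  The packaged default table is a *synthetic stand-in* (frequencies in
  [0.05, 0.45], |β| in [0.05, 0.25], mixed signs, synthetic p ≤ 1e-6)
  because the real effect-size table sits behind a controlled-access
  accession; users holding the real table can supply it via
  `cohortConfig(oligoSnps = ...)`. The qualitative conclusions below do not
  depend on the stand-in's particular values;
* **10,000 weak polygenic SNPs** with MAF ~ U(0.01, 0.45) and reported
  per-SNP odds ratios decreasing linearly from 1.005 to 1 (cases vs true
  controls) and 1.003 to 1 (putative controls vs true controls), p-values
  spread over (1e-5, 0.1].

**Risk-direction alignment.** The weak-SNP design states that 70%/30% of
SNPs have a minor/major risk allele while all reported odds ratios are ≥ 1.
We implement this as an *alignment probability*: the reported effect stays
attached to the minor allele with β = log(OR) ≥ 0, and the generative risk
direction matches it with probability `riskMinorProp = 0.70` (for the other
30% the major allele carries the risk, so the scored weight opposes the true
direction). This reading is forced by the mathematics of the design: if
every weak SNP's scoring weight pointed in its true direction, adding true
weak signal to a score could never reduce its expected discrimination, and
the oligogenic score could not beat the full polygenic score even in
principle. With 30% misalignment the weak-SNP aggregate carries more noise
than labelled-group signal, and the characteristic ordering emerges:
AUC(ORS.full) > AUC(PRS.full), while PRS.AD — which separates the ε4 term
from the diluted polygenic sum — is best of all. The acceptance test
asserts exactly this ordering of 10-seed mean AUCs at the full design size.
Draw order is documented and seeded (variant-level frequencies and signs
first, then genotypes by subgroup), making cohorts bit-reproducible;
`simulatePopulationPanel()` regenerates the same variant layout and draws a
neutral panel at the true-control frequencies, for population-referencing
experiments.

Putative cases are analysed as controls throughout, matching the design
premise that young control cohorts contain future cases. Ages in the
simulated metadata are set to constants consistent with that premise (cases
above the late typical onset, controls below the early one); the age-group
summary machinery (`ageGroupSummary()`, bins 55–65, 65–75, 75–85, 85+,
left-closed) is exercised against generated age trends in the tests.

What the generator deliberately does **not** emulate: linkage
disequilibrium between the simulated SNPs (genotypes are independent;
LD behaviour is tested separately with `makeLdFixture()`'s latent-block
construction, whose within-block r² hits its target via the allele-copy
probability q = r2^(1/4)), ancestry structure, genotyping error and
missingness patterns, age-at-onset survival processes, and effect-size
estimation noise. Passing tests therefore demonstrate the *mechanisms*
(contamination-driven ranking reversal, reference-dependent extreme counts),
not calibrated real-data performance.

## Numerical choices

* The mixture solver brackets the control frequency in (0, 1) and requires
  a residual below 1e-10 (`uniroot` tolerance 1e-14).
* Clumping tie-breaks are deterministic (p, then chromosome, then
  position), so output is invariant to input row order.
* r² uses pairwise-complete observations and returns 0 for constant
  vectors; fewer than two complete pairs is an error at the single-pair
  level and treated as no-evidence (r² = 0) inside clumping.
* Scoring streams the dosage matrix in 2,000-variant chunks, keeping peak
  memory modest at the full simulation size (20,000 × 10,068).
* Separation in logistic fits is flagged when `glm` warns or any
  coefficient exceeds 25 in absolute value; the fallback is ridge
  (`glmnet`, alpha = 0, lambda = 1e-3).
* Haldane correction applies to all four cells whenever any cell is zero,
  and the CI is computed on the corrected counts.

## Problem sizes used by the tests

The acceptance suite runs the simulation at its full design size (10 seeds ×
20,000 samples × 10,068 SNPs) for the AUC-ordering property, 20 seeded
reduced cohorts (300 study + 400 population samples, 128 SNPs) for the
standardisation-enrichment property, 50 random 12-variant panels for the
clumping oracle, and 100,000 standard-normal draws for the tail-fraction
calibration. Unit tests use small deterministic fixtures built in code.

## Known limitations

* Only biallelic SNPs are modelled; multi-allelic records are rejected at
  read time.
* No haplotype phasing: the ε2/ε4 coding of the CT/CT double heterozygote
  is a convention, and ε1 is ignored.
* Bayesian shrinkage methods (LDpred-style, PRS-CS, SBayesR) and LDAK
  weighting are out of scope; their per-sample score files can be ingested
  with `readScoreSet()` for extreme-overlap comparisons
  (`overlapExtremes()`), but the methods themselves are not reimplemented.
* Genotype QC, imputation and ancestry outlier handling are assumed done
  upstream.
* The harmonisation rules (ambiguous-variant removal, complement
  resolution) are stated conventions; cohort-specific pipelines may differ.
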