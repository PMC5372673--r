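---
title: "Methods: cellular-sensitivity QTL mapping with cytotoxQTL"
author: "cytotoxQTL maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular-sensitivity QTL mapping with cytotoxQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotoxQTL)
```

## The analysis this package implements

cytotoxQTL implements a triangulation strategy for pharmacogenomic
discovery on genotyped cell-line panels (e.g. lymphoblastoid cell lines).
The chain of evidence runs:

1. **Phenotype**: each cell line's sensitivity to a drug is summarized as
   the IC50 of its dose-response survival curve, analysed on the log2
   scale.
2. **Drug QTLs (dQTLs)**: every SNP is regressed against log2 IC50; SNPs
   reaching a nominal p <= 0.001 are drug-associated.
3. **Functional triangulation**: drug-associated SNPs are tested for
   enrichment of expression QTLs (eQTLs, SNP vs gene expression at
   p <= 0.0001) and protein QTLs (pQTLs, SNP vs protein expression at the
   same threshold) using MAF-matched permutation sets.
4. **mRNA-independent pQTLs**: each protein is residualized on its
   encoding gene's mRNA; SNP associations that survive in the residuals
   cannot be carried by transcript abundance.
5. **Protein-phenotype association**: proteins are regressed against
   log2 IC50 with Benjamini-Hochberg FDR control and quantile-quantile
   diagnostics.

At n = 68 unrelated samples the per-SNP regression is ordinary least
squares on minor-allele copies with an intercept and no covariates; the
two-sided p-value comes from the t distribution with n - 2 degrees of
freedom. No kinship or principal-component correction is applied: the
intended panel is a set of unrelated lines from one population, and the
package deliberately mirrors that operating point. eQTL/pQTL status is
genome-wide (the best trait anywhere), not restricted to a cis window.

## Dose-response phenotyping

Survival curves are percent viability relative to a no-drug control,
measured on a fixed concentration grid (default 50, 100, 175, 250, 375,
500 uM). `fitIC50()` fits the four-parameter logistic

$$ s(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
          {1 + (c/\mathrm{IC50})^{h}} $$

with bottom in [0, 30], top in [70, 130], positive hill slope h, and IC50
constrained to [min(conc)/10, max(conc) x 10]. The bounds encode that the
assay is normalized to a control near 100%; an unbounded 4PL on six points
is ill-posed. The optimizer (Levenberg-Marquardt via minpack.lm) is run
from a small grid of starts — hill in {0.8, 1.5, 3}, plateaus at the
control-normalized (0, 100) and at data-driven values — because the
4-parameter surface on few points has local optima where plateau and slope
trade off, and a data-driven plateau start stalls at the bounds whenever
the tested range does not reach the plateaus. The best SSE wins.

If the fit fails, or the curve rises by more than 10 percentage points
between consecutive concentrations, the estimate falls back to linear
interpolation of the 50% crossing on the log2 concentration axis. Curves
that never cross 50% are censored (`above_max` / `below_min`) and excluded
from the phenotype vector; the flags make explicit a choice the source
assay leaves open (whether out-of-range IC50s are extrapolated or
censored — we censor). Replicate rows for the same (sample,
concentration) are averaged before fitting; the mean is the simplest
defensible aggregate and is recorded in provenance.

Normality of the log2 IC50 phenotype is reported with the
Lilliefors-corrected Kolmogorov-Smirnov test: mean and SD are estimated
from the same data, so the plain KS test against a fitted normal would be
anti-conservative.

Two small assay formulas ship with the phenotyping module.
`ddctFoldChange()` computes qPCR relative expression from the double
difference of threshold cycles; because published write-ups disagree on
the sign convention, both `2^-ddct` (Livak, the default) and `2^ddct`
(`"asWritten"`) are implemented and the convention used is recorded in the
output — the two are exact reciprocals. `relativeResistance()` is the
double ratio of knockdown vs scrambled-control survival with and without
drug.

## Genotype handling

Genotypes enter as VCF hard calls or as a dosage TSV and are stored in a
`GenotypeMatrix` (a `SummarizedExperiment`, SNPs x samples). Every SNP is
oriented so the stored dosage counts the minor allele; the flip is
flagged. Filters retain SNPs with MAF >= 5% and Hardy-Weinberg exact-test
p >= 0.001. The HWE test is the exact conditional test (probabilities of
heterozygote counts given allele counts, summed over configurations no
more probable than the observed one), computed by the standard recurrence;
monomorphic SNPs return p = 1 by convention. Missing GT policy: SNPs with
more than 5% missing calls are dropped, the remainder mean-imputed with a
per-SNP count recorded — the source analyses are silent on missing data,
so the policy is explicit and logged.

LD pruning is greedy keep-best: candidates are visited by ascending p
(ties: chromosome, position, SNP id) and kept iff their squared dosage
correlation with every kept SNP within 1 Mb on the same chromosome is
<= 0.2. The underlying study reports a pruned hit count without stating
its procedure, so the pruning parameters are this package's choice and
the pruned count is not treated as a reproducible quantity.

## MAF-matched permutation enrichment

The enrichment statistic is the number of flagged QTLs in the
drug-associated SNP set. Its null distribution comes from B = 1000 random
SNP sets drawn from the post-filter universe so that each set matches the
target's minor-allele-frequency histogram *exactly* in bins of width 0.02
(sampling without replacement within each bin). Exact per-bin matching is
the strictest reading of "matching MAF distributions" and is cheap; the
bin width is configurable. Whether matching should instead pair each SNP
with its nearest-frequency neighbour is an open design question; binning
was chosen and parameterized. Target SNPs stay eligible for sampling —
depleting the universe of the target would bias expected counts upward in
small universes.

The empirical p-value is add-one smoothed,
$p = (1 + \#\{b: \mathrm{null}_b \ge \mathrm{observed}\})/(1 + B)$, so the
smallest reportable value at B = 1000 is 1/1001 and p = 0 is impossible —
standard permutation practice, and it makes the boundary report
"p <= 0.001" exactly representable. Enrichment defaults to the LD-pruned
drug-QTL set, with `usePruned = FALSE` as a sensitivity analysis on the
unpruned set (which of the two the source flow used is ambiguous; both are
supported).

## mRNA-independent protein QTLs

For each protein, `residualizeProteinOnMrna()` regresses protein on the
encoding gene's mRNA (OLS with intercept over complete pairs) when the
mRNA is detected in at least 50% of samples, and otherwise returns
centered protein values labelled `unadjusted_mrna_missing` — the
situation of a transcript detected above background in only a handful of
lines, where no adjustment is possible and pretending otherwise would
discard the protein signal. The 50% detection threshold is exposed in
`AnalysisConfig` because the source handling of undetectable mRNA is
descriptive only. Residuals at floating-point rounding level are snapped
to zero so that an exactly mediated protein yields a degenerate (not
noise-driven) scan. SNPs whose best residual-trait association reaches
p <= 0.0001 are flagged mRNA-independent pQTLs. This is a regression
device, not formal mediation analysis: no Sobel test or causal estimand is
implied.

## The synthetic cohort generator

The generator exists to give the analysis a cohort whose ground truth is
known, with the statistical structure the analysis assumes:

* **Genotypes**: each SNP is two Bernoulli(MAF) allele draws, so genotype
  frequencies are in Hardy-Weinberg proportions in expectation. LD blocks
  are induced by a Gaussian copula (exchangeable latent correlation within
  a block, thresholded at qnorm(MAF)); real LD is empirical and
  block-stationary structure is enough to exercise the pruner and the
  frequency matcher. The dosage correlation is necessarily below the
  latent correlation, increasingly so for rare alleles.
* **Effect scaling**: a planted effect with variance_explained v gets its
  coefficient scaled against the *population* dosage variance 2f(1-f), not
  the realized sample variance, so realized in-sample R2 fluctuates around
  v exactly as effect sizes behave in real cohorts. The recorded ground
  truth satisfies genetic variance / trait variance = v to 1e-12. With
  zero residual noise a trait is fully determined by its genetic part and
  the truth records variance explained 1 regardless of the request.
* **Proteins**: *mediated* effects load on the encoding gene's simulated
  mRNA (the genotype association exists only through the transcript and
  vanishes in mRNA residuals); *direct* effects load on the dosage and
  bypass mRNA. Isoform pairs are constrained to opposite-sign genotype
  effects, mimicking a 38/75 kDa isoform pair with discordant directions.
  "Undetected" genes are emitted as missing values (not zeros) in all but
  3 randomly chosen samples, so the conditional module must make a real
  adjustment decision.
* **Dose-response**: true log2 IC50 is the population mean (default
  log2(176.5) uM) plus the planted genetic terms plus Gaussian noise; the
  total log2 IC50 SD defaults to 0.45, back-computed from a reported mean
  IC50 of 176.5 +/- 6.6 uM (SEM over 68 lines, i.e. an SD of ~54 uM).
  Survival is the 2-parameter-plateau logistic (bottom 0, top 100, default
  hill 1.5) evaluated on the concentration grid plus additive Gaussian
  noise truncated at zero; values above 100% are allowed, as normalized
  viability readouts exceed the control. The default per-point noise SD is
  2%: the emitted curves represent replicate-averaged measurements (the
  emulated assay averages >= 2 biological x 6 technical replicates, which
  shrinks raw per-well noise several-fold).

What the generator does **not** emulate: realistic allele-frequency
spectra or recombination maps, imputation dosage uncertainty, plate or
batch effects, heavy-tailed expression noise, and polygenic background.
Tests passing on these cohorts therefore demonstrate correctness and
calibration of the statistical machinery, not robustness to every
pathology of real data.

Determinism: every generator is a pure function of (config, seed). One
root seed spawns fixed per-stage streams (genotypes, expression, proteins,
dose-response, permutation sets), so adding a stage never perturbs the
randomness of earlier stages, and a full `runPipeline()` run reproduces
every artifact byte for byte. The run manifest is deliberately free of
wall-clock timestamps (they live in a side log) to keep reruns
bit-identical.

## Numerical choices and degenerate inputs

* Degenerate regressions (constant dosage or trait, n < 3) return a
  flagged result with beta = 0 and p = 1 instead of raising, so
  genome-scale scans never abort mid-run.
* Perfect fits report r2 = 1 with p = 0; the r2 = t^2/(t^2 + n - 2)
  identity holds to 1e-9 everywhere else.
* Missing trait values are dropped pairwise with the per-result n
  recorded; samples without a phenotype (censored IC50s) enter scans as
  missing.
* Undefined LD (a constant dosage vector) is flagged and treated as r2 = 0
  by the pruner.
* p-values of exactly 0 entering Q-Q construction are clipped to the
  smallest positive double with a warning.
* TSV writers serialize numbers at full double precision (17 significant
  digits) so write/read round trips are bit-identical for finite values.

## Problem sizes used by the test-suite studies

The simulation studies shipped with the package run at the analysis'
operating point, n = 68 samples, with panel sizes chosen to estimate each
quantity comfortably: 10,000 SNP-trait pairs for null-calibration KS
checks; 1,000 replicates for the R2-recovery study of a planted
variance-explained-0.36 phenotype effect; 200 replicates each for the
mediated/direct protein-QTL discrimination study; 5,000 SNPs with two
50-SNP LD blocks for the enrichment study (two causal drug effects of
variance explained 0.36, 50 planted eQTL carriers among the 100 block
SNPs, a ~5% background eQTL rate, 1,000 MAF-matched permutation sets).
Full-scale panels from the emulated study design (18,227 genes, 441
proteins, millions of SNPs) are documentation defaults, not test sizes.

A note on discrimination power: at n = 68 a direct protein effect of
R2 = 0.21 sits almost exactly at the two-sided p = 1e-4 detection
boundary (expected |t| ~ 4.19 vs critical ~ 4.17), so its per-replicate
flagging probability is ~0.5 by construction; the package reports this
honestly rather than inflating the effect or relaxing the threshold. The
fully mediated construction is flagged at the nominal error rate.

## Known limitations

* No covariate or population-structure correction; panels with
  relatedness or admixture need upstream handling.
* Protein intensities are regressed as provided (no log or z-transform);
  whether the source data were transformed is unstated, so the package
  documents rather than guesses.
* The residual device removes linear mRNA dependence only.
* Imputation of genotypes from a reference panel is out of scope; the
  reader accepts fractional dosages but the generator emits hard calls,
  and no fidelity claim is made about imputed data.
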