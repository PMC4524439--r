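---
title: "Models and methods in methylGDM"
author: "methylGDM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methylGDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

methylGDM implements an integrated epigenome-wide and transcriptome-wide
association analysis for matched case-control studies of gestational
diabetes mellitus (GDM) in placental tissue: site-level and gene-level
robust-Wald association models, bump-hunting detection of differentially
methylated regions (DMRs), linear-mixed-model validation of
pyrosequenced regions with effect-modification tests, permutation-based
Spearman correlation networks inside a genomic window (an MHC-like
region), and gene-ontology (GO) enrichment with a resampling null that
corrects the non-random probe design of methylation arrays. Every stage
is driven end to end by a synthetic cohort generator that records its
injected ground truth, so the whole pipeline is testable without any
external download.

This vignette explains the statistical models, the tunable parameters
and their defaults, what the simulator does and does not emulate, and
the numerical and design choices a maintainer should know about.

# Data model

Methylation arrays report two fluorescence channels per CpG probe,
methylated (M) and unmethylated (U). The methylation level is

$$\beta = \frac{M}{M + U + 100},$$

which lies in [0, 1) — the +100 offset regularizes low-intensity probes.
`MethIntensitySet` (a `SummarizedExperiment` with assays `Meth` and
`Unmeth`) holds the channels; `BetaSet` holds betas plus provenance
flags recording which preprocessing steps have run. Probe annotation
(chromosome, 1-based position, chemistry type I/II, SNP-at-target and
X-cross-hybridization flags, nearest gene) travels in `rowData`; BED
exports are 0-based half-open.

## Preprocessing

1. **Quantile normalization** (`normalizeIntensities()`): both channels
   are normalized jointly across samples via
   `limma::normalizeQuantiles(ties = TRUE)`, removing between-array
   distributional differences.
2. **Beta conversion** (`computeBeta()`): the formula above,
   elementwise; negative intensities are an error naming the probe and
   sample.
3. **Probe-type adjustment** (`adjustProbeType()`): type II chemistry
   compresses betas toward 0.5 relative to type I. Per sample, type II
   values are mapped onto the type I empirical distribution by rank
   (`p = (rank-1)/(n-1)`, type-7 quantiles), which preserves type II
   rank order, leaves type I untouched, and is a fixed point when the
   distributions already agree. This is a distributional-alignment
   stand-in for beta-mixture normalization; a full three-state
   mixture-EM method can be swapped in behind the same interface.
4. **Probe filtering** (`filterProbes()`): retain autosomal probes
   without a SNP at the target site and without cross-hybridization to
   the X chromosome; a probe failing several criteria is counted under
   each but removed once, and un-annotated probes are an error rather
   than being silently retained.

A caveat we quantified during development: between-array quantile
normalization attenuates genuine case-control shifts slightly. With a
+0.10 beta shift injected at 1% of probes (n = 80), the recovered
effect is on average about 0.003 smaller after normalization, and the
probe-type map contributes a further ~0.002 at type II probes. The
attenuation does not shrink with the fraction of affected probes (it is
a local rank-compression phenomenon), so it is a property of the
normalization itself, shared by any pipeline of this design. The
association model applied to unnormalized betas is unbiased to
Monte-Carlo precision; the test suite checks estimator bias at that
interface and sensitivity through the full chain.

Expression arrays are processed by quantile-baseline background
subtraction (per sample, subtract the 2.5th-percentile intensity and
floor at 1 before log2 — a monotone simplification of convolution-model
background correction, hook left to swap in the full method), quantile
normalization, and **median polish** (`stats::medpolish`, rows first,
tolerance 1e-6, at most 20 sweeps) summarizing each gene's probes into
one per-sample value; single-probe genes pass through unchanged. qRT-PCR
validation uses `deltaCt()` = mean Ct of the target's replicates minus
mean Ct of the reference gene (GAPDH by convention).

# Surrogate adjustment for batch and ethnicity

Chip, chip-row and chip-column assignments, plus self-reported
ethnicity measured with error, can confound site-specific analyses even
after normalization — what survives between-array normalization is
*probe-specific* batch structure. `estimateSurrogates()` is a
data-driven stand-in for independent-surrogate-variable analysis:

1. residualize the feature-by-sample matrix on the full primary design
   (exposure included, so exposure signal cannot leak into the
   surrogates);
2. take the right singular vectors of the residual matrix, keeping only
   components whose singular values exceed the 95th percentile of
   singular values from row-permuted (and re-residualized) copies of
   the matrix — permutation parallel analysis, the same idea used for
   dimension selection in surrogate-variable analysis. On pure noise
   this keeps essentially nothing, so null data yield an empty
   selection rather than hovering at the screening threshold;
3. screen each kept component against each confounder label with
   one-way ANOVA F tests (component scores are near-Gaussian linear
   combinations; a Kruskal-Wallis option exists), and select components
   with Benjamini-Hochberg q < 0.05 against any confounder.

`kMax` defaults to `min(10, n/5)` for identifiability at cohort scale.
Selected components enter the downstream models via `modelFrame()`.
`batchVarianceExplained(..., excess = TRUE)` reports the mean
per-feature R² of a batch factor above its chance level, the quantity
used to verify that adjustment removes injected batch variance.

# Association models

Site-specific methylation (and gene-level expression) is modeled by
ordinary least squares on the GDM indicator, maternal age (years),
pre-pregnancy BMI (kg/m²), infant sex, maternal smoking, and the
selected surrogates. Because beta-value variance depends on the
methylation level itself, Wald tests use heteroscedasticity-consistent
(sandwich) standard errors. The default flavor is **HC1** (the
degrees-of-freedom-corrected sandwich) with a residual-df t reference:
at n ≈ 82 this combination is calibrated (null rejection ≈ 0.05 at
α = 0.05), whereas HC3 combined with a t reference applies two
small-sample corrections at once and is measurably conservative
(≈ 0.03); HC3 and HC0 remain available (`hcType`), as does a
normal-reference option (`dfMethod`). Matched-pair structure is not
modeled directly — models adjust for the matching factors, and the
covariate set keeps pairing information; covariates constant across the
sample are dropped (they cannot confound and would break the fit).

`runEWAS()`/`runTWAS()` use a single-pass matrix formulation of the
same estimator (the robust variance of the exposure coefficient is a
weighted cross-product with the feature's squared residuals); the
single-feature path `fitFeatureModel()` delegates to
`sandwich::vcovHC`, and the two are checked against each other in the
tests. Default significance thresholds: 0.001 for methylation, 0.01 for
expression, with expression reporting restricted to coding genes.

# Bump hunting

`findBumps()` flags probes whose |t| exceeds the 99th percentile of all
retained probes, then chains flagged probes into regions: consecutive
candidates at most 500 bp apart form a run. Three readings the
literature leaves open are fixed as follows:

* *Strict contiguity* (default): a retained sub-threshold probe lying
  between two candidates breaks the run — "contiguous" is read
  literally; `strict = FALSE` chains candidates across intervening
  probes.
* *Mixed signs*: runs are split where the effect changes sign — a DMR
  is directionally coherent.
* *Summary effect*: the mean member effect by default; `"area"` (the
  sum) is available.

Runs of fewer than `minProbes = 2` probes are reported separately as
site-level hits. The threshold quantile is taken over all retained
probes genome-wide. Candidate regions for pyrosequencing validation
(`rankCandidatesForValidation()`) must have an unflagged peak probe
(SNP/cross-hybridization flags complicate primers and may reflect
polymorphism) with p < 0.001, and are ranked by absolute summary
effect. The implementation is validated against a brute-force
maximal-run enumerator on hundreds of random instances.

# Regional mixed models and effect modification

Pyrosequencing reports percent methylation `100·C/(C+T)` per CpG.
`fitRegionModel()` fits a linear mixed model across the CpGs of one
region: fixed effects for GDM and the covariates (ethnicity included),
a random intercept per sample (REML via `lme4`), and a Wald 95% CI with
a normal reference on the percent scale. A singular fit (zero random
intercept variance) triggers a fixed-effects refit with cluster-robust
(by sample) standard errors, flagged in the output.
`testEffectModification()` adds a dichotomous modifier and its
interaction with GDM, reports the interaction Wald p, and refits each
stratum separately; `dichotomizeAtMedian()` fixes thresholds at the
discovery cohort's median so a validation cohort is split on the
discovery scale.

# Window correlation networks

Within a window (the MHC analogue; coordinates configurable), the
feature set is every CpG within a closed ±10 kb flank of the window and
every gene whose TSS lies inside it. All CpG-by-gene and gene-by-gene
pairs are tested with Spearman correlation; significance comes from
permutations of the expression vector, with one shared permutation
stream per seed so each edge's p-value is independent of visiting
order. The two-sided permutation p is the fraction of permuted |rho|
at or above the observed; a zero count is imputed as 1e-6 (the
convention for p = 0 under 10,000 permutations). Benjamini-Hochberg
correction runs within each edge family separately (the "regional"
FDR); the methylation-expression family returns all q < 0.05 edges and
the co-expression family the 100 largest-|rho| among them.
`collapseClusters()` summarizes window methylation by greedy
left-to-right chaining (extend while the next CpG is ≤ 5 kb from the
last member and the span stays ≤ 10 kb; every CpG lands in exactly one
cluster), and `groupDifferenceProfile()` gives the unadjusted
case-minus-control mean per cluster or gene, to be compared across
random control windows.

# GO enrichment with design-bias correction

Terms are restricted to those annotating 20-1500 genes after true-path
propagation. Redundancy is reduced via Jiang-Conrath similarity:
`d = IC(a) + IC(b) − 2·IC(MICA)` with
`IC(t) = −log(annotated(t)/annotated(root))`, scaled to (0, 1] as
`1/(1+d)` (a `1 − min(1, d)` scaling is available; the 0.7 cutoff
applies to whichever is configured). Clusters are the connected
components of the ≥ 0.7 similarity graph (single linkage, the minimal
reading of "highly similar terms"), each represented by its
largest-annotation member, ties to the lexicographically smaller id.
Note that under JC two *sibling* terms with identical gene sets are not
maximally similar (their MICA is an ancestor); a true duplicate appears
as a parent-child pair, which is how the generator plants them.

Methylation enrichment cannot use a hypergeometric null: genes carry
very different probe counts on the array, so the genes reachable from a
random significant-CpG set are not a uniform draw. The resampling null
redraws `|sig|` probes from all retained probes (without replacement,
matching sampling loci from the array), maps each draw to closest genes
(`assignClosestGene()`: distance to the nearer gene boundary, 0 inside,
ties to the smaller gene id), and recomputes each term's odds ratio
with Haldane-Anscombe 0.5 corrections in observed and null tables
alike. The upper-tail p uses the `+1/(N+1)` permutation convention, so
it is never exactly zero. Expression enrichment uses the one-sided
hypergeometric test over the expression gene universe (configurable).
When probe counts are balanced the two nulls coincide (mean |Δp| well
below 0.02 at 10,000 resamples in the acceptance suite); with a
probe-dense term planted, the hypergeometric misfires on random CpG
draws while the resampling p stays uniform — the bias the method
exists to fix.

# The synthetic cohort

`generateCohort()` draws matched pairs: identical sex, smoking and
ethnicity within pair, ages within 5 years, BMI within a few kg/m²;
chips are partially confounded with ethnicity through a home-chip
mixing parameter (default 0.5 — strong enough that surrogate
adjustment is non-trivial, weak enough to stay identifiable).
`generateProbeAnnotation()` lays probes down by a background Poisson
process (mean gap 20 kb) punctuated by island bursts of 2-8 probes at
30-450 bp gaps, so bump hunting sees realistic runs; ~5% of probes go
to chrX and ~2% each get SNP/cross-hybridization flags, independent of
effect assignment. `generateMethylation()` draws bimodal baselines
(beta mixtures concentrated near 0.1 and 0.9 plus a mid component),
compresses type II probes toward 0.5 (slope 0.8), injects site,
regional and within-block case effects on the beta scale (clipping to
[0.01, 0.97] with a warning and a ledger entry; the ledger stores the
*realized* post-clip effect), and inverts the beta formula exactly so
that zero-noise data round-trip to machine precision. Noise is
log-normal and multiplicative per channel (sd 0.15, giving mid-range
beta SD ≈ 0.05 — typical technical replication for this platform;
justified by the type-I-error suite rather than by any published
value). Batch effects are *probe-specific* log-normal factors per
chip/row/column level (global per-sample shifts would be removed by
quantile normalization by construction). `generateExpression()` builds
probe intensities additively on the log2 scale (gene signal + fixed
probe affinity + optional batch + noise, ~21 probes per transcript),
so median polish can invert it; block genes share a common case
down-shift plus a per-sample latent factor that creates the dense
positive co-expression the window network should find.
`generateTermUniverse()` builds a rooted random DAG whose propagated
sizes span below/inside/above the 20-1500 window, plants near-duplicate
parent-child term pairs (~95% gene overlap) for the redundancy
reduction, and draws heterogeneous probes-per-gene counts (1-40) so the
design bias is present. `generatePyroCounts()` draws binomial C counts
at the true beta.

What the simulator does **not** emulate: bisulfite conversion
chemistry, dye bias, copy-number artifacts, sex-chromosome dosage,
genuine genomic sequence context, linkage between neighbouring CpGs
beyond injected regions, and population stratification beyond a
categorical ethnicity label. Passing tests therefore demonstrate that
the statistical machinery recovers what it claims under a faithful
noise model — not that any biological conclusion transfers to a real
cohort.

# Numerical choices and degenerate inputs

* Quantile normalization resolves ties by averaging tied quantiles;
  single-sample input is returned unchanged with a warning.
* Probe-type adjustment needs ≥ 50 probes of each type per sample,
  otherwise it skips that sample with a warning; a constant type II
  column maps to the type I median.
* A constant feature in the association model returns effect 0, p 1,
  flagged degenerate; rank-deficient designs are an error naming the
  collinear columns.
* Median polish sweeps rows then columns, tolerance 1e-6, ≤ 20 sweeps;
  the estimate at the cap is used.
* Permutation p-values use `>=` with a 1e-12 numerical guard; the
  permutation index stream is generated once per seed.
* The mixed model falls back to cluster-robust OLS on singular fits.
* Pipeline child seeds are derived deterministically from the master
  seed and stay below 2^31.

# Problem sizes

The default `pipelineConfig()` runs a desk-scale study: 10 pairs, 4,000
probes, 400 genes, 40 terms, 1,000 permutations and 1,000 enrichment
resamples — a full `runPipeline()` completes in well under a minute on
one core and is bit-identical under a fixed seed. The validation suite
uses larger, targeted experiments (e.g. 41 pairs with ~2,000 probes for
type-I calibration; 200 simulations of 40 pairs for recovery and for
the mixed model; 500 random instances for the bump-hunting oracle),
chosen to give stable Monte-Carlo estimates while keeping the whole
suite in the minutes range.

# Known limitations

* The probe-type adjustment aligns marginal distributions; it does not
  model the three methylation states explicitly and can leave a small
  residual attenuation at strongly shifted type II probes.
* The ISVA stand-in uses orthogonal (SVD) components rather than
  independent components; confounders that manifest only in higher
  moments of the score distribution would be missed.
* Regional inference is descriptive (threshold-and-chain with effect
  ranking); no family-wise permutation inference over regions is
  attempted.
* The resampling enrichment conditions on the significant-CpG *count*,
  not on the spatial clustering of the significant set.
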