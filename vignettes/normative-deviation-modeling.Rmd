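---
title: "Normative deviation modeling of regional brain features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation modeling of regional brain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdev)
```

## The problem

Cortical gray-matter volume declines robustly from childhood to adulthood,
and psychiatric symptoms that emerge in that window are increasingly read
as disruptions of this maturation. Case-control designs struggle here for
two reasons: diagnostic groups are clinically heterogeneous, and the
general liability to psychopathology (the *p*-factor) is shared across
disorders, so "disorder" effects can be disorder-general in disguise.

`normdev` implements a normative-modeling workflow for this setting. It
scores each person's regional brain features against a model of healthy
neurodevelopment, then asks three questions of the resulting deviations:

1. Do multivariate deviation patterns predict orthogonal psychopathology
   dimensions out of sample better than the raw features do?
2. Are ROI-level deviation correlations stronger for the general factor
   than for specific symptom dimensions?
3. How much of the spatial overlap between case-control effect-size maps
   of two disorders is carried by the general factor?

Because the motivating class of datasets is access-restricted, the package
ships a synthetic cohort generator that reproduces the statistical
structure these analyses assume. Every claim the test suite makes is a
claim about that generative structure, not about any clinical dataset.

## The normative model

For each region $j$, a Gaussian-process regression is fit on healthy
training subjects to predict the feature $y_{ij}$ from age and sex. The GP
provides a predicted value $\hat y_{ij}$, a predictive uncertainty
$\sigma_{ij}$ for each new subject, and a learned normative variance
$\sigma_{nj}$ describing how much healthy subjects scatter around the
trajectory. Each scored subject gets a deviation z-score

$$z_{ij} = \frac{y_{ij} - \hat y_{ij}}{\sqrt{\sigma_{ij}^2 + \sigma_{nj}^2}},$$

negative when the feature sits below its normative expectation.

**Kernel.** The GP covariance is a sum of three terms: a radial-basis
kernel over standardized age (smooth, potentially nonlinear age effects),
a linear kernel over the full input (age plus a 0/1 sex indicator, giving
an additive sex offset and a linear age floor), and a white-noise term.
Hyperparameters (four log-scale amplitudes/lengthscales) are set by
maximizing the log marginal likelihood with analytic gradients (L-BFGS-B)
from five starting points by default — one data-informed start plus random
restarts — which in practice removes sensitivity to local optima in this
4-parameter space.

**Variance separation.** $\sigma_{nj}$ is taken from the learned
white-noise standard deviation, and $\sigma_{ij}$ is the posterior *latent*
standard deviation excluding the noise term. The two variance components
in the z-score denominator are therefore distinct and non-overlapping:
$\sigma_{ij}$ shrinks toward zero as training data accumulate near a test
point, while $\sigma_{nj}$ converges to the population scatter. One GP is
fit jointly on (age, sex) rather than stratifying by sex; with an additive
sex offset in the generating process this is the more data-efficient
choice, and the linear kernel term can absorb it exactly.

**Standardization.** Features are centered and scaled per region using
training statistics only. The z-score is algebraically invariant to this
(numerator and denominator scale together), which the tests assert
indirectly by checking the z equation against unstandardized quantities.

**Sample structure.** `split_cohort()` keeps all clinical subjects in the
test set, moves a chosen number of healthy subjects to the test set so it
spans the full severity range, and trains on the remaining healthy
subjects. `crossval_deviations()` additionally scores every *training*
subject with k-fold refits (contiguous blocks over a seeded shuffle of
sorted subject ids, so fold membership does not depend on row order; the
folds are not age/sex-stratified), so downstream analyses can use
deviations for training subjects without self-scoring.

## Predicting psychopathology dimensions

The six psychopathology dimensions (overall psychopathology plus
anxious-misery, externalizing, fear, psychosis-positive and
psychosis-negative) are mutually orthogonal bifactor scores; the package
takes them as inputs (the confirmatory factor model that produces them is
upstream, external software) and provides the rank-based inverse normal
transformation — Blom offset $(r - 3/8)/(n + 1/4)$ with average ranks for
ties — used to enforce normality of such scores.

`repeated_cv_predict()` runs repeated k-fold cross-validation (defaults:
100 repeats of 10 folds) of a ridge regression ($\alpha = 1$, closed-form
solve with an unpenalized intercept) from feature principal components to
one dimension. Within each fold, leakage is prevented three ways:

- the target's nuisance regression (age, sex by default; extensible to
  QA, socioeconomic or cognitive covariates) is fit on training rows only
  and applied to the test rows;
- PCA is estimated and centered on training rows only, keeping components
  that individually explain at least 1% of variance; and
- when two feature kinds are compared, the component count selected on
  deviations is imposed on the raw-feature run (`n_components_override`)
  so both models see the same input dimensionality.

Scores (negative RMSE, negative MAE, and the correlation between true and
predicted targets — error metrics are sign-flipped so higher is always
better) are averaged over folds, giving one value per repeat. Fold
shuffles are seeded per repeat index, so runs on different feature kinds
with the same configuration are paired repeat-by-repeat; that pairing is
what licenses the exact test below.

**Permutation significance.** The observed point estimate (mean over
repeats) is compared against scores from models trained on permutations
of the target; the p-value is the plain proportion of permuted scores at
or above the observed one (no add-one smoothing, so its granularity floor
is one over the permutation count and an exact zero is possible). All
permutations share one fixed fold partition: permuting the target leaves
the feature side untouched, so the fold-wise PCA and ridge operator are
computed once and reused, which is what makes 200-permutation desk runs
and larger cheap. When calibrating the null it matters that the observed
statistic be computed the same way as the permuted ones (one pass, same
partition); the permutation-calibration test does exactly that and finds
uniform p-values. With a multi-repeat observed average the test becomes
slightly conservative, which is the same asymmetry present in the
original repeated-CV-plus-permutation design.

**Comparing feature kinds.** The "exact test of differences" between the
two per-repeat score distributions is implemented as a paired sign-flip
permutation test on the per-repeat differences: all $2^n$ flips are
enumerated for $n \le 20$ pairs, otherwise a Monte-Carlo sample of flips
(including the identity, so the smallest attainable p is `1/n_flips`)
approximates the two-sided p. The literature phrase names a procedure
whose formula is not commonly reproduced; the sign-flip test is the
standard exact paired test for this situation and the implementation is
pluggable behind the `method` argument.

Multiple dimensions are corrected with Benjamini-Hochberg FDR at
q = 0.05 (`fdr_correct()`, a thin wrapper over the standard step-up
procedure, kept as an explicit module so the decision rule is testable
against a brute-force implementation).

## Regional analyses

`roi_average()` averages deviations over named parcel sets (the shipped
default map sketches vmPFC/mOFC, inferior temporal, daCC and insula
blocks; real atlas memberships are study-specific and user-supplied).
`residualized_correlation()` correlates OLS residuals of both variables
on covariates (T1 QA and SNR in the reference design), with a
partial-correlation t test on $n - 2 - k$ degrees of freedom.

`bootstrap_delta_r()` asks whether the general factor's ROI effect size
beats a specific dimension's: in each bootstrap draw (subjects resampled
with replacement; the residualization is refit on the resampled rows so
the CI reflects all estimation steps), it records
$|r_{\mathrm{overall}}| - |r_{\mathrm{specific}}|$, and declares the
general factor stronger when the lower bound of the 99% percentile CI
exceeds zero (equivalent to a Bonferroni-style p < 0.01 decision). The
percentile CI was chosen over BCa for transparency and because coverage
at the design's n is already nominal (the acceptance suite measures it);
draws with a degenerate (constant) ROI vector are redrawn and counted.
Swapping the two dimensions negates the distribution exactly, and a fixed
seed reproduces it bit-for-bit.

`mass_univariate()` correlates every parcel with every dimension —
residualized for QA covariates by default, on the whole sample, since a
mass-univariate screen has no train/test split — and corrects all
parcels-by-dimensions tests in a single BH family (2400 tests in the
400-parcel, 6-dimension design).

## Case-control analysis

`match_controls()` pairs each case with a healthy control by greedy 1:1
nearest-neighbour matching without replacement: exact on sex, Euclidean
on standardized age/QA/SNR, cases processed in seeded random order, with
standardized-mean-difference diagnostics. The matching algorithm is a
deliberate simplification (no propensity scores, no optimal matching):
with the generator's covariate structure it achieves |SMD| < 0.2 with
room to spare, and the analysis consumes only the matched sets. When two
disorders are analyzed, the second match draws from the pool minus the
first match's controls, so the control sets are disjoint and the two
effect-size maps are estimated independently. Comorbid cases (meeting
both disorder rules) are excluded from both groups by the generator's
labeling.

`cohens_d_map()` computes the regional standardized mean difference with
n−1-weighted pooled sd. `control_for_factor()` residualizes deviations on
one factor *within the scope of one case-control set at a time*, so
general-factor control never mixes the two disorder analyses.
`spatial_correlation()` is the Pearson correlation of two d maps across
regions. `d_shift_test()` summarizes shrinkage: a paired t test over
regions of $\mathrm{sign}(d^{\mathrm{before}})\,(d^{\mathrm{before}} -
d^{\mathrm{after}})$, oriented so a positive statistic means the d
distribution moved toward zero after control. The reference analyses
report a shift t without fully specifying its construction; this signed
paired form was chosen because it is sensitive to proportional shrinkage
regardless of each region's sign, and the degenerate all-zero-difference
case returns t = 0, p = 1 rather than failing.

## The synthetic cohort generator

`generate_cohort()` draws, for `n_subjects` and `n_regions`:

- **Ages** uniform on 8–22 years and sex with a configurable ratio,
  matching a community-ascertained developmental sample.
- **Trajectories**: regional volume follows a logistic-plus-linear
  decline, `baseline + amplitude * plogis(-(age - midpoint)/width) +
  slope*age + sex_offset*male`, with parameters drawn once per region
  (baselines ~ N(12, 2), amplitudes 1–3, midpoints 11–16 years, widths
  1.5–3 years, slopes −0.05–0, male offsets ~ N(0.5, 0.15), in arbitrary
  volume units) — a smooth monotone decline through adolescence with an
  additive sex offset, the qualitative shape normative models of cortical
  volume are built to capture.
- **Factor scores**: six exactly orthogonal, unit-variance columns from
  Gram-Schmidt on a centered Gaussian draw. Generating scores directly —
  rather than simulating item-level symptoms and refitting a bifactor
  model — reflects the fact that the factor model is upstream of this
  pipeline. The inverse normal transformation is a no-op on these
  Gaussian scores by construction.
- **Deviations**: the latent deviation of region $j$ is
  $z_{ij} = \sum_k \beta_{jk} f_{ik} + c_j \varepsilon_{ij}$ with
  $c_j = \sqrt{1 - \sum_k \beta_{jk}^2}$, so each configured effect
  (region set, factor, r) holds *exactly* in population: the correlation
  between the factor and the latent deviation is $\beta_{jk}$, and
  `true_roi_correlation()` returns the closed-form value for ROI
  averages. Volumes are `trajectory + sd_j * z`, so deviation-linked
  signal is a small fraction of raw-volume variance — the regime in which
  normative scoring should help prediction. Overlapping effect
  assignments with conflicting sizes are rejected.
- **QA covariates** (T1 quality, SNR) drawn independently of everything
  else by default, so residualization on them is a consistency check
  rather than a confound correction.
- **Diagnosis labels** from deterministic thresholds on factor scores:
  a disorder rule fires when all its named factors exceed their cutoffs;
  subjects meeting two disorder rules are `other_clinical` (comorbidity
  exclusion); non-cases are `healthy` only if all scores sit below
  `healthy_max`. The defaults give roughly 30% healthy and roughly
  9–11% each for depression (general + anxious-misery) and ADHD
  (general + externalizing) — proportions in line with the reference
  cohort design.
- **Heteroscedasticity**: optionally the residual sd grows linearly with
  age (`het_age_slope`) to exercise the GP's variance estimation; the
  default is homoscedastic.

What the generator does *not* emulate: spatial autocorrelation between
parcels beyond factor-induced correlation, site or scanner effects,
age-by-factor interactions, non-Gaussian deviation tails, and any
item-level symptom structure. Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes, not that real cortical
data satisfy those assumptions.

## Numerical choices and degenerate inputs

- GP: jitter 1e-8 on the kernel diagonal; hyperparameters bounded in
  log-space (noise sd floor 1e-3); a failed Cholesky marks a restart as
  infeasible rather than aborting. Fits sort subjects by id first, so
  results are independent of input row order.
- Constant feature columns, constant residual vectors, constant factors
  within a residualization scope, and zero pooled sds are errors naming
  the offending region/column, not silent NaNs.
- Correlations between a truncation-degenerate prediction (zero variance)
  and the target are scored 0 rather than NA inside cross-validation.
- The permutation p and the Monte-Carlo exact test use a 1e-12 tolerance
  on score comparisons so floating-point ties count as ties.
- All stochastic steps take explicit integer seeds, restore the caller's
  RNG state, and derive internal streams by fixed offsets, so whole-run
  reproducibility follows from one seed.

## Problem sizes used by the tests and acceptance script

The packaged checks run at the design's structural scale but with desk
replication counts, chosen so the whole suite completes in minutes on one
core while keeping every estimate's sampling error well inside the
asserted bands: normative calibration at 281 training / 200 held-out
subjects and 50 regions; prediction comparisons at 990 test subjects and
100 regions with 20 repeats and 200 permutations; bootstrap coverage with
500 replicates of 1,000 bootstraps (the acceptance script reports one
10,000-bootstrap run); case-control analyses at 1,500 subjects and 60
regions; and the full 400-parcel, 2,400-test mass-univariate family at
n = 990. The `paper` preset in `pipeline_config()` restores the
full-scale replication counts (100 repeats, 100,000 permutations, 10,000
bootstraps).

## Calibration: what can and cannot be expected at finite n

A perfectly calibrated normative model yields held-out healthy z-scores
that are standard normal per region. With 200 held-out subjects, the
*sample* mean of a region's z-scores has standard error
$1/\sqrt{200} \approx 0.071$ and the sample sd has standard error
$\approx 0.05$, so even ground-truth z-scores land outside a ±0.1 band
around 0 (or a ±0.1 band around 1 for the sd) in a nontrivial fraction
of regions — an irreducible property of the sample size, which the test
suite demonstrates by scoring the generator's own latent deviations. The
statistically meaningful calibration check, which the suite asserts, is
distributional: the per-region Kolmogorov-Smirnov statistic against the
standard normal stays below its 1% critical value in at least 95% of
regions, and the fitted $\sigma_{nj}$ tracks the generating residual sd
within a few percent.

## Known limitations

- Exact GP inference is $O(n^3)$ per region; fine for hundreds of
  training subjects, not for tens of thousands (sparse or approximate GPs
  would be the next step, as would transferring normative models across
  sites/scanners, which this package does not attempt).
- The permutation null re-runs one CV pass per permutation rather than
  the full repeat average; the resulting p-values are exact under a
  1-repeat observed statistic and mildly conservative otherwise.
- Greedy matching is order-dependent (hence seeded) and not optimal;
  balance is diagnosed, not guaranteed.
- The pipeline driver caches on file existence plus a configuration
  hash; it does not hash file *contents* of intermediate inputs, so
  hand-editing an intermediate file without deleting it will not trigger
  recomputation downstream.
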