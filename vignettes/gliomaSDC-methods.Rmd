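---
title: "Diffusion metrics for IDH genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion metrics for IDH genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaSDC)
```

## The three metrics

gliomaSDC computes three pixelwise metrics from a multi-b-value
diffusion-weighted series (b in s/mm²), each a two-point contrast chosen to
isolate a different tissue property of diffuse gliomas:

- **SDC (slow diffusion coefficient)**, `computeSDC()`:
  $[S(b_1) - S(b_2)]/(b_2 - b_1)$ with $b_1 = 500$, $b_2 = 750$ by default.
  A linear signal difference over a high-b interval: perfusion has decayed
  away by b = 500, so the residual slope indexes slow (tissue) diffusion
  while avoiding the log-ratio's amplification of T2 effects. Reported in
  au/s, the unit label the field uses for this quantity (dimensionally the
  ratio is au·mm²/s; the label is kept for comparability).
- **DDVD (diffusion-derived vessel density)**, `computeDDVD()`:
  the per-pixel signal drop between b = 0 and b = 10, a microvascular
  perfusion surrogate — over that tiny b-interval only the fast
  (pseudo-diffusion) compartment decays appreciably. The defining form is a
  ROI quotient, $S_{b0}/\mathrm{area}_{b0} - S_{b10}/\mathrm{area}_{b10}$;
  with a common mask on both volumes this equals the ROI mean of the
  pixelwise difference map exactly, an identity the test suite asserts.
- **ADC (apparent diffusion coefficient)**, `computeADC()`:
  $\ln[S(b_1)/S(b_2)]/(b_2 - b_1)$ from b = 0 and 1000, the conventional
  mono-exponential estimate in mm²/s. Voxels with a non-positive signal are
  flagged NaN and counted rather than silently dropped or clamped.

Maps are whole-volume and mask-independent; the ROI enters only in
`roiAggregate()`, whose per-lesion statistic is the **mean** over valid
in-mask voxels. The mean is the only statistic consistent with DDVD's
defining equation (itself a ROI mean), so it is used for all three metrics.
Negative SDC/DDVD voxels (noise) are retained: clipping at zero would bias
group means upward.

Two further numerical policies worth knowing:

- No intensity normalization is applied by default; the metrics operate on
  raw arbitrary-unit intensities, which presumes scanner-side intensity
  normalization. SDC and DDVD therefore scale with the signal (exact scale
  covariance, tested), while ADC is scale-invariant; absolute SDC/DDVD
  values are not comparable across differently scaled acquisitions.
- Geometry is a contract, not a preference: volumes with mismatched grids
  or affines are rejected, never resampled. Registration belongs upstream.

## The combined genotype model

The probability that a glioma is IDH-mutant is modelled logistically on the
lesion-level triplet:

$$p = \frac{1}{1 + \exp[-(\beta_1\,\mathrm{SDC} + \beta_2\,\mathrm{DDVD}
  + \beta_3\,\mathrm{ADC} + \beta_0)]}$$

with SDC in au/s, DDVD in au/pixel and **ADC in 10⁻⁴ mm²/s**.
`referenceModel()` ships the fixed published coefficient set
(8.941, −0.124, 0.034, −1.229) as an immutable object named
`paper-2025-reference`; `fitLogistic()` estimates the same model form on a
new cohort by unregularized maximum likelihood (binomial IRLS, tolerance
1e-8 on the deviance, at most 100 iterations) and reports standard errors,
convergence and the in-sample AUC. Complete separation is detected and
raised as an error instead of returning divergent coefficients.

Because the coefficients are meaningless if ADC arrives in mm²/s, the unit
travels with the value: `MetricTriplet` carries a mandatory ADC unit tag,
conversion (`adcToModelUnits()`) is idempotent, and cohort tables must
supply ADC under the unit-named column `adc_e4_mm2_per_s`. A mismatch is an
error, never a silent rescale. Classification ties at the probability
threshold are called positive (documented convention).

## Cohort statistics

Group comparisons use the Mann-Whitney U test (`mannWhitney()`) and the
Kruskal-Wallis test (`kruskalWallis()`), correlations use Pearson's r with
Fisher-z confidence intervals (`pearsonCorrelation()`), matching standard
biostatistics practice for these data. Design choices where the field's
software differs:

- Mann-Whitney p-values are exact by full enumeration of group assignments
  for combined n ≤ 20 (valid with ties), and otherwise use the
  tie-corrected normal approximation with continuity correction — the
  behavior of common commercial packages. With the continuity correction
  disabled, the k = 2 Kruskal-Wallis chi-square p equals the Mann-Whitney
  normal p to 1e-6 (tested).
- No multiple-testing correction is applied anywhere, matching the analysis
  the package reproduces.
- Inter-reader agreement uses ICC(A,1): two-way random effects, absolute
  agreement, single measurement, with the F-based confidence interval on
  Satterthwaite degrees of freedom. The source analysis does not name its
  ICC form; this is the standard choice for inter-reader reliability of a
  continuous measurement.
- Immunohistochemistry partially-positive cases (coded 0.5) are carried as
  their own level and *dropped*, never merged, where an analysis excludes
  them.

## ROC analysis and the cutoff table

`rocCurve()` builds the empirical ROC over all distinct thresholds with
trapezoidal AUC; ties follow the Mann-Whitney convention (one half), so
AUC = U/(n₁n₂) identically — the suite checks this against a brute-force
pairwise oracle on 100 random instances. Orientation is an explicit flag
(higher SDC ⇒ IDH-mutant) and is never auto-flipped.

`cutoffTable()` reproduces the published table format: the rule is the
strict "predict positive if value > threshold"; candidate thresholds are
midpoints between consecutive distinct observed values; sensitivity and
specificity are exact count fractions; LR⁺ = sens/(1 − spec) is computed on
those fractions (rounding percentages first would give, e.g., 25.64 where
the exact fractions give 25.67) and is `Inf` at specificity 1.

Confidence intervals for proportions default to the **hybrid Wilson/Brown
method**: the Wilson score interval, except that when the success count
(lower bound) or failure count (upper bound) is 1 or 2 the bound is
replaced by the one-sided Poisson chi-square bound
$\chi^2_{2k,\alpha}/(2n)$, and the bounds are exact 0/100 at empty/full
counts. This is the default of widely used biostatistics software and is
the only method that reproduces every printed bound of the published
cutoff table (plain Wilson differs in the upper bounds at 1–2 failures,
e.g. 34/35; Clopper-Pearson differs throughout). `method = "wilson"` gives
the unmodified score interval, which the tests cross-check against
`prop.test(correct = FALSE)`.

## What the simulators emulate — and what they do not

**Phantom** (`simulatePhantom()`): voxel signal follows the bi-exponential
IVIM decay $S(b) = S_0[f e^{-bD^*} + (1-f)e^{-bD_t}]$, corrupted by Rician
noise of scale $S_0/\mathrm{snr}$ (magnitude MRI; Gaussian available for
analytic checks). The default 32×32×8 layout has three regions — normal
background, a "wildtype-like" lesion (f = 0.12, D_t = 0.7×10⁻³ mm²/s: high
perfusion, dense tissue ⇒ low SDC, high DDVD) and a "mutant-like" lesion
(f = 0.04, D_t = 1.3×10⁻³: the converse) — sized so full-pipeline tests run
in seconds. These tissue parameters are illustrative: no voxel-level glioma
parameter values are published, so the phantom supports algorithmic
validation (closed-form oracles, scale covariance, noise convergence), not
claims about glioma physiology. Scanner artifacts, motion, susceptibility
distortion and T2/TE dependence are deliberately not modelled.

**Cohort generator** (`simulateCohort()`): per group, metric triplets are
drawn from a multivariate normal on the metric scale — the simplest
structure consistent with the published means ± SDs and medians — truncated
at zero for SDC and ADC (a negligible correction at the default
parameters). `defaultCohortSpec()` encodes the published genotype design:
33 wildtype cases at SDC 0.339 ± 0.055 au/s versus 30 mutant cases at
0.437 ± 0.097 au/s, grade composition 19/6/33 with 5 ungraded NEC cases,
and Ki-67 located at the published group medians. Between-metric
correlations default to the published values (SDC–ADC +0.705, SDC–DDVD
−0.212) with the unreported DDVD–ADC set to 0; a non-positive-definite
user matrix is rejected unless projection to the nearest correlation
matrix is requested. Ki-67 is a linear function of SDC plus noise scaled to
a within-group correlation of −0.382, clamped to [0, 100] %. DDVD and ADC
group statistics are unpublished; defaults (wildtype 35 ± 12 au/pixel,
10 ± 2 ×10⁻⁴ mm²/s; mutant 25 ± 10, 13 ± 2.5) follow the qualitative
direction of glioma imaging (wildtype: more perfusion, lower ADC) at
typical magnitudes.

`gradeCohortSpec()` centres the three grade groups on the published SDC
medians (0.472, 0.441, 0.364 au/s at n = 19, 6, 33). The grade-wise spread
is unpublished; it is calibrated once to 0.065, 0.065, 0.050 au/s — tighter
than the pooled IDH groups, as grade-specific groups are more homogeneous —
so that the generator reproduces the hallmark grade-wise Kruskal-Wallis
significance (p < 10⁻⁴) in over 90% of seeded replicates, the property the
cohort must have to stand in for the real one.

Passing tests on these simulations show the *pipeline* is correct under the
stated generative model; they cannot show that real gliomas follow a
truncated multivariate normal, nor validate the reference coefficients on
external data.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`phantomSpec`,
`cohortSpec`, `runConfig`); a fixed seed gives byte-identical outputs,
including the pipeline's JSON report. The test suite uses phantoms of
32×32×8 voxels, cohorts of 63 subjects, 200 seeded replicates for the
grade calibration, 1000 replicates for the binormal AUC surrogate
(closed form $\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2}) = 0.810$),
n = 5000 for logistic parameter recovery and n = 10⁵ for generator moment
recovery — sizes at which the checked tolerances (3 SE for coefficients,
1% for moments, 0.02 for correlations) are informative while the whole
suite runs in about a minute.

## Known limitations

- Arbitrary-unit SDC/DDVD values are scanner- and protocol-specific; the
  reference model's coefficients inherit that dependence.
- The per-lesion value may come from a single representative slice or a
  full 3-D mask; the package accepts either and does not enforce the
  310-voxel ROI extent used in the source cohort.
- No IVIM bi-exponential *fitting*, diffusion kurtosis, or histogram and
  radiomic features: the two-point metrics exist precisely to avoid the
  acquisition and fitting cost of full IVIM.
- `fitLogistic()` is in-sample by design; no cross-validation or penalized
  selection is provided.
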