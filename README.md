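# gliomaSDC

Diffusion-weighted MRI (DWI) can separate IDH-mutant from IDH-wildtype
diffuse gliomas — the key molecular split of the WHO CNS5 classification —
without contrast agents or special hardware. gliomaSDC implements the full
quantitative pipeline around three two-point diffusion metrics computed
from a multi-b-value acquisition (b = 0, 10, 500, 750, 1000 s/mm²):

- **SDC** (slow diffusion coefficient): `[S(b₁) − S(b₂)]/(b₂ − b₁)` from
  b = 500/750, in au/s — a linear high-b signal slope indexing slow tissue
  diffusion while avoiding the log-ratio's T2 sensitivity;
- **DDVD** (diffusion-derived vessel density): the per-pixel signal drop
  between b = 0 and 10, in au/pixel — a microvascular perfusion surrogate;
- **ADC**: `ln[S(b₁)/S(b₂)]/(b₂ − b₁)` from b = 0/1000, in mm²/s.

On top of the pixelwise maps and ROI aggregation it provides the
cohort-level machinery: Mann-Whitney / Kruskal-Wallis group tests, Pearson
correlations with Fisher-z CIs, inter-reader ICC(A,1), empirical ROC
analysis with a publication-style cutoff table (sensitivity, specificity,
hybrid Wilson/Brown 95% CIs, positive likelihood ratios), and the combined
logistic genotype model

```
P(IDH-mutant) = 1 / (1 + exp[−(8.941·SDC − 0.124·DDVD + 0.034·ADC − 1.229)])
```

(SDC in au/s, DDVD in au/pixel, ADC in 10⁻⁴ mm²/s), shipped as an immutable
reference coefficient set and refittable to new cohorts by maximum
likelihood. Bi-exponential (IVIM) phantom and cohort simulators with Rician
noise make every stage testable without patient data.

It is aimed at quantitative-imaging researchers who want to apply or
re-derive these metrics on their own multi-b-value DWI, and at
methodologists who need a reproducible reference implementation of the
cutoff-table and combined-model analysis.

## Worked example

```r
library(gliomaSDC)

# simulate the default three-region phantom and map the metrics
ph   <- simulatePhantom(phantomSpec(seed = 1))
mm   <- computeMetricMaps(ph$series)          # SDC, DDVD, ADC maps
trip <- roiAggregate(mm, roiMask(ph$regionMap == 3L))
trip
#> MetricTriplet: SDC 0.5562 au/s, DDVD 19.65 au/pixel, ADC 13.41 1e-4 mm2/s

# a synthetic 63-case cohort with the published genotype group structure
co <- simulateCohort(defaultCohortSpec(seed = 1))
rocCurve(co$sdc_au_per_s, co$idh_gene)
#> ROCResult: AUC = 0.8152 (30 positives vs 33 negatives, rule value > threshold)

youdenRow(cutoffTable(co$sdc_au_per_s, co$idh_gene))
#>    threshold tp fn tn fp sensitivity sensLow sensHigh specificity specLow
#> 35    0.3931 22  8 27  6       73.33   55.55    85.82       81.82   65.61
#>    specHigh likelihoodRatio
#> 35    91.39           4.033

# the published reference model, with unit-tagged inputs
predictProbability(metricTriplet(0.437, 30, 10, adcUnit = "1e-4 mm2/s"))
#> [1] 0.3314

# refit the same model form to this cohort
fit <- fitLogistic(co)
fit$coeffs
#> LogisticCoefficients [refit]
#>   eta = 7.524*SDC -0.08667*DDVD +0.6908*ADC -8.536
#>   units: SDC au/s; DDVD au/pixel; ADC 1e-4 mm2/s
fit$auc
#> [1] 0.904
```

Reading: on this seeded cohort, SDC alone separates the genotypes with an
AUC of 0.815 (higher SDC ⇒ IDH-mutant); the Youden-optimal cutoff
(> 0.393 au/s) gives 73% sensitivity and 82% specificity, i.e. a positive
likelihood ratio of about 4; the reference model assigns a 0.33 mutant
probability to a lesion with SDC 0.437, DDVD 30, ADC 10×10⁻⁴; and
combining all three metrics raises the in-sample AUC to 0.904.

Real data enter through `loadDWISeries()` (4-D NIfTI or per-b volumes plus
an FSL-style `.bval`), `loadROIMask()` and `readCohort()`; the end-to-end
workflow, including JSON/Markdown reporting, is `runPipeline(runConfig(...))`
or the `inst/cli/sdc-glioma.R` command-line front end.

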