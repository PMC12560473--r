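Package: gliomaSDC
Title: Slow Diffusion Coefficient, DDVD and ADC Mapping for IDH Genotyping
    of Diffuse Gliomas
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pixelwise computation of three diffusion-weighted MRI metrics
    from multi-b-value acquisitions: the slow diffusion coefficient (SDC,
    a linear signal-difference metric between b = 500 and 750 s/mm2), the
    diffusion-derived vessel density (DDVD, the per-pixel signal drop
    between b = 0 and 10 s/mm2) and the conventional apparent diffusion
    coefficient (ADC, b = 0 and 1000 s/mm2). Provides ROI aggregation,
    cohort-level nonparametric group tests, correlations with Fisher-z
    confidence intervals, inter-reader intraclass correlation, empirical
    ROC analysis with cutoff tables (sensitivity, specificity, hybrid
    Wilson/Brown confidence intervals, positive likelihood ratios), and a
    combined three-metric logistic model for the probability of a glioma
    being IDH-mutant, shipped with a fixed published reference coefficient
    set and refittable to new cohorts. Includes bi-exponential
    (perfusion + diffusion) phantom and cohort simulators with Rician
    noise for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
biocViews: Software, MedicalImaging, Classification, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
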