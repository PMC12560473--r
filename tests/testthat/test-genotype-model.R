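test_that("the reference model evaluates its logistic form exactly", {
  ref <- referenceModel()
  expect_equal(unname(coef(ref)),
               c(8.941, -0.124, 0.034, -1.229))

  # zero triplet: p = 1/(1+e^{1.229})
  t0 <- metricTriplet(0, 0, 0, adcUnit = "1e-4 mm2/s")
  expect_equal(predictProbability(t0, ref), 1 / (1 + exp(1.229)),
               tolerance = 1e-12)
  expect_equal(round(predictProbability(t0, ref), 4), 0.2264)

  # eta = 8.941*0.437 - 0.124*30 + 0.034*10 - 1.229 = -0.7018
  t1 <- metricTriplet(0.437, 30, 10, adcUnit = "1e-4 mm2/s")
  expect_equal(predictProbability(t1, ref), plogis(-0.701783),
               tolerance = 1e-6)
  expect_equal(round(predictProbability(t1, ref), 4), 0.3314)

  # all-zero coefficients: p = 0.5 everywhere
  null <- logisticCoefficients(0, 0, 0, 0)
  expect_equal(predictProbability(t1, null), 0.5)
})

test_that("probabilities are strictly monotone with the published sign pattern", {
  ref <- referenceModel()
  base <- metricTriplet(0.4, 30, 11, adcUnit = "1e-4 mm2/s")
  p0 <- predictProbability(base, ref)
  up <- function(sdc = 0.4, ddvd = 30, adc = 11)
    predictProbability(metricTriplet(sdc, ddvd, adc,
                                     adcUnit = "1e-4 mm2/s"), ref)
  for (d in c(0.01, 0.1, 1)) {
    expect_gt(up(sdc = 0.4 + d / 10), p0)     # increasing in SDC
    expect_lt(up(ddvd = 30 + d), p0)          # decreasing in DDVD
    expect_gt(up(adc = 11 + d), p0)           # increasing in ADC
  }
  expect_true(p0 > 0 && p0 < 1)
})

test_that("unit tags drive a single ADC conversion, never a double one", {
  ref <- referenceModel()
  raw <- metricTriplet(0.437, 30, 10e-4, adcUnit = "mm2/s")
  tagged <- metricTriplet(0.437, 30, 10, adcUnit = "1e-4 mm2/s")
  expect_equal(predictProbability(raw, ref),
               predictProbability(tagged, ref), tolerance = 1e-12)
  # conversion is idempotent
  expect_identical(adcToModelUnits(adcToModelUnits(raw)),
                   adcToModelUnits(raw))
  # a cohort frame must carry the unit-named ADC column
  bad <- data.frame(sdc_au_per_s = 0.4, ddvd_au_per_pixel = 30,
                    adc_mm2_per_s = 1e-3)
  expect_error(predictProbability(bad, ref), "adc_e4_mm2_per_s")
})

test_that("classification applies the documented tie rule and handles empty input", {
  co <- data.frame(subject_id = c("a", "b", "c"),
                   sdc_au_per_s = c(0.6, 0.1, 0.35),
                   ddvd_au_per_pixel = c(20, 45, 30),
                   adc_e4_mm2_per_s = c(13, 8, 11))
  cls <- classifyCohort(co)
  expect_equal(cls$predictedClass, as.integer(cls$probability >= 0.5))

  # probability 0.842 is called mutant-positive at the 0.5 threshold
  expect_equal(classifyCohort(co[1, , drop = FALSE])$predictedClass, 1L)

  # exactly-at-threshold is positive
  cls2 <- classifyCohort(co, threshold = cls$probability[3])
  expect_equal(cls2$predictedClass[3], 1L)

  empty <- classifyCohort(co[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

simulateFromModel <- function(n, coeffs, seed) {
  set.seed(seed)
  df <- data.frame(sdc_au_per_s = rnorm(n, 0.39, 0.08),
                   ddvd_au_per_pixel = rnorm(n, 30, 11),
                   adc_e4_mm2_per_s = rnorm(n, 11.5, 2.5))
  p <- predictProbability(df, coeffs)
  df$idh_gene <- rbinom(n, 1, p)
  df$subject_id <- seq_len(n)
  df
}

test_that("the fit recovers generating coefficients within 3 SE", {
  df <- simulateFromModel(5000, referenceModel(), seed = 121)
  fit <- fitLogistic(df)
  expect_true(fit$converged)
  cf <- coef(fit$coeffs)
  truth <- coef(referenceModel())
  for (nm in names(truth))
    expect_lt(abs(cf[[nm]] - truth[[nm]]), 3 * fit$se[[nm]])
})

test_that("independent labels give slope coefficients near zero", {
  set.seed(131)
  df <- simulateFromModel(4000, logisticCoefficients(0, 0, 0, 0),
                          seed = 131)
  fit <- fitLogistic(df)
  for (nm in c("sdc", "ddvd", "adc"))
    expect_lt(abs(coef(fit$coeffs)[[nm]]), 3 * fit$se[[nm]])
})

test_that("separation and degenerate labels are reported, not returned", {
  df <- data.frame(sdc_au_per_s = c(1:5 / 10, 6:10 / 10),
                   ddvd_au_per_pixel = 30, adc_e4_mm2_per_s = 11,
                   idh_gene = rep(c(0, 1), each = 5))
  expect_error(suppressWarnings(fitLogistic(df)), "separation")
  df$idh_gene <- 1
  expect_error(fitLogistic(df), "single class")
})

test_that("the combined fit dominates single-metric AUCs in-sample", {
  co <- simulateCohort(defaultCohortSpec(seed = 17))
  fit <- fitLogistic(co)
  for (m in c("sdc_au_per_s", "ddvd_au_per_pixel", "adc_e4_mm2_per_s")) {
    single <- auc(rocCurve(co[[m]], co$idh_gene))
    expect_gte(fit$auc + 1e-12, max(single, 1 - single))
  }
  # AUC of probabilities equals AUC of the linear predictor (monotone map)
  p <- predictProbability(co, fit$coeffs)
  eta <- qlogis(p)
  expect_equal(auc(rocCurve(p, co$idh_gene)),
               auc(rocCurve(eta, co$idh_gene)), tolerance = 1e-12)
})

test_that("IHC partial-positive cases are dropped, not merged", {
  co <- simulateCohort(defaultCohortSpec(seed = 19))
  fit <- fitLogistic(co, label = "idh_ihc")
  expect_equal(fit$n, sum(co$idh_ihc != 0.5))
})

test_that("coefficients round-trip through JSON", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "coef.json")
  writeCoefficients(referenceModel(), p)
  back <- readCoefficients(p)
  expect_equal(coef(back), coef(referenceModel()))
  expect_identical(back@label, "paper-2025-reference")
})
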