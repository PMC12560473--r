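test_that("SDC map matches hand values and the decay closed form", {
  s <- dwiSeries(c(500, 750),
                 list(array(250, c(2, 2, 1)), array(200, c(2, 2, 1))))
  expect_true(all(computeSDC(s) == (250 - 200) / 250))

  same <- dwiSeries(c(500, 750),
                    list(array(42, c(2, 2, 1)), array(42, c(2, 2, 1))))
  expect_true(all(computeSDC(same) == 0))

  # mono-exponential S0=1000, D=1e-3: SDC = (606.531-472.367)/250
  mono <- monoExpSeries(S0 = 1000, D = 1e-3)
  expect_equal(unique(as.vector(computeSDC(mono))),
               1000 * (exp(-0.5) - exp(-0.75)) / 250, tolerance = 1e-12)
  expect_equal(unique(as.vector(computeSDC(mono))), 0.53666,
               tolerance = 1e-4)

  expect_error(computeSDC(mono, 750, 500), "b1 < b2")
  expect_error(computeSDC(mono, 500, 600), "no volume at b = 600")
})

test_that("ADC recovers D exactly on mono-exponential series, any b-pair", {
  mono <- monoExpSeries(S0 = 1000, D = 1e-3)
  for (pair in list(c(0, 1000), c(0, 500), c(500, 750), c(10, 750))) {
    adc <- computeADC(mono, pair[1], pair[2])
    expect_equal(unique(as.vector(adc$map)), 1e-3, tolerance = 1e-12)
  }
  # equal signals -> ADC 0
  same <- dwiSeries(c(0, 1000),
                    list(array(7, c(2, 2, 1)), array(7, c(2, 2, 1))))
  expect_true(all(computeADC(same)$map == 0))
})

test_that("non-positive signal voxels are NaN-flagged, others unaffected", {
  v0 <- array(1000, c(2, 2, 1))
  v1 <- array(367.879441, c(2, 2, 1))
  v1[1, 1, 1] <- 0
  s <- dwiSeries(c(0, 1000), list(v0, v1))
  adc <- computeADC(s)
  expect_true(is.nan(adc$map[1, 1, 1]))
  expect_false(adc$valid[1, 1, 1])
  expect_equal(adc$map[2, 2, 1], 1e-3, tolerance = 1e-8)
  expect_equal(sum(adc$valid), 3)
})

test_that("DDVD scalar equals the ROI mean of its pixelwise map, exactly", {
  # 100-pixel ROI, signal sums 10000 and 9000 -> 100 - 90 = 10 au/pixel
  v0 <- array(100, c(10, 10, 1))
  v10 <- array(90, c(10, 10, 1))
  s <- dwiSeries(c(0, 10), list(v0, v10))
  m <- roiMask(array(1, c(10, 10, 1)))
  dd <- computeDDVD(s, m)
  expect_equal(dd$scalar, 10)

  # identical volumes -> 0
  s2 <- dwiSeries(c(0, 10), list(v0, v0))
  expect_equal(computeDDVD(s2, m)$scalar, 0)

  # exact map/scalar identity on a random mask over a noisy phantom
  ph <- simulatePhantom(phantomSpec(seed = 6,
    regions = defaultPhantomRegions(snr = 30)$regions))
  set.seed(8)
  inc <- array(runif(prod(gridDim(ph$series))) < 0.3, gridDim(ph$series))
  msk <- roiMask(inc)
  dd2 <- computeDDVD(ph$series, msk)
  expect_identical(dd2$scalar, mean(dd2$map[maskArray(msk)]))
})

test_that("DDVD matches the bi-exponential closed form", {
  p <- tissueParams(S0 = 1000, f = 0.2, Dstar = 50e-3, Dt = 1e-3,
                    snr = Inf)
  map <- array(1L, c(3, 3, 1))
  ph <- simulatePhantom(phantomSpec(bValues = c(0, 10, 500, 750),
                                    regions = list(p), regionMap = map))
  dd <- computeDDVD(ph$series, roiMask(array(1, c(3, 3, 1))))
  truth <- 1000 * (0.2 * (1 - exp(-0.5)) + 0.8 * (1 - exp(-0.01)))
  expect_equal(dd$scalar, truth, tolerance = 1e-12)
  expect_equal(dd$scalar, 86.66, tolerance = 1e-4)
})

test_that("scale covariance: c*signal scales SDC and DDVD, leaves ADC fixed", {
  ph <- simulatePhantom(phantomSpec(seed = 11,
    regions = defaultPhantomRegions(snr = 40)$regions))
  s1 <- ph$series
  cfac <- 3.7
  s2 <- dwiSeries(bValues(s1),
                  lapply(s1@volumes, function(v) cfac * v))
  m1 <- computeMetricMaps(s1); m2 <- computeMetricMaps(s2)
  expect_equal(m2@sdc, cfac * m1@sdc, tolerance = 1e-12)
  expect_equal(m2@ddvd, cfac * m1@ddvd, tolerance = 1e-12)
  expect_equal(m2@adc, m1@adc, tolerance = 1e-12)
})

test_that("ROI aggregation is the mean over valid in-mask voxels", {
  d <- c(4, 4, 2)
  mk <- function(x) array(x, d)
  maps <- new("MetricMaps", sdc = mk(0.4), ddvd = mk(30),
              adc = mk(1.1e-3), adcValid = mk(TRUE),
              bPairs = list(sdc = c(500, 750), ddvd = c(0, 10),
                            adc = c(0, 1000)))
  tr <- roiAggregate(maps, roiMask(mk(1)))
  expect_equal(tr@sdc, 0.4)
  expect_equal(tr@ddvd, 30)
  expect_equal(tr@adc, 11)                   # converted to 1e-4 mm2/s
  expect_identical(tr@adcUnit, "1e-4 mm2/s")

  # two-voxel mean
  sdc2 <- mk(0); sdc2[1, 1, 1] <- 0.3; sdc2[2, 1, 1] <- 0.5
  maps2 <- new("MetricMaps", sdc = sdc2, ddvd = mk(1), adc = mk(1e-3),
               adcValid = mk(TRUE), bPairs = maps@bPairs)
  inc <- mk(0); inc[1:2, 1, 1] <- 1
  expect_equal(roiAggregate(maps2, roiMask(inc))@sdc, 0.4)

  # invalid ADC voxels are excluded and counted; all-invalid errors
  adc3 <- mk(1e-3); adc3[1, 1, 1] <- NaN
  valid3 <- mk(TRUE); valid3[1, 1, 1] <- FALSE
  maps3 <- new("MetricMaps", sdc = mk(0.4), ddvd = mk(30), adc = adc3,
               adcValid = valid3, bPairs = maps@bPairs)
  tr3 <- roiAggregate(maps3, roiMask(mk(1)))
  expect_equal(unname(tr3@nInvalid["adc"]), 1L)
  expect_equal(tr3@adc, 10)
  maps4 <- new("MetricMaps", sdc = mk(0.4), ddvd = mk(30), adc = mk(NaN),
               adcValid = mk(FALSE), bPairs = maps@bPairs)
  expect_error(roiAggregate(maps4, roiMask(mk(1))), "adc")
})

test_that("wildtype-like tissue has lower SDC and higher DDVD than mutant-like", {
  ph <- simulatePhantom(phantomSpec())    # noiseless default regions
  mm <- computeMetricMaps(ph$series)
  wt <- roiMask(ph$regionMap == 2L)
  mu <- roiMask(ph$regionMap == 3L)
  twt <- roiAggregate(mm, wt); tmu <- roiAggregate(mm, mu)
  expect_lt(twt@sdc, tmu@sdc)
  expect_gt(twt@ddvd, tmu@ddvd)
  expect_lt(twt@adc, tmu@adc)
})

test_that("noisy ROI SDC stays within sampling error of the noiseless value", {
  p <- tissueParams(S0 = 1000, f = 0.04, Dstar = 20e-3, Dt = 1.3e-3,
                    snr = 50)
  map <- array(1L, c(32, 32, 1))
  inc <- array(0, c(32, 32, 1)); inc[seq_len(310)] <- 1
  ph <- simulatePhantom(phantomSpec(regions = list(p), regionMap = map,
                                    seed = 12))
  trip <- roiAggregate(computeMetricMaps(ph$series), roiMask(inc))
  truth <- (ivimSignal(500, p) - ivimSignal(750, p)) / 250
  # per-voxel SDC noise SD ~ sqrt(2)*(S0/snr)/250; SE over 310 voxels
  se <- sqrt(2) * (1000 / 50) / 250 / sqrt(310)
  expect_lt(abs(trip@sdc - truth), 2 * se + 0.002)  # small Rician bias slack
})

test_that("metric maps write to NIfTI with unit annotations", {
  dir <- withr::local_tempdir()
  ph <- simulatePhantom(phantomSpec(seed = 5))
  mm <- computeMetricMaps(ph$series)
  out <- writeMetricMaps(mm, dir)
  expect_true(all(file.exists(out)))
  back <- RNifti::readNifti(out[["sdc"]])
  expect_equal(array(as.numeric(back), dim(back)), mm@sdc,
               tolerance = 1e-6)
})
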