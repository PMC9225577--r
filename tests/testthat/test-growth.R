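test_that("logistic fits recover noiseless generator parameters", {
  s <- logisticSeries(K = 1.2, r = 0.6, N0 = 0.02)
  f <- fitLogistic(s$time, s$od)
  expect_true(f$converged)
  expect_equal(f$r, 0.6, tolerance = 1e-3)
  expect_equal(f$K, 1.2, tolerance = 1e-3)
  expect_equal(f$N0, 0.02, tolerance = 1e-3)
  expect_equal(f$t_dd * f$r, log(2), tolerance = 1e-12)
  ## r = ln 2 per hour means a doubling time of exactly one hour
  s2 <- logisticSeries(K = 1, r = log(2), N0 = 0.02)
  expect_equal(fitLogistic(s2$time, s2$od)$t_dd, 1, tolerance = 1e-3)
})

test_that("flat and decreasing series are flagged no-growth, not fitted", {
  t <- seq(0, 24, by = 0.5)
  f <- fitLogistic(t, rep(0.02, length(t)))
  expect_true(f$noGrowth)
  expect_true(is.na(f$r))
  f2 <- fitLogistic(t, 0.5 * exp(-0.1 * t))
  expect_true(f2$noGrowth)
  expect_error(fitLogistic(1:4, c(0.1, 0.2, 0.3, 0.4)), ">= 8 time points")
  expect_error(fitLogistic(t, -abs(rnorm(length(t)))), "negative OD600")
})

test_that("respiration correction subtracts the mean control drop", {
  expect_equal(cumulativeRespiration(1.00, 0.60, 1.00, 0.95), 0.35)
  expect_equal(cumulativeRespiration(1.00, 0.60,
                                     c(1.00, 1.00), c(0.95, 0.93)), 0.34)
  expect_equal(cumulativeRespiration(1.00, 0.95, 1.00, 0.95), 0)
  expect_error(cumulativeRespiration(1.0, NA, 1.0, 0.95), "missing paired")
})

test_that("measured interaction strength is the growth ratio minus one", {
  expect_identical(measuredInteraction(0, 0.2), -1)
  expect_identical(measuredInteraction(0.2, 0.2), 0)
  expect_equal(measuredInteraction(0.30, 0.20), 0.5)
  expect_error(measuredInteraction(0.1, 0), "must be positive")
  expect_error(measuredInteraction(-0.1, 0.2), "clamped")
})

test_that("the MIS matrix combines mean ratios with per-recipient testing", {
  gv <- rbind(
    data.frame(isolate = "r1", medium = "SDM", replicate = 1:3,
               value = c(0.20, 0.21, 0.19)),
    data.frame(isolate = "r1", medium = "i1", replicate = 1:3,
               value = c(0.10, 0.11, 0.09)),
    data.frame(isolate = "r1", medium = "i2", replicate = 1:3,
               value = c(0.20, 0.21, 0.19)),
    data.frame(isolate = "r1", medium = "i3", replicate = 1:3,
               value = c(0, 0, 0)))
  mis <- misMatrix(gv, metric = "final_od")
  s <- interactionStrengths(mis)
  expect_equal(s["r1", "i1"], 0.10 / 0.20 - 1, tolerance = 1e-12)
  ## independent two-sample oracle agrees the halving is significant
  expect_lt(t.test(c(0.10, 0.11, 0.09), c(0.20, 0.21, 0.19),
                   var.equal = TRUE)$p.value, 0.05)
  expect_true(isSignificant(mis)["r1", "i1"])
  expect_identical(unname(s["r1", "i2"]), 0)
  expect_false(isSignificant(mis)["r1", "i2"])
  expect_equal(s["r1", "i3"], -1)      # no growth at all
  expect_true(all(s >= -1, na.rm = TRUE))
  expect_error(misMatrix(gv[gv$medium != "SDM", ]), "no growth in the reference")
})

test_that("final growth is blank-corrected at the last time point and clamped", {
  od <- rbind(
    data.frame(isolate = "r1", medium = "SDM", replicate = 1,
               time_h = c(0, 24, 48), od600 = c(0.02, 0.5, 0.62)),
    data.frame(isolate = "r1", medium = "i1", replicate = 1,
               time_h = c(0, 24, 48), od600 = c(0.02, 0.02, 0.03)),
    data.frame(isolate = "none", medium = "SDM", replicate = 1,
               time_h = c(0, 24, 48), od600 = c(0.02, 0.02, 0.02)),
    data.frame(isolate = "none", medium = "i1", replicate = 1,
               time_h = c(0, 24, 48), od600 = c(0.04, 0.04, 0.04)))
  fg <- finalGrowth(od)
  expect_equal(fg$value[fg$medium == "SDM"], 0.60)
  expect_equal(fg$value[fg$medium == "i1"], 0)   # 0.03 - 0.04, clamped
})

test_that("fitted parameters recover simulated growth across a community", {
  truth <- simulateTruth(nIsolates = 4, nMetabolites = 20, seed = 8,
                         crossFeeding = FALSE)
  mono <- simulateMonocultures(truth, cv = 0, nReplicates = 2, seed = 8)
  fits <- fitGrowthCurves(mono$growth)
  fits <- fits[!fits$no_growth, ]
  r_true <- truth@growthRate[fits$isolate]
  expect_lt(median(abs(fits$r - r_true) / r_true), 0.01)
})
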