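test_that("risk-group specs have unit mass, positive RRs, and monotone bands", {
  gs <- riskGroupSpec(log(1.5), width = 5)
  expect_length(gs@rr, 20L)
  expect_equal(sum(gs@startWeights), 1)
  expect_true(all(diff(gs@rr) > 0))
  # discrete 20-band mean RR approximates the lognormal mean E[exp(bZ)]
  expect_equal(sum(gs@startWeights * gs@rr), exp(log(1.5)^2 / 2),
               tolerance = 0.01)
  gs1 <- riskGroupSpec(log(1.5), width = 100)
  expect_equal(gs1@rr, 1)
})

test_that("unit relative risks make the baseline equal the marginal incidence exactly", {
  rt <- rateTable(seq(45, 75, 5), seq(50, 80, 5),
                  incidence = seq(1, 7) * 1e-3,
                  mortality = seq(1, 7) * 5e-3)
  gs <- riskGroupSpec(0, width = 5)
  bh <- solveBaselineHazard(rt, gs)
  lamM <- rep(rt@incidence, each = 5)
  expect_equal(bh@hazard, lamM, tolerance = 1e-14)
  expect_lte(attr(bh, "iterations"), 2L)
})

test_that("with negligible depletion the baseline tends to lambda_m / E[RR]", {
  rt <- rateTable(c(40, 50), c(50, 60), incidence = c(1e-8, 1e-8),
                  mortality = c(0, 0))
  gs <- new("RiskGroupSpec", bandLow = c(0, 50), bandHigh = c(50, 100),
            rr = c(1, 3), startWeights = c(0.5, 0.5), perSdLogHR = NA_real_)
  bh <- solveBaselineHazard(rt, gs)
  expect_equal(bh@hazard, rep(1e-8 / 2, 20), tolerance = 1e-6)
})

test_that("the converged baseline satisfies the marginal constraint at every age step", {
  b <- log(1.8)
  rt <- rateTable(seq(45, 75, 5), seq(50, 80, 5),
                  incidence = c(1, 2, 3, 4, 5, 6, 7) * 1e-3,
                  mortality = exp(-10 + 0.09 * seq(47.5, 77.5, 5)))
  gs <- riskGroupSpec(b, width = 5)
  bh <- solveBaselineHazard(rt, gs, tol = 1e-10)
  piM <- attr(bh, "atRiskWeights")
  lamM <- rep(rt@incidence, each = 5)
  recon <- as.numeric(piM %*% gs@rr) * bh@hazard
  expect_lt(max(abs(recon - lamM)), 1e-8)
})

test_that("the solver recovers the generating baseline from an analytic rate table", {
  b <- log(1.5)
  cfg <- simConfig(perSdLogHR = b, baselineHazard = 0.002,
                   mortalityHazard = function(a) exp(-10 + 0.09 * a),
                   seed = 1L)
  rt <- makeRateTable(cfg, cbind(seq(45, 75, 5), seq(50, 80, 5)))
  bh <- solveBaselineHazard(rt, riskGroupSpec(b, width = 5))
  relerr <- abs(bh@hazard / 0.002 - 1)
  # the analytic table ignores risk-set depletion, so the inversion drifts
  # slowly with age: ~0.2% at entry (20-band discretization of E[exp(bZ)])
  # growing to ~1.4% after 35 years
  expect_lt(max(relerr[bh@age <= 65]), 0.01)
  expect_lt(max(relerr), 0.02)
})

test_that("five-year absolute risk matches the constant-hazard closed form", {
  rt <- rateTable(50, 60, incidence = 0.01, mortality = 0.02)
  gs <- riskGroupSpec(0.3, width = 100)  # single band, RR = 1
  bh <- solveBaselineHazard(rt, gs)
  expect_equal(bh@hazard, rep(0.01, 10))
  ar <- fiveYearAbsoluteRisk(bh, rt, gs, ages = 50)
  expect_equal(ar$ar5, 0.01 / 0.03 * (1 - exp(-0.15)), tolerance = 1e-10)

  # zero baseline -> zero risk
  rt0 <- rateTable(50, 60, incidence = 0, mortality = 0.02)
  bh0 <- solveBaselineHazard(rt0, gs)
  ar0 <- fiveYearAbsoluteRisk(bh0, rt0, gs, ages = 50)
  expect_equal(ar0$ar5, 0)

  expect_error(fiveYearAbsoluteRisk(bh, rt, gs, ages = 58),
               "coverage")
})

test_that("absolute risk increases with relative risk and respects the cumulative bound", {
  b <- log(1.6)
  rt <- rateTable(seq(45, 75, 5), seq(50, 80, 5),
                  incidence = rep(2e-3, 7), mortality = rep(8e-3, 7))
  gs <- riskGroupSpec(b, width = 5)
  bh <- solveBaselineHazard(rt, gs)
  ar <- fiveYearAbsoluteRisk(bh, rt, gs, ages = c(50, 60, 70))
  for (a in c(50, 60, 70)) {
    r <- ar$ar5[ar$age == a]
    expect_true(all(diff(r) > 0))          # monotone in RR
    h5 <- 5 * bh@hazard[match(a, bh@age)] * gs@rr
    expect_true(all(r <= 1 - exp(-h5) + 1e-12))
  }
  # longer horizon, larger risk
  ar10 <- fiveYearAbsoluteRisk(bh, rt, gs, ages = 50, horizon = 10)
  expect_true(all(ar10$ar5 > ar$ar5[ar$age == 50]))
})

test_that("marginal consistency of group-mixture risks holds after convergence", {
  gs1 <- riskGroupSpec(0, width = 5)
  rt <- rateTable(seq(45, 75, 5), seq(50, 80, 5),
                  incidence = rep(2e-3, 7),
                  mortality = exp(-10 + 0.09 * seq(47.5, 77.5, 5)))
  bh1 <- solveBaselineHazard(rt, gs1)
  expect_lt(marginalCheck(bh1, rt, gs1), 1e-14)

  gs2 <- riskGroupSpec(log(1.8), width = 5)
  bh2 <- solveBaselineHazard(rt, gs2)
  expect_lt(marginalCheck(bh2, rt, gs2), 1e-5)
})

test_that("per-subject risk prediction indexes the curve by age and PRS band", {
  b <- log(1.5)
  rt <- rateTable(c(45, 50, 55), c(50, 55, 60), incidence = rep(2e-3, 3),
                  mortality = rep(6e-3, 3))
  gs <- riskGroupSpec(b, width = 25)  # 4 bands for a small test
  bh <- solveBaselineHazard(rt, gs)
  curve <- fiveYearAbsoluteRisk(bh, rt, gs, ages = 45:55)
  z <- c(-2, -0.5, 0.5, 2)
  pred <- predictFiveYearRisk(z, c(45.4, 45.9, 45.2, 45.7), curve, gs)
  expect_equal(pred,
               curve$ar5[curve$age == 45][.rankGroupsForTest(z, 4)])
  expect_true(all(diff(pred) > 0))
  expect_error(predictFiveYearRisk(z, rep(80, 4), curve, gs), "cover")
})

test_that("microsimulation under the solved baseline reproduces the marginal incidence", {
  b <- log(1.5)
  cfg <- simConfig(perSdLogHR = b, baselineHazard = 0.003,
                   mortalityHazard = function(a) exp(-10 + 0.09 * a),
                   seed = 1L)
  rt <- makeRateTable(cfg, cbind(seq(50, 70, 5), seq(55, 75, 5)))
  gs <- riskGroupSpec(b, width = 5)
  bh <- solveBaselineHazard(rt, gs)
  ms <- microsimulateIncidence(bh, rt, gs, n = 2e5, seed = 9L)
  expect_true(all(abs(ms$observed - ms$expected) <= 3 * ms$se))
})
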