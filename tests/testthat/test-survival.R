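test_that("follow-up construction applies the cap and competing censorings", {
  co <- data.frame(time = c(8, 22, 17.3, 21),
                   event = c("cancer", "death", "censored", "cancer"))
  fu <- computeFollowUp(co, capYears = 20)
  expect_equal(fu$time, c(8, 20, 17.3, 20))
  expect_equal(fu$event, c(1L, 0L, 0L, 0L))
  expect_error(computeFollowUp(data.frame(time = -1, event = "cancer")),
               "negative")
})

test_that("quantile groups are balanced with the middle group as reference", {
  a <- assignQuantileGroups(1:10, K = 5)
  expect_equal(as.integer(table(a$group)), rep(2L, 5))
  expect_identical(a$reference, 3L)
  expect_equal(a$group[1:2], c(1L, 1L))
  expect_equal(a$group[9:10], c(5L, 5L))

  expect_error(assignQuantileGroups(rep(1, 10), K = 5), "distinct")
  expect_error(assignQuantileGroups(1:3, K = 5), "at least K")
  expect_message(ae <- assignQuantileGroups(1:8, K = 4), "reference")
  expect_identical(ae$reference, 2L)

  set.seed(51)
  big <- assignQuantileGroups(rnorm(21694), K = 5)
  sizes <- as.integer(table(big$group))
  expect_lte(max(sizes) - min(sizes), 1L)
})

test_that("Cox fits match the grid-search partial-likelihood oracle on tiny data", {
  toy <- data.frame(time = c(2, 4, 6), event = c(1L, 1L, 0L),
                    x = c(1, 0, 2))
  fit <- fitCox(toy$time, toy$event, data.frame(x = toy$x))
  expect_equal(unname(fit$coef["x"]),
               gridCoxOracle(toy$time, toy$event, toy$x),
               tolerance = 1e-4)

  set.seed(52)
  done <- 0
  while (done < 12) {
    n <- sample(4:6, 1)
    time <- sample(1:4, n, TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    event <- rbinom(n, 1, 0.7)
    x <- sample(-1:2, n, TRUE)
    if (sum(event) < 1 || length(unique(x)) < 2) next
    ref <- tryCatch(gridCoxOracle(time, event, x), error = function(e) NA)
    if (!is.finite(ref) || abs(ref) > 3.5) next  # monotone likelihood
    fit <- suppressWarnings(fitCox(time, event, data.frame(x = x)))
    if (fit$divergent) next
    expect_equal(unname(fit$coef["x"]), ref, tolerance = 1e-3)
    done <- done + 1
  }
})

test_that("Cox fitting rejects degenerate inputs and flags divergence", {
  expect_error(fitCox(c(1, 2, 3), c(1, 1, 0),
                      data.frame(x = c(2, 2, 2))), "constant covariate")
  expect_error(fitCox(c(1, 2, 3), c(0, 0, 0),
                      data.frame(x = c(1, 2, 3))), "no events")
  # perfectly separating covariate -> monotone likelihood warning
  expect_warning(
    fit <- fitCox(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                  data.frame(x = c(5, 4, 3, 2, 1, 0))),
    "monotone")
  expect_true(fit$divergent)
})

test_that("hazard-ratio tables have a unit reference and case counts that partition events", {
  set.seed(53)
  cfg <- simConfig(nSamples = 6000L, baselineHazard = 0.004, seed = 53L)
  z <- rnorm(6000)
  co <- simulateCohort(cfg, z)
  fu <- computeFollowUp(co)
  hr <- hrTable(z, fu$time, fu$event, co$age_at_recruitment, K = 5)
  expect_equal(hr$table$hr[3], 1)
  expect_true(all(is.na(hr$table$ci_low[3])))
  expect_equal(sum(hr$table$n_cases), sum(fu$event))
  expect_equal(sum(hr$table$n), 6000L)
  expect_true(all(hr$table$ci_low[-3] <= hr$table$hr[-3] &
                    hr$table$hr[-3] <= hr$table$ci_high[-3]))
  expect_true(hr$perSD$ci_low <= hr$perSD$hr &
                hr$perSD$hr <= hr$perSD$ci_high)
  expect_true(hr$pTrend > 0 && hr$pTrend <= 1)
  expect_true(hr$phPValue > 0 && hr$phPValue <= 1)
})

test_that("top-vs-middle quintile hazard ratio follows the truncated-normal prediction", {
  b <- log(1.5)
  cfg <- simConfig(nSamples = 20000L, perSdLogHR = b,
                   baselineHazard = 0.003, seed = 54L)
  z <- rnorm(20000)
  co <- simulateCohort(cfg, z, seed = 541L)
  fu <- computeFollowUp(co)
  hr <- hrTable(z, fu$time, fu$event, co$age_at_recruitment, K = 5)
  # E[Z | top 20%] - E[Z | middle 20%] = dnorm(qnorm(.8))/.2 ~ 1.40
  want <- exp(b * dnorm(qnorm(0.8)) / 0.2)
  expect_lt(abs(log(hr$table$hr[5] / want)), 0.30)
})

test_that("per-SD hazard ratios are invariant to affine rescaling of the raw score", {
  set.seed(55)
  cfg <- simConfig(nSamples = 3000L, baselineHazard = 0.005, seed = 55L)
  raw <- rnorm(3000, 10, 4)
  z1 <- standardizePRS(raw)
  z2 <- standardizePRS(-2 * raw + 5)
  co <- simulateCohort(cfg, z1)
  fu <- computeFollowUp(co)
  f1 <- fitCox(fu$time, fu$event,
               data.frame(z = z1, age = co$age_at_recruitment))
  f2 <- fitCox(fu$time, fu$event,
               data.frame(z = -z2, age = co$age_at_recruitment))
  expect_equal(unname(f1$coef["z"]), unname(f2$coef["z"]),
               tolerance = 1e-10)
})

test_that("trend and proportional-hazards tests reject degenerate inputs", {
  expect_error(trendTest(rep(1L, 10), runif(10), rbinom(10, 1, 0.5),
                         rnorm(10)), "two populated groups")
  fit <- suppressWarnings(fitCox(c(1, 2, 3, 4), c(1, 0, 1, 0),
                                 data.frame(x = c(1, 0, 1, 2))))
  p <- phCheck(fit)
  expect_true(all(p > 0 & p <= 1))
})
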