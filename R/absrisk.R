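#' PRS percentile bands with truncated-normal relative risks
#'
#' Divides the standardized PRS into percentile bands (default 20 bands of
#' width 5) and assigns each band the relative risk
#' RR_g = exp(beta * E[Z | band]) where beta is the per-SD log hazard
#' ratio and E[Z | band] is the mean of a standard normal truncated to the
#' band's quantile interval.  Starting weights are the band widths.
#'
#' @param perSdLogHR per-SD log hazard ratio.
#' @param width band width in percentiles (must divide 100).
#' @return a \linkS4class{RiskGroupSpec}.
#' @export
riskGroupSpec <- function(perSdLogHR, width = 5) {
  stopifnot(100 %% width == 0)
  lo <- seq(0, 100 - width, by = width)
  hi <- lo + width
  qlo <- qnorm(lo / 100); qhi <- qnorm(hi / 100)
  # truncated standard normal mean on (qlo, qhi)
  ez <- (dnorm(qlo) - dnorm(qhi)) / (hi / 100 - lo / 100)
  new("RiskGroupSpec", bandLow = lo, bandHigh = hi,
      rr = exp(perSdLogHR * ez),
      startWeights = rep(width / 100, length(lo)),
      perSdLogHR = perSdLogHR)
}

# expand a RateTable to 1-year steps (ages a0 .. amax-1)
.expandRates <- function(rates) {
  a0 <- min(rates@ageLow); aMax <- max(rates@ageHigh)
  age <- seq(a0, aMax - 1)
  band <- findInterval(age, rates@ageLow)
  list(age = age, incidence = rates@incidence[band],
       mortality = rates@mortality[band])
}

#' Solve the PRS-group-constrained baseline hazard
#'
#' Finds the baseline cancer hazard lambda0(a) on 1-year age steps such
#' that the population marginal incidence is reproduced when the
#' group-specific hazards lambda0(a) RR_g are averaged over the surviving
#' group mixture:
#' lambda_m(a) = sum_g pi_g(a) lambda0(a) RR_g,
#' where pi_g(a) are at-risk weights that start at the band proportions
#' and are depleted by both the group-specific cancer hazard and the
#' shared competing mortality.  Iterates
#' lambda0(a) <- lambda_m(a) / sum_g pi_g(a) RR_g and recomputes the
#' at-risk weights from group survival until the largest change in
#' lambda0 falls below \code{tol}.
#'
#' @param rates a \linkS4class{RateTable} (marginal incidence and
#'   mortality).
#' @param groups a \linkS4class{RiskGroupSpec}.
#' @param tol convergence tolerance on max |change in lambda0|.
#' @param maxIter iteration cap.
#' @return a \linkS4class{BaselineHazard}; the converged at-risk weights
#'   are attached as attribute \code{"atRiskWeights"} (ages x groups).
#' @export
solveBaselineHazard <- function(rates, groups, tol = 1e-8,
                                maxIter = 1000L) {
  stopifnot(is(rates, "RateTable"), is(groups, "RiskGroupSpec"))
  ex <- .expandRates(rates)
  lamM <- ex$incidence; m <- ex$mortality
  nA <- length(lamM)
  rr <- groups@rr; w0 <- groups@startWeights
  G <- length(rr)
  piM <- matrix(w0, nA, G, byrow = TRUE)
  lam0 <- rep(0, nA)
  for (iter in seq_len(maxIter)) {
    denom <- as.numeric(piM %*% rr)
    if (any(denom <= 0 & lamM > 0))
      stop("marginal incidence positive where all group weights vanish")
    lam0new <- ifelse(denom > 0, lamM / denom, 0)
    # group survival to the start of each age step (cancer + mortality)
    cumH <- outer(.cumsum0(lam0new), rr) + .cumsum0(m)
    Sg <- exp(-cumH)
    piM <- sweep(Sg, 2, w0, "*")
    piM <- piM / rowSums(piM)
    if (max(abs(lam0new - lam0)) < tol) {
      bh <- new("BaselineHazard", age = ex$age, hazard = lam0new)
      attr(bh, "atRiskWeights") <- piM
      attr(bh, "iterations") <- iter
      return(bh)
    }
    lam0 <- lam0new
  }
  stop("baseline-hazard iteration did not converge in ", maxIter,
       " iterations; residual ", signif(max(abs(lam0new - lam0)), 3))
}

#' Five-year absolute risk by age and PRS band
#'
#' With piecewise-constant hazards on 1-year steps and death as the
#' competing event, the probability of the cancer within [a, a + horizon)
#' given alive and cancer-free at a is
#' sum over steps u of  h_g(u) / (h_g(u) + m(u)) * (1 - exp(-(h_g + m)))
#' * exp(-sum of earlier (h_g + m)),  with h_g = lambda0 RR_g.
#'
#' @param bh a \linkS4class{BaselineHazard}.
#' @param rates a \linkS4class{RateTable} supplying mortality.
#' @param groups a \linkS4class{RiskGroupSpec}.
#' @param ages starting ages (1-year steps must cover [a, a + horizon)).
#' @param horizon window in years (default 5).
#' @return long data.frame: \code{age}, \code{band} (group index),
#'   \code{band_low}, \code{band_high}, \code{ar5}.
#' @export
fiveYearAbsoluteRisk <- function(bh, rates, groups, ages, horizon = 5) {
  stopifnot(is(bh, "BaselineHazard"), is(groups, "RiskGroupSpec"))
  ex <- .expandRates(rates)
  if (any(!(ages %in% bh@age)) ||
      any(!((max(ages) + horizon - 1) %in% bh@age)))
    stop("requested ages exceed the baseline hazard's coverage")
  out <- vector("list", length(ages))
  for (k in seq_along(ages)) {
    a <- ages[k]
    steps <- match(seq(a, a + horizon - 1), bh@age)
    l0 <- bh@hazard[steps]
    mm <- ex$mortality[match(seq(a, a + horizon - 1), ex$age)]
    ar <- vapply(seq_along(groups@rr), function(g) {
      h <- l0 * groups@rr[g]
      tot <- h + mm
      surv <- exp(-.cumsum0(tot))
      term <- ifelse(tot > 0, h / tot * (1 - exp(-tot)), 0)
      sum(term * surv)
    }, numeric(1))
    out[[k]] <- data.frame(age = a, band = seq_along(groups@rr),
                           band_low = groups@bandLow,
                           band_high = groups@bandHigh, ar5 = ar)
  }
  do.call(rbind, out)
}

#' Marginal-consistency residual of a converged absolute-risk solution
#'
#' Verifies the defining constraint: at every starting age, the mixture of
#' group-level 5-year risks weighted by the at-risk group distribution
#' must equal the 5-year risk computed directly from the marginal
#' incidence.  Returns the maximum absolute discrepancy over starting
#' ages.
#'
#' @param bh a converged \linkS4class{BaselineHazard} (from
#'   \code{\link{solveBaselineHazard}}).
#' @param rates the \linkS4class{RateTable} it was solved against.
#' @param groups the \linkS4class{RiskGroupSpec}.
#' @param horizon window in years.
#' @return the residual (a single number).
#' @export
marginalCheck <- function(bh, rates, groups, horizon = 5) {
  ex <- .expandRates(rates)
  piM <- attr(bh, "atRiskWeights")
  ages <- bh@age[bh@age + horizon - 1 <= max(bh@age)]
  curve <- fiveYearAbsoluteRisk(bh, rates, groups, ages, horizon)
  resid <- 0
  for (a in ages) {
    i <- match(a, bh@age)
    mix <- sum(piM[i, ] * curve$ar5[curve$age == a])
    steps <- match(seq(a, a + horizon - 1), ex$age)
    lm_ <- ex$incidence[steps]; mm <- ex$mortality[steps]
    tot <- lm_ + mm
    surv <- exp(-.cumsum0(tot))
    marg <- sum(ifelse(tot > 0, lm_ / tot * (1 - exp(-tot)), 0) * surv)
    resid <- max(resid, abs(mix - marg))
  }
  resid
}

#' Per-subject predicted 5-year absolute risk
#'
#' Looks up the band-level 5-year risk for each subject's (integer) age at
#' recruitment and PRS percentile band.
#'
#' @param z standardized PRS (band assignment by empirical percentile).
#' @param age age at recruitment (floored to the 1-year grid).
#' @param curve output of \code{\link{fiveYearAbsoluteRisk}} covering the
#'   cohort's ages.
#' @param groups the \linkS4class{RiskGroupSpec} used for the curve.
#' @return numeric vector of predicted 5-year risks.
#' @export
predictFiveYearRisk <- function(z, age, curve, groups) {
  G <- length(groups@rr)
  band <- .rankGroups(z, G)
  a <- floor(age)
  key <- paste(curve$age, curve$band)
  idx <- match(paste(a, band), key)
  if (anyNA(idx))
    stop("absolute-risk curve does not cover all subject ages")
  curve$ar5[idx]
}

#' Forward microsimulation of incidence under a solved baseline hazard
#'
#' Simulates subjects from the youngest rate-table age under the
#' group-specific hazards lambda0(a) RR_g with competing mortality, and
#' returns per-band empirical incidence (cancer events / person-years)
#' with Monte-Carlo standard errors, for checking that the solved
#' baseline reproduces the marginal rates.
#'
#' @param bh a \linkS4class{BaselineHazard}.
#' @param rates the \linkS4class{RateTable} (for mortality and band
#'   layout).
#' @param groups the \linkS4class{RiskGroupSpec}.
#' @param n number of simulated subjects.
#' @param seed RNG seed.
#' @return data.frame per band: \code{age_low}, \code{age_high},
#'   \code{expected} (table incidence), \code{observed}, \code{se}
#'   (sqrt(events)/person-years), \code{events}, \code{person_years}.
#' @export
microsimulateIncidence <- function(bh, rates, groups, n = 1e6,
                                   seed = 1L) {
  set.seed(seed)
  ex <- .expandRates(rates)
  nA <- length(ex$age)
  grp <- sample.int(length(groups@rr), n, replace = TRUE,
                    prob = groups@startWeights)
  rrInd <- groups@rr[grp]
  alive <- rep(TRUE, n)
  events <- numeric(nA); pt <- numeric(nA)
  for (i in seq_len(nA)) {
    idx <- which(alive)
    if (!length(idx)) break
    h <- bh@hazard[i] * rrInd[idx]
    mm <- ex$mortality[i]
    tot <- h + mm
    tEv <- ifelse(tot > 0, rexp(length(idx)) / tot, Inf)
    isEv <- tEv < 1
    cancer <- isEv & (runif(length(idx)) < h / pmax(tot, 1e-300))
    pt[i] <- sum(pmin(tEv, 1))
    events[i] <- sum(cancer)
    alive[idx[isEv]] <- FALSE
  }
  band <- findInterval(ex$age, rates@ageLow)
  ev <- tapply(events, band, sum)
  py <- tapply(pt, band, sum)
  data.frame(age_low = rates@ageLow, age_high = rates@ageHigh,
             expected = rates@incidence,
             observed = as.numeric(ev / py),
             se = as.numeric(sqrt(ev) / py),
             events = as.numeric(ev), person_years = as.numeric(py))
}
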