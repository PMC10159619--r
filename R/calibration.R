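#' Expected versus observed 5-year risk by PRS decile
#'
#' Splits the cohort into deciles of the PRS; expected is the mean
#' predicted 5-year risk in the decile, observed is the proportion with
#' the cancer within the horizon.  Subjects dying cancer-free within the
#' window stay in the denominator, which is consistent with a predictor
#' that already accounts for competing mortality.
#'
#' @param z standardized PRS.
#' @param time,event follow-up time and 0/1 cancer indicator.
#' @param predicted per-subject predicted risk over the horizon (e.g. from
#'   \code{\link{predictFiveYearRisk}}).
#' @param horizon window in years (default 5).
#' @param nGroups number of PRS groups (default 10 deciles).
#' @return data.frame per decile: \code{decile}, \code{n},
#'   \code{expected}, \code{observed}, \code{observed_count}.
#' @export
decileExpectedObserved <- function(z, time, event, predicted, horizon = 5,
                                   nGroups = 10L) {
  n <- length(z)
  if (n < nGroups) stop("need at least ", nGroups, " subjects")
  stopifnot(length(time) == n, length(event) == n, length(predicted) == n)
  d <- .rankGroups(z, nGroups)
  obsEv <- as.integer(time <= horizon & event == 1L)
  data.frame(
    decile = seq_len(nGroups),
    n = as.integer(table(factor(d, levels = seq_len(nGroups)))),
    expected = as.numeric(tapply(predicted, factor(d,
                                                   levels = seq_len(nGroups)),
                                 mean)),
    observed = as.numeric(tapply(obsEv, factor(d,
                                               levels = seq_len(nGroups)),
                                 mean)),
    observed_count = as.integer(tapply(obsEv,
                                       factor(d,
                                              levels = seq_len(nGroups)),
                                       sum))
  )
}

#' Calibration slope and intercept
#'
#' Ordinary least squares of observed on expected proportions across the
#' PRS groups.  A slope above 1 means the model underestimates absolute
#' risk; below 1, overestimates.
#'
#' @param expected,observed per-group proportions (>= 3 groups with
#'   distinct expected values).
#' @param conf confidence level for the slope interval.
#' @return list: \code{slope}, \code{intercept}, \code{ciLow},
#'   \code{ciHigh}.
#' @export
calibrationSlope <- function(expected, observed, conf = 0.95) {
  if (length(expected) < 3L)
    stop("need at least 3 calibration points")
  if (length(unique(expected)) < 2L)
    stop("expected proportions are all equal; slope undefined")
  fit <- lm(observed ~ expected)
  ci <- suppressWarnings(confint(fit, "expected", level = conf))
  list(slope = unname(coef(fit)["expected"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       ciLow = ci[1], ciHigh = ci[2])
}

#' Hosmer-Lemeshow goodness-of-fit over PRS groups
#'
#' Chi-square statistic sum (O - E)^2 / (E (1 - E/n)) over groups, with
#' df = usable groups - 2 (the within-sample calibration convention).
#' Groups with zero expected and zero observed events are skipped with a
#' warning and the df reduced; a zero-expected group with observed events
#' yields an infinite statistic (p = 0).
#'
#' @param n per-group sizes.
#' @param expected per-group expected proportions.
#' @param observedCounts per-group observed event counts.
#' @return list: \code{statistic}, \code{df}, \code{pValue},
#'   \code{nGroupsUsed}.
#' @export
hosmerLemeshow <- function(n, expected, observedCounts) {
  stopifnot(length(n) == length(expected),
            length(n) == length(observedCounts))
  E <- n * expected
  O <- observedCounts
  degenerate <- E == 0 & O == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " group(s) with zero expected and observed events skipped; ",
            "degrees of freedom reduced")
  }
  use <- !degenerate
  if (sum(use) < 3L) stop("fewer than 3 usable groups")
  if (any(E[use] == 0)) {
    warning("observed events in a zero-expected group")
    return(list(statistic = Inf, df = as.integer(sum(use) - 2L),
                pValue = 0, nGroupsUsed = as.integer(sum(use))))
  }
  denom <- E[use] * (1 - E[use] / n[use])
  denom[denom == 0] <- NA  # saturated cell (expected == n)
  stat <- sum(((O[use] - E[use])^2 / denom), na.rm = TRUE)
  df <- as.integer(sum(use) - 2L)
  list(statistic = stat, df = df,
       pValue = pchisq(stat, df, lower.tail = FALSE),
       nGroupsUsed = as.integer(sum(use)))
}

#' Full calibration report for one score
#'
#' Convenience wrapper: decile table, slope, and Hosmer-Lemeshow test.
#'
#' @inheritParams decileExpectedObserved
#' @return list: \code{deciles}, \code{slope} (list), \code{hl} (list).
#' @export
calibrationReport <- function(z, time, event, predicted, horizon = 5) {
  dec <- decileExpectedObserved(z, time, event, predicted, horizon)
  sl <- calibrationSlope(dec$expected, dec$observed)
  hl <- hosmerLemeshow(dec$n, dec$expected, dec$observed_count)
  list(deciles = dec, slope = sl, hl = hl)
}
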