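#' Compare standardized PRS distributions between cases and controls
#'
#' Welch two-sample t-test (two-sided) of the standardized PRS in incident
#' cases versus non-cases.
#'
#' @param zCases,zControls standardized PRS in each group (>= 2 values
#'   each).
#' @return a list: \code{meanCases}, \code{meanControls}, \code{tStat},
#'   \code{df}, \code{pValue}.
#' @export
compareDistributions <- function(zCases, zControls) {
  if (length(zCases) < 2L || length(zControls) < 2L)
    stop("each group needs at least 2 observations")
  tt <- t.test(zCases, zControls, var.equal = FALSE)
  list(meanCases = mean(zCases), meanControls = mean(zControls),
       tStat = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value)
}

#' AUC as the Mann-Whitney concordance probability
#'
#' AUC is the probability that a random case outranks a random non-case,
#' with ties counted 1/2; for a single monotone predictor this equals the
#' AUC of the corresponding logistic model.  The 95% CI uses the DeLong
#' variance estimator (fast placement-value form), chosen over the
#' bootstrap for determinism.
#'
#' @param scores numeric predictor.
#' @param labels binary case indicator (logical or 0/1).
#' @param conf confidence level.
#' @return a list: \code{auc}, \code{ciLow}, \code{ciHigh}, \code{se},
#'   \code{nCases}, \code{nControls}.
#' @examples
#' aucMW(c(3, 1, 2, 0, 2, 1), c(1, 1, 1, 0, 0, 0))$auc  # 7/9
#' @export
aucMW <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  m <- sum(labels); n <- sum(!labels)
  if (m == 0L || n == 0L)
    stop("both cases and controls must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
  # placement values: V10_i = fraction of controls below case i (ties 1/2)
  v10 <- (r[labels] - rank(scores[labels])) / n
  v01 <- 1 - (r[!labels] - rank(scores[!labels])) / m
  s2 <- if (m > 1) var(v10) / m else 0
  s2 <- s2 + if (n > 1) var(v01) / n else 0
  se <- sqrt(s2)
  zc <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ciLow = max(0, auc - zc * se),
       ciHigh = min(1, auc + zc * se), se = se,
       nCases = m, nControls = n)
}

#' Age-adjusted discrimination
#'
#' Ranks the linear predictor of a logistic model of case status on the
#' PRS and age, so the AUC reflects the joint two-covariate score.
#'
#' @param scores,labels as in \code{\link{aucMW}}.
#' @param age age at recruitment.
#' @return as \code{\link{aucMW}}, computed on the fitted linear predictor.
#' @export
aucAdjusted <- function(scores, labels, age) {
  fit <- glm(as.logical(labels) ~ scores + age, family = binomial())
  aucMW(fit$linear.predictors, labels)
}

#' Cumulative/dynamic time-dependent AUC at a horizon
#'
#' Cases are subjects with an observed event by the horizon; controls are
#' subjects still at risk beyond it.  Censoring before the horizon is
#' handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution (Chambless-Diao
#' style cumulative/dynamic estimator).
#'
#' @param time follow-up time.
#' @param event event indicator (1 = event of interest).
#' @param scores numeric predictor.
#' @param horizon evaluation time in the same units as \code{time}.
#' @return the estimated AUC(t = horizon) in [0, 1].
#' @export
aucCD <- function(time, event, scores, horizon = 5) {
  event <- as.integer(event)
  caseIdx <- which(time <= horizon & event == 1L)
  ctrlIdx <- which(time > horizon)
  if (length(caseIdx) == 0L)
    stop("no events observed before the horizon")
  if (length(ctrlIdx) == 0L)
    stop("no subjects at risk past the horizon")
  # KM of the censoring distribution G(t)
  cens <- 1L - event
  G <- survival::survfit(survival::Surv(time, cens) ~ 1)
  gAt <- function(t) {
    # left-continuous G(t-)
    s <- c(1, G$surv)
    tt <- c(0, G$time)
    s[findInterval(t - 1e-10, tt)]
  }
  wCase <- 1 / pmax(gAt(time[caseIdx]), 1e-10)
  wCtrl <- rep(1 / pmax(gAt(horizon), 1e-10), length(ctrlIdx))
  sc <- scores[caseIdx]; sn <- scores[ctrlIdx]
  cmp <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
  num <- as.numeric(t(wCase) %*% cmp %*% wCtrl)
  num / (sum(wCase) * sum(wCtrl))
}

#' Select the best-performing PRS
#'
#' Argmax of the unadjusted AUC; exact ties are broken by the smaller
#' fraction of score variants missing from the panel, then by
#' lexicographic score id (ties are reported via \code{message}).
#'
#' @param results list of per-score results, each a list with \code{pgsId},
#'   \code{auc}, and \code{missingFraction}.
#' @return the selected \code{pgsId}.
#' @export
selectBestPRS <- function(results) {
  if (length(results) == 0L) stop("no discrimination results supplied")
  auc <- vapply(results, function(r) r$auc, numeric(1))
  mf <- vapply(results, function(r)
    if (is.null(r$missingFraction)) 0 else r$missingFraction, numeric(1))
  id <- vapply(results, function(r) r$pgsId, character(1))
  best <- which(auc == max(auc))
  if (length(best) > 1L) {
    message("AUC tie among ", paste(id[best], collapse = ", "),
            "; broken by missing fraction then id")
    best <- best[order(mf[best], id[best])]
  }
  unname(id[best[1]])
}
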