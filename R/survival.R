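#' @importFrom survival coxph Surv cox.zph
NULL

#' Follow-up construction for a site-specific cancer endpoint
#'
#' Time runs from recruitment to the first of cancer diagnosis, death, or
#' the administrative end, capped at \code{capYears}.  The event indicator
#' is 1 only for the site-specific cancer occurring at or before the cap;
#' death and the administrative end are censorings for the cancer
#' endpoint.
#'
#' @param cohort cohort data.frame with columns \code{time} (years) and
#'   \code{event} (\code{"cancer"}, \code{"death"}, \code{"censored"}).
#' @param capYears follow-up cap in years (default 20).
#' @return data.frame with columns \code{time} (capped) and \code{event}
#'   (0/1).
#' @export
computeFollowUp <- function(cohort, capYears = 20) {
  if (any(cohort$time < 0)) stop("negative follow-up time")
  t2 <- pmin(cohort$time, capYears)
  ev <- as.integer(cohort$event == "cancer" & cohort$time <= capYears)
  data.frame(time = t2, event = ev)
}

#' Assign balanced PRS quantile groups
#'
#' Ranks subjects by PRS and cuts into K groups of near-equal size
#' (difference at most one when values are distinct); boundary ties are
#' resolved by stable rank order and reported.  The middle group (for K=5,
#' the 40-60% band) is flagged as the reference, reflecting average
#' population risk; for even K the lower-middle group K/2 is used and
#' reported.
#'
#' @param z standardized PRS.
#' @param K number of groups (default 5).
#' @return list with \code{group} (integer 1..K), \code{K},
#'   \code{reference}.
#' @export
assignQuantileGroups <- function(z, K = 5L) {
  K <- as.integer(K)
  if (length(z) < K) stop("need at least K samples")
  if (length(unique(z)) < K)
    stop("fewer distinct PRS values than groups")
  ref <- if (K %% 2L == 1L) (K + 1L) %/% 2L else {
    message("even K: using group ", K %/% 2L, " as reference")
    K %/% 2L
  }
  list(group = .rankGroups(z, K), K = K, reference = ref)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling on time since
#' recruitment; Wald confidence intervals from the coefficient covariance.
#' Constant covariates are rejected (non-identifiable); monotone-likelihood
#' divergence (unbounded coefficients) is flagged.
#'
#' @param time,event follow-up time and 0/1 event indicator.
#' @param covariates data.frame of covariates (factors and numerics).
#' @return list of class \code{"CoxFit"}: \code{coef} (log HR),
#'   \code{cov}, \code{loglik}, \code{nEvents}, \code{divergent},
#'   \code{model} (the underlying fit).
#' @export
fitCox <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1L) stop("no events: cannot fit Cox model")
  for (nmc in names(covariates)) {
    v <- covariates[[nmc]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate '", nmc, "' is not identifiable")
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  divergent <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = "efron",
          x = TRUE, y = TRUE, model = TRUE),
    warning = function(w) {
      if (grepl("infinite|converge|out of iterations", conditionMessage(w)))
        divergent <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)) > 15, na.rm = TRUE)) divergent <- TRUE
  if (divergent)
    warning("monotone likelihood: coefficient estimate diverged; ",
            "estimates capped by the fitter")
  structure(list(coef = coef(fit), cov = vcov(fit),
                 loglik = fit$loglik[length(fit$loglik)],
                 nEvents = sum(event), divergent = divergent, model = fit),
            class = "CoxFit")
}

#' Hazard-ratio table across PRS quantile groups
#'
#' Fits an age-adjusted Cox model with K-1 group indicators against the
#' middle reference group, and a companion per-SD model with the
#' standardized PRS entered continuously.  Reports per-group HR, Wald 95%
#' CI, case counts, the ordinal trend-test p, and the
#' proportional-hazards score-test p for the PRS terms.
#'
#' @param z standardized PRS.
#' @param time,event follow-up (from \code{\link{computeFollowUp}}).
#' @param age age at recruitment.
#' @param K number of quantile groups (default 5).
#' @param extraCovariates optional data.frame of additional adjustment
#'   covariates for the per-SD model (the fully adjusted specification).
#' @return list with \code{table} (data.frame: group, n, n_cases, hr,
#'   ci_low, ci_high, divergent), \code{perSD} (hr, ci_low, ci_high, p),
#'   \code{pTrend}, \code{phPValue}, \code{assignment}.
#' @export
hrTable <- function(z, time, event, age, K = 5L, extraCovariates = NULL) {
  asg <- assignQuantileGroups(z, K)
  grp <- factor(asg$group, levels = c(asg$reference,
                                      setdiff(seq_len(asg$K),
                                              asg$reference)))
  fit <- fitCox(time, event, data.frame(grp = grp, age = age))
  cf <- fit$coef
  se <- sqrt(diag(fit$cov))
  tab <- data.frame(group = seq_len(asg$K),
                    n = as.integer(table(asg$group)),
                    n_cases = as.integer(tapply(event, asg$group, sum)),
                    hr = 1, ci_low = NA_real_, ci_high = NA_real_,
                    divergent = FALSE)
  for (g in setdiff(seq_len(asg$K), asg$reference)) {
    nmg <- paste0("grp", g)
    i <- match(nmg, names(cf))
    tab$hr[g] <- exp(cf[i])
    tab$ci_low[g] <- exp(cf[i] - 1.96 * se[i])
    tab$ci_high[g] <- exp(cf[i] + 1.96 * se[i])
    tab$divergent[g] <- abs(cf[i]) > 15 || tab$n_cases[g] == 0L
  }
  covSD <- data.frame(z = z, age = age)
  if (!is.null(extraCovariates)) covSD <- cbind(covSD, extraCovariates)
  fitSD <- fitCox(time, event, covSD)
  i <- match("z", names(fitSD$coef))
  seSD <- unname(sqrt(diag(fitSD$cov))[i])
  perSD <- list(hr = exp(fitSD$coef[[i]]),
                ci_low = exp(fitSD$coef[[i]] - 1.96 * seSD),
                ci_high = exp(fitSD$coef[[i]] + 1.96 * seSD),
                p = 2 * pnorm(-abs(fitSD$coef[[i]] / seSD)))
  ph <- phCheck(fitSD)
  list(table = tab, perSD = perSD,
       pTrend = trendTest(asg$group, time, event, age),
       phPValue = unname(ph["z"]), assignment = asg)
}

#' Ordinal trend test across PRS groups
#'
#' Enters the group index 1..K as a single continuous covariate in an
#' age-adjusted Cox model and returns the two-sided Wald p-value.
#'
#' @param groups integer group assignment 1..K.
#' @param time,event follow-up.
#' @param age age at recruitment.
#' @return the two-sided Wald p-value.
#' @export
trendTest <- function(groups, time, event, age) {
  if (length(unique(groups)) < 2L)
    stop("trend test needs at least two populated groups")
  fit <- fitCox(time, event, data.frame(ord = as.numeric(groups),
                                        age = age))
  i <- match("ord", names(fit$coef))
  se <- sqrt(diag(fit$cov))[i]
  2 * pnorm(-abs(fit$coef[[i]] / se))
}

#' Proportional-hazards assumption check
#'
#' Score test on scaled Schoenfeld residuals against a time transform
#' (identity by default), per covariate.
#'
#' @param fit a \code{"CoxFit"} from \code{\link{fitCox}}.
#' @param transform time transform passed to the score test.
#' @return named vector of per-covariate p-values.
#' @export
phCheck <- function(fit, transform = "identity") {
  stopifnot(inherits(fit, "CoxFit"))
  if (fit$nEvents == 0L) stop("no events: proportional-hazards test undefined")
  zph <- cox.zph(fit$model, transform = transform, global = FALSE)
  p <- zph$table[, "p"]
  names(p) <- rownames(zph$table)
  p
}
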