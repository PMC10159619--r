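#' Create a synthetic-cohort configuration
#'
#' Defaults emulate a population-based prospective cohort of middle-aged
#' East Asian adults: 20,000 subjects, recruitment ages from a shifted
#' lognormal with median 54 and quartiles near 49 and 63 (truncated to
#' 45-74), up to 20 years of follow-up, incident cancer under a
#' proportional-hazards PRS effect with per-SD HR 1.5 and a constant
#' baseline of 0.002 per person-year (roughly the breast-cancer event
#' yield of such a cohort), and competing all-cause mortality following a
#' Gompertz curve exp(-10 + 0.09 age).
#'
#' @param nSamples,nVariants cohort and panel size.
#' @param mafRange uniform range for simulated minor allele frequencies.
#' @param weightSd SD of simulated per-allele log-odds weights.
#' @param perSdLogHR true log hazard ratio per SD of standardized PRS.
#' @param baselineHazard cancer hazard per person-year (constant or
#'   function of age).
#' @param mortalityHazard all-cause mortality per person-year (constant or
#'   function of age).
#' @param recruitAgeMeanlog,recruitAgeSdlog,recruitAgeMin,recruitAgeMax
#'   shifted-lognormal recruitment-age model: age = 45 + lognormal,
#'   truncated to [min, max].
#' @param adminCensorYears administrative censoring (years).
#' @param sexRatio proportion female.
#' @param seed integer seed for all generator randomness.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSamples = 20000L, nVariants = 100L,
                      mafRange = c(0.05, 0.5), weightSd = 0.05,
                      perSdLogHR = log(1.5),
                      baselineHazard = 0.002,
                      mortalityHazard = function(a) exp(-10 + 0.09 * a),
                      recruitAgeMeanlog = log(9),
                      recruitAgeSdlog = 1.03,
                      recruitAgeMin = 45, recruitAgeMax = 74,
                      adminCensorYears = 20, sexRatio = 0.557,
                      seed = 1L) {
  new("SimConfig", nSamples = as.integer(nSamples),
      nVariants = as.integer(nVariants), mafRange = mafRange,
      weightSd = weightSd, perSdLogHR = perSdLogHR,
      baselineHazard = baselineHazard, mortalityHazard = mortalityHazard,
      recruitAgeMeanlog = recruitAgeMeanlog,
      recruitAgeSdlog = recruitAgeSdlog,
      recruitAgeMin = recruitAgeMin, recruitAgeMax = recruitAgeMax,
      adminCensorYears = adminCensorYears, sexRatio = sexRatio,
      seed = as.integer(seed))
}

#' Simulate a genotype panel under Hardy-Weinberg proportions
#'
#' Draws per-variant allele frequencies uniformly from \code{mafRange} and
#' hard genotypes (0/1/2 copies of the counted allele) with probabilities
#' ((1-p)^2, 2p(1-p), p^2); variants are independent (no linkage
#' disequilibrium).  Variant metadata is filled consistently: empirical
#' MAF, imputation INFO 1, Hardy-Weinberg exact-test p from the simulated
#' genotype counts, call rate 1.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param chrom chromosome label for the simulated variants.
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulateGenotypes <- function(cfg, chrom = "1") {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  nV <- cfg@nVariants; nS <- cfg@nSamples
  p <- runif(nV, cfg@mafRange[1], cfg@mafRange[2])
  d <- matrix(rbinom(nV * nS, 2L, rep(p, nS)), nrow = nV, ncol = nS)
  vid <- sprintf("rs%06d", seq_len(nV))
  alleles <- c("A", "C", "G", "T")
  aa <- sample(alleles, nV, replace = TRUE)
  bb <- vapply(aa, function(x) sample(setdiff(alleles, x), 1L),
               character(1), USE.NAMES = FALSE)
  af <- rowMeans(d) / 2
  hwe <- vapply(seq_len(nV), function(i) {
    het <- sum(d[i, ] == 1L)
    nAlt <- sum(d[i, ])
    .hweExactP(het, min(nAlt, 2L * nS - nAlt), max(nAlt, 2L * nS - nAlt))
  }, numeric(1))
  meta <- data.frame(variant_id = vid, chrom = chrom,
                     pos = seq_len(nV) * 1000L,
                     allele_a = aa, allele_b = bb,
                     maf = pmin(af, 1 - af), info = 1, hwe_p = hwe,
                     call_rate = 1, n_alleles = 2L,
                     stringsAsFactors = FALSE)
  GenotypePanel(d, meta,
                sampleIds = sprintf("S%05d", seq_len(nS)))
}

#' Simulate prospective follow-up given a standardized PRS
#'
#' Generates recruitment ages, then event histories on 1-year age steps
#' with piecewise-constant hazards: cancer hazard
#' baselineHazard(age) * exp(perSdLogHR * z) and competing death hazard
#' mortalityHazard(age).  Within a step the two causes compete as
#' exponentials; observed time is the first of cancer, death, or
#' administrative censoring at \code{adminCensorYears}.  Baseline
#' covariates (dialect, education, BMI, smoking, alcohol, physical
#' activity, family history) are drawn independent of outcome so adjusted
#' and unadjusted models agree in expectation.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param z standardized PRS, one value per subject (length
#'   \code{nSamples}).
#' @param seed optional seed override (default derived from
#'   \code{cfg@seed} so genotype and outcome draws are independent).
#' @return a data.frame (cohort table): \code{sample_id}, \code{sex},
#'   \code{age_at_recruitment}, \code{time} (years since recruitment),
#'   \code{event} (\code{"cancer"}, \code{"death"}, \code{"censored"}),
#'   and covariate columns.
#' @export
simulateCohort <- function(cfg, z, seed = .subSeed(cfg@seed, 1L)) {
  stopifnot(is(cfg, "SimConfig"), length(z) == cfg@nSamples)
  set.seed(seed)
  n <- cfg@nSamples
  lam <- .asRateFun(cfg@baselineHazard)
  mor <- .asRateFun(cfg@mortalityHazard)

  raw <- cfg@recruitAgeMin +
    rlnorm(n, cfg@recruitAgeMeanlog, cfg@recruitAgeSdlog)
  age0 <- pmin(pmax(raw, cfg@recruitAgeMin), cfg@recruitAgeMax)

  horizon <- ceiling(cfg@adminCensorYears)
  time <- rep(cfg@adminCensorYears, n)
  event <- rep("censored", n)
  active <- rep(TRUE, n)
  for (u in seq_len(horizon) - 1L) {
    if (!any(active)) break
    stepLen <- min(1, cfg@adminCensorYears - u)
    if (stepLen <= 0) break
    a <- floor(age0[active]) + u
    hC <- lam(a) * exp(cfg@perSdLogHR * z[active])
    hD <- mor(a)
    tot <- hC + hD
    tEv <- ifelse(tot > 0, rexp(sum(active)) / tot, Inf)
    isEv <- tEv < stepLen
    cause <- runif(sum(active)) < ifelse(tot > 0, hC / tot, 0)
    idx <- which(active)
    hit <- idx[isEv]
    time[hit] <- u + tEv[isEv]
    event[hit] <- ifelse(cause[isEv], "cancer", "death")
    active[hit] <- FALSE
  }

  sex <- ifelse(runif(n) < cfg@sexRatio, "female", "male")
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    sex = sex,
    age_at_recruitment = age0,
    time = time,
    event = event,
    dialect = sample(c("hokkien", "cantonese"), n, TRUE, c(0.49, 0.51)),
    education = sample(c("none", "primary", "secondary_plus"), n, TRUE,
                       c(0.21, 0.45, 0.34)),
    bmi = pmax(15, rnorm(n, 23, 3.3)),
    smoking = sample(c("never", "ex", "current"), n, TRUE,
                     c(0.72, 0.11, 0.17)),
    alcohol = sample(c("never", "weekly", "daily"), n, TRUE,
                     c(0.88, 0.09, 0.03)),
    moderate_pa = sample(c("none", "1-3h", "3h+"), n, TRUE,
                         c(0.76, 0.15, 0.09)),
    vigorous_pa = sample(c("no", "yes"), n, TRUE, c(0.85, 0.15)),
    family_history = sample(c("no", "yes"), n, TRUE, c(0.84, 0.16)),
    stringsAsFactors = FALSE
  )
}

#' Analytic population rate table implied by the generator
#'
#' The marginal cancer incidence in each age band is
#' baselineHazard(a) * E[exp(perSdLogHR * Z)] with Z standard normal,
#' i.e. baseline * exp(perSdLogHR^2 / 2) (lognormal mean identity,
#' evaluated per 1-year step and averaged within the band); mortality is
#' the configured all-cause rate.  This plays the role of the population
#' registry consumed by the absolute-risk module.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param bands two-column matrix or data.frame of band bounds
#'   (low, high), contiguous half-open intervals in years.
#' @return a \linkS4class{RateTable}.
#' @export
makeRateTable <- function(cfg, bands) {
  stopifnot(is(cfg, "SimConfig"))
  bands <- as.matrix(bands)
  lo <- as.numeric(bands[, 1]); hi <- as.numeric(bands[, 2])
  if (any(hi <= lo)) stop("invalid band: high bound must exceed low bound")
  if (length(lo) > 1 && any(abs(lo[-1] - hi[-length(hi)]) > 1e-9))
    stop("age bands must be contiguous and non-overlapping")
  lam <- .asRateFun(cfg@baselineHazard)
  mor <- .asRateFun(cfg@mortalityHazard)
  frail <- exp(cfg@perSdLogHR^2 / 2)
  inc <- mapply(function(l, h) mean(lam(seq(l, h - 1))) * frail, lo, hi)
  mrt <- mapply(function(l, h) mean(mor(seq(l, h - 1))), lo, hi)
  new("RateTable", ageLow = lo, ageHigh = hi,
      incidence = inc, mortality = mrt)
}

#' Construct a RateTable from explicit rates
#'
#' @param ageLow,ageHigh contiguous half-open band bounds in years.
#' @param incidence,mortality per person-year rates.
#' @return a \linkS4class{RateTable}.
#' @export
rateTable <- function(ageLow, ageHigh, incidence, mortality) {
  new("RateTable", ageLow = as.numeric(ageLow),
      ageHigh = as.numeric(ageHigh),
      incidence = as.numeric(incidence), mortality = as.numeric(mortality))
}

#' Read / write rate tables as CSV
#'
#' Columns \code{age_low}, \code{age_high}, \code{incidence},
#' \code{mortality}.
#'
#' @param path CSV path.
#' @return \code{readRateTable}: a \linkS4class{RateTable}.
#' @export
readRateTable <- function(path) {
  d <- utils::read.csv(path)
  rateTable(d$age_low, d$age_high, d$incidence, d$mortality)
}

#' @rdname readRateTable
#' @param x a \linkS4class{RateTable}.
#' @return \code{writeRateTable}: \code{path}, invisibly.
#' @export
writeRateTable <- function(x, path) {
  write.csv(rateBands(x), path, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort tables as CSV
#'
#' @param path CSV path.
#' @return \code{readCohortTable}: the cohort data.frame.
#' @export
readCohortTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age_at_recruitment", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$time < 0)) stop("negative follow-up time in cohort table")
  d
}

#' @rdname readCohortTable
#' @param cohort cohort data.frame.
#' @return \code{writeCohortTable}: \code{path}, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
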