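#' Assemble and validate a pipeline configuration
#'
#' @param scorefiles character vector of scoring-file paths.
#' @param genotypes either a \linkS4class{GenotypePanel}, a VCF path, or a
#'   list with \code{dosage} and \code{meta} TSV paths.
#' @param cohort cohort data.frame or CSV path (columns \code{sample_id},
#'   \code{sex}, \code{age_at_recruitment}, \code{time}, \code{event}).
#' @param rateTables named list (by stratum name) of
#'   \linkS4class{RateTable} objects or CSV paths.
#' @param strata named list of stratum definitions, each a list with
#'   \code{sex} (\code{"female"}, \code{"male"}, or \code{"all"}).
#' @param qc list of QC threshold overrides for
#'   \code{\link{qcFilterVariants}}.
#' @param K PRS quantile groups for hazard-ratio tables (default 5).
#' @param bandWidth absolute-risk percentile band width (default 5).
#' @param horizon risk window in years (default 5; must not exceed
#'   \code{capYears}).
#' @param capYears follow-up cap (default 20).
#' @param outDir optional output directory for the written report.
#' @return a validated config (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(scorefiles, genotypes, cohort, rateTables,
                           strata = list(female = list(sex = "female"),
                                         male = list(sex = "male")),
                           qc = list(), K = 5L, bandWidth = 5,
                           horizon = 5, capYears = 20, outDir = NULL) {
  if (horizon > capYears)
    stop("horizon must not exceed the follow-up cap")
  for (p in scorefiles)
    if (!file.exists(p)) stop("scoring file not found: ", p)
  if (is.character(genotypes) && !file.exists(genotypes))
    stop("genotype file not found: ", genotypes)
  if (is.list(genotypes) && !is(genotypes, "GenotypePanel"))
    for (p in unlist(genotypes))
      if (!file.exists(p)) stop("genotype file not found: ", p)
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort table not found: ", cohort)
  if (is.null(names(rateTables)) ||
      !all(names(strata) %in% names(rateTables)))
    stop("rateTables must be named to cover every stratum")
  for (rt in rateTables)
    if (is.character(rt) && !file.exists(rt))
      stop("rate table not found: ", rt)
  structure(list(scorefiles = scorefiles, genotypes = genotypes,
                 cohort = cohort, rateTables = rateTables,
                 strata = strata, qc = qc, K = as.integer(K),
                 bandWidth = bandWidth, horizon = horizon,
                 capYears = capYears, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of \code{\link{pipelineConfig}};
#'   relative paths are resolved against the JSON file's directory.
#' @return a validated config.
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  geno <- if (is.character(j$genotypes)) resolve(j$genotypes) else
    lapply(j$genotypes, resolve)
  strata <- lapply(j$strata, function(s) as.list(s))
  pipelineConfig(
    scorefiles = resolve(unlist(j$scorefiles)),
    genotypes = geno,
    cohort = resolve(j$cohort),
    rateTables = lapply(j$rateTables, resolve),
    strata = strata,
    qc = if (is.null(j$qc)) list() else as.list(j$qc),
    K = if (is.null(j$K)) 5L else j$K,
    bandWidth = if (is.null(j$bandWidth)) 5 else j$bandWidth,
    horizon = if (is.null(j$horizon)) 5 else j$horizon,
    capYears = if (is.null(j$capYears)) 20 else j$capYears,
    outDir = j$outDir)
}

.loadGenotypes <- function(genotypes) {
  if (is(genotypes, "GenotypePanel")) return(genotypes)
  if (is.character(genotypes)) return(readGenotypeVCF(genotypes))
  readGenotypeTSV(genotypes$dosage, genotypes$meta)
}

.loadCohort <- function(cohort) {
  if (is.data.frame(cohort)) cohort else readCohortTable(cohort)
}

.loadRateTable <- function(rt) {
  if (is(rt, "RateTable")) rt else readRateTable(rt)
}

#' Run the full PRS evaluation pipeline
#'
#' For each stratum (typically one sex): parses and QC-filters inputs,
#' harmonizes and scores every scoring file, standardizes within the
#' stratum, then evaluates distribution (case/control t-test),
#' discrimination (Mann-Whitney AUC with DeLong CI, age-adjusted AUC,
#' and the cumulative/dynamic AUC at the horizon), selects the best score
#' by unadjusted AUC, and for that score produces the quantile
#' hazard-ratio table, the per-SD Cox model, the 5-year absolute-risk
#' curves by PRS percentile band under competing mortality, and the
#' decile calibration report.  A stage error marks the stratum failed and
#' the remaining strata continue.  The pipeline itself draws no random
#' numbers, so a rerun on the same inputs is identical.
#'
#' @param config a \code{"PipelineConfig"} from
#'   \code{\link{pipelineConfig}}.
#' @return the evaluation report (nested list); written as JSON to
#'   \code{outDir} when configured.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  panel <- .loadGenotypes(config$genotypes)
  panel <- do.call(qcFilterVariants, c(list(panel), config$qc))
  cohortAll <- .loadCohort(config$cohort)
  scores <- lapply(config$scorefiles, parseScoreFile)

  report <- list(strata = list())
  for (sname in names(config$strata)) {
    res <- tryCatch(
      .runStratum(sname, config$strata[[sname]], panel, cohortAll,
                  scores, .loadRateTable(config$rateTables[[sname]]),
                  config),
      error = function(e)
        list(status = "failed", reason = conditionMessage(e)))
    report$strata[[sname]] <- res
  }
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    tmp <- tempfile(tmpdir = config$outDir)
    jsonlite::write_json(.reportForJSON(report), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    file.rename(tmp, file.path(config$outDir, "evaluation_report.json"))
  }
  report
}

.runStratum <- function(sname, stratum, panel, cohortAll, scores, rates,
                        config) {
  idx <- if (identical(stratum$sex, "all")) seq_len(nrow(cohortAll)) else
    which(cohortAll$sex == stratum$sex)
  if (length(idx) < config$K)
    stop("stratum '", sname, "' has too few subjects")
  cohort <- cohortAll[idx, , drop = FALSE]
  fu <- computeFollowUp(cohort, config$capYears)
  isCase <- fu$event == 1L

  perScore <- list()
  discs <- list()
  for (sc in scores) {
    map <- harmonizeVariants(sc, panel)
    prs <- computePRS(sc, panel, map)
    sampleIdx <- match(cohort$sample_id, names(rawScore(prs)))
    if (anyNA(sampleIdx))
      stop("cohort samples absent from the genotype panel")
    prs <- standardizePRS(prs, stratum = sampleIdx)
    z <- zScore(prs)[sampleIdx]
    dist <- compareDistributions(z[isCase], z[!isCase])
    disc <- aucMW(z, isCase)
    disc$pgsId <- pgsId(sc)
    disc$missingFraction <- missingFraction(map)
    disc$aucAdjusted <- aucAdjusted(z, isCase,
                                    cohort$age_at_recruitment)$auc
    disc$aucCD5y <- aucCD(fu$time, fu$event, z, config$horizon)
    discs[[pgsId(sc)]] <- disc
    rep_ <- harmonizationReport(map)
    perScore[[pgsId(sc)]] <- list(
      harmonization = list(
        nScoreVariants = rep_@nScoreVariants, nDirect = rep_@nDirect,
        nSwapped = rep_@nSwapped, nComplement = rep_@nComplement,
        nPalindromicDropped = rep_@nPalindromicDropped,
        nMissing = rep_@nMissing,
        missingFraction = missingFraction(rep_)),
      distribution = dist, discrimination = disc, z = z)
  }

  bestId <- selectBestPRS(discs)
  zBest <- perScore[[bestId]]$z
  covCols <- intersect(c("dialect", "education", "bmi", "smoking",
                         "alcohol", "moderate_pa", "vigorous_pa",
                         "family_history"), names(cohort))
  hr <- hrTable(zBest, fu$time, fu$event, cohort$age_at_recruitment,
                K = config$K,
                extraCovariates = if (length(covCols))
                  cohort[, covCols, drop = FALSE])

  groups <- riskGroupSpec(log(hr$perSD$hr), width = config$bandWidth)
  bh <- solveBaselineHazard(rates, groups)
  aMin <- max(min(bh@age), floor(min(cohort$age_at_recruitment)))
  aMax <- min(max(bh@age) - config$horizon + 1,
              floor(max(cohort$age_at_recruitment)))
  curve <- fiveYearAbsoluteRisk(bh, rates, groups, ages = aMin:aMax,
                                horizon = config$horizon)
  predicted <- predictFiveYearRisk(zBest, cohort$age_at_recruitment,
                                   curve, groups)
  calib <- calibrationReport(zBest, fu$time, fu$event, predicted,
                             horizon = config$horizon)

  for (id in names(perScore)) perScore[[id]]$z <- NULL
  list(status = "ok", n = nrow(cohort), nCases = sum(isCase),
       scores = perScore, bestPrs = bestId, hr = hr,
       absoluteRisk = list(curve = curve,
                           marginalResidual = marginalCheck(bh, rates,
                                                            groups,
                                                            config$horizon)),
       calibration = calib)
}

# strip model objects so the report serializes cleanly
.reportForJSON <- function(report) {
  for (s in names(report$strata)) {
    hr <- report$strata[[s]]$hr
    if (!is.null(hr)) {
      hr$assignment <- NULL
      report$strata[[s]]$hr <- hr
    }
  }
  report
}

#' Write a complete runnable synthetic input set
#'
#' Generates genotypes, two scoring files (the first causal for the
#' simulated outcome, the second sharing part of its variants), the
#' cohort table, and per-sex rate tables, writing each in the dialect its
#' paired reader consumes, plus a ready \code{config.json}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @param vcf write genotypes as VCF instead of dosage TSV.
#' @return the \code{\link{pipelineConfig}} for the written files,
#'   invisibly.
#' @export
simulateDemo <- function(cfg, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  panel <- simulateGenotypes(cfg)
  nV <- cfg@nVariants
  m <- variantMeta(panel)

  set.seed(.subSeed(cfg@seed, 2L))
  k <- max(2L, floor(0.6 * nV))
  pick1 <- seq_len(k)
  pick2 <- seq(nV - k + 1L, nV)
  mkScore <- function(rows, id) {
    w <- rnorm(length(rows), 0, cfg@weightSd)
    swap <- runif(length(rows)) < 0.5
    ScoreFile(data.frame(
      variant_id = m$variant_id[rows], chrom = m$chrom[rows],
      pos = m$pos[rows],
      effect_allele = ifelse(swap, m$allele_a[rows], m$allele_b[rows]),
      other_allele = ifelse(swap, m$allele_b[rows], m$allele_a[rows]),
      weight = w, stringsAsFactors = FALSE),
      pgsId = id, traitLabel = "simulated trait")
  }
  sc1 <- mkScore(pick1, "PGSSIM001")
  sc2 <- mkScore(pick2, "PGSSIM002")

  map1 <- harmonizeVariants(sc1, panel)
  zTrue <- standardizePRS(rawScore(computePRS(sc1, panel, map1)))
  cohort <- simulateCohort(cfg, zTrue)

  bandLow <- seq(floor(cfg@recruitAgeMin / 5) * 5, 80, by = 5)
  bands <- cbind(bandLow, bandLow + 5)
  rt <- makeRateTable(cfg, bands)

  paths <- list(
    score1 = file.path(dir, "PGSSIM001.txt"),
    score2 = file.path(dir, "PGSSIM002.txt"),
    cohort = file.path(dir, "cohort.csv"),
    rates = file.path(dir, "rates.csv"))
  writeScoreFile(sc1, paths$score1)
  writeScoreFile(sc2, paths$score2)
  writeCohortTable(cohort, paths$cohort)
  writeRateTable(rt, paths$rates)
  if (vcf) {
    geno <- file.path(dir, "genotypes.vcf")
    writeGenotypeVCF(panel, geno)
  } else {
    geno <- list(dosage = file.path(dir, "dosages.tsv"),
                 meta = file.path(dir, "variants.tsv"))
    writeGenotypeTSV(panel, geno$dosage, geno$meta)
  }
  cfgOut <- pipelineConfig(
    scorefiles = c(paths$score1, paths$score2),
    genotypes = geno, cohort = paths$cohort,
    rateTables = list(female = paths$rates, male = paths$rates),
    strata = list(female = list(sex = "female"),
                  male = list(sex = "male")))
  jsonlite::write_json(
    list(scorefiles = c(paths$score1, paths$score2),
         genotypes = geno, cohort = paths$cohort,
         rateTables = list(female = paths$rates, male = paths$rates),
         strata = list(female = list(sex = "female"),
                       male = list(sex = "male"))),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(cfgOut)
}
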