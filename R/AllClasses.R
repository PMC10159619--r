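#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats sd qnorm pnorm dnorm quantile rbinom rexp runif rlnorm
#'   rnorm t.test lm confint pchisq coef vcov glm binomial setNames var
#'   complete.cases
#' @importFrom utils read.delim read.csv write.csv write.table head
NULL

## ---------------------------------------------------------------------------
## Scoring-side containers
## ---------------------------------------------------------------------------

#' ScoreFile: a parsed polygenic score
#'
#' Holds the variants of one published polygenic score: identifier, genomic
#' position, effect and other allele, and the per-allele weight.  Weights are
#' always stored on the natural-log odds scale; scores distributed as odds
#' ratios are log-transformed at parse time (recorded in \code{weightType}).
#'
#' @slot pgsId score accession (e.g. a PGS Catalog id), or \code{""}.
#' @slot traitLabel reported trait, or \code{""}.
#' @slot weightType \code{"log_odds"} or \code{"odds_ratio"} (the scale the
#'   weights were distributed on; stored weights are always log odds).
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele} (may be NA),
#'   \code{weight}.
#' @aliases ScoreFile-class
#' @exportClass ScoreFile
setClass("ScoreFile",
  representation(
    pgsId = "character",
    traitLabel = "character",
    weightType = "character",
    variants = "data.frame"
  )
)

setValidity("ScoreFile", function(object) {
  v <- object@variants
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "weight")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) == 0L)
    return("score contains no variants")
  if (!all(is.finite(v$weight)))
    return("all weights must be finite")
  if (!object@weightType %in% c("log_odds", "odds_ratio"))
    return("weightType must be 'log_odds' or 'odds_ratio'")
  both <- !is.na(v$other_allele)
  if (any(v$effect_allele[both] == v$other_allele[both]))
    return("effect_allele must differ from other_allele")
  key <- paste(v$chrom, v$pos,
               pmin(v$effect_allele, ifelse(is.na(v$other_allele), "",
                                            v$other_allele)),
               pmax(v$effect_allele, ifelse(is.na(v$other_allele), "",
                                            v$other_allele)))
  if (anyDuplicated(key))
    return("duplicate (chrom, pos, allele-pair) entries")
  TRUE
})

#' GenotypePanel: per-sample risk-allele dosages with variant metadata
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"dosage"}
#' (variants x samples, values in [0, 2] or NA for missing; the dosage counts
#' \code{allele_b}) and per-variant metadata in \code{rowData}:
#' \code{variant_id}, \code{chrom}, \code{pos}, \code{allele_a},
#' \code{allele_b}, \code{maf}, \code{info}, \code{hwe_p}, \code{call_rate},
#' \code{n_alleles}.
#'
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  need <- c("variant_id", "chrom", "pos", "allele_a", "allele_b",
            "maf", "info", "hwe_p", "call_rate", "n_alleles")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    return(paste("rowData lacks:", paste(miss, collapse = ", ")))
  d <- SummarizedExperiment::assay(object, "dosage")
  dd <- d[!is.na(d)]
  if (length(dd) && (min(dd) < 0 || max(dd) > 2))
    return("non-missing dosages must lie in [0, 2]")
  TRUE
})

#' HarmonizationReport: accounting of score-to-panel variant matching
#'
#' The five counts partition the score's variant list: matched directly,
#' matched with effect/other swapped (dosage transformed 2 - x), matched on
#' the opposite strand, dropped as strand-ambiguous palindromic (A/T, C/G),
#' or absent from the panel.
#'
#' @slot nScoreVariants total variants in the score.
#' @slot nDirect,nSwapped,nComplement matched counts by orientation
#'   (complement includes complement-swapped).
#' @slot nPalindromicDropped palindromic variants dropped by policy.
#' @slot nMissing unmatched variants.
#' @aliases HarmonizationReport-class
#' @exportClass HarmonizationReport
setClass("HarmonizationReport",
  representation(
    nScoreVariants = "integer",
    nDirect = "integer",
    nSwapped = "integer",
    nComplement = "integer",
    nPalindromicDropped = "integer",
    nMissing = "integer"
  )
)

setValidity("HarmonizationReport", function(object) {
  tot <- object@nDirect + object@nSwapped + object@nComplement +
    object@nPalindromicDropped + object@nMissing
  if (tot != object@nScoreVariants)
    return("matching counts must partition the score's variant list")
  if (any(c(object@nScoreVariants, object@nDirect, object@nSwapped,
            object@nComplement, object@nPalindromicDropped,
            object@nMissing) < 0L))
    return("counts must be non-negative")
  TRUE
})

#' HarmonizationMap: resolved score-variant to panel-column mapping
#'
#' @slot pgsId score accession.
#' @slot map data.frame with one row per matched score variant:
#'   \code{score_row}, \code{panel_row}, \code{orientation} (one of
#'   \code{direct}, \code{swapped}, \code{complement},
#'   \code{complement_swapped}), \code{flip} (logical; TRUE means the stored
#'   dosage x is used as 2 - x).
#' @slot report the \linkS4class{HarmonizationReport}.
#' @aliases HarmonizationMap-class
#' @exportClass HarmonizationMap
setClass("HarmonizationMap",
  representation(
    pgsId = "character",
    map = "data.frame",
    report = "HarmonizationReport"
  )
)

#' PRSVector: raw and standardized per-sample scores
#'
#' @slot pgsId score accession.
#' @slot raw per-sample weighted allele-dosage sum.
#' @slot standardized z-scaled score (length 0 until
#'   \code{\link{standardizePRS}} is applied).
#' @slot nImputed per-sample count of mean-imputed missing dosages.
#' @aliases PRSVector-class
#' @exportClass PRSVector
setClass("PRSVector",
  representation(
    pgsId = "character",
    raw = "numeric",
    standardized = "numeric",
    nImputed = "integer"
  )
)

setValidity("PRSVector", function(object) {
  if (length(object@standardized) &&
      length(object@standardized) != length(object@raw))
    return("standardized must match raw in length (or be empty)")
  if (length(object@nImputed) &&
      length(object@nImputed) != length(object@raw))
    return("nImputed must match raw in length (or be empty)")
  TRUE
})

## ---------------------------------------------------------------------------
## Population rates and simulation configuration
## ---------------------------------------------------------------------------

#' RateTable: age-band population incidence and all-cause mortality
#'
#' Half-open age bands [ageLow, ageHigh) with per person-year rates:
#' marginal cancer incidence and all-cause mortality.  Bands must be
#' contiguous and non-overlapping.
#'
#' @slot ageLow,ageHigh band bounds in years.
#' @slot incidence marginal cancer incidence per person-year.
#' @slot mortality all-cause mortality per person-year.
#' @aliases RateTable-class
#' @exportClass RateTable
setClass("RateTable",
  representation(
    ageLow = "numeric",
    ageHigh = "numeric",
    incidence = "numeric",
    mortality = "numeric"
  )
)

setValidity("RateTable", function(object) {
  n <- length(object@ageLow)
  if (length(object@ageHigh) != n || length(object@incidence) != n ||
      length(object@mortality) != n)
    return("all slots must have equal length")
  if (n == 0L) return("rate table is empty")
  if (any(object@ageHigh <= object@ageLow))
    return("ageHigh must exceed ageLow in every band")
  if (n > 1L && any(abs(object@ageLow[-1] - object@ageHigh[-n]) > 1e-9))
    return("age bands must be contiguous and non-overlapping")
  if (any(object@incidence < 0) || any(object@mortality < 0))
    return("rates must be non-negative")
  TRUE
})

#' SimConfig: parameters of the synthetic prospective cohort
#'
#' Defaults describe the emulated study conditions: a cohort of 20,000
#' middle-aged adults (recruitment ages median 54, IQR roughly 49-63,
#' truncated to 45-74), followed up to 20 years with incident cancer under a
#' proportional-hazards PRS effect (per-SD HR 1.5), competing all-cause
#' mortality rising with age, and administrative censoring.
#'
#' @slot nSamples number of subjects.
#' @slot nVariants number of independent biallelic variants.
#' @slot mafRange minor-allele-frequency range (uniform draw), in (0, 0.5].
#' @slot weightSd SD of simulated per-allele log-odds weights.
#' @slot perSdLogHR true log hazard ratio per SD of standardized PRS.
#' @slot baselineHazard cancer hazard per person-year: a constant or a
#'   function of age.
#' @slot mortalityHazard all-cause mortality per person-year: constant or
#'   function of age.
#' @slot recruitAgeMeanlog,recruitAgeSdlog shifted-lognormal recruitment-age
#'   parameters (age = 45 + lognormal, truncated to [recruitAgeMin,
#'   recruitAgeMax]).
#' @slot recruitAgeMin,recruitAgeMax recruitment age limits in years.
#' @slot adminCensorYears administrative censoring time (years).
#' @slot sexRatio proportion of female subjects.
#' @slot seed integer seed; all generator randomness flows from it.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSamples = "integer",
    nVariants = "integer",
    mafRange = "numeric",
    weightSd = "numeric",
    perSdLogHR = "numeric",
    baselineHazard = "ANY",
    mortalityHazard = "ANY",
    recruitAgeMeanlog = "numeric",
    recruitAgeSdlog = "numeric",
    recruitAgeMin = "numeric",
    recruitAgeMax = "numeric",
    adminCensorYears = "numeric",
    sexRatio = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nSamples < 2L) return("nSamples must be >= 2")
  if (object@nVariants < 1L) return("nVariants must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    return("mafRange must lie within (0, 0.5]")
  if (object@adminCensorYears <= 0) return("adminCensorYears must be > 0")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    return("sexRatio must be in [0, 1]")
  for (h in list(object@baselineHazard, object@mortalityHazard)) {
    if (is.numeric(h)) {
      if (any(h < 0)) return("rates must be non-negative")
    } else if (!is.function(h)) {
      return("hazards must be numeric constants or functions of age")
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Absolute-risk containers
## ---------------------------------------------------------------------------

#' RiskGroupSpec: PRS percentile bands with relative risks
#'
#' Percentile bands of the standardized PRS (default 20 bands of width 5)
#' with per-band relative risk RR_g = exp(beta * E[Z | band]) where beta is
#' the per-SD log hazard ratio and E[Z | band] is the truncated standard
#' normal mean within the band; starting weights are the band widths.
#'
#' @slot bandLow,bandHigh percentile bounds (0-100).
#' @slot rr per-band relative risk (> 0).
#' @slot startWeights population proportions at the starting age (sum 1).
#' @slot perSdLogHR the per-SD log hazard ratio the bands were derived from.
#' @aliases RiskGroupSpec-class
#' @exportClass RiskGroupSpec
setClass("RiskGroupSpec",
  representation(
    bandLow = "numeric",
    bandHigh = "numeric",
    rr = "numeric",
    startWeights = "numeric",
    perSdLogHR = "numeric"
  )
)

setValidity("RiskGroupSpec", function(object) {
  if (any(object@rr <= 0)) return("relative risks must be > 0")
  if (abs(sum(object@startWeights) - 1) > 1e-8)
    return("startWeights must sum to 1")
  if (length(object@rr) != length(object@bandLow) ||
      length(object@rr) != length(object@startWeights))
    return("band slots must have equal length")
  TRUE
})

#' BaselineHazard: solved PRS-group-constrained baseline hazard
#'
#' Per 1-year age step baseline cancer hazard lambda0(a) such that the
#' population marginal incidence is recovered when averaged over the
#' surviving PRS-group mixture.
#'
#' @slot age integer age steps (start of each 1-year interval).
#' @slot hazard baseline hazard per person-year at each step.
#' @aliases BaselineHazard-class
#' @exportClass BaselineHazard
setClass("BaselineHazard",
  representation(age = "numeric", hazard = "numeric")
)

setValidity("BaselineHazard", function(object) {
  if (length(object@age) != length(object@hazard))
    return("age and hazard must have equal length")
  if (any(!is.finite(object@hazard)) || any(object@hazard < 0))
    return("hazard must be finite and non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ScoreFile", function(object) {
  cat("ScoreFile", if (nzchar(object@pgsId)) object@pgsId else "<unnamed>",
      if (nzchar(object@traitLabel)) paste0("(", object@traitLabel, ")"),
      "\n  ", nrow(object@variants), " variants; weights stored as log odds",
      if (object@weightType == "odds_ratio")
        " (converted from odds ratios)", "\n", sep = "")
})

setMethod("show", "HarmonizationReport", function(object) {
  cat("HarmonizationReport: ", object@nScoreVariants, " score variants\n",
      "  direct ", object@nDirect,
      ", swapped ", object@nSwapped,
      ", strand-complement ", object@nComplement,
      ", palindromic dropped ", object@nPalindromicDropped,
      ", missing ", object@nMissing,
      " (", sprintf("%.1f%%", 100 * missingFraction(object)), ")\n",
      sep = "")
})

setMethod("show", "HarmonizationMap", function(object) {
  cat("HarmonizationMap for", object@pgsId, "\n")
  show(object@report)
})

setMethod("show", "PRSVector", function(object) {
  cat("PRSVector", object@pgsId, ":", length(object@raw), "samples;",
      if (length(object@standardized)) "standardized" else "raw only", "\n")
})

setMethod("show", "RateTable", function(object) {
  cat("RateTable:", length(object@ageLow), "age bands, ",
      object@ageLow[1], "-", object@ageHigh[length(object@ageHigh)],
      "years\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "subjects,", object@nVariants,
      "variants, per-SD HR", sprintf("%.3f", exp(object@perSdLogHR)),
      ", seed", object@seed, "\n")
})

setMethod("show", "RiskGroupSpec", function(object) {
  cat("RiskGroupSpec:", length(object@rr), "PRS percentile bands, RR range",
      sprintf("%.3f-%.3f", min(object@rr), max(object@rr)), "\n")
})

setMethod("show", "BaselineHazard", function(object) {
  cat("BaselineHazard over ages", min(object@age), "-", max(object@age) + 1,
      "\n")
})
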