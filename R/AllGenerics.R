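#' Accessors for PRSeval containers
#'
#' Small accessor generics: \code{pgsId} returns the score accession;
#' \code{dosageMatrix} the variants-by-samples dosage assay;
#' \code{variantMeta} the per-variant metadata as a data.frame;
#' \code{missingFraction} the fraction of score variants absent from the
#' panel; \code{rawScore} / \code{zScore} the raw and standardized
#' per-sample scores; \code{rateBands} a rate table as a data.frame.
#'
#' @param x,object a PRSeval container.
#' @return the accessed component.
#' @name accessors
#' @aliases pgsId dosageMatrix variantMeta missingFraction rawScore zScore
#'   rateBands
NULL

#' @rdname accessors
#' @export
setGeneric("pgsId", function(x) standardGeneric("pgsId"))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setGeneric("variantMeta", function(x) standardGeneric("variantMeta"))

#' @rdname accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname accessors
#' @export
setGeneric("rawScore", function(x) standardGeneric("rawScore"))

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname accessors
#' @export
setGeneric("rateBands", function(x) standardGeneric("rateBands"))

#' @rdname accessors
setMethod("pgsId", "ScoreFile", function(x) x@pgsId)

#' @rdname accessors
setMethod("pgsId", "PRSVector", function(x) x@pgsId)

#' @rdname accessors
setMethod("pgsId", "HarmonizationMap", function(x) x@pgsId)

#' @rdname accessors
setMethod("dosageMatrix", "GenotypePanel", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
setMethod("variantMeta", "GenotypePanel", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
setMethod("missingFraction", "HarmonizationReport", function(x)
  (x@nMissing + x@nPalindromicDropped) / x@nScoreVariants)

#' @rdname accessors
setMethod("missingFraction", "HarmonizationMap", function(x)
  missingFraction(x@report))

#' @rdname accessors
setMethod("rawScore", "PRSVector", function(x) x@raw)

#' @rdname accessors
setMethod("zScore", "PRSVector", function(x) {
  if (!length(x@standardized))
    stop("PRS has not been standardized; call standardizePRS() first")
  x@standardized
})

#' @rdname accessors
setMethod("rateBands", "RateTable", function(x)
  data.frame(age_low = x@ageLow, age_high = x@ageHigh,
             incidence = x@incidence, mortality = x@mortality))

#' Harmonization report of a mapping
#'
#' @param x a \linkS4class{HarmonizationMap}.
#' @return the \linkS4class{HarmonizationReport}.
#' @export
setGeneric("harmonizationReport",
           function(x) standardGeneric("harmonizationReport"))

#' @rdname harmonizationReport
setMethod("harmonizationReport", "HarmonizationMap", function(x) x@report)
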