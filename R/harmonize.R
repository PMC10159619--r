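#' Harmonize a score's variants against a genotype panel
#'
#' Resolves each score variant to a panel variant and an allele orientation.
#' Matching is by (chrom, pos) by default (rsIDs are unreliable across
#' builds) or by variant id.  Orientations: \code{direct} (effect allele is
#' the panel's counted allele \code{allele_b}), \code{swapped} (effect
#' allele is \code{allele_a}; dosage used as 2 - x), \code{complement} and
#' \code{complement_swapped} (same after strand complementing the score's
#' alleles).  Palindromic variants (A/T, C/G) are strand-ambiguous and are
#' dropped under the default policy; no frequency-based disambiguation is
#' attempted because silent strand errors corrupt scores.  Unmatched
#' variants are counted as missing.  No liftover is performed: positions
#' must already be on the same genome-build convention.
#'
#' @param score a \linkS4class{ScoreFile}.
#' @param g a \linkS4class{GenotypePanel}.
#' @param matchBy \code{"position"} (default) or \code{"rsid"}.
#' @param palindromicPolicy \code{"drop"} (default) or \code{"keep"} (treat
#'   as if on the reported strand).
#' @return a \linkS4class{HarmonizationMap} (mapping plus
#'   \linkS4class{HarmonizationReport}).
#' @export
harmonizeVariants <- function(score, g,
                              matchBy = c("position", "rsid"),
                              palindromicPolicy = c("drop", "keep")) {
  stopifnot(is(score, "ScoreFile"), is(g, "GenotypePanel"))
  matchBy <- match.arg(matchBy)
  palindromicPolicy <- match.arg(palindromicPolicy)
  sv <- score@variants
  pm <- variantMeta(g)

  scoreKey <- if (matchBy == "position") paste(sv$chrom, sv$pos) else
    sv$variant_id
  panelKey <- if (matchBy == "position") paste(pm$chrom, pm$pos) else
    pm$variant_id
  candIdx <- split(seq_len(nrow(pm)), panelKey)

  n <- nrow(sv)
  pal <- .isPalindromic(sv$effect_allele, sv$other_allele)
  orientation <- rep(NA_character_, n)
  panelRow <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    if (pal[i] && palindromicPolicy == "drop") next
    cands <- candIdx[[scoreKey[i]]]
    if (is.null(cands)) next
    hits <- integer(0); oris <- character(0)
    for (j in cands) {
      ori <- .orientAlleles(sv$effect_allele[i], sv$other_allele[i],
                            pm$allele_a[j], pm$allele_b[j],
                            allowComplement = !pal[i])
      if (!is.na(ori)) { hits <- c(hits, j); oris <- c(oris, ori) }
    }
    if (length(hits) > 1L)
      stop("ambiguous harmonization for score variant ", sv$variant_id[i],
           ": panel candidates ", paste(pm$variant_id[hits], collapse = ", "))
    if (length(hits) == 1L) {
      panelRow[i] <- hits
      orientation[i] <- oris
    }
  }

  matched <- !is.na(panelRow)
  rep_ <- new("HarmonizationReport",
    nScoreVariants = n,
    nDirect = sum(orientation == "direct", na.rm = TRUE),
    nSwapped = sum(orientation == "swapped", na.rm = TRUE),
    nComplement = sum(orientation %in% c("complement",
                                         "complement_swapped")),
    nPalindromicDropped = as.integer(sum(pal &
                                           palindromicPolicy == "drop")),
    nMissing = as.integer(sum(!matched & !(pal &
                                             palindromicPolicy == "drop"))))

  new("HarmonizationMap", pgsId = score@pgsId,
      map = data.frame(score_row = which(matched),
                       panel_row = panelRow[matched],
                       orientation = orientation[matched],
                       flip = orientation[matched] %in%
                         c("swapped", "complement_swapped"),
                       stringsAsFactors = FALSE),
      report = rep_)
}

# classify effect/other alleles against panel (allele_a, allele_b) where
# allele_b is the counted allele; returns orientation or NA
.orientAlleles <- function(eff, oth, a, b, allowComplement = TRUE) {
  if (!is.na(oth)) {
    if (eff == b && oth == a) return("direct")
    if (eff == a && oth == b) return("swapped")
    if (allowComplement) {
      ce <- .revcomp(eff); co <- .revcomp(oth)
      if (ce == b && co == a) return("complement")
      if (ce == a && co == b) return("complement_swapped")
    }
  } else {
    if (eff == b) return("direct")
    if (eff == a) return("swapped")
    if (allowComplement) {
      ce <- .revcomp(eff)
      if (ce == b) return("complement")
      if (ce == a) return("complement_swapped")
    }
  }
  NA_character_
}

#' Compute raw polygenic risk scores
#'
#' Allelic score sum: for each sample, raw PRS = sum over matched variants
#' of weight times effect-allele dosage, with swapped orientations using
#' 2 - x.  Missing dosages follow \code{missingPolicy}:
#' \code{"impute_mean"} (default) substitutes twice the sample effect-allele
#' frequency at that variant, the default behaviour of standard allelic
#' scoring tools; \code{"zero"} contributes nothing (audit mode).
#'
#' @param score a \linkS4class{ScoreFile}.
#' @param g a \linkS4class{GenotypePanel}.
#' @param map a \linkS4class{HarmonizationMap} from
#'   \code{\link{harmonizeVariants}}.
#' @param missingPolicy \code{"impute_mean"} or \code{"zero"}.
#' @return a \linkS4class{PRSVector} with \code{raw} filled,
#'   \code{standardized} empty, and per-sample imputation counts.
#' @examples
#' # three variants with weights .1 .2 .3 and dosage 1 each: raw PRS = 0.6
#' @export
computePRS <- function(score, g, map,
                       missingPolicy = c("impute_mean", "zero")) {
  stopifnot(is(score, "ScoreFile"), is(g, "GenotypePanel"),
            is(map, "HarmonizationMap"))
  missingPolicy <- match.arg(missingPolicy)
  mp <- map@map
  if (nrow(mp) == 0L)
    stop("no score variants matched the genotype panel")
  d <- dosageMatrix(g)
  w <- score@variants$weight[mp$score_row]
  X <- d[mp$panel_row, , drop = FALSE]
  X[mp$flip, ] <- 2 - X[mp$flip, , drop = FALSE]
  miss <- is.na(X)
  nImp <- integer(ncol(X))
  if (any(miss)) {
    if (missingPolicy == "impute_mean") {
      ef <- rowMeans(X, na.rm = TRUE) / 2   # effect-allele frequency
      fill <- (2 * ef)[row(X)[miss]]
      X[miss] <- fill
      nImp <- as.integer(colSums(miss))
    } else {
      X[miss] <- 0
      nImp <- as.integer(colSums(miss))
    }
  }
  raw <- colSums(X * w)
  names(raw) <- colnames(d)
  new("PRSVector", pgsId = score@pgsId, raw = raw,
      standardized = numeric(0), nImputed = nImp)
}

#' Standardize a PRS to z-scale
#'
#' Subtracts the mean and divides by the sample SD computed over a
#' standardization stratum (default: all samples), then applies the
#' transform to every sample.  In sex-stratified analyses the stratum is
#' the sex-specific analysis set.
#'
#' @param prs a \linkS4class{PRSVector} or a numeric vector of raw scores.
#' @param stratum optional logical or integer index of the samples defining
#'   the mean/SD.
#' @return the same type as \code{prs} with standardized values filled.
#' @export
standardizePRS <- function(prs, stratum = NULL) {
  raw <- if (is(prs, "PRSVector")) prs@raw else as.numeric(prs)
  idx <- if (is.null(stratum)) seq_along(raw) else seq_along(raw)[stratum]
  if (length(idx) < 2L)
    stop("standardization stratum must contain at least 2 samples")
  mu <- mean(raw[idx])
  s <- sd(raw[idx])
  if (!is.finite(s) || s == 0)
    stop("degenerate score: zero standard deviation in stratum")
  z <- (raw - mu) / s
  if (is(prs, "PRSVector")) {
    prs@standardized <- z
    prs
  } else z
}
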