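#' Construct a ScoreFile from a variant table
#'
#' @param variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele} (NA allowed) and
#'   \code{weight} (log odds ratios).
#' @param pgsId,traitLabel optional metadata strings.
#' @param weightType scale the weights were supplied on; \code{"odds_ratio"}
#'   records that the stored log-odds weights were converted at parse time.
#' @return a \linkS4class{ScoreFile}.
#' @export
ScoreFile <- function(variants, pgsId = "", traitLabel = "",
                      weightType = "log_odds") {
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  variants$weight <- as.numeric(variants$weight)
  rownames(variants) <- NULL
  new("ScoreFile", pgsId = pgsId, traitLabel = traitLabel,
      weightType = weightType,
      variants = variants[, c("variant_id", "chrom", "pos", "effect_allele",
                              "other_allele", "weight")])
}

# weight-type metadata values that disqualify a score
.excludedWeightTypes <- c("odds ratio over expected risk",
                          "inverse-variance", "inverse variance",
                          "unweighted")

.normalizeWeightType <- function(wt) {
  w <- tolower(trimws(wt))
  if (any(vapply(.excludedWeightTypes, function(x) grepl(x, w, fixed = TRUE),
                 logical(1))))
    return("excluded")
  if (grepl("log", w) || grepl("beta", w)) return("log_odds")
  if (grepl("^or$", w) || grepl("odds ratio", w)) return("odds_ratio")
  "other"
}

#' Parse a PGS-Catalog-style scoring file
#'
#' Reads a tab-separated scoring file with \code{#}-prefixed metadata header
#' lines (\code{pgs_id}, \code{trait_reported}, \code{weight_type}, ...).
#' One variant per body row.  Column names follow the PGS Catalog dialect:
#' \code{effect_allele} (required), \code{effect_weight} or \code{OR}
#' (required), \code{other_allele}/\code{reference_allele},
#' \code{rsID}/\code{rsid}, \code{chr_name}/\code{chr},
#' \code{chr_position}/\code{pos}.  Odds-ratio weights (column named
#' \code{OR}/\code{odds_ratio} or metadata \code{weight_type} declaring odds
#' ratios) are converted to natural-log odds so downstream arithmetic is
#' uniform.  Scores whose declared weight type is among the excluded kinds
#' (odds ratio over expected risk, inverse-variance, unweighted) are
#' rejected.  Duplicate (chrom, pos, allele-pair) rows are dropped with a
#' warning.
#'
#' @param path path to the scoring file.
#' @return a \linkS4class{ScoreFile}; weights stored as log odds ratios.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("#pgs_id=PGS000001", "#weight_type=log(OR)",
#'   "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
#'   "rs1\t1\t100\tA\tG\t0.1", "rs2\t2\t200\tC\tT\t-0.2"), f)
#' sf <- parseScoreFile(f)
#' sf@variants$weight  # 0.1 -0.2
#' @export
parseScoreFile <- function(path) {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metaLines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 2L) stop("scoring file has no variant rows: ", path)

  meta <- list()
  for (ml in metaLines) {
    kv <- sub("^#+\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- trimws(sub("=.*$", "", kv))
      v <- trimws(sub("^[^=]*=", "", kv))
      meta[[tolower(k)]] <- v
    }
  }

  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(tab)
  pick <- function(cands) {
    hit <- nm[tolower(nm) %in% tolower(cands)]
    if (length(hit)) hit[1] else NA_character_
  }

  effCol <- pick(c("effect_allele", "A1", "allele1"))
  if (is.na(effCol))
    stop("scoring file lacks an effect-allele column ('effect_allele')")
  wColLog <- pick(c("effect_weight", "weight", "beta", "hm_beta"))
  wColOR <- pick(c("OR", "odds_ratio", "hazard_ratio"))
  if (is.na(wColLog) && is.na(wColOR))
    stop("scoring file lacks a weight column ('effect_weight' or 'OR')")

  wtDeclared <- if (!is.null(meta$weight_type))
    .normalizeWeightType(meta$weight_type) else NA_character_
  if (identical(wtDeclared, "excluded"))
    stop("weight type '", meta$weight_type,
         "' is excluded (only odds ratios or log odds ratios are supported)")
  if (identical(wtDeclared, "other"))
    stop("unrecognized weight type '", meta$weight_type,
         "' (only odds ratios or log odds ratios are supported)")

  orScale <- identical(wtDeclared, "odds_ratio") ||
    (is.na(wColLog) && !is.na(wColOR))
  wCol <- if (!is.na(wColLog) && !orScale) wColLog else
    if (!is.na(wColOR)) wColOR else wColLog
  w <- as.numeric(tab[[wCol]])
  if (orScale) {
    if (any(w <= 0, na.rm = TRUE))
      stop("odds-ratio weights must be positive")
    w <- log(w)
  }
  if (any(!is.finite(w)))
    stop("non-finite weights in column '", wCol, "'")

  othCol <- pick(c("other_allele", "reference_allele", "A2", "allele2",
                   "hm_inferOtherAllele"))
  idCol <- pick(c("rsID", "rsid", "variant_id", "ID", "SNP"))
  chrCol <- pick(c("chr_name", "chr", "chrom", "chromosome"))
  posCol <- pick(c("chr_position", "pos", "position", "bp"))

  chrom <- if (!is.na(chrCol)) as.character(tab[[chrCol]]) else
    rep(NA_character_, nrow(tab))
  pos <- if (!is.na(posCol)) as.integer(tab[[posCol]]) else
    rep(NA_integer_, nrow(tab))
  vid <- if (!is.na(idCol)) as.character(tab[[idCol]]) else
    paste0(chrom, ":", pos)

  v <- data.frame(
    variant_id = vid, chrom = chrom, pos = pos,
    effect_allele = toupper(as.character(tab[[effCol]])),
    other_allele = if (!is.na(othCol))
      toupper(as.character(tab[[othCol]])) else NA_character_,
    weight = w, stringsAsFactors = FALSE
  )

  key <- paste(v$chrom, v$pos,
               pmin(v$effect_allele, ifelse(is.na(v$other_allele), "",
                                            v$other_allele)),
               pmax(v$effect_allele, ifelse(is.na(v$other_allele), "",
                                            v$other_allele)))
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)),
            " duplicate variant entries in ", basename(path))
    v <- v[!duplicated(key), , drop = FALSE]
  }

  ScoreFile(v,
            pgsId = if (!is.null(meta$pgs_id)) meta$pgs_id else "",
            traitLabel = if (!is.null(meta$trait_reported))
              meta$trait_reported else "",
            weightType = if (orScale) "odds_ratio" else "log_odds")
}

#' Write a ScoreFile in the PGS-Catalog dialect
#'
#' @param score a \linkS4class{ScoreFile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreFile <- function(score, path) {
  stopifnot(is(score, "ScoreFile"))
  hdr <- c(
    paste0("#pgs_id=", score@pgsId),
    paste0("#trait_reported=", score@traitLabel),
    "#weight_type=log(OR)"
  )
  v <- score@variants
  out <- data.frame(rsID = v$variant_id, chr_name = v$chrom,
                    chr_position = v$pos, effect_allele = v$effect_allele,
                    other_allele = v$other_allele, effect_weight = v$weight)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  invisible(path)
}
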