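#' Construct a GenotypePanel
#'
#' @param dosage variants x samples numeric matrix of counted-allele
#'   (\code{allele_b}) dosages in [0, 2]; NA marks missing.
#' @param variants data.frame with per-variant columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{allele_a}, \code{allele_b} and
#'   optionally \code{maf}, \code{info}, \code{hwe_p}, \code{call_rate},
#'   \code{n_alleles} (missing metadata filled with permissive defaults,
#'   MAF recomputed from dosages).
#' @param sampleIds sample identifiers (defaults to dosage colnames).
#' @return a \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(dosage, variants, sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(ncol(dosage)))
  stopifnot(nrow(dosage) == nrow(variants))
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  defaults <- list(
    maf = pmin(af, 1 - af),
    info = rep(1, nrow(variants)),
    hwe_p = rep(1, nrow(variants)),
    call_rate = rowMeans(!is.na(dosage)),
    n_alleles = rep(2L, nrow(variants))
  )
  for (col in names(defaults))
    if (is.null(variants[[col]])) variants[[col]] <- defaults[[col]]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  rd <- S4Vectors::DataFrame(variants)
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd)
  new("GenotypePanel", se)
}

#' Variant-level quality-control filter
#'
#' Retains variants passing the standard post-imputation filters:
#' imputation INFO >= 0.8, MAF >= 0.01, Hardy-Weinberg exact p >= 1e-6,
#' call rate >= 0.95, and biallelic only.  Thresholds are configurable;
#' the defaults are the conventional values for imputed array data.
#' Exclusions are recorded per variant (first failing criterion) in
#' \code{metadata(result)$qcLog}.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param infoMin,mafMin,hwePMin,callRateMin,biallelicOnly thresholds.
#' @return the filtered \linkS4class{GenotypePanel} (possibly with zero
#'   variants, with a warning).
#' @export
qcFilterVariants <- function(g, infoMin = 0.8, mafMin = 0.01,
                             hwePMin = 1e-6, callRateMin = 0.95,
                             biallelicOnly = TRUE) {
  stopifnot(is(g, "GenotypePanel"))
  m <- variantMeta(g)
  reason <- rep(NA_character_, nrow(m))
  reason[is.na(reason) & m$info < infoMin] <- "low_info"
  reason[is.na(reason) & m$maf < mafMin] <- "low_maf"
  reason[is.na(reason) & m$hwe_p < hwePMin] <- "hwe_outlier"
  reason[is.na(reason) & m$call_rate < callRateMin] <- "low_call_rate"
  if (biallelicOnly)
    reason[is.na(reason) & m$n_alleles != 2L] <- "not_biallelic"
  keep <- is.na(reason)
  out <- g[keep, ]
  S4Vectors::metadata(out)$qcLog <- data.frame(
    variant_id = m$variant_id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  if (!any(keep)) warning("no variants pass QC")
  out
}

#' Read a dosage matrix with its variant-metadata sidecar
#'
#' The dosage file is tab-separated, variants in rows (first column
#' \code{variant_id}, remaining columns one per sample).  The sidecar is
#' tab-separated with columns \code{variant_id}, \code{chrom}, \code{pos},
#' \code{allele_a}, \code{allele_b}, \code{maf}, \code{info}, \code{hwe_p},
#' \code{call_rate}, \code{n_alleles}.
#'
#' @param dosagePath,metaPath file paths.
#' @return a \linkS4class{GenotypePanel}.
#' @export
readGenotypeTSV <- function(dosagePath, metaPath) {
  d <- as.data.frame(data.table::fread(dosagePath, sep = "\t"))
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  dm <- as.matrix(d[, -1, drop = FALSE])
  rownames(dm) <- d[[1]]
  meta <- meta[match(d[[1]], meta$variant_id), , drop = FALSE]
  if (anyNA(meta$variant_id))
    stop("variant metadata sidecar does not cover all dosage rows")
  GenotypePanel(dm, meta, sampleIds = colnames(dm))
}

#' Write a GenotypePanel as dosage TSV plus metadata sidecar
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param dosagePath,metaPath output paths.
#' @return \code{dosagePath}, invisibly.
#' @export
writeGenotypeTSV <- function(g, dosagePath, metaPath) {
  d <- dosageMatrix(g)
  dt <- data.table::data.table(variant_id = rownames(d))
  dt <- cbind(dt, data.table::as.data.table(d))
  data.table::fwrite(dt, dosagePath, sep = "\t", quote = FALSE)
  write.table(variantMeta(g), metaPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dosagePath)
}

#' Read genotype dosages from a VCF
#'
#' Uses the \code{DS} FORMAT field when present (imputed dosage of the ALT
#' allele) and falls back to counting ALT alleles in \code{GT}.  Per-variant
#' metadata is taken from the INFO field when present (keys \code{MAF},
#' \code{R2} for imputation quality, \code{HWE}, \code{CR}) and otherwise
#' recomputed from the dosages.  \code{allele_b} (the counted allele) is
#' ALT; \code{allele_a} is REF.  Multiallelic records are kept with
#' \code{n_alleles} set accordingly so QC can drop them.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a \linkS4class{GenotypePanel}.
#' @export
readGenotypeVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(x) {
      ifelse(is.na(x) | grepl("\\.", x), NA_real_,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a != "0"), numeric(1)))
    }
    ds <- apply(gt, 2, cnt)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  }
  infoGet <- function(key) {
    val <- suppressWarnings(as.numeric(sub(
      paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", fix$INFO,
      perl = TRUE)))
    val[!grepl(paste0("(^|;)", key, "="), fix$INFO)] <- NA
    val
  }
  nAlt <- vapply(strsplit(fix$ALT, ","), length, integer(1))
  meta <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = sub(",.*$", "", fix$ALT),
    maf = infoGet("MAF"), info = infoGet("R2"), hwe_p = infoGet("HWE"),
    call_rate = infoGet("CR"), n_alleles = nAlt + 1L,
    stringsAsFactors = FALSE)
  af <- rowMeans(ds, na.rm = TRUE) / 2
  meta$maf[is.na(meta$maf)] <- pmin(af, 1 - af)[is.na(meta$maf)]
  meta$info[is.na(meta$info)] <- 1
  meta$hwe_p[is.na(meta$hwe_p)] <- 1
  meta$call_rate[is.na(meta$call_rate)] <-
    rowMeans(!is.na(ds))[is.na(meta$call_rate)]
  GenotypePanel(ds, meta, sampleIds = colnames(ds))
}

#' Write a GenotypePanel as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT (rounded hard genotype) and DS FORMAT
#' fields and INFO keys \code{MAF}, \code{R2}, \code{HWE}, \code{CR}
#' carrying the variant metadata, readable by \code{\link{readGenotypeVCF}}.
#'
#' @param g a \linkS4class{GenotypePanel}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVCF <- function(g, path) {
  d <- dosageMatrix(g)
  m <- variantMeta(g)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##INFO=<ID=HWE,Number=1,Type=Float,Description=\"HWE exact p\">",
    "##INFO=<ID=CR,Number=1,Type=Float,Description=\"Call rate\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t")
  )
  gtOf <- function(x) {
    ifelse(is.na(x), "./.",
           c("0/0", "0/1", "1/1")[pmin(pmax(round(x), 0), 2) + 1])
  }
  rows <- vapply(seq_len(nrow(d)), function(i) {
    info <- sprintf("MAF=%.6g;R2=%.6g;HWE=%.6g;CR=%.6g",
                    m$maf[i], m$info[i], m$hwe_p[i], m$call_rate[i])
    geno <- paste0(gtOf(d[i, ]), ":",
                   ifelse(is.na(d[i, ]), ".", sprintf("%.4g", d[i, ])))
    paste(c(m$chrom[i], m$pos[i], m$variant_id[i], m$allele_a[i],
            m$allele_b[i], ".", "PASS", info, "GT:DS", geno),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
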