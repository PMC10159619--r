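test_that("parseScoreFile reads weights, metadata, and log-transforms odds ratios", {
  p <- writeTestScoreFile(c(
    "#pgs_id=PGS000123", "#trait_reported=test trait",
    "#weight_type=log(OR)",
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "rs1\t1\t100\tA\tG\t0.1",
    "rs2\t2\t200\tC\tT\t-0.2"))
  sf <- parseScoreFile(p)
  expect_s4_class(sf, "ScoreFile")
  expect_identical(pgsId(sf), "PGS000123")
  expect_equal(sf@variants$weight, c(0.1, -0.2))
  expect_identical(sf@weightType, "log_odds")

  pOR <- writeTestScoreFile(c(
    "#pgs_id=PGSOR",
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\tOR",
    "rs1\t1\t100\tA\tG\t1.0",
    "rs2\t1\t200\tC\tG\t2.0"))
  sfOR <- parseScoreFile(pOR)
  expect_equal(sfOR@variants$weight, c(0, log(2)))
  expect_identical(sfOR@weightType, "odds_ratio")
})

test_that("parseScoreFile rejects excluded weight types and missing columns", {
  pBad <- writeTestScoreFile(c(
    "#weight_type=odds ratio over expected risk",
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "rs1\t1\t100\tA\tG\t0.1"))
  expect_error(parseScoreFile(pBad), "excluded")

  pNoEff <- writeTestScoreFile(c(
    "rsID\tchr_name\tchr_position\tother_allele\teffect_weight",
    "rs1\t1\t100\tG\t0.1"))
  expect_error(parseScoreFile(pNoEff), "effect_allele")

  pNoW <- writeTestScoreFile(c(
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele",
    "rs1\t1\t100\tA\tG"))
  expect_error(parseScoreFile(pNoW), "weight")
})

test_that("parseScoreFile drops duplicate variant entries with a warning", {
  p <- writeTestScoreFile(c(
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "rs1\t1\t100\tA\tG\t0.1",
    "rs1b\t1\t100\tG\tA\t0.2",
    "rs2\t1\t200\tC\tG\t0.3"))
  expect_warning(sf <- parseScoreFile(p), "duplicate")
  expect_equal(nrow(sf@variants), 2L)
})

test_that("scorefile writer round-trips through the parser", {
  sc <- makeScore(c("G", "T"), c("A", "C"), c(0.25, -0.5), id = "PGSRT")
  path <- tempfile(fileext = ".txt")
  writeScoreFile(sc, path)
  back <- parseScoreFile(path)
  expect_identical(pgsId(back), "PGSRT")
  expect_equal(back@variants$weight, sc@variants$weight)
  expect_identical(back@variants$effect_allele, sc@variants$effect_allele)
})

test_that("variant QC applies the standard post-imputation filters", {
  d <- matrix(1, 6, 4)
  meta <- data.frame(
    variant_id = paste0("v", 1:6), chrom = "1", pos = 1:6 * 100L,
    allele_a = "A", allele_b = "G",
    maf = c(0.3, 0.3, 0.009, 0.3, 0.3, 0.3),
    info = c(1, 0.79, 0.99, 1, 1, 1),
    hwe_p = c(1, 1, 1, 1e-7, 1, 1),
    call_rate = c(1, 1, 1, 1, 0.94, 1),
    n_alleles = c(2L, 2L, 2L, 2L, 2L, 3L))
  g <- GenotypePanel(d, meta)
  out <- qcFilterVariants(g)
  expect_identical(variantMeta(out)$variant_id, "v1")
  log <- S4Vectors::metadata(out)$qcLog
  expect_setequal(log$reason, c("low_info", "low_maf", "hwe_outlier",
                                "low_call_rate", "not_biallelic"))
  # boundary values are kept
  meta2 <- meta[1, ]
  meta2$info <- 0.8; meta2$maf <- 0.01; meta2$hwe_p <- 1e-6
  meta2$call_rate <- 0.95
  g2 <- GenotypePanel(matrix(1, 1, 4), meta2)
  expect_equal(nrow(variantMeta(qcFilterVariants(g2))), 1L)
  expect_warning(qcFilterVariants(GenotypePanel(matrix(1, 1, 4),
                                                transform(meta2,
                                                          info = 0.5))),
                 "no variants")
})

test_that("harmonization resolves all four orientations and drops palindromic variants", {
  # panel counts G at v1 (A,G); counts C at v2 (T,C); v3 palindromic A/T
  g <- makePanel(matrix(c(1, 2, 0), 3, 1),
                 alleleA = c("A", "T", "A"), alleleB = c("G", "C", "T"))
  direct <- makeScore("G", "A", 0.1, pos = 100L)
  swapped <- makeScore("A", "G", 0.1, pos = 100L)
  compl <- makeScore("C", "T", 0.1, pos = 100L)   # revcomp -> (G, A)
  complSw <- makeScore("T", "C", 0.1, pos = 100L)
  pal <- makeScore("A", "T", 0.1, pos = 300L)
  absent <- makeScore("G", "A", 0.1, pos = 999L)

  o <- function(sc) harmonizeVariants(sc, g)@map$orientation
  expect_identical(o(direct), "direct")
  expect_identical(o(swapped), "swapped")
  expect_identical(o(compl), "complement")
  expect_identical(o(complSw), "complement_swapped")
  expect_false(harmonizeVariants(swapped, g)@map$flip == FALSE)

  repPal <- harmonizationReport(harmonizeVariants(pal, g))
  expect_identical(repPal@nPalindromicDropped, 1L)
  repMiss <- harmonizationReport(harmonizeVariants(absent, g))
  expect_identical(repMiss@nMissing, 1L)
})

test_that("harmonization reports partition the score's variant list", {
  set.seed(11)
  for (rep_ in 1:20) {
    nV <- sample(3:12, 1)
    pairs <- replicate(nV, randAllelePair())
    g <- makePanel(matrix(sample(0:2, nV * 3, TRUE), nV, 3),
                   alleleA = pairs[1, ], alleleB = pairs[2, ])
    # score mixes: matched direct/swapped, palindromic, missing
    eff <- ifelse(runif(nV) < 0.5, pairs[2, ], pairs[1, ])
    oth <- ifelse(eff == pairs[2, ], pairs[1, ], pairs[2, ])
    pal <- sample(nV, 1)
    eff[pal] <- "A"; oth[pal] <- "T"
    pos <- seq_len(nV) * 100L
    pos[sample(nV, 1)] <- 99999L  # unmatched
    sc <- makeScore(eff, oth, rnorm(nV), pos = pos)
    r <- harmonizationReport(harmonizeVariants(sc, g))
    expect_identical(r@nDirect + r@nSwapped + r@nComplement +
                       r@nPalindromicDropped + r@nMissing,
                     r@nScoreVariants)
  }
})

test_that("ambiguous multi-candidate matches raise an error naming candidates", {
  d <- matrix(c(1, 2), 2, 1)
  meta <- data.frame(variant_id = c("va", "vb"), chrom = "1",
                     pos = c(100L, 100L), allele_a = c("A", "A"),
                     allele_b = c("G", "G"))
  g <- GenotypePanel(d, meta)
  sc <- makeScore("G", "A", 0.1, pos = 100L)
  expect_error(harmonizeVariants(sc, g), "ambiguous")
})

test_that("computePRS matches hand-computed sums and handles orientation", {
  g <- makePanel(matrix(1, 3, 2))
  sc <- makeScore(rep("G", 3), rep("A", 3), c(0.1, 0.2, 0.3))
  prs <- computePRS(sc, g, harmonizeVariants(sc, g))
  expect_equal(unname(rawScore(prs)), c(0.6, 0.6))

  gz <- makePanel(matrix(0, 3, 2))
  expect_equal(unname(rawScore(computePRS(sc, gz,
                                          harmonizeVariants(sc, gz)))),
               c(0, 0))

  # swapped orientation: stored dosage 2 contributes beta * (2 - 2) = 0
  g2 <- makePanel(matrix(2, 1, 1))
  scSw <- makeScore("A", "G", 0.3)
  expect_equal(unname(rawScore(computePRS(scSw, g2,
                                          harmonizeVariants(scSw, g2)))),
               0)

  scMiss <- makeScore("G", "A", 0.1, pos = 5000L)
  expect_error(computePRS(scMiss, g, harmonizeVariants(scMiss, g)),
               "no score variants matched")
})

test_that("missing dosages follow the chosen policy and are counted", {
  d <- matrix(c(2, 0, NA, 2), 2, 2)  # variant 1 missing for sample 2
  g <- makePanel(d)
  sc <- makeScore(rep("G", 2), rep("A", 2), c(1, 1))
  map <- harmonizeVariants(sc, g)
  pm <- computePRS(sc, g, map, missingPolicy = "impute_mean")
  # effect-allele freq at v1 = 2/2/2 = 1 -> imputed dosage 2
  expect_equal(unname(rawScore(pm)), c(2, 4))
  expect_equal(pm@nImputed, c(0L, 1L))
  pz <- computePRS(sc, g, map, missingPolicy = "zero")
  expect_equal(unname(rawScore(pz)), c(2, 2))
})

test_that("scoring equals the double-loop oracle on random instances", {
  set.seed(21)
  for (rep_ in 1:25) {
    nV <- sample(2:20, 1); nS <- sample(2:10, 1)
    pairs <- replicate(nV, randAllelePair())
    d <- matrix(sample(0:2, nV * nS, TRUE), nV, nS)
    g <- makePanel(d, alleleA = pairs[1, ], alleleB = pairs[2, ])
    ori <- sample(c("direct", "swapped", "complement",
                    "complement_swapped"), nV, TRUE)
    eff <- ifelse(ori %in% c("direct", "complement"),
                  pairs[2, ], pairs[1, ])
    oth <- ifelse(ori %in% c("direct", "complement"),
                  pairs[1, ], pairs[2, ])
    comp <- ori %in% c("complement", "complement_swapped")
    eff[comp] <- revcompBase(eff[comp]); oth[comp] <- revcompBase(oth[comp])
    w <- round(rnorm(nV), 3)
    sc <- makeScore(eff, oth, w)
    map <- harmonizeVariants(sc, g)
    expect_identical(map@map$orientation, ori)
    got <- unname(rawScore(computePRS(sc, g, map)))
    want <- brutePRS(w[map@map$score_row], d[map@map$panel_row, ,
                                             drop = FALSE], map@map$flip)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("relabeling a panel variant's counted allele leaves the PRS unchanged", {
  set.seed(22)
  nV <- 8; nS <- 6
  pairs <- replicate(nV, randAllelePair())
  d <- matrix(sample(0:2, nV * nS, TRUE), nV, nS)
  g <- makePanel(d, alleleA = pairs[1, ], alleleB = pairs[2, ])
  sc <- makeScore(pairs[2, ], pairs[1, ], rnorm(nV))
  base <- rawScore(computePRS(sc, g, harmonizeVariants(sc, g)))
  for (k in seq_len(nV)) {
    d2 <- d; d2[k, ] <- 2 - d2[k, ]
    a2 <- pairs[1, ]; b2 <- pairs[2, ]
    tmp <- a2[k]; a2[k] <- b2[k]; b2[k] <- tmp
    g2 <- makePanel(d2, alleleA = a2, alleleB = b2)
    flipped <- rawScore(computePRS(sc, g2, harmonizeVariants(sc, g2)))
    expect_equal(unname(flipped), unname(base), tolerance = 1e-12)
  }
})

test_that("standardization centers, scales, and is idempotent and affine-invariant", {
  expect_equal(standardizePRS(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardizePRS(rep(2, 5)), "degenerate")
  expect_error(standardizePRS(c(1)), "at least 2")
  x <- rnorm(50)
  z <- standardizePRS(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(standardizePRS(z), z, tolerance = 1e-12)
  expect_equal(standardizePRS(3 * x - 7), z, tolerance = 1e-12)

  # stratum mean/SD applied to all samples
  z2 <- standardizePRS(c(1, 2, 3, 100), stratum = 1:3)
  expect_equal(z2[1:3], c(-1, 0, 1))
  expect_equal(z2[4], 98)

  prs <- new("PRSVector", pgsId = "p", raw = x,
             standardized = numeric(0), nImputed = integer(0))
  expect_equal(zScore(standardizePRS(prs)), z)
  expect_error(zScore(prs), "standardized")
})
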