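# Independent oracles and small fixture builders used across the suite.

# double-loop allelic score sum: the scoring oracle, independent of the
# vectorized implementation
brutePRS <- function(weights, dosage, flip) {
  nS <- ncol(dosage)
  out <- numeric(nS)
  for (s in seq_len(nS)) {
    acc <- 0
    for (k in seq_along(weights)) {
      x <- dosage[k, s]
      if (flip[k]) x <- 2 - x
      acc <- acc + weights[k] * x
    }
    out[s] <- acc
  }
  out
}

# brute-force pairwise AUC with ties counted one half
bruteAUC <- function(scores, labels) {
  cases <- scores[as.logical(labels)]
  ctrls <- scores[!as.logical(labels)]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Efron-tie log partial likelihood for a single covariate
logPLEfron <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(w[D]); sumR <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sumR - l / d * sumD)
  }
  ll
}

# grid-search maximizer of the Efron partial likelihood (step 1e-3,
# then local refinement)
gridCoxOracle <- function(time, event, x, lo = -4, hi = 4) {
  grid <- seq(lo, hi, by = 1e-3)
  ll <- vapply(grid, logPLEfron, numeric(1), time = time, event = event,
               x = x)
  b0 <- grid[which.max(ll)]
  opt <- optimize(function(b) -logPLEfron(b, time, event, x),
                  interval = c(b0 - 2e-3, b0 + 2e-3), tol = 1e-8)
  opt$minimum
}

# tiny genotype panel from an explicit dosage matrix (variants x samples)
makePanel <- function(dosage, alleleA = NULL, alleleB = NULL,
                      chrom = "1", pos = NULL) {
  nV <- nrow(dosage)
  if (is.null(alleleA)) alleleA <- rep("A", nV)
  if (is.null(alleleB)) alleleB <- rep("G", nV)
  if (is.null(pos)) pos <- seq_len(nV) * 100L
  GenotypePanel(dosage, data.frame(
    variant_id = paste0("v", seq_len(nV)), chrom = chrom, pos = pos,
    allele_a = alleleA, allele_b = alleleB, stringsAsFactors = FALSE))
}

makeScore <- function(effect, other, weight, chrom = "1", pos = NULL,
                      id = "PGSTEST") {
  if (is.null(pos)) pos <- seq_along(effect) * 100L
  ScoreFile(data.frame(
    variant_id = paste0("v", seq_along(effect)), chrom = chrom, pos = pos,
    effect_allele = effect, other_allele = other, weight = weight,
    stringsAsFactors = FALSE), pgsId = id)
}

# write a minimal scoring file and return its path
writeTestScoreFile <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# random non-palindromic allele pair
randAllelePair <- function() {
  repeat {
    p <- sample(c("A", "C", "G", "T"), 2)
    if (chartr("ACGT", "TGCA", p[1]) != p[2]) return(p)
  }
}

revcompBase <- function(x) chartr("ACGT", "TGCA", x)

# independent re-derivation of balanced rank-based grouping
.rankGroupsForTest <- function(z, K) {
  ceiling(K * rank(z, ties.method = "first") / length(z))
}

# closed-form 5-year competing-risk probability under constant hazards
ar5Const <- function(h, m, horizon = 5) {
  r <- h + m
  ifelse(r == 0, 0, h / r * (1 - exp(-horizon * r)))
}

# direct per-subject competing-risk outcome draw over one window:
# returns 1 if the cancer occurs within `horizon` years
drawWindowOutcome <- function(h, m, horizon = 5) {
  r <- h + m
  tEv <- ifelse(r > 0, rexp(length(h)) / r, Inf)
  cancer <- runif(length(h)) < ifelse(r > 0, h / r, 0)
  as.integer(tEv <= horizon & cancer)
}
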