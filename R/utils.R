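# internal helpers shared across modules

# reverse complement for SNV / short indel allele strings (ACGT only)
.revcomp <- function(a) {
  vapply(a, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# palindromic = allele pair is its own strand complement (A/T or C/G SNV)
.isPalindromic <- function(effect, other) {
  !is.na(other) & nchar(effect) == 1L & nchar(other) == 1L &
    .revcomp(effect) == other
}

# coerce a constant or function(age) to a vectorized rate function
.asRateFun <- function(h) {
  if (is.function(h)) {
    function(a) {
      r <- h(a)
      if (length(r) == 1L) r <- rep(r, length(a))
      r
    }
  } else {
    force(h)
    function(a) rep(h[1], length(a))
  }
}

# lagged cumulative sum: sum over indices strictly before i
.cumsum0 <- function(x) c(0, cumsum(x))[seq_along(x)]

# exact Hardy-Weinberg test for a biallelic SNP (two-sided, summing all
# heterozygote configurations with probability <= that observed)
.hweExactP <- function(nAB, nA, nB) {
  # nAB: observed heterozygotes; nA/nB: minor/major allele counts
  if (nA > nB) { tmp <- nA; nA <- nB; nB <- tmp }
  n <- (nA + nB) / 2
  if (nA == 0) return(1)
  hetsPossible <- seq(nA %% 2, nA, by = 2)
  # unnormalized log-probabilities of each heterozygote count
  na <- (nA - hetsPossible) / 2    # minor homozygotes
  nb <- n - hetsPossible - na      # major homozygotes
  lp <- lgamma(n + 1) - lgamma(na + 1) - lgamma(hetsPossible + 1) -
    lgamma(nb + 1) + hetsPossible * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(nAB, hetsPossible)]
  if (is.na(obs)) stop("impossible heterozygote count for allele totals")
  min(1, sum(p[p <= obs + 1e-12]))
}

# balanced quantile-group assignment: stable rank order breaks boundary ties
# so group sizes differ by at most one
.rankGroups <- function(z, K) {
  n <- length(z)
  r <- rank(z, ties.method = "first")
  grp <- ceiling(K * r / n)
  # report when tied values straddle a cut-point
  for (g in seq_len(K - 1)) {
    cut <- max(z[grp == g])
    if (any(z[grp == g + 1] == cut))
      message("tied PRS values cross the boundary between groups ",
              g, " and ", g + 1, "; resolved by stable rank order")
  }
  as.integer(grp)
}

# derived seed streams kept below 2^31
.subSeed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k) %%
                                           2147483647)
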