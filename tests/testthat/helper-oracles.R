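# Independent oracle implementations and small fixture builders.
# Oracles deliberately use direct enumeration / textbook formulas and
# share no code with the package internals they check.

# GLMatrix with certain genotypes (log-likelihood 0 for the true
# genotype, `logOther` elsewhere); G is individuals x sites in {0,1,2}
certainGL <- function(G, chrom = "1", pos = NULL, logOther = -60) {
  nI <- nrow(G); nS <- ncol(G)
  if (is.null(pos)) pos <- seq_len(nS) * 10L
  gl <- array(logOther, dim = c(nS, nI, 3L))
  for (i in seq_len(nI)) for (s in seq_len(nS))
    gl[s, i, G[i, s] + 1L] <- 0
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                                  major = "A", minor = "C")
  poplik:::newGLMatrix(sites, gl, sprintf("ind%03d", seq_len(nI)))
}

# GLMatrix with random normalized log triplets
randomGL <- function(nSites, nInd, seed = 1) {
  set.seed(seed)
  gl <- array(log(stats::runif(nSites * nInd * 3)),
              dim = c(nSites, nInd, 3L))
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  for (k in 1:3) gl[, , k] <- matrix(gl[, , k] - mx, nrow = nSites)
  sites <- GenomicRanges::GRanges("1",
                                  IRanges::IRanges(seq_len(nSites) * 10L,
                                                   seq_len(nSites) * 10L),
                                  major = "A", minor = "C")
  poplik:::newGLMatrix(sites, gl, sprintf("ind%03d", seq_len(nInd)))
}

# brute-force SAF: enumerate all 3^N genotype vectors, weight each by
# prod L_i(g_i) * prod C(2,g_i) / C(2N, j)
oracleSAF <- function(glLinear) {
  N <- nrow(glLinear)                    # individuals x 3 (linear scale)
  out <- numeric(2 * N + 1)
  grid <- expand.grid(rep(list(0:2), N))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    j <- sum(g)
    w <- prod(glLinear[cbind(seq_len(N), g + 1L)]) * prod(choose(2, g))
    out[j + 1] <- out[j + 1] + w
  }
  out / choose(2 * N, 0:(2 * N))
}

# textbook Tajima's D from a haplotype matrix (haplotypes x sites),
# computed from pairwise differences and the segregating-site count
oracleTajimaD <- function(H) {
  n <- nrow(H)
  S <- sum(apply(H, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  piTot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    piTot <- piTot + sum(H[i, ] != H[j, ])
  piMean <- piTot / choose(n, 2)
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (piMean - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# textbook Hudson Fst (Bhatia ratio-of-sums) from two genotype matrices,
# written independently of the package's estimator
oracleHudsonFst <- function(G1, G2) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(G1))) {
    x1 <- G1[, s]; x2 <- G2[, s]
    n1 <- 2 * sum(!is.na(x1)); n2 <- 2 * sum(!is.na(x2))
    p1 <- sum(x1, na.rm = TRUE) / n1; p2 <- sum(x2, na.rm = TRUE) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# brute-force Garud H from explicit haplotype-class counting
oracleGarudH <- function(block) {
  keys <- apply(block, 1, paste, collapse = ",")
  counts <- sort(tabulate(factor(keys)), decreasing = TRUE)
  p <- counts / sum(counts)
  while (length(p) < 3) p <- c(p, 0)
  H1 <- sum(p^2)
  c(H1 = H1,
    H12 = H1 + 2 * p[1] * p[2],
    H123 = H1 + 2 * p[1] * p[2] + 2 * p[1] * p[3] + 2 * p[2] * p[3],
    H2H1 = (H1 - p[1]^2) / H1)
}

# grid-search ML allele frequency maximizing the HWE mixture likelihood
oracleGridMaf <- function(glSite, step = 1e-4) {
  L <- exp(glSite)                       # individuals x 3
  fGrid <- seq(0, 1, by = step)
  ll <- vapply(fGrid, function(f) {
    h <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    sum(log(L %*% h))
  }, 0)
  f <- fGrid[which.max(ll)]
  min(f, 1 - f)
}

# direct pedigree-sampling oracle: expected genotype concordance of two
# sibs given parental haplotypes, by Monte Carlo transmission
oracleSibConcordance <- function(hapP1, hapP2, nRep = 200, seed = 42) {
  set.seed(seed)
  S <- length(hapP1$a)
  conc <- numeric(nRep)
  for (r in seq_len(nRep)) {
    kid <- function() {
      ifelse(stats::runif(S) < 0.5, hapP1$a, hapP1$b) +
        ifelse(stats::runif(S) < 0.5, hapP2$a, hapP2$b)
    }
    conc[r] <- mean(kid() == kid())
  }
  mean(conc)
}
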