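#' Site allele-frequency likelihoods for a population
#'
#' For each site, the likelihood of every possible population
#' minor-allele count j = 0..2N, marginalizing individual genotypes:
#' \deqn{SAF(j) = \sum_{g: \sum g_i = j} \prod_i L_i(g_i) P(g | j)}
#' where configurations are weighted by the hypergeometric probability of
#' assigning j allele copies to 2N chromosomes. Computed by iterative
#' polynomial convolution of per-individual likelihood triplets weighted
#' by the genotype multiplicity (1, 2, 1), with a final division by
#' \eqn{\binom{2N}{j}}; equal (to 1e-8) to brute-force enumeration over
#' all genotype vectors for small N.
#'
#' @param gl a [GLMatrix].
#' @param individuals optional subset (ids or indices) defining the
#'   population.
#' @return a [SAFMatrix] with log-scaled, max-normalized rows.
#' @export
safLikelihoods <- function(gl, individuals = NULL) {
  if (!is.null(individuals)) gl <- subsetGL(gl, individuals = individuals)
  if (nInd(gl) < 1L) stop("at least one individual required")
  L <- linearGL(glArray(gl))
  nS <- nSites(gl); N <- nInd(gl)
  S <- matrix(1, nS, 1L)
  logScale <- numeric(nS)
  for (i in seq_len(N)) {
    a0 <- L[, i, 1]; a1 <- 2 * L[, i, 2]; a2 <- L[, i, 3]
    m <- ncol(S)
    Snew <- matrix(0, nS, m + 2L)
    Snew[, 1:m] <- S * a0
    Snew[, 2:(m + 1L)] <- Snew[, 2:(m + 1L), drop = FALSE] + S * a1
    Snew[, 3:(m + 2L)] <- Snew[, 3:(m + 2L), drop = FALSE] + S * a2
    S <- Snew
    if (i %% 8L == 0L || i == N) {
      mx <- rowMax(S)
      mx[mx == 0] <- 1
      S <- S / mx
      logScale <- logScale + log(mx)
    }
  }
  logSaf <- log(pmax(S, 0)) + logScale -
    rep(lchoose(2L * N, 0:(2L * N)), each = nS)
  logSaf <- logSaf - rowMax(logSaf)
  new("SAFMatrix", sites = glSites(gl), saf = logSaf, nChrom = 2L * N)
}

# fold a linear-scale SAF matrix (sites x 2N+1) to N+1 minor-allele
# classes by summing symmetric columns
foldLinearSaf <- function(P) {
  K <- ncol(P) - 1L
  half <- K %/% 2L
  out <- P[, 1:(half + 1L), drop = FALSE]
  for (j in 0:(half - 1L))
    out[, j + 1L] <- out[, j + 1L] + P[, K - j + 1L]
  out
}

#' Estimate the site-frequency spectrum by EM
#'
#' Maximizes \eqn{\sum_s \log \sum_j SFS_j SAF_s(j)} over the SFS
#' simplex (realSFS-style), scaled to expected site counts. Folding sums
#' the j and 2N-j site allele-frequency classes before the EM. The EM
#' log-likelihood is non-decreasing; iteration stops when the gain drops
#' below \code{tol} or at \code{maxIter}.
#'
#' @param saf a [SAFMatrix].
#' @param folded estimate the folded (minor-allele) spectrum.
#' @param tol,maxIter EM convergence controls.
#' @return an [SFSpectrum] with attribute \code{trace} (per-iteration
#'   log-likelihood).
#' @export
estimateSfs <- function(saf, folded = TRUE, tol = 1e-6, maxIter = 500L) {
  if (nSites(saf) < 1L) stop("at least one site required")
  P <- exp(saf@saf)
  if (folded) P <- foldLinearSaf(P)
  K <- ncol(P)
  flat <- rowSums(abs(P - P[, 1]) > 1e-12) == 0
  if (all(flat)) {
    warning("all sites uninformative; returning uniform SFS")
    return(new("SFSpectrum", counts = rep(nrow(P) / K, K), folded = folded,
               nChrom = saf@nChrom, logLik = NA_real_, nIter = 0L))
  }
  sfs <- rep(1 / K, K)
  trace <- numeric(0)
  llPrev <- -Inf
  for (it in seq_len(maxIter)) {
    d <- as.vector(P %*% sfs)
    ll <- sum(log(pmax(d, 1e-300)))
    trace <- c(trace, ll)
    post <- (P * rep(sfs, each = nrow(P))) / d
    sfs <- colMeans(post)
    sfs <- sfs / sum(sfs)
    if (is.finite(llPrev) && ll - llPrev < tol) break
    llPrev <- ll
  }
  out <- new("SFSpectrum", counts = sfs * nrow(P), folded = folded,
             nChrom = saf@nChrom, logLik = trace[length(trace)],
             nIter = length(trace))
  attr(out, "trace") <- trace
  out
}

#' Tajima's D normalization constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants as functions of the
#' number of sampled chromosomes n, per the standard 1989 definitions.
#'
#' @param n number of chromosomes (>= 2).
#' @return named list of the eight constants.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-site posterior diversity expectations
#'
#' Empirical-Bayes posterior over allele-count classes,
#' \eqn{P(j) \propto SFS_j \, SAF_s(j)}, yielding per-site expected
#' pairwise diversity \eqn{E[\pi] = \sum_j P(j) 2j(2N-j)/(2N(2N-1))},
#' the probability the site segregates, and the per-site Watterson
#' contribution \eqn{P(seg)/a_1}.
#'
#' @param saf a [SAFMatrix].
#' @param sfs an [SFSpectrum] from the same population (same 2N).
#' @return data.frame(chrom, pos, pi, thetaW, pSeg), one row per site.
#' @export
perSiteThetas <- function(saf, sfs) {
  if (sfs@nChrom != saf@nChrom)
    stop("SFS and SAF disagree on the number of chromosomes")
  P <- exp(saf@saf)
  if (sfs@folded) P <- foldLinearSaf(P)
  prior <- sfs@counts / sum(sfs@counts)
  W <- P * rep(prior, each = nrow(P))
  W <- W / rowSums(W)
  n <- saf@nChrom
  j <- if (sfs@folded) 0:(n %/% 2L) else 0:n
  wPi <- 2 * j * (n - j) / (n * (n - 1))
  segClass <- if (sfs@folded) j >= 1L else (j >= 1L & j <= n - 1L)
  a1 <- tajimaConstants(n)$a1
  pSeg <- rowSums(W[, segClass, drop = FALSE])
  data.frame(chrom = as.character(seqnames(saf@sites)),
             pos = start(saf@sites),
             pi = as.vector(W %*% wPi), thetaW = pSeg / a1, pSeg = pSeg)
}

#' Windowed diversity: pi, Watterson's theta and Tajima's D
#'
#' Sliding windows (0-based half-open, BED convention) over per-site
#' posterior expectations. Window \code{pi} and \code{thetaW} are
#' per-evaluated-site averages; Tajima's D uses the window totals,
#' \deqn{D = (\pi_{sum} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}
#' with S the expected number of segregating sites. Windows whose S is
#' numerically zero (below 1e-8) report D as missing, not 0.
#'
#' @param thetas data.frame from [perSiteThetas()].
#' @param nChrom number of chromosomes (for the D constants).
#' @param windowBp,stepBp window size and step in bp.
#' @param chromLengths named lengths; defaults to the maximum observed
#'   position per chromosome.
#' @return data.frame(chrom, start, end, n_sites, pi, thetaW, tajD).
#' @export
windowedDiversity <- function(thetas, nChrom, windowBp = 10000,
                              stepBp = 5000, chromLengths = NULL) {
  k <- tajimaConstants(nChrom)
  out <- list()
  for (chr in unique(thetas$chrom)) {
    d <- thetas[thetas$chrom == chr, ]
    len <- if (!is.null(chromLengths) && chr %in% names(chromLengths))
      chromLengths[[chr]] else max(d$pos)
    w <- slidingWindows0(len, windowBp, stepBp)
    res <- lapply(seq_len(nrow(w)), function(i) {
      inWin <- d$pos - 1L >= w$start[i] & d$pos - 1L < w$end[i]
      n <- sum(inWin)
      if (n == 0L)
        return(data.frame(chrom = chr, start = w$start[i], end = w$end[i],
                          n_sites = 0L, pi = NA_real_, thetaW = NA_real_,
                          tajD = NA_real_))
      piSum <- sum(d$pi[inWin]); S <- sum(d$pSeg[inWin])
      denom <- sqrt(k$e1 * S + k$e2 * S * max(S - 1, 0))
      data.frame(chrom = chr, start = w$start[i], end = w$end[i],
                 n_sites = n, pi = piSum / n, thetaW = S / k$a1 / n,
                 tajD = if (S > 1e-8 && denom > 0)
                   (piSum - S / k$a1) / denom else NA_real_)
    })
    out[[chr]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide diversity from per-site expectations
#'
#' Totals across all evaluated sites: per-site pi and thetaW rates and
#' the genome-wide Tajima's D computed from the totals (the windowed
#' scan reports the per-window alternative).
#'
#' @param thetas data.frame from [perSiteThetas()].
#' @param nChrom number of chromosomes.
#' @return one-row data.frame(n_sites, pi, thetaW, tajD).
#' @export
genomewideDiversity <- function(thetas, nChrom) {
  k <- tajimaConstants(nChrom)
  S <- sum(thetas$pSeg)
  piSum <- sum(thetas$pi)
  denom <- sqrt(k$e1 * S + k$e2 * S * max(S - 1, 0))
  data.frame(n_sites = nrow(thetas), pi = piSum / nrow(thetas),
             thetaW = S / k$a1 / nrow(thetas),
             tajD = if (S > 1e-8 && denom > 0) (piSum - S / k$a1) / denom
             else NA_real_)
}

#' Effective population size from theta
#'
#' \eqn{N_e = \theta / (4 \mu)} for a per-site theta and a per-bp,
#' per-generation mutation rate.
#'
#' @param thetaPerSite per-site theta (pi or Watterson flavour).
#' @param mu mutation rate per bp per generation (> 0).
#' @return Ne estimate.
#' @export
estimateNe <- function(thetaPerSite, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("mu must be > 0")
  thetaPerSite / (4 * mu)
}

#' Write / read an SFS as a whitespace-separated vector file
#'
#' realSFS-compatible shape: one line of expected class counts.
#'
#' @param sfs an [SFSpectrum].
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeSfs <- function(sfs, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(sprintf("%.6f", sfsCounts(sfs)), collapse = " "), path)
  invisible(path)
}
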