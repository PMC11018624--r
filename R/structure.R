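#' Posterior expected genotype dosages
#'
#' \eqn{E[g] = \sum_k k L(k) HWE(k|f) / \sum_k L(k) HWE(k|f)} per
#' individual and site; missing individual-sites take the prior mean 2f.
#'
#' @param gl a [GLMatrix].
#' @param freqs per-site minor-allele frequencies (defaults to the ML
#'   frequencies estimated from the GLs).
#' @return individuals x sites matrix of expected minor-allele dosages.
#' @export
posteriorDosages <- function(gl, freqs = NULL) {
  a <- glArray(gl)
  if (is.null(freqs)) freqs <- estimateMafEM(a)$freq
  L <- linearGL(a)
  h0 <- (1 - freqs)^2; h1 <- 2 * freqs * (1 - freqs); h2 <- freqs^2
  num <- L[, , 2] * h1 + 2 * L[, , 3] * h2
  den <- L[, , 1] * h0 + num - L[, , 3] * h2
  eg <- num / pmax(den, 1e-300)
  miss <- glMissing(a)
  eg[miss] <- (2 * freqs)[row(eg)[miss]]
  t(eg)
}

#' Genotype-likelihood PCA via the standardized covariance matrix
#'
#' \deqn{C_{ij} = \frac{1}{S} \sum_s \frac{(E[g_{is}]-2f_s)
#'   (E[g_{js}]-2f_s)}{2 f_s (1-f_s)}}
#' followed by eigendecomposition in descending eigenvalue order;
#' PC scores are eigenvectors scaled by the square root of their
#' eigenvalue. Monomorphic sites (f of 0 or 1) are excluded with a
#' warning. Single-pass with fixed per-site frequencies; an optional
#' iterated mode re-estimates individual allele frequencies from the
#' top PCs before the final pass.
#'
#' @param gl a [GLMatrix].
#' @param freqs per-site frequencies (default: ML estimates).
#' @param nPcs number of PCs to return.
#' @param iterate extra frequency-re-estimation passes (default 0).
#' @return list(cov, values, vectors, scores, sitesUsed).
#' @export
covariancePca <- function(gl, freqs = NULL, nPcs = 10L, iterate = 0L) {
  if (nInd(gl) < 2L) stop("need at least two individuals")
  a <- glArray(gl)
  if (is.null(freqs)) freqs <- estimateMafEM(a)$freq
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic site(s) excluded from the covariance")
    gl <- subsetGL(gl, sites = which(poly))
    freqs <- freqs[poly]
  }
  if (nSites(gl) < 2L) stop("need at least two polymorphic sites")
  D <- posteriorDosages(gl, freqs)        # individuals x sites
  for (r in seq_len(iterate)) {
    ## pcangsd-flavoured refinement: individual frequencies from top PCs
    X <- sweep(D, 2L, 2 * freqs)
    sv <- svd(X, nu = min(nPcs, nrow(D) - 1L), nv = 0)
    proj <- sv$u %*% (t(sv$u) %*% X)
    indF <- pmin(pmax((proj + rep(2 * freqs, each = nrow(D))) / 2, 1e-4),
                 1 - 1e-4) / 1          # individual allele frequencies
    D <- posteriorDosageMatrix(gl, t(indF))
  }
  X <- sweep(D, 2L, 2 * freqs)
  X <- sweep(X, 2L, sqrt(2 * freqs * (1 - freqs)), "/")
  C <- tcrossprod(X) / ncol(X)
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  nPcs <- min(nPcs, ncol(eig$vectors))
  scores <- eig$vectors[, seq_len(nPcs), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(nPcs)], 0)), nPcs)
  rownames(C) <- colnames(C) <- glSamples(gl)
  rownames(scores) <- glSamples(gl)
  colnames(scores) <- paste0("PC", seq_len(nPcs))
  list(cov = C, values = eig$values, vectors = eig$vectors,
       scores = scores, sitesUsed = nSites(gl))
}

# dosages under per-individual, per-site frequencies (sites x ind matrix)
posteriorDosageMatrix <- function(gl, fMat) {
  a <- glArray(gl)
  L <- linearGL(a)
  h0 <- (1 - fMat)^2; h1 <- 2 * fMat * (1 - fMat); h2 <- fMat^2
  num <- L[, , 2] * h1 + 2 * L[, , 3] * h2
  den <- L[, , 1] * h0 + L[, , 2] * h1 + L[, , 3] * h2
  eg <- num / pmax(den, 1e-300)
  miss <- glMissing(a)
  eg[miss] <- (2 * fMat)[miss]
  t(eg)
}

#' Admixture proportions from genotype likelihoods by EM
#'
#' The NGSadmix model: \eqn{P(data_{is}) = \sum_g L_{is}(g)
#' \binom{2}{g} \pi_{is}^g (1-\pi_{is})^{2-g}} with
#' \eqn{\pi_{is} = \sum_k Q_{ik} F_{sk}}. EM updates keep the
#' log-likelihood non-decreasing; convergence at a gain below
#' \code{tol} or \code{maxIter} iterations. Several seeded starts are
#' run and the best likelihood reported.
#'
#' @param gl a [GLMatrix].
#' @param K number of ancestral clusters (>= 1, <= individuals).
#' @param seed base seed; start s uses a seed derived from it.
#' @param nStarts number of seeded starts.
#' @param tol,maxIter EM controls.
#' @return an [AdmixtureFit].
#' @export
admixtureEm <- function(gl, K, seed = 1L, nStarts = 3L, tol = 1e-6,
                        maxIter = 2000L) {
  K <- as.integer(K)
  N <- nInd(gl); S <- nSites(gl)
  if (K < 1L) stop("K must be >= 1")
  if (K > N) stop("K exceeds the number of individuals")
  a <- glArray(gl)
  L <- linearGL(a)
  L0 <- t(L[, , 1]); L1 <- t(L[, , 2]); L2 <- t(L[, , 3])  # ind x sites
  fHat <- estimateMafEM(a)$freq
  fHat[is.na(fHat)] <- 0.5
  best <- NULL
  for (s in seq_len(nStarts)) {
    set.seed(childSeed(seed, s))
    Q <- matrix(stats::rexp(N * K), N, K)
    Q <- Q / rowSums(Q)
    F <- matrix(pmin(pmax(rep(fHat, K) +
                            stats::rnorm(S * K, 0, 0.05), 0.01), 0.99), S, K)
    trace <- numeric(0); llPrev <- -Inf
    for (it in seq_len(maxIter)) {
      Pi <- Q %*% t(F)
      Pi <- pmin(pmax(Pi, 1e-9), 1 - 1e-9)
      pd <- L0 * (1 - Pi)^2 + L1 * 2 * Pi * (1 - Pi) + L2 * Pi^2
      ll <- sum(log(pmax(pd, 1e-300)))
      trace <- c(trace, ll)
      Eg <- (L1 * 2 * Pi * (1 - Pi) + 2 * L2 * Pi^2) / pmax(pd, 1e-300)
      sumA <- matrix(0, N, K); Fnew <- matrix(0, S, K)
      for (k in seq_len(K)) {
        Ak <- Eg * (Q[, k] * rep(F[, k], each = N)) / Pi          # minor
        Bk <- (2 - Eg) * (Q[, k] * rep(1 - F[, k], each = N)) /
          (1 - Pi)                                                 # major
        ca <- colSums(Ak); cb <- colSums(Bk)
        Fnew[, k] <- ca / pmax(ca + cb, 1e-300)
        sumA[, k] <- rowSums(Ak) + rowSums(Bk)
      }
      Qnew <- sumA / (2 * S)
      Qnew <- Qnew / rowSums(Qnew)
      F <- pmin(pmax(Fnew, 1e-6), 1 - 1e-6)
      Q <- Qnew
      if (is.finite(llPrev) && ll - llPrev < tol) break
      llPrev <- ll
    }
    if (is.null(best) || trace[length(trace)] > best@logLik) {
      best <- new("AdmixtureFit", K = K, Q = Q, F = F,
                  logLik = trace[length(trace)], trace = trace)
    }
  }
  rownames(best@Q) <- glSamples(gl)
  best
}
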