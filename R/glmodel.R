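#' Genotype likelihoods for one individual at one site
#'
#' The samtools-style diallelic GL model. For a genotype carrying k
#' copies of the minor allele (k = 0, 1, 2),
#' \deqn{L(k) = \prod_i [(k/2) P(b_i | minor) + (1-k/2) P(b_i | major)]}
#' with \eqn{P(b | a) = 1 - e_i} when the read base equals the allele and
#' \eqn{e_i/3} otherwise, \eqn{e_i = 10^{-q_i/10}}.
#'
#' @param bases character vector of observed read bases.
#' @param quals phred-scaled base qualities (recycled).
#' @param major,minor the two alleles.
#' @param normalize return log likelihoods shifted so the maximum is 0
#'   (the GLMatrix convention); \code{FALSE} returns raw log products.
#' @return numeric triplet of log likelihoods for k = 0, 1, 2; the flat
#'   triplet (0, 0, 0) when no reads are supplied.
#' @examples
#' genotypeLikelihoods(c("A", "A", "A", "A"), 30, "A", "C",
#'                     normalize = FALSE)
#' @export
genotypeLikelihoods <- function(bases, quals, major, minor, normalize = TRUE) {
  if (length(bases) == 0L) return(c(0, 0, 0))
  e <- 10^(-rep(quals, length.out = length(bases)) / 10)
  pMajor <- ifelse(bases == major, 1 - e, e / 3)
  pMinor <- ifelse(bases == minor, 1 - e, e / 3)
  ll <- vapply(0:2, function(k)
    sum(log((k / 2) * pMinor + (1 - k / 2) * pMajor)), 0)
  if (normalize) ll - max(ll) else ll
}

# vectorized log-GL computation from ref/alt/other counts at constant
# error rate; returns sites x individuals x 3 array normalized so the
# per-individual maximum is 0 and zero-depth entries are flat
glFromCounts <- function(nA1, nA2, nOther, phred) {
  e <- 10^(-phred / 10)
  gl <- array(0, dim = c(nrow(nA1), ncol(nA1), 3L))
  for (k in 0:2) {
    p1 <- (1 - k / 2) * (1 - e) + (k / 2) * (e / 3)   # read = allele1
    p2 <- (k / 2) * (1 - e) + (1 - k / 2) * (e / 3)   # read = allele2
    gl[, , k + 1L] <- nA1 * log(p1) + nA2 * log(p2) + nOther * log(e / 3)
  }
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  for (k in 1:3) gl[, , k] <- gl[, , k] - mx
  depth0 <- nA1 + nA2 + nOther == 0L
  if (any(depth0)) for (k in 1:3) {
    slc <- gl[, , k]; slc[depth0] <- 0; gl[, , k] <- slc
  }
  gl
}

#' Filter configuration for site and individual culling
#'
#' Thresholds mirroring ANGSD-style GL calling: reads below
#' \code{minBaseQ} are excluded before GL computation; sites are dropped
#' when total (across-individual) depth exceeds \code{maxTotalDepth},
#' when fewer than \code{minIndFraction} of individuals have data, when
#' the polymorphism likelihood-ratio p-value exceeds \code{snpPvalueMax},
#' or when the minor-allele frequency is below \code{mafMin}. Setting
#' \code{polymorphismFiltersOn = FALSE} skips the SNP-p, depth and MAF
#' rules so monomorphic sites are retained (the diversity path).
#'
#' @param maxTotalDepth,minBaseQ,minIndFraction,snpPvalueMax,mafMin
#'   thresholds (see description).
#' @param polymorphismFiltersOn logical flag.
#' @return a list of class \code{poplik_filters}.
#' @export
filterConfig <- function(maxTotalDepth = 6000, minBaseQ = 30,
                         minIndFraction = 0.25, snpPvalueMax = 0.05,
                         mafMin = 0.05, polymorphismFiltersOn = TRUE) {
  stopifnot(minIndFraction >= 0, minIndFraction <= 1,
            snpPvalueMax >= 0, snpPvalueMax <= 1, mafMin >= 0, mafMin < 0.5)
  structure(list(maxTotalDepth = maxTotalDepth, minBaseQ = minBaseQ,
                 minIndFraction = minIndFraction,
                 snpPvalueMax = snpPvalueMax, mafMin = mafMin,
                 polymorphismFiltersOn = polymorphismFiltersOn),
            class = "poplik_filters")
}

#' Genotype likelihoods for all sites of a pileup
#'
#' Computes normalized log GLs for every site and individual and
#' designates major/minor alleles from the maximum-likelihood allele
#' frequency (the minor allele is the less frequent one); triplets are
#' stored in (major/major, major/minor, minor/minor) order.
#'
#' @param pileup a [ReadPileup].
#' @param minBaseQ reads below this phred quality are excluded before GL
#'   computation (all reads of a pileup share one quality).
#' @return a [GLMatrix]; an attribute-free object whose site mcols carry
#'   the designated major/minor alleles.
#' @export
pileupGL <- function(pileup, minBaseQ = 0) {
  nRef <- pileup@nRef; nAlt <- pileup@nAlt; nOther <- pileup@nOther
  if (pileup@baseQual < minBaseQ) {
    nRef[] <- 0L; nAlt[] <- 0L; nOther[] <- 0L
  }
  gl <- glFromCounts(nRef, nAlt, nOther, pileup@baseQual)
  sites <- pileup@sites
  major <- mcols(sites)$ref
  minor <- mcols(sites)$alt
  ## orient by estimated allele-2 frequency: minor = less frequent
  f <- estimateMafEM(gl)$freq
  swap <- !is.na(f) & f > 0.5
  if (any(swap)) {
    gl[swap, , ] <- gl[swap, , 3:1, drop = FALSE]
    tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  }
  mcols(sites) <- DataFrame(major = major, minor = minor)
  newGLMatrix(sites, gl, pileup@samples)
}

# constructor enforcing site order
newGLMatrix <- function(sites, gl, samples) {
  o <- siteOrder(sites)
  if (is.unsorted(o)) {
    sites <- sites[o]
    gl <- gl[o, , , drop = FALSE]
  }
  new("GLMatrix", sites = sites, gl = gl, samples = samples)
}

# EM for the ML frequency of allele 2 from normalized log GL triplets;
# vectorized over sites, run from several starts (the HWE mixture
# likelihood can be multimodal) keeping the per-site best. Returns freq
# (allele-2), maf = min(f, 1-f), loglik at the optimum and at f = 0,
# and the usable-individual count.
estimateMafEM <- function(gl, tol = 1e-8, maxIter = 500L,
                          starts = c(0.2, 0.5, 0.9)) {
  L <- linearGL(gl)                     # sites x ind x 3
  miss <- glMissing(gl)
  nUse <- rowSums(!miss)
  L0 <- matrix(L[, , 1], nrow = dim(L)[1])
  L1 <- matrix(L[, , 2], nrow = dim(L)[1])
  L2 <- matrix(L[, , 3], nrow = dim(L)[1])
  ## missing individuals contribute a constant; excluding them from the
  ## dosage average is equivalent and keeps the EM exact
  W0 <- L0; W1 <- L1; W2 <- L2
  W0[miss] <- 0; W1[miss] <- 0; W2[miss] <- 0
  active <- nUse > 0
  ll <- function(fr) {
    h0 <- (1 - fr)^2; h1 <- 2 * fr * (1 - fr); h2 <- fr^2
    m <- L0 * h0 + L1 * h1 + L2 * h2
    m[miss] <- 1
    rowSums(log(pmax(m, 1e-300)))
  }
  bestF <- rep(NA_real_, dim(L)[1])
  bestLL <- rep(-Inf, dim(L)[1])
  for (f0 in starts) {
    f <- rep(f0, dim(L)[1])
    for (it in seq_len(maxIter)) {
      h0 <- (1 - f)^2; h1 <- 2 * f * (1 - f); h2 <- f^2
      d <- W0 * h0 + W1 * h1 + W2 * h2
      d[d == 0 | miss] <- Inf             # guard; no dosage contribution
      eg <- (W1 * h1 + 2 * W2 * h2) / d
      fNew <- ifelse(active, rowSums(eg) / (2 * pmax(nUse, 1)), NA_real_)
      delta <- abs(fNew - f)
      f <- fNew
      if (all(delta[active] < tol, na.rm = TRUE)) break
    }
    llf <- ll(f)
    better <- active & (llf > bestLL)
    bestF[better] <- f[better]
    bestLL[better] <- llf[better]
  }
  bestLL[!active] <- NA_real_
  list(freq = bestF, maf = pmin(bestF, 1 - bestF), logLik = bestLL,
       logLik0 = ll(0), nUsable = nUse)
}

#' Maximum-likelihood minor-allele frequency at one site
#'
#' EM maximization of \eqn{\sum_i \log \sum_k L_i(k) HWE(k | f)} with
#' \eqn{HWE = \{(1-f)^2, 2f(1-f), f^2\}}; iterated to |df| < 1e-8 with a
#' 500-iteration cap (near-flat likelihoods converge slowly). Returns
#' the folded frequency \code{min(f, 1-f)}.
#'
#' @param glSite individuals x 3 matrix of normalized log GL triplets.
#' @return list with \code{maf}, the unfolded allele-2 \code{freq}, and
#'   the log-likelihoods at the optimum and at f = 0.
#' @export
estimateMaf <- function(glSite) {
  glSite <- as.matrix(glSite)
  gl <- array(glSite, dim = c(1L, nrow(glSite), 3L))
  fit <- estimateMafEM(gl)
  if (fit$nUsable[1] == 0L)
    stop("all individuals missing: site unusable")
  list(maf = fit$maf[1], freq = fit$freq[1],
       logLik = fit$logLik[1], logLik0 = fit$logLik0[1])
}

#' Likelihood-ratio test for polymorphism at each site
#'
#' LRT = 2 [l(f-hat) - l(0)] against the chi-squared distribution with
#' one degree of freedom; sites are considered polymorphic (retained)
#' when p <= the configured threshold.
#'
#' @param gl a [GLMatrix].
#' @return data.frame(maf, statistic, p_value), one row per site.
#' @export
snpLrt <- function(gl) {
  fit <- estimateMafEM(glArray(gl))
  stat <- pmax(2 * (fit$logLik - fit$logLik0), 0)
  data.frame(maf = fit$maf, statistic = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Apply site filters to a pileup
#'
#' Computes GLs with the base-quality rule, then drops sites per the
#' [filterConfig()] rules; returns the retained [GLMatrix] with a
#' \code{filterLog} attribute counting sites removed by each rule.
#' Zero surviving sites yields an empty GLMatrix with a warning.
#'
#' @param pileup a [ReadPileup].
#' @param cfg a [filterConfig()] list.
#' @return a [GLMatrix] with attribute \code{filterLog}.
#' @export
filterSites <- function(pileup, cfg = filterConfig()) {
  gl <- pileupGL(pileup, minBaseQ = cfg$minBaseQ)
  a <- glArray(gl)
  miss <- glMissing(a)
  keep <- rep(TRUE, nSites(gl))
  log <- c(total = nSites(gl))
  fracInd <- rowMeans(!miss)
  dropInd <- fracInd < cfg$minIndFraction
  keep <- keep & !dropInd
  log["minInd"] <- sum(dropInd)
  if (cfg$polymorphismFiltersOn) {
    depth <- rowSums(pileup@nRef + pileup@nAlt + pileup@nOther)
    if (pileup@baseQual < cfg$minBaseQ) depth[] <- 0
    dropDepth <- depth > cfg$maxTotalDepth
    lrt <- snpLrt(gl)
    dropSnp <- !is.na(lrt$p_value) & lrt$p_value > cfg$snpPvalueMax
    dropSnp[is.na(lrt$p_value)] <- TRUE
    dropMaf <- is.na(lrt$maf) | lrt$maf < cfg$mafMin
    log["maxDepth"] <- sum(dropDepth & keep)
    keep <- keep & !dropDepth
    log["snpP"] <- sum(dropSnp & keep)
    keep <- keep & !dropSnp
    log["maf"] <- sum(dropMaf & keep)
    keep <- keep & !dropMaf
  }
  log["retained"] <- sum(keep)
  if (!any(keep)) warning("no sites survive filtering")
  out <- newGLMatrix(glSites(gl)[keep], a[keep, , , drop = FALSE],
                     glSamples(gl))
  attr(out, "filterLog") <- log
  out
}

#' Remove individuals with excessive missingness
#'
#' Individuals whose fraction of flat (missing) triplets strictly
#' exceeds \code{maxMissing} are removed and listed.
#'
#' @param gl a [GLMatrix].
#' @param maxMissing maximum tolerated missing fraction (strict).
#' @return list(gl = pruned GLMatrix, removed = ids, missingness =
#'   named per-individual fractions).
#' @export
filterIndividuals <- function(gl, maxMissing = 0.25) {
  a <- glArray(gl)
  fracMiss <- colMeans(glMissing(a))
  names(fracMiss) <- glSamples(gl)
  drop <- fracMiss > maxMissing
  if (all(drop)) stop("all individuals exceed the missingness threshold")
  out <- newGLMatrix(glSites(gl), a[, !drop, , drop = FALSE],
                     glSamples(gl)[!drop])
  list(gl = out, removed = glSamples(gl)[drop], missingness = fracMiss)
}

#' Write a GLMatrix in BEAGLE genotype-likelihood text format
#'
#' Header \code{marker allele1 allele2} then three columns per
#' individual of linear-scale likelihoods normalized to sum 1, in
#' (major/major, major/minor, minor/minor) order; markers are encoded
#' \code{chrom_pos}.
#'
#' @param gl a [GLMatrix].
#' @param path output file (plain text; use a .gz path for compression).
#' @return invisibly, \code{path}.
#' @export
writeBeagle <- function(gl, path) {
  a <- linearGL(glArray(gl))
  tot <- a[, , 1] + a[, , 2] + a[, , 3]
  for (k in 1:3) a[, , k] <- a[, , k] / tot
  sites <- glSites(gl)
  n <- nInd(gl)
  header <- c("marker", "allele1", "allele2",
              rep(glSamples(gl), each = 3L))
  cols <- vector("list", 3L + 3L * n)
  cols[[1]] <- paste(as.character(seqnames(sites)), start(sites), sep = "_")
  cols[[2]] <- mcols(sites)$major
  cols[[3]] <- mcols(sites)$minor
  for (i in seq_len(n)) for (k in 1:3)
    cols[[3L + 3L * (i - 1L) + k]] <- sprintf("%.6g", a[, i, k])
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(paste(header, collapse = "\t"), con)
  if (nSites(gl))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  close(con)
  invisible(path)
}

#' Read a BEAGLE genotype-likelihood file
#'
#' Inverse of [writeBeagle()]: markers \code{chrom_pos} are split on the
#' final underscore, likelihood triplets are renormalized to the
#' log-scale, max-zero GLMatrix convention, and triplets that are exactly
#' flat become missing.
#'
#' @param path BEAGLE file (optionally gzipped).
#' @return a [GLMatrix].
#' @export
readBeagle <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L || (ncol(tab) - 3L) %% 3L != 0L)
    stop("malformed BEAGLE file: ", path)
  samples <- unique(colnames(tab)[-(1:3)])
  if (length(samples) * 3L != ncol(tab) - 3L)
    stop("malformed BEAGLE header: sample columns not in triplets")
  chrom <- sub("_[0-9]+$", "", tab$marker)
  pos <- suppressWarnings(as.integer(sub("^.*_", "", tab$marker)))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed BEAGLE marker at line ", bad[1] + 1L)
  nS <- nrow(tab); nI <- length(samples)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -(1:3), drop = FALSE])), nrow = nS))
  bad <- which(rowSums(is.na(vals)) > 0)
  if (length(bad))
    stop("malformed BEAGLE likelihoods at line ", bad[1] + 1L)
  gl <- array(0, dim = c(nS, nI, 3L))
  for (i in seq_len(nI)) gl[, i, ] <- vals[, (3L * i - 2L):(3L * i)]
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  flat <- abs(gl[, , 1] - gl[, , 2]) < 1e-12 &
    abs(gl[, , 2] - gl[, , 3]) < 1e-12
  for (k in 1:3) {
    slc <- log(pmax(gl[, , k], 1e-300) / pmax(mx, 1e-300))
    slc[flat] <- 0
    gl[, , k] <- slc
  }
  sites <- GRanges(chrom, IRanges(pos, pos),
                   major = tab$allele1, minor = tab$allele2)
  newGLMatrix(sites, gl, samples)
}

#' Subset a GLMatrix by individuals and/or sites
#'
#' @param gl a [GLMatrix].
#' @param individuals sample ids or indices (optional).
#' @param sites logical or integer site index (optional).
#' @return a [GLMatrix].
#' @export
subsetGL <- function(gl, individuals = NULL, sites = NULL) {
  a <- glArray(gl); s <- glSites(gl); ids <- glSamples(gl)
  if (!is.null(sites)) {
    s <- s[sites]
    a <- a[sites, , , drop = FALSE]
  }
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, ids)
    ids <- ids[individuals]
    a <- a[, individuals, , drop = FALSE]
  }
  newGLMatrix(s, a, ids)
}
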