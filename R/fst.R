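#' Joint two-population site-frequency spectrum by EM
#'
#' Maximizes \eqn{\sum_s \log \sum_{j_1 j_2} M_{j_1 j_2} SAF^1_s(j_1)
#' SAF^2_s(j_2)} over the (2N1+1) x (2N2+1) simplex; same convergence
#' contract as the 1D EM. Both SAFs must cover the same site list with a
#' shared minor-allele polarization (the spectrum classes count the
#' shared minor allele, so allele identity is preserved for Fst).
#'
#' @param saf1,saf2 [SAFMatrix] objects over identical sites.
#' @param tol,maxIter EM controls.
#' @return a [Joint2DSFS] with attribute \code{trace}.
#' @export
jointSfs <- function(saf1, saf2, tol = 1e-6, maxIter = 500L) {
  if (nSites(saf1) != nSites(saf2) ||
      !all(start(saf1@sites) == start(saf2@sites)) ||
      !all(as.character(seqnames(saf1@sites)) ==
             as.character(seqnames(saf2@sites))))
    stop("site lists differ between the two SAF matrices")
  P1 <- exp(saf1@saf); P2 <- exp(saf2@saf)
  K1 <- ncol(P1); K2 <- ncol(P2); nS <- nrow(P1)
  M <- matrix(1 / (K1 * K2), K1, K2)
  trace <- numeric(0); llPrev <- -Inf
  for (it in seq_len(maxIter)) {
    A <- P1 %*% M                     # sites x K2
    d <- rowSums(A * P2)
    ll <- sum(log(pmax(d, 1e-300)))
    trace <- c(trace, ll)
    M <- M * (t(P1 / d) %*% P2) / nS
    M <- pmax(M, 0)
    M <- M / sum(M)
    if (is.finite(llPrev) && ll - llPrev < tol) break
    llPrev <- ll
  }
  out <- new("Joint2DSFS", counts = M * nS, nChrom1 = saf1@nChrom,
             nChrom2 = saf2@nChrom, logLik = trace[length(trace)],
             nIter = length(trace))
  attr(out, "trace") <- trace
  out
}

# posterior mean minor-allele frequencies per site under the 2D-SFS prior
posteriorPairFreqs <- function(saf1, saf2, sfs2d) {
  P1 <- exp(saf1@saf); P2 <- exp(saf2@saf)
  M <- sfsCounts(sfs2d) / sum(sfsCounts(sfs2d))
  j1 <- 0:saf1@nChrom; j2 <- 0:saf2@nChrom
  A <- P1 %*% M
  d <- rowSums(A * P2)
  e1 <- rowSums(((P1 * rep(j1, each = nrow(P1))) %*% M) * P2) / d
  e2 <- rowSums((P1 %*% (M * rep(j2, each = length(j1)))) * P2) / d
  data.frame(p1 = e1 / saf1@nChrom, p2 = e2 / saf2@nChrom)
}

#' Hudson/Bhatia per-site Fst components
#'
#' For per-site allele frequencies p1, p2 with chromosome sample sizes
#' n1, n2:
#' \deqn{\alpha = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
#'   \frac{p_2(1-p_2)}{n_2-1}, \quad
#'   \beta = p_1(1-p_2) + p_2(1-p_1)}
#' Negative \eqn{\alpha} is expected at undifferentiated sites and is
#' retained. Windowed and genome-wide Fst are ratios of sums.
#'
#' @param p1,p2 per-site allele frequencies of a shared allele.
#' @param n1,n2 chromosome sample sizes (>= 2).
#' @param sites optional GRanges (or data.frame chrom/pos) carried along.
#' @return data.frame(chrom, pos, alpha, beta) (chrom/pos NA when no
#'   sites are supplied).
#' @export
fstComponents <- function(p1, p2, n1, n2, sites = NULL) {
  if (n1 < 2 || n2 < 2) stop("chromosome sample sizes must be >= 2")
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  if (is.null(sites)) {
    chrom <- rep(NA_character_, length(p1)); pos <- rep(NA_integer_, length(p1))
  } else if (is(sites, "GRanges")) {
    chrom <- as.character(seqnames(sites)); pos <- start(sites)
  } else {
    chrom <- sites$chrom; pos <- sites$pos
  }
  data.frame(chrom = chrom, pos = pos, alpha = alpha, beta = beta)
}

#' Fst components from the genotype-likelihood path
#'
#' Computes SAFs for the two populations, the joint 2D SFS, posterior
#' mean frequencies under that prior, and the Hudson/Bhatia components.
#'
#' @param gl a [GLMatrix] covering both populations.
#' @param inds1,inds2 sample ids or indices of the two populations.
#' @param tol,maxIter passed to [jointSfs()].
#' @return list(components, sfs2d, saf1, saf2).
#' @export
fstFromGL <- function(gl, inds1, inds2, tol = 1e-6, maxIter = 500L) {
  saf1 <- safLikelihoods(gl, inds1)
  saf2 <- safLikelihoods(gl, inds2)
  sfs2d <- jointSfs(saf1, saf2, tol = tol, maxIter = maxIter)
  pf <- posteriorPairFreqs(saf1, saf2, sfs2d)
  comp <- fstComponents(pf$p1, pf$p2, saf1@nChrom, saf2@nChrom,
                        sites = glSites(gl))
  list(components = comp, sfs2d = sfs2d, saf1 = saf1, saf2 = saf2)
}

#' Fst components from called or true genotypes
#'
#' Sample allele frequencies from two genotype matrices (individuals x
#' sites, 0/1/2 alternate-allele counts, NA missing), then
#' Hudson/Bhatia components with per-site chromosome counts.
#'
#' @param G1,G2 genotype matrices over the same sites.
#' @param sites optional GRanges or data.frame(chrom, pos).
#' @return data.frame(chrom, pos, alpha, beta).
#' @export
fstFromGenotypes <- function(G1, G2, sites = NULL) {
  n1 <- 2 * colSums(!is.na(G1)); n2 <- 2 * colSums(!is.na(G2))
  ok <- n1 >= 2 & n2 >= 2
  p1 <- colSums(G1, na.rm = TRUE) / pmax(n1, 1)
  p2 <- colSums(G2, na.rm = TRUE) / pmax(n2, 1)
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
    p2 * (1 - p2) / pmax(n2 - 1, 1)
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  alpha[!ok] <- NA; beta[!ok] <- NA
  if (is.null(sites)) {
    chrom <- rep(NA_character_, ncol(G1)); pos <- seq_len(ncol(G1))
  } else if (is(sites, "GRanges")) {
    chrom <- as.character(seqnames(sites)); pos <- start(sites)
  } else {
    chrom <- sites$chrom; pos <- sites$pos
  }
  data.frame(chrom = chrom, pos = pos, alpha = alpha, beta = beta)
}

#' Windowed Fst as a ratio of sums
#'
#' Window Fst = sum(alpha)/sum(beta) over sites in 0-based half-open
#' windows advancing by \code{stepBp}; windows with zero total beta are
#' reported missing.
#'
#' @param components data.frame(chrom, pos, alpha, beta).
#' @param windowBp,stepBp window size and step in bp.
#' @param chromLengths optional named chromosome lengths.
#' @return data.frame(chrom, start, end, n_sites, fst).
#' @export
windowedFst <- function(components, windowBp = 10000, stepBp = 5000,
                        chromLengths = NULL) {
  components <- components[!is.na(components$alpha), ]
  out <- list()
  for (chr in unique(components$chrom)) {
    d <- components[components$chrom == chr, ]
    len <- if (!is.null(chromLengths) && chr %in% names(chromLengths))
      chromLengths[[chr]] else max(d$pos)
    w <- slidingWindows0(len, windowBp, stepBp)
    res <- lapply(seq_len(nrow(w)), function(i) {
      inWin <- d$pos - 1L >= w$start[i] & d$pos - 1L < w$end[i]
      sa <- sum(d$alpha[inWin]); sb <- sum(d$beta[inWin])
      data.frame(chrom = chr, start = w$start[i], end = w$end[i],
                 n_sites = sum(inWin),
                 fst = if (sb > 0) sa / sb else NA_real_)
    })
    out[[chr]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide Fst
#'
#' Ratio of sums over all retained sites, plus the unweighted mean of
#' window Fst for comparison when windows are supplied.
#'
#' @param components data.frame(chrom, pos, alpha, beta).
#' @param windows optional output of [windowedFst()].
#' @return list(fst = ratio of sums, meanWindowFst, n_sites).
#' @export
genomewideFst <- function(components, windows = NULL) {
  ok <- !is.na(components$alpha)
  list(fst = sum(components$alpha[ok]) / sum(components$beta[ok]),
       meanWindowFst = if (!is.null(windows))
         mean(windows$fst, na.rm = TRUE) else NA_real_,
       n_sites = sum(ok))
}

#' Designate outlier windows from the mode of the Fst distribution
#'
#' The distance d between the smallest window Fst and the modal window
#' Fst sets the threshold: windows with Fst more than 3d above the mode
#' (the right-hand side of the distribution) are flagged. The mode is
#' estimated deterministically by a Gaussian kernel density (Silverman
#' bandwidth) on a 512-point grid over [min, max].
#'
#' @param windows data.frame with an \code{fst} column (NA windows are
#'   ignored for the threshold and never flagged).
#' @param multiplier the distance multiplier (default 3).
#' @param minWindows minimum windows for a meaningful mode.
#' @return the input with columns \code{is_outlier}, and attributes
#'   \code{mode}, \code{threshold}.
#' @export
designateOutliers <- function(windows, multiplier = 3, minWindows = 30L) {
  x <- windows$fst[!is.na(windows$fst)]
  if (length(x) < minWindows)
    stop("need at least ", minWindows,
         " windows for a meaningful mode (see minWindows)")
  if (diff(range(x)) == 0) {
    warning("all window Fst values equal; no outliers designated")
    windows$is_outlier <- FALSE
    attr(windows, "mode") <- x[1]
    attr(windows, "threshold") <- NA_real_
    return(windows)
  }
  dens <- stats::density(x, bw = "nrd0", n = 512L,
                         from = min(x), to = max(x))
  mode <- dens$x[which.max(dens$y)]
  d <- mode - min(x)
  threshold <- mode + multiplier * d
  windows$is_outlier <- !is.na(windows$fst) & windows$fst > threshold
  if (d == 0) {
    warning("modal Fst equals the minimum; no outliers designated")
    windows$is_outlier <- FALSE
  }
  attr(windows, "mode") <- mode
  attr(windows, "threshold") <- threshold
  windows
}

#' Intersect outlier windows with a gene annotation
#'
#' Reports every gene whose span overlaps any outlier window by at least
#' 1 bp, with the peak Fst among overlapping outlier windows, sorted
#' descending. Window coordinates are 0-based half-open; GFF3 genes are
#' 1-based inclusive and converted internally.
#'
#' @param windows output of [designateOutliers()] (only rows with
#'   \code{is_outlier} are used).
#' @param annotation a GFF3 path or a GRanges of features (rows with
#'   \code{type == "gene"} are used; all rows if no type column).
#' @return data.frame(gene_id, chrom, start, end, peak_fst, n_windows).
#' @export
intersectGenes <- function(windows, annotation) {
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  genes <- annotation
  if (!is.null(mcols(genes)$type))
    genes <- genes[mcols(genes)$type == "gene"]
  out <- windows[windows$is_outlier, , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      peak_fst = numeric(), n_windows = integer()))
  winGr <- GRanges(out$chrom, IRanges(out$start + 1L, out$end))
  hits <- findOverlaps(genes, winGr, minoverlap = 1L)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      peak_fst = numeric(), n_windows = integer()))
  ids <- mcols(genes)$ID %||% mcols(genes)$Name %||%
    as.character(seq_along(genes))
  df <- data.frame(gene = S4Vectors::queryHits(hits),
                   fst = out$fst[S4Vectors::subjectHits(hits)])
  agg <- stats::aggregate(fst ~ gene, df,
                          function(v) c(max(v), length(v)))
  g <- agg$gene
  res <- data.frame(gene_id = as.character(ids[g]),
                    chrom = as.character(seqnames(genes))[g],
                    start = start(genes)[g], end = end(genes)[g],
                    peak_fst = agg$fst[, 1], n_windows = agg$fst[, 2])
  res <- res[order(-res$peak_fst), ]
  rownames(res) <- NULL
  res
}
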