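#' Great-circle (geodesic) distance in kilometres
#'
#' WGS84 geodesic distance via \code{geosphere::distGeo}, vectorized
#' over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree coordinates.
#' @return distance(s) in km.
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Pairwise geographic distance matrix
#'
#' @param lat,lon coordinates, one per label.
#' @param labels names for the matrix dimensions.
#' @return symmetric km matrix with zero diagonal.
#' @export
geoDistanceMatrix <- function(lat, lon, labels = NULL) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n))
    m[i, ] <- greatCircleKm(lat[i], lon[i], lat, lon)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Mantel test between a genetic and a geographic matrix
#'
#' Pearson correlation of the vectorized off-diagonal triangles with a
#' joint row/column permutation null (vegan's implementation);
#' one-sided greater by default (positive-association alternative),
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})}.
#'
#' @param genetic,geographic symmetric matrices with matching labels.
#' @param nPerm number of permutations.
#' @param seed seed for the permutation stream.
#' @return list(r, p, nPerm).
#' @export
mantelTest <- function(genetic, geographic, nPerm = 999L, seed = 1L) {
  stopifnot(identical(dim(genetic), dim(geographic)))
  if (nrow(genetic) < 4L) stop("need at least 4 labels")
  v1 <- genetic[lower.tri(genetic)]
  v2 <- geographic[lower.tri(geographic)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a distance triangle; Mantel r undefined")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                       method = "pearson", permutations = nPerm)
  list(r = unname(fit$statistic), p = fit$signif, nPerm = nPerm)
}

#' Mantel correlogram over distance classes
#'
#' Per distance class, the standardized Mantel statistic between the
#' genetic matrix and the class-membership indicator matrix, with
#' permutation p-values under progressive Holm correction (vegan's
#' \code{mantel.correlog}). Classes with fewer than 10 member pairs are
#' flagged low-support.
#'
#' @param genetic symmetric genetic distance matrix.
#' @param geographic symmetric km matrix.
#' @param breaks class break points in km (strictly increasing,
#'   covering the observed distances), or NULL for Sturges classes.
#' @param nPerm permutations per class.
#' @param seed permutation seed.
#' @return data.frame(class_lo, class_hi, class_mid, n_pairs, r, p,
#'   p_corrected, low_support).
#' @export
mantelCorrelogram <- function(genetic, geographic, breaks = NULL,
                              nPerm = 999L, seed = 1L) {
  stopifnot(identical(dim(genetic), dim(geographic)))
  if (!is.null(breaks)) {
    if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
    if (max(geographic) > max(breaks) || min(geographic[upper.tri(geographic)]) < min(breaks))
      stop("breaks must cover the observed distances")
  }
  set.seed(seed)
  fit <- vegan::mantel.correlog(
    D.eco = stats::as.dist(genetic), D.geo = stats::as.dist(geographic),
    break.pts = breaks, cutoff = FALSE, nperm = nPerm, mult = "holm",
    progressive = TRUE)
  m <- as.data.frame(fit$mantel.res)
  colnames(m) <- c("class_mid", "n_dist", "r", "p", "p_corrected")
  lo <- fit$break.pts[-length(fit$break.pts)]
  hi <- fit$break.pts[-1]
  geo <- geographic[upper.tri(geographic)]
  nPairs <- vapply(seq_along(lo), function(i)
    sum(geo > lo[i] & geo <= hi[i] |
          (i == 1L & geo >= lo[i] & geo <= hi[i])), 0)
  out <- data.frame(class_lo = lo, class_hi = hi,
                    class_mid = m$class_mid, n_pairs = nPairs,
                    r = m$r, p = m$p, p_corrected = m$p_corrected,
                    low_support = nPairs < 10)
  if (any(out$n_pairs == 0))
    warning("empty distance class(es); entries reported missing")
  out
}

#' Between-site Fst matrix for isolation by distance
#'
#' Applies the genotype-path Hudson/Bhatia estimator to every pair of
#' geographic sampling sites with at least \code{minN} individuals
#' each; small-sample pairs are excluded (NA). The diagonal is 0 by
#' construction.
#'
#' @param G individuals x sites genotype matrix ({0,1,2}, NA missing).
#' @param siteLabels per-individual geographic site labels.
#' @param minN minimum individuals per site.
#' @return list(fst = symmetric matrix over retained sites,
#'   n = per-site sample sizes).
#' @export
siteFstMatrix <- function(G, siteLabels, minN = 4L) {
  counts <- table(siteLabels)
  keep <- names(counts)[counts >= minN]
  m <- matrix(NA_real_, length(keep), length(keep),
              dimnames = list(keep, keep))
  diag(m) <- 0
  if (length(keep) >= 2L) {
    for (i in seq_along(keep)[-length(keep)]) for (j in (i + 1L):length(keep)) {
      comp <- fstFromGenotypes(G[siteLabels == keep[i], , drop = FALSE],
                               G[siteLabels == keep[j], , drop = FALSE])
      f <- genomewideFst(comp)$fst
      m[i, j] <- m[j, i] <- f
    }
  }
  list(fst = m, n = as.integer(counts[keep]))
}
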