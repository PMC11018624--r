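#' Hard-call genotypes from genotype likelihoods
#'
#' Posterior argmax under an HWE prior at the supplied (or ML) allele
#' frequency; calls with posterior below \code{minPosterior} and missing
#' individual-sites are NA.
#'
#' @param gl a [GLMatrix].
#' @param freqs per-site minor-allele frequencies (default ML).
#' @param minPosterior minimum posterior probability to call.
#' @return individuals x sites matrix in {0, 1, 2, NA} counting the
#'   minor allele.
#' @export
callGenotypes <- function(gl, freqs = NULL, minPosterior = 0.95) {
  a <- glArray(gl)
  if (is.null(freqs)) freqs <- estimateMafEM(a)$freq
  L <- linearGL(a)
  h <- cbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2)
  post <- array(0, dim = dim(L))
  for (k in 1:3) post[, , k] <- L[, , k] * h[, k]
  tot <- post[, , 1] + post[, , 2] + post[, , 3]
  for (k in 1:3) post[, , k] <- post[, , k] / pmax(tot, 1e-300)
  g0 <- post[, , 1]; g1 <- post[, , 2]; g2 <- post[, , 3]
  pmax3 <- pmax(g0, g1, g2)
  call <- ifelse(g1 > g0 & g1 >= g2, 1L, ifelse(g2 > g0 & g2 > g1, 2L, 0L))
  call[pmax3 < minPosterior | glMissing(a)] <- NA_integer_
  t(call)
}

#' KING-robust pairwise kinship
#'
#' For each pair, over sites non-missing in both individuals:
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} +
#'   N_{Aa}^{(j)}}}
#' (shared heterozygotes minus twice the opposite homozygotes, over the
#' summed heterozygote counts). Self-pairs give exactly 0.5; unrelated
#' individuals from a structured sample can be strongly negative. Sites
#' within \code{mask} intervals (e.g. inversion polymorphisms, which
#' inflate apparent relatedness) are excluded first.
#'
#' @param G individuals x sites genotype matrix in {0, 1, 2, NA}.
#' @param sites optional GRanges of the site coordinates (required when
#'   \code{mask} is given).
#' @param mask GRanges of intervals to exclude.
#' @param ids sample identifiers (default rownames).
#' @return data.frame(id1, id2, n_sites, n_both_het, n_opposite_hom,
#'   n_het_1, n_het_2, phi) for all unordered pairs, with the full
#'   symmetric phi matrix as attribute \code{phiMatrix}.
#' @export
kingKinship <- function(G, sites = NULL, mask = NULL, ids = rownames(G)) {
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(G)))
  if (!is.null(mask)) {
    if (is.null(sites)) stop("mask requires site coordinates")
    drop <- IRanges::overlapsAny(sites, mask)
    G <- G[, !drop, drop = FALSE]
  }
  obs <- !is.na(G)
  het <- G == 1L & obs
  hom0 <- G == 0L & obs
  hom2 <- G == 2L & obs
  storage.mode(het) <- "double"
  storage.mode(hom0) <- "double"
  storage.mode(hom2) <- "double"
  storage.mode(obs) <- "double"
  bothHet <- tcrossprod(het)
  oppHom <- tcrossprod(hom0, hom2)
  oppHom <- oppHom + t(oppHom)
  hetI <- het %*% t(obs)                # hets of i at sites seen in j
  nShared <- tcrossprod(obs)
  denom <- hetI + t(hetI)
  phi <- (bothHet - 2 * oppHom) / denom
  phi[denom == 0 | nShared == 0] <- NA_real_
  dimnames(phi) <- list(ids, ids)
  pair <- which(upper.tri(phi), arr.ind = TRUE)
  res <- data.frame(
    id1 = ids[pair[, 1]], id2 = ids[pair[, 2]],
    n_sites = nShared[pair], n_both_het = bothHet[pair],
    n_opposite_hom = oppHom[pair], n_het_1 = hetI[pair],
    n_het_2 = t(hetI)[pair], phi = phi[pair])
  attr(res, "phiMatrix") <- phi
  res
}

#' Classify pairwise relationships from KING kinship
#'
#' KING's powers-of-two bins: duplicate/monozygotic at phi > 0.354,
#' first degree in (0.177, 0.354], second degree in (0.0884, 0.177],
#' otherwise unrelated. First-degree pairs with at least one opposite
#' homozygote are labelled full sibs (parent-offspring pairs show
#' essentially none).
#'
#' @param kinship data.frame from [kingKinship()].
#' @return the input with a \code{relationship} column.
#' @export
classifyRelationships <- function(kinship) {
  phi <- kinship$phi
  rel <- rep("unrelated", nrow(kinship))
  rel[!is.na(phi) & phi > 0.0884] <- "second_degree"
  first <- !is.na(phi) & phi > 0.177
  rel[first & kinship$n_opposite_hom > 0] <- "full_sib"
  rel[first & kinship$n_opposite_hom == 0] <- "parent_offspring"
  rel[!is.na(phi) & phi > 0.354] <- "duplicate"
  rel[is.na(phi)] <- NA_character_
  kinship$relationship <- rel
  kinship
}
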