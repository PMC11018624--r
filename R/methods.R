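#' Accessors for poplik objects
#'
#' Small accessor family: \code{glSites()} returns the site GRanges,
#' \code{glSamples()} the sample ids, \code{glArray()} the raw log-GL
#' array, \code{nSites()}/\code{nInd()} the dimensions, and
#' \code{sfsCounts()} the spectrum vector or matrix.
#'
#' @param x a poplik object.
#' @return the requested component.
#' @name accessors
#' @aliases glSites glSamples glArray nSites nInd sfsCounts
NULL

#' @rdname accessors
#' @export
setGeneric("glSites", function(x) standardGeneric("glSites"))
#' @rdname accessors
#' @export
setGeneric("glSamples", function(x) standardGeneric("glSamples"))
#' @rdname accessors
#' @export
setGeneric("glArray", function(x) standardGeneric("glArray"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname accessors
setMethod("glSites", "GLMatrix", function(x) x@sites)
#' @rdname accessors
setMethod("glSites", "SAFMatrix", function(x) x@sites)
#' @rdname accessors
setMethod("glSites", "ReadPileup", function(x) x@sites)
#' @rdname accessors
setMethod("glSamples", "GLMatrix", function(x) x@samples)
#' @rdname accessors
setMethod("glSamples", "ReadPileup", function(x) x@samples)
#' @rdname accessors
setMethod("glArray", "GLMatrix", function(x) x@gl)
#' @rdname accessors
setMethod("nSites", "GLMatrix", function(x) length(x@sites))
#' @rdname accessors
setMethod("nSites", "SAFMatrix", function(x) length(x@sites))
#' @rdname accessors
setMethod("nSites", "ReadPileup", function(x) length(x@sites))
#' @rdname accessors
setMethod("nInd", "GLMatrix", function(x) length(x@samples))
#' @rdname accessors
setMethod("nInd", "ReadPileup", function(x) length(x@samples))
#' @rdname accessors
setMethod("sfsCounts", "SFSpectrum", function(x) x@counts)
#' @rdname accessors
setMethod("sfsCounts", "Joint2DSFS", function(x) x@counts)

setMethod("show", "GLMatrix", function(object) {
  cat(sprintf("GLMatrix: %d sites x %d individuals\n",
              nSites(object), nInd(object)))
  if (nSites(object)) {
    miss <- mean(apply(object@gl, c(1, 2), function(v) all(v == 0)))
    cat(sprintf("  chroms: %s\n  missing individual-sites: %.1f%%\n",
                paste(unique(as.character(seqnames(object@sites))),
                      collapse = ", "), 100 * miss))
  }
})

setMethod("show", "ReadPileup", function(object) {
  cat(sprintf("ReadPileup: %d sites x %d individuals, base quality Q%g\n",
              nSites(object), nInd(object), object@baseQual))
  if (nSites(object))
    cat(sprintf("  mean depth: %.2fx\n",
                mean(object@nRef + object@nAlt + object@nOther)))
})

setMethod("show", "SAFMatrix", function(object) {
  cat(sprintf("SAFMatrix: %d sites, 2N = %d chromosomes\n",
              nSites(object), object@nChrom))
})

setMethod("show", "SFSpectrum", function(object) {
  cat(sprintf("%s SFS, 2N = %d, %d classes, %.0f sites (logLik %.2f)\n",
              if (object@folded) "folded" else "unfolded", object@nChrom,
              length(object@counts), sum(object@counts), object@logLik))
})

setMethod("show", "Joint2DSFS", function(object) {
  cat(sprintf("joint 2D SFS: (%d+1) x (%d+1) classes, %.0f sites\n",
              object@nChrom1, object@nChrom2, sum(object@counts)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d pops x %d diploids, Fst target %.3g",
    " (species level %.3g)\n  %d chrom(s) x %g bp, SNP density %g,",
    " coverage %.1fx, Q%g, seed %d\n"),
    object@nPops, object@nDipPerPop[1], object@targetFst,
    object@speciesFst, length(object@chroms), object@seqLength[1],
    object@mutDensity, object@meanCoverage, object@baseError, object@seed))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(paste0(
    "SimulationTruth: %d individuals x %d SNPs, %d pops, %d sib pair(s),",
    " %d sweep window(s)\n"),
    nrow(object@genotypes), length(object@sites), ncol(object@popFreqs),
    nrow(object@pedigree) %/% 2L, length(object@sweepWindows)))
})

setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf("AdmixtureFit: K = %d, %d individuals, logLik %.2f (%d iter)\n",
              object@K, nrow(object@Q), object@logLik, length(object@trace)))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s strand, %s): %d exon(s), CDS %d bp\n",
              object@geneId, object@strand, object@chrom,
              length(object@exons), sum(width(object@cds))))
})
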