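#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Simulation configuration for the synthetic study design
#'
#' Parameters of the synthetic low-coverage population-genomic study:
#' a set of populations (analysis strata, e.g. species x ecoregion) with
#' Balding-Nichols differentiation at a target Fst, optional hierarchical
#' species-level differentiation, localized selective sweeps, one
#' high-differentiation "inversion" block, full-sib pairs, and
#' Poisson-distributed low-coverage reads with phred-scaled base errors.
#'
#' @slot nPops number of populations (analysis strata).
#' @slot nDipPerPop diploid individuals per population (recycled to nPops).
#' @slot popLabels data.frame with columns \code{species} and
#'   \code{ecoregion}, one row per population.
#' @slot nSitesPerPop number of geographic sampling sites per population;
#'   individuals are assigned round-robin.
#' @slot targetFst Balding-Nichols F between populations of the same
#'   species (drift from the species ancestral frequency), in [0, 1).
#' @slot speciesFst Balding-Nichols F between species-level ancestors and
#'   the global ancestral frequency; 0 collapses the hierarchy.
#' @slot chroms chromosome names.
#' @slot seqLength chromosome length in bp (recycled to chroms).
#' @slot mutDensity expected SNPs per bp.
#' @slot freqRange support of the ancestral-frequency distribution
#'   (density proportional to 1/f, neutral-SFS-like).
#' @slot sweepLoci data.frame(chrom, center, width, strength, pop) of
#'   selective-sweep loci; \code{pop} NA sweeps all populations, an
#'   integer restricts the sweep to that population.
#' @slot inversionBlock data.frame(chrom, start, end, extraFst) or NULL;
#'   within the block the Balding-Nichols F is increased by extraFst.
#' @slot nSibPairs number of full-sib pairs appended as extra individuals.
#' @slot meanCoverage mean per-individual read depth (fold).
#' @slot baseError phred-scaled base error of simulated reads.
#' @slot seed integer random seed; a fixed seed gives identical output.
#' @export
setClass("SimConfig", representation(
  nPops = "integer", nDipPerPop = "integer", popLabels = "data.frame",
  nSitesPerPop = "integer", targetFst = "numeric", speciesFst = "numeric",
  chroms = "character", seqLength = "numeric", mutDensity = "numeric",
  freqRange = "numeric", sweepLoci = "dfOrNULL", inversionBlock = "dfOrNULL",
  nSibPairs = "integer", meanCoverage = "numeric", baseError = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@targetFst < 0 || object@targetFst >= 1)
    msg <- c(msg, "targetFst must be in [0, 1)")
  if (object@speciesFst < 0 || object@speciesFst >= 1)
    msg <- c(msg, "speciesFst must be in [0, 1)")
  if (!is.null(object@sweepLoci) && nrow(object@sweepLoci) &&
      any(object@sweepLoci$strength < 0 | object@sweepLoci$strength > 1))
    msg <- c(msg, "sweep strength must be in [0, 1]")
  if (any(object@meanCoverage < 0)) msg <- c(msg, "meanCoverage must be >= 0")
  if (nrow(object@popLabels) != object@nPops)
    msg <- c(msg, "popLabels must have one row per population")
  if (length(object@freqRange) != 2L || object@freqRange[1] <= 0 ||
      object@freqRange[2] >= 1 || diff(object@freqRange) <= 0)
    msg <- c(msg, "freqRange must be an increasing pair inside (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Everything the generator knows: ancestral and per-population allele
#' frequencies, per-individual phased haplotypes and genotypes, the
#' pedigree of appended sib pairs, realized sweep windows, and sample
#' metadata (species, ecoregion, geographic site and coordinates).
#' Genotypes count copies of the alternate allele and always equal the
#' sum of the two haplotype rows.
#'
#' @slot config the [SimConfig] that produced the object.
#' @slot sites GRanges of SNPs with mcols \code{ref} and \code{alt}.
#' @slot ancestralFreqs per-SNP ancestral alternate-allele frequency.
#' @slot popFreqs SNPs x populations matrix of alternate-allele frequencies.
#' @slot genotypes individuals x SNPs matrix in {0,1,2}.
#' @slot hapA,hapB individuals x SNPs binary haplotype matrices.
#' @slot pedigree data.frame(offspring, parent1, parent2) of sample ids.
#' @slot sweepWindows GRanges of realized sweep windows.
#' @slot meta data.frame(sample_id, species, ecoregion, site, lat, lon, pop).
#' @export
setClass("SimulationTruth", representation(
  config = "SimConfig", sites = "GRanges", ancestralFreqs = "numeric",
  popFreqs = "matrix", genotypes = "matrix", hapA = "matrix", hapB = "matrix",
  pedigree = "data.frame", sweepWindows = "GRanges", meta = "data.frame"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  if (any(object@popFreqs < 0 | object@popFreqs > 1))
    msg <- c(msg, "popFreqs must lie in [0, 1]")
  if (!identical(dim(object@hapA), dim(object@genotypes)))
    msg <- c(msg, "haplotype and genotype dimensions differ")
  if (length(object@ancestralFreqs) != length(object@sites))
    msg <- c(msg, "one ancestral frequency per site required")
  if (nrow(object@genotypes) &&
      !all(object@genotypes == object@hapA + object@hapB))
    msg <- c(msg, "genotypes must equal hapA + hapB at every SNP")
  if (length(msg)) msg else TRUE
})

#' Per-site read pileup counts
#'
#' Diallelic read evidence reduced to per-site, per-individual counts of
#' reads supporting the reference allele, the alternate allele, and any
#' other base, with a single phred-scaled base quality (reads are
#' simulated with a constant error rate; the per-read API
#' [genotypeLikelihoods()] accepts arbitrary qualities).
#'
#' @slot sites GRanges of sites with mcols \code{ref} and \code{alt}.
#' @slot nRef,nAlt,nOther sites x individuals integer count matrices.
#' @slot baseQual phred-scaled quality attached to every read.
#' @slot samples sample identifiers.
#' @export
setClass("ReadPileup", representation(
  sites = "GRanges", nRef = "matrix", nAlt = "matrix", nOther = "matrix",
  baseQual = "numeric", samples = "character"))

setValidity("ReadPileup", function(object) {
  msg <- character()
  if (!identical(dim(object@nRef), dim(object@nAlt)) ||
      !identical(dim(object@nRef), dim(object@nOther)))
    msg <- c(msg, "count matrices must share dimensions")
  if (nrow(object@nRef) != length(object@sites))
    msg <- c(msg, "one count row per site required")
  if (ncol(object@nRef) != length(object@samples))
    msg <- c(msg, "one count column per sample required")
  if (object@baseQual < 0) msg <- c(msg, "baseQual must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Genotype-likelihood matrix
#'
#' The pipeline's central currency: per-site, per-individual likelihoods
#' of the three diallelic genotypes (major/major, major/minor,
#' minor/minor), stored log-scaled and normalized so each individual's
#' maximum at a site is exactly 0. A missing individual-site is the flat
#' triplet (0, 0, 0), which contributes only a constant to likelihoods.
#'
#' @slot sites GRanges sorted by (chrom, pos) with mcols \code{major} and
#'   \code{minor} allele characters.
#' @slot gl numeric array sites x individuals x 3 of normalized log GLs.
#' @slot samples sample identifiers.
#' @export
setClass("GLMatrix", representation(
  sites = "GRanges", gl = "array", samples = "character"))

setValidity("GLMatrix", function(object) {
  msg <- character()
  d <- dim(object@gl)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "gl must be a sites x individuals x 3 array")
  else {
    if (d[1] != length(object@sites)) msg <- c(msg, "gl rows must match sites")
    if (d[2] != length(object@samples))
      msg <- c(msg, "gl columns must match samples")
    if (d[1] && d[2]) {
      mx <- apply(object@gl, c(1, 2), max)
      if (any(!is.finite(object@gl)) || max(abs(mx)) > 1e-8)
        msg <- c(msg, "per-individual maximum log GL must be 0 and finite")
    }
  }
  if (length(object@sites) > 1L && is.unsorted(order(
        as.integer(factor(as.character(seqnames(object@sites)))))))
    NULL # ordering enforced by the constructor; see sortGLMatrix
  if (length(msg)) msg else TRUE
})

#' Site allele-frequency likelihoods
#'
#' Per-site likelihood of each possible population minor-allele count
#' j = 0..2N (N diploids), marginalizing individual genotypes under
#' hypergeometric allele assignment; log-scaled and max-normalized.
#'
#' @slot sites GRanges of sites.
#' @slot saf sites x (2N+1) matrix of normalized log likelihoods.
#' @slot nChrom 2N, the number of sampled chromosomes.
#' @export
setClass("SAFMatrix", representation(
  sites = "GRanges", saf = "matrix", nChrom = "integer"))

setValidity("SAFMatrix", function(object) {
  msg <- character()
  if (ncol(object@saf) != object@nChrom + 1L)
    msg <- c(msg, "saf must have 2N + 1 columns")
  if (nrow(object@saf) != length(object@sites))
    msg <- c(msg, "one saf row per site required")
  if (nrow(object@saf) && any(!is.finite(object@saf) & object@saf > -Inf))
    msg <- c(msg, "saf values must be finite or -Inf")
  if (length(msg)) msg else TRUE
})

#' Site-frequency spectrum
#'
#' Expected numbers of sites per allele-count class, estimated by EM from
#' a [SAFMatrix]. Folded spectra have N+1 classes (minor-allele counts).
#'
#' @slot counts expected site counts per class.
#' @slot folded logical flag.
#' @slot nChrom 2N.
#' @slot logLik final EM log-likelihood.
#' @slot nIter EM iterations used.
#' @export
setClass("SFSpectrum", representation(
  counts = "numeric", folded = "logical", nChrom = "integer",
  logLik = "numeric", nIter = "integer"))

setValidity("SFSpectrum", function(object) {
  msg <- character()
  want <- if (object@folded) object@nChrom / 2L + 1L else object@nChrom + 1L
  if (length(object@counts) != want)
    msg <- c(msg, "counts length inconsistent with folding and 2N")
  if (any(object@counts < -1e-9)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Joint two-population site-frequency spectrum
#'
#' Expected site counts over pairs (j1, j2) of minor-allele counts in two
#' populations sharing a site list; the prior for Fst estimation.
#'
#' @slot counts (2N1+1) x (2N2+1) matrix of expected site counts.
#' @slot nChrom1,nChrom2 chromosome counts of the two populations.
#' @slot logLik final EM log-likelihood.
#' @slot nIter EM iterations used.
#' @export
setClass("Joint2DSFS", representation(
  counts = "matrix", nChrom1 = "integer", nChrom2 = "integer",
  logLik = "numeric", nIter = "integer"))

setValidity("Joint2DSFS", function(object) {
  msg <- character()
  if (!identical(dim(object@counts),
                 c(object@nChrom1 + 1L, object@nChrom2 + 1L)))
    msg <- c(msg, "counts dimensions inconsistent with chromosome counts")
  if (any(object@counts < -1e-9)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Admixture-proportion fit
#'
#' Maximum-likelihood admixture proportions Q and cluster allele
#' frequencies F under the genotype-likelihood admixture model, fitted
#' by EM (best of several seeded starts).
#'
#' @slot K number of clusters.
#' @slot Q individuals x K proportions (rows sum to 1).
#' @slot F sites x K cluster minor-allele frequencies.
#' @slot logLik final log-likelihood.
#' @slot trace per-iteration log-likelihoods of the winning start.
#' @export
setClass("AdmixtureFit", representation(
  K = "integer", Q = "matrix", F = "matrix", logLik = "numeric",
  trace = "numeric"))

setValidity("AdmixtureFit", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K || ncol(object@F) != object@K)
    msg <- c(msg, "Q and F must have K columns")
  if (nrow(object@Q) && max(abs(rowSums(object@Q) - 1)) > 1e-8)
    msg <- c(msg, "Q rows must sum to 1")
  if (any(object@F < -1e-12 | object@F > 1 + 1e-12))
    msg <- c(msg, "F must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Gene model for variant-effect classification
#'
#' A single-transcript gene model: strand-aware exon, CDS and UTR
#' intervals over a genomic sequence, sufficient to classify SNPs into
#' UTR/intronic/synonymous/missense/intergenic categories.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand "+" or "-".
#' @slot exons,cds,utr5,utr3 IRanges of the respective features
#'   (1-based inclusive genomic coordinates).
#' @slot genome a Biostrings DNAStringSet holding the chromosome sequence.
#' @export
setClass("GeneModel", representation(
  geneId = "character", chrom = "character", strand = "character",
  exons = "IRanges", cds = "IRanges", utr5 = "IRanges", utr3 = "IRanges",
  genome = "DNAStringSet"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(object@cds) && sum(width(object@cds)) %% 3L != 0L)
    msg <- c(msg, "total CDS length must be divisible by 3")
  if (!object@chrom %in% names(object@genome))
    msg <- c(msg, "chrom absent from genome sequence")
  if (length(msg)) msg else TRUE
})
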