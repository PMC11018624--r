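#' Build a simulation configuration
#'
#' Constructs a [SimConfig] describing a synthetic low-coverage study.
#' Defaults emulate the sampling design the package targets: two
#' species-like groups, each sampled across three ecoregions (six
#' analysis strata), differentiated under a hierarchical Balding-Nichols
#' model (strong species-level divergence, weak ecoregion-level
#' divergence), with one selective-sweep locus per species on the X-like
#' chromosome, an elevated-differentiation "inversion" block on 2L, two
#' full-sib pairs, and ~14x Poisson coverage with Q30 base errors.
#'
#' Ancestral allele frequencies are drawn with density proportional to
#' 1/f on \code{freqRange} (a neutral-SFS-like law); the default support
#' [0.001, 0.999] reaches low enough frequencies that binomial sampling
#' of individuals reproduces the neutral 1/j sample spectrum, so neutral
#' simulations give Tajima's D near 0.
#'
#' @param nPops number of populations (analysis strata).
#' @param nDipPerPop diploids per population.
#' @param popLabels data.frame(species, ecoregion), one row per pop;
#'   defaults to two species x three ecoregions when \code{nPops} is 6,
#'   else generic labels.
#' @param nSitesPerPop geographic sampling sites per population.
#' @param targetFst within-species Balding-Nichols F.
#' @param speciesFst species-level Balding-Nichols F (0 = single level).
#' @param chroms,seqLength chromosome names and lengths (bp).
#' @param mutDensity expected SNPs per bp.
#' @param freqRange support of the 1/f ancestral-frequency density.
#' @param sweepLoci data.frame(chrom, center, width, strength, pop) or
#'   NULL. \code{pop = NA} sweeps all populations jointly, a species
#'   name sweeps that species' strata, an index sweeps one population.
#' @param inversionBlock data.frame(chrom, start, end, extraFst) or NULL.
#' @param nSibPairs number of appended full-sib pairs.
#' @param meanCoverage mean read depth per individual (fold).
#' @param baseError phred-scaled base error for simulated reads.
#' @param seed integer seed; identical configs give identical output.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(nPops = 2, nDipPerPop = 10, targetFst = 0.1,
#'                  seqLength = 5e4, seed = 1)
#' cfg
#' @export
simConfig <- function(nPops = 6L, nDipPerPop = 12L, popLabels = NULL,
                      nSitesPerPop = 3L, targetFst = 0.01, speciesFst = 0.1,
                      chroms = c("2L", "3L", "X"), seqLength = 4e5,
                      mutDensity = 0.005, freqRange = c(0.001, 0.999),
                      sweepLoci = NULL, inversionBlock = NULL,
                      nSibPairs = 0L, meanCoverage = 14, baseError = 30,
                      seed = 1L) {
  nPops <- as.integer(nPops)
  ## tolerate YAML-style scalars arriving as strings (e.g. "1.0e5")
  targetFst <- as.numeric(targetFst); speciesFst <- as.numeric(speciesFst)
  seqLength <- as.numeric(seqLength); mutDensity <- as.numeric(mutDensity)
  freqRange <- as.numeric(freqRange); meanCoverage <- as.numeric(meanCoverage)
  baseError <- as.numeric(baseError)
  if (is.null(popLabels)) {
    if (nPops == 6L) {
      popLabels <- data.frame(
        species = rep(c("speciesA", "speciesB"), each = 3L),
        ecoregion = rep(c("CS", "DF", "RF"), 2L))
    } else {
      popLabels <- data.frame(species = "speciesA",
                              ecoregion = paste0("pop", seq_len(nPops)))
    }
  }
  if (length(unique(popLabels$species)) == 1L) speciesFst <- 0
  new("SimConfig", nPops = nPops,
      nDipPerPop = rep(as.integer(nDipPerPop), length.out = nPops),
      popLabels = popLabels, nSitesPerPop = as.integer(nSitesPerPop),
      targetFst = targetFst, speciesFst = speciesFst,
      chroms = chroms, seqLength = rep(seqLength, length.out = length(chroms)),
      mutDensity = mutDensity, freqRange = freqRange,
      sweepLoci = sweepLoci, inversionBlock = inversionBlock,
      nSibPairs = as.integer(nSibPairs), meanCoverage = meanCoverage,
      baseError = baseError, seed = as.integer(seed))
}

#' Default configuration of the synthetic end-to-end study
#'
#' The study design used by [runPipeline()] and the acceptance analyses:
#' two species-like groups x three ecoregions, one sweep locus per
#' species on chromosome X (only that species' strata are swept,
#' emulating a resistance locus under recent selection), a 60-kb
#' elevated-differentiation inversion-like block on 2L, and two full-sib
#' pairs.
#'
#' @param seed integer seed.
#' @return a [SimConfig].
#' @export
defaultStudyConfig <- function(seed = 1L) {
  simConfig(
    nPops = 6L, nDipPerPop = 12L, nSitesPerPop = 3L,
    targetFst = 0.01, speciesFst = 0.10,
    chroms = c("2L", "3L", "X"), seqLength = 4e5, mutDensity = 0.005,
    sweepLoci = data.frame(
      chrom = c("X", "X"), center = c(1e5, 3e5), width = c(4e4, 4e4),
      strength = c(0.8, 0.8), pop = c("speciesA", "speciesB")),
    inversionBlock = data.frame(chrom = "2L", start = 1e5, end = 1.6e5,
                                extraFst = 0.08),
    nSibPairs = 2L, meanCoverage = 14, baseError = 30, seed = seed)
}

# sweep target resolution: NA = every population; a species name = all
# strata of that species; otherwise an exact population index
sweepPops <- function(cfg, pop) {
  if (is.na(pop)) return(seq_len(cfg@nPops))
  if (is.character(pop) && pop %in% cfg@popLabels$species)
    return(which(cfg@popLabels$species == pop))
  as.integer(pop)
}

#' Simulate structured population frequencies, haplotypes and relatives
#'
#' Draws ancestral allele frequencies from a 1/f density on the
#' configured support, per-population frequencies from the
#' Balding-Nichols Beta(f(1-F)/F, (1-f)(1-F)/F) law (hierarchically when
#' \code{speciesFst > 0}; degenerate at F = 0), phased haplotypes and
#' genotypes binomially, then applies configured sweeps to the founder
#' haplotypes and finally appends full-sib pairs by Mendelian
#' transmission from stored parental haplotypes. Within the configured
#' inversion block the population-level F is increased by
#' \code{extraFst}, emulating block-wise elevated differentiation.
#'
#' @param config a [SimConfig].
#' @return a [SimulationTruth].
#' @examples
#' truth <- simulateFrequencies(simConfig(nPops = 2, nDipPerPop = 6,
#'   targetFst = 0.1, seqLength = 2e4, seed = 7))
#' truth
#' @export
simulateFrequencies <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ## site coordinates per chromosome
  sitesList <- lapply(seq_along(config@chroms), function(i) {
    len <- config@seqLength[i]
    n <- stats::rpois(1, len * config@mutDensity)
    sort(sample.int(len, min(n, len)))
  })
  chrom <- rep(config@chroms, lengths(sitesList))
  pos <- unlist(sitesList, use.names = FALSE)
  nSnp <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nSnp, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sites <- GRanges(chrom, IRanges(pos, pos), ref = ref, alt = unname(alt))
  seqlengths(sites) <- stats::setNames(config@seqLength, config@chroms)

  anc <- rInvFreq(nSnp, config@freqRange[1], config@freqRange[2])

  ## hierarchical Balding-Nichols: species ancestors, then populations
  species <- config@popLabels$species
  specFreq <- sapply(unique(species), function(s)
    rBaldingNichols(anc, config@speciesFst))
  if (is.null(dim(specFreq))) specFreq <- matrix(specFreq, ncol = 1)
  colnames(specFreq) <- unique(species)

  Fpop <- rep(config@targetFst, nSnp)
  if (!is.null(config@inversionBlock) && nrow(config@inversionBlock)) {
    for (r in seq_len(nrow(config@inversionBlock))) {
      blk <- config@inversionBlock[r, ]
      inBlk <- chrom == blk$chrom & pos >= blk$start & pos <= blk$end
      Fpop[inBlk] <- pmin(Fpop[inBlk] + blk$extraFst, 0.99)
    }
  }
  popFreqs <- matrix(0, nSnp, config@nPops)
  for (p in seq_len(config@nPops)) {
    base <- specFreq[, species[p]]
    pf <- base
    draw <- Fpop > 0
    if (any(draw)) {
      a <- base[draw] * (1 - Fpop[draw]) / Fpop[draw]
      b <- (1 - base[draw]) * (1 - Fpop[draw]) / Fpop[draw]
      pf[draw] <- stats::rbeta(sum(draw), a, b)
    }
    popFreqs[, p] <- pf
  }

  ## founder haplotypes
  nFounder <- sum(config@nDipPerPop)
  popOf <- rep(seq_len(config@nPops), config@nDipPerPop)
  pMat <- t(popFreqs[, popOf, drop = FALSE])      # founders x snps
  hapA <- matrix(stats::rbinom(nFounder * nSnp, 1L, pMat), nFounder, nSnp)
  hapB <- matrix(stats::rbinom(nFounder * nSnp, 1L, pMat), nFounder, nSnp)

  meta <- data.frame(
    sample_id = sprintf("ind%03d", seq_len(nFounder)),
    species = species[popOf], ecoregion = config@popLabels$ecoregion[popOf],
    pop = popOf, stringsAsFactors = FALSE)

  truth <- new("SimulationTruth", config = config, sites = sites,
               ancestralFreqs = anc, popFreqs = popFreqs,
               genotypes = hapA + hapB, hapA = hapA, hapB = hapB,
               pedigree = data.frame(offspring = character(),
                                     parent1 = character(),
                                     parent2 = character()),
               sweepWindows = GRanges(), meta = meta)

  ## sweeps on founders (before sib transmission, so pedigrees stay
  ## Mendelian-consistent)
  if (!is.null(config@sweepLoci) && nrow(config@sweepLoci)) {
    for (r in seq_len(nrow(config@sweepLoci))) {
      sw <- config@sweepLoci[r, ]
      truth <- applySweep(truth, chrom = sw$chrom, center = sw$center,
                          width = sw$width, strength = sw$strength,
                          pops = sweepPops(config, sw$pop))
    }
  }

  ## full-sib pairs appended as extra individuals
  if (config@nSibPairs > 0L) truth <- addSibPairs(truth, config@nSibPairs)

  truth@meta <- cbind(truth@meta, assignCoordinates(config, truth@meta$pop))
  validObject(truth)
  truth
}

# grid of geographic site labels spanning roughly 300 km; individuals are
# assigned round-robin to their population's labels
assignCoordinates <- function(config, popOf) {
  nLab <- config@nPops * config@nSitesPerPop
  ncolG <- ceiling(sqrt(nLab))
  nrowG <- ceiling(nLab / ncolG)
  latSpan <- 2.7                       # ~300 km north-south
  lonSpan <- 2.7
  grid <- expand.grid(col = seq_len(ncolG), row = seq_len(nrowG))[seq_len(nLab), ]
  lab <- data.frame(
    site = sprintf("site%02d", seq_len(nLab)),
    lat = 5 + (grid$row - 1) * latSpan / max(1, nrowG - 1),
    lon = -3 + (grid$col - 1) * lonSpan / max(1, ncolG - 1))
  labOfPop <- split(seq_len(nLab), rep(seq_len(config@nPops),
                                       each = config@nSitesPerPop))
  idx <- integer(length(popOf))
  for (p in unique(popOf)) {
    members <- which(popOf == p)
    idx[members] <- labOfPop[[p]][(seq_along(members) - 1L) %%
                                    config@nSitesPerPop + 1L]
  }
  lab[idx, , drop = FALSE]
}

#' Apply a haplotype-copying selective sweep
#'
#' Within the sweep window a fraction \code{strength} of the targeted
#' populations' haplotypes is replaced by copies of one randomly chosen
#' "swept" haplotype; genotypes are re-derived. This cheap stand-in for a
#' forward sweep directly produces the elevated haplotype homozygosity
#' that H12/H123 detect.
#'
#' @param truth a [SimulationTruth].
#' @param chrom,center,width sweep window (bp; window is
#'   center +/- width/2).
#' @param strength fraction of haplotypes replaced, in [0, 1].
#' @param pops integer vector of target populations (default: all).
#' @return the modified [SimulationTruth] with the window recorded.
#' @export
applySweep <- function(truth, chrom, center, width, strength, pops = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  cfg <- truth@config
  pos <- start(truth@sites)
  win <- as.character(seqnames(truth@sites)) == chrom &
    pos >= center - width / 2 & pos <= center + width / 2
  if (!any(win)) {
    warning("sweep window contains no simulated SNPs; no-op")
    return(truth)
  }
  if (is.null(pops)) pops <- seq_len(cfg@nPops)
  inds <- which(truth@meta$pop %in% pops)
  if (strength > 0 && length(inds)) {
    hapIdx <- cbind(rep(inds, 2L), rep(c(1L, 2L), each = length(inds)))
    donor <- hapIdx[sample.int(nrow(hapIdx), 1L), ]
    donorHap <- if (donor[2] == 1L) truth@hapA[donor[1], win] else
      truth@hapB[donor[1], win]
    nRepl <- round(strength * nrow(hapIdx))
    repl <- hapIdx[sample.int(nrow(hapIdx), nRepl), , drop = FALSE]
    for (r in seq_len(nrow(repl))) {
      if (repl[r, 2] == 1L) truth@hapA[repl[r, 1], win] <- donorHap
      else truth@hapB[repl[r, 1], win] <- donorHap
    }
    truth@genotypes <- truth@hapA + truth@hapB
  }
  gr <- GRanges(chrom, IRanges(max(1, center - width / 2), center + width / 2))
  truth@sweepWindows <- c(truth@sweepWindows, gr)
  truth
}

# append n full-sib pairs; parents are existing founder individuals,
# offspring receive one independently chosen allele per parent per site
# (free recombination between SNPs)
addSibPairs <- function(truth, nPairs) {
  cfg <- truth@config
  nSnp <- length(truth@sites)
  for (k in seq_len(nPairs)) {
    p <- (k - 1L) %% cfg@nPops + 1L
    members <- which(truth@meta$pop == p)
    par <- members[c(2L * k - 1L, 2L * k) %% length(members) + 1L]
    if (par[1] == par[2]) par <- members[1:2]
    kids <- matrix(0L, 2L, nSnp)
    kidA <- matrix(0L, 2L, nSnp); kidB <- matrix(0L, 2L, nSnp)
    for (o in 1:2) {
      pick1 <- stats::runif(nSnp) < 0.5
      kidA[o, ] <- ifelse(pick1, truth@hapA[par[1], ], truth@hapB[par[1], ])
      pick2 <- stats::runif(nSnp) < 0.5
      kidB[o, ] <- ifelse(pick2, truth@hapA[par[2], ], truth@hapB[par[2], ])
      kids[o, ] <- kidA[o, ] + kidB[o, ]
    }
    ids <- sprintf("sib%02d_%d", k, 1:2)
    truth@hapA <- rbind(truth@hapA, kidA)
    truth@hapB <- rbind(truth@hapB, kidB)
    truth@genotypes <- rbind(truth@genotypes, kids)
    truth@meta <- rbind(truth@meta, data.frame(
      sample_id = ids, species = truth@meta$species[par[1]],
      ecoregion = truth@meta$ecoregion[par[1]], pop = p))
    truth@pedigree <- rbind(truth@pedigree, data.frame(
      offspring = ids,
      parent1 = truth@meta$sample_id[par[1]],
      parent2 = truth@meta$sample_id[par[2]]))
  }
  truth
}

#' Simulate low-coverage reads over simulated genotypes
#'
#' Per individual and site the read count is Poisson(\code{meanCoverage});
#' each read is drawn from the individual's two alleles with equal
#' probability and flipped to a uniformly chosen different base with
#' probability \code{10^(-baseError/10)}. Reads are emitted as per-site
#' ref/alt/other counts with the configured constant quality.
#'
#' @param truth a [SimulationTruth].
#' @param meanCoverage,baseError override the configured values.
#' @param seed seed for the read-sampling stream (derived from the
#'   config seed by default so truth and reads are jointly reproducible).
#' @return a [ReadPileup].
#' @export
simulateReads <- function(truth, meanCoverage = truth@config@meanCoverage,
                          baseError = truth@config@baseError,
                          seed = childSeed(truth@config@seed, 1L)) {
  set.seed(seed)
  G <- t(truth@genotypes)                       # sites x individuals
  nS <- nrow(G); nI <- ncol(G)
  e <- 10^(-baseError / 10)
  depth <- matrix(stats::rpois(nS * nI, meanCoverage), nS, nI)
  pAlt <- (G / 2) * (1 - e) + (1 - G / 2) * (e / 3)
  pRef <- (1 - G / 2) * (1 - e) + (G / 2) * (e / 3)
  nAlt <- matrix(stats::rbinom(nS * nI, depth, pAlt), nS, nI)
  pRefGivenRest <- ifelse(depth - nAlt > 0, pRef / (1 - pAlt), 0)
  nRef <- matrix(stats::rbinom(nS * nI, depth - nAlt,
                               pmin(pRefGivenRest, 1)), nS, nI)
  nOther <- depth - nAlt - nRef
  new("ReadPileup", sites = truth@sites, nRef = nRef, nAlt = nAlt,
      nOther = nOther, baseQual = baseError,
      samples = truth@meta$sample_id)
}

#' Write the simulation truth, metadata and annotation to a directory
#'
#' Emits the ground-truth tables as TSV (per-SNP frequencies, genotypes,
#' pedigree, sweep windows), the sample metadata TSV
#' (sample_id, species, ecoregion, site, lat, lon), a synthetic GFF3
#' annotation with one "IR gene" centred on each sweep window, and a
#' random genome FASTA consistent with the reference alleles.
#'
#' @param truth a [SimulationTruth].
#' @param dir output directory (created if needed).
#' @param writeGenome also write the FASTA (can be large).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(truth, dir, writeGenome = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    meta = file.path(dir, "samples.tsv"),
    freqs = file.path(dir, "truth_freqs.tsv"),
    genotypes = file.path(dir, "truth_genotypes.tsv"),
    pedigree = file.path(dir, "truth_pedigree.tsv"),
    sweeps = file.path(dir, "truth_sweeps.tsv"),
    gff = file.path(dir, "annotation.gff3"))
  utils::write.table(truth@meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fr <- data.frame(chrom = as.character(seqnames(truth@sites)),
                   pos = start(truth@sites),
                   ref = mcols(truth@sites)$ref,
                   alt = mcols(truth@sites)$alt,
                   ancestral = truth@ancestralFreqs)
  colnames(truth@popFreqs) <- paste0("pop", seq_len(ncol(truth@popFreqs)))
  utils::write.table(cbind(fr, truth@popFreqs), paths["freqs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- as.data.frame(t(truth@genotypes))
  colnames(gt) <- truth@meta$sample_id
  utils::write.table(cbind(fr[, 1:2], gt), paths["genotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth@pedigree, paths["pedigree"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sw <- data.frame(chrom = as.character(seqnames(truth@sweepWindows)),
                   start = start(truth@sweepWindows),
                   end = end(truth@sweepWindows))
  utils::write.table(sw, paths["sweeps"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeSyntheticAnnotation(truth, paths["gff"])
  if (writeGenome) {
    paths <- c(paths, genome = file.path(dir, "genome.fa"))
    Biostrings::writeXStringSet(syntheticGenome(truth), paths["genome"])
  }
  invisible(paths)
}

#' Synthetic genome sequence consistent with simulated reference alleles
#'
#' Random uniform background sequence with the simulated reference allele
#' planted at every SNP position; labelled synthetic, for exercising the
#' annotation/effect path.
#'
#' @param truth a [SimulationTruth].
#' @param seed seed for the background sequence.
#' @return a Biostrings DNAStringSet, one entry per chromosome.
#' @export
syntheticGenome <- function(truth, seed = childSeed(truth@config@seed, 2L)) {
  set.seed(seed)
  cfg <- truth@config
  seqs <- lapply(seq_along(cfg@chroms), function(i) {
    len <- cfg@seqLength[i]
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    onChr <- as.character(seqnames(truth@sites)) == cfg@chroms[i]
    s[start(truth@sites)[onChr]] <- mcols(truth@sites)$ref[onChr]
    paste(s, collapse = "")
  })
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- cfg@chroms
  g
}

#' Write a synthetic GFF3 annotation with one IR-like gene per sweep
#'
#' Each sweep window receives a plus-strand single-transcript gene
#' centred on the window, with 5'/3' UTR, two exons, an intron and a CDS
#' whose length is a multiple of 3; background "filler" genes are tiled
#' elsewhere so gene-window intersection has negatives to reject.
#'
#' @param truth a [SimulationTruth].
#' @param file output GFF3 path.
#' @return invisibly, the GRanges exported.
#' @export
writeSyntheticAnnotation <- function(truth, file) {
  cfg <- truth@config
  rows <- list()
  geneNo <- 0L
  addGene <- function(chrom, centre, id) {
    # layout (plus strand): 5'UTR 200, exon1 = UTR+CDS1(300), intron 200,
    # exon2 = CDS2(300)+3'UTR 200
    s <- round(centre) - 600L
    if (s < 1) s <- 1L
    gene <- c(s, s + 1199L)
    utr5 <- c(s, s + 199L); cds1 <- c(s + 200L, s + 499L)
    intron <- c(s + 500L, s + 699L)
    cds2 <- c(s + 700L, s + 999L); utr3 <- c(s + 1000L, s + 1199L)
    feat <- function(type, rng, attrs)
      data.frame(chrom = chrom, source = "poplik", type = type,
                 start = rng[1], end = rng[2], score = ".", strand = "+",
                 phase = if (type == "CDS") "0" else ".", attrs = attrs)
    tid <- paste0(id, ".t1")
    rbind(
      feat("gene", gene, sprintf("ID=%s;Name=%s", id, id)),
      feat("mRNA", gene, sprintf("ID=%s;Parent=%s", tid, id)),
      feat("five_prime_UTR", utr5, sprintf("ID=%s.u5;Parent=%s", id, tid)),
      feat("exon", c(utr5[1], cds1[2]), sprintf("ID=%s.e1;Parent=%s", id, tid)),
      feat("CDS", cds1, sprintf("ID=%s.c1;Parent=%s", id, tid)),
      feat("exon", c(cds2[1], utr3[2]), sprintf("ID=%s.e2;Parent=%s", id, tid)),
      feat("CDS", cds2, sprintf("ID=%s.c2;Parent=%s", id, tid)),
      feat("three_prime_UTR", utr3, sprintf("ID=%s.u3;Parent=%s", id, tid)))
  }
  sw <- truth@sweepWindows
  for (i in seq_along(sw)) {
    geneNo <- geneNo + 1L
    rows[[length(rows) + 1L]] <- addGene(
      as.character(seqnames(sw))[i], (start(sw)[i] + end(sw)[i]) / 2,
      sprintf("IRgene%02d", geneNo))
  }
  for (ci in seq_along(cfg@chroms)) {
    centres <- seq(2e4, cfg@seqLength[ci] - 2e4, by = 5e4)
    for (ce in centres) {
      near <- any(as.character(seqnames(sw)) == cfg@chroms[ci] &
                    abs((start(sw) + end(sw)) / 2 - ce) < 3e4)
      if (near) next
      geneNo <- geneNo + 1L
      rows[[length(rows) + 1L]] <- addGene(cfg@chroms[ci], ce,
                                           sprintf("gene%03d", geneNo))
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(file, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(tab)
}
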