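#' Subset a pileup by individuals
#'
#' @param pileup a [ReadPileup].
#' @param individuals sample ids or indices.
#' @return a [ReadPileup] over the selected individuals.
#' @export
subsetPileup <- function(pileup, individuals) {
  if (is.character(individuals))
    individuals <- match(individuals, pileup@samples)
  new("ReadPileup", sites = pileup@sites,
      nRef = pileup@nRef[, individuals, drop = FALSE],
      nAlt = pileup@nAlt[, individuals, drop = FALSE],
      nOther = pileup@nOther[, individuals, drop = FALSE],
      baseQual = pileup@baseQual, samples = pileup@samples[individuals])
}

#' Run configuration for the end-to-end pipeline
#'
#' Assembles every tunable of the full analysis with the package
#' defaults: ANGSD-style filter thresholds (total depth 6000, base
#' quality 30, individual fraction 0.25, SNP p 0.05, MAF 0.05), 10-kb
#' windows with 5-kb step, 100-SNP haplotype windows, the 3x
#' mode-distance outlier multiplier, and a mutation rate for Ne.
#' Values can also be loaded from a YAML file with the same field
#' names.
#'
#' @param sim a [SimConfig] (the simulated study) or NULL when reading
#'   external inputs.
#' @param windowBp,stepBp Fst/diversity window size and step (bp).
#' @param hWindowSnps haplotype-window size in SNPs.
#' @param outlierMultiplier mode-distance multiplier.
#' @param filters a [filterConfig()].
#' @param mu per-bp per-generation mutation rate for Ne (no
#'   authoritative default exists; the value is a required, documented
#'   choice).
#' @param admixtureK clusters for the admixture fit.
#' @param pcaChrom chromosome used for PCA/admixture (all when absent).
#' @param nPerm Mantel permutations.
#' @param seed master seed.
#' @return a list of class \code{poplik_run_config}.
#' @export
runConfig <- function(sim = defaultStudyConfig(seed), windowBp = 10000,
                      stepBp = 5000, hWindowSnps = 100L,
                      outlierMultiplier = 3, filters = filterConfig(),
                      mu = 3.5e-9, admixtureK = 2L, pcaChrom = "3L",
                      nPerm = 999L, seed = 1L) {
  structure(list(sim = sim, windowBp = as.numeric(windowBp),
                 stepBp = as.numeric(stepBp),
                 hWindowSnps = as.integer(hWindowSnps),
                 outlierMultiplier = as.numeric(outlierMultiplier),
                 filters = filters, mu = as.numeric(mu),
                 admixtureK = as.integer(admixtureK), pcaChrom = pcaChrom,
                 nPerm = as.integer(nPerm), seed = as.integer(seed)),
            class = "poplik_run_config")
}

#' Read a run configuration from YAML
#'
#' Flat YAML fields override [runConfig()] defaults; \code{sim} and
#' \code{filters} sub-sections override [simConfig()] and
#' [filterConfig()] arguments.
#'
#' @param path YAML file.
#' @return a \code{poplik_run_config}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim %||% list()
  if (!is.null(simArgs$sweepLoci))
    simArgs$sweepLoci <- as.data.frame(simArgs$sweepLoci)
  if (!is.null(simArgs$inversionBlock))
    simArgs$inversionBlock <- as.data.frame(simArgs$inversionBlock)
  filtArgs <- y$filters %||% list()
  top <- y[setdiff(names(y), c("sim", "filters"))]
  args <- c(list(sim = do.call(simConfig, simArgs),
                 filters = do.call(filterConfig, filtArgs)), top)
  do.call(runConfig, args)
}

writeTsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated study
#'
#' simulate -> genotype likelihoods and filters (per analysis stratum)
#' -> folded SFS, pi/theta/Tajima's D and Ne per stratum -> pairwise 2D
#' SFS, windowed Fst, outlier windows and gene intersection -> Garud H
#' scan -> PCA, admixture, kinship (inversion-masked) and relationship
#' classes -> isolation-by-distance Mantel tests and correlogram.
#' Every stage writes TSV outputs under \code{outDir} plus a JSON
#' manifest (inputs, parameters, seeds, row counts); reruns with an
#' identical configuration reproduce the outputs exactly.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config = runConfig(), outDir, quiet = FALSE) {
  t0 <- Sys.time()
  stage <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = list(
    windowBp = config$windowBp, stepBp = config$stepBp,
    hWindowSnps = config$hWindowSnps,
    outlierMultiplier = config$outlierMultiplier,
    filters = unclass(config$filters), mu = config$mu,
    admixtureK = config$admixtureK, nPerm = config$nPerm,
    seed = config$seed))
  counts <- list()

  stage("[simulate] generating study (seed %d)", config$seed)
  truth <- simulateFrequencies(config$sim)
  pileup <- simulateReads(truth)
  writeSimulation(truth, file.path(outDir, "sim"))
  gffPath <- file.path(outDir, "sim", "annotation.gff3")
  meta <- truth@meta
  chromLens <- stats::setNames(config$sim@seqLength, config$sim@chroms)
  counts$snps_simulated <- length(truth@sites)
  counts$individuals <- nrow(meta)

  strata <- split(seq_len(nrow(meta)),
                  paste(meta$species, meta$ecoregion, sep = "."))

  stage("[diversity] per-stratum SFS and thetas")
  divRows <- list(); divWindows <- list()
  noPoly <- config$filters
  noPoly$polymorphismFiltersOn <- FALSE
  for (st in names(strata)) {
    glDiv <- filterSites(subsetPileup(pileup, strata[[st]]), noPoly)
    saf <- safLikelihoods(glDiv)
    sfs <- estimateSfs(saf, folded = TRUE)
    th <- perSiteThetas(saf, sfs)
    win <- windowedDiversity(th, saf@nChrom, config$windowBp,
                             config$stepBp, chromLens)
    gw <- genomewideDiversity(th, saf@nChrom)
    divRows[[st]] <- data.frame(
      stratum = st, n_ind = length(strata[[st]]), gw,
      meanWindowTajD = mean(win$tajD, na.rm = TRUE),
      Ne = estimateNe(gw$pi, config$mu))
    win$stratum <- st
    divWindows[[st]] <- win
    writeSfs(sfs, file.path(outDir, "diversity",
                            paste0("sfs_", st, ".txt")))
  }
  diversityTable <- do.call(rbind, c(divRows, make.row.names = FALSE))
  writeTsv(diversityTable, file.path(outDir, "diversity", "diversity_table.tsv"))
  writeTsv(do.call(rbind, c(divWindows, make.row.names = FALSE)),
           file.path(outDir, "diversity", "diversity_windows.tsv"))
  counts$diversity_strata <- nrow(diversityTable)

  stage("[fst] pairwise comparisons, outliers and genes")
  specOf <- vapply(names(strata), function(s)
    meta$species[strata[[s]][1]], "")
  pairs <- list()
  for (sp in unique(specOf)) {
    nm <- names(strata)[specOf == sp]
    if (length(nm) >= 2L)
      for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1L):length(nm))
        pairs[[length(pairs) + 1L]] <- c(nm[i], nm[j])
  }
  if (length(unique(specOf)) == 2L) {
    sps <- unique(specOf)
    pairs[[length(pairs) + 1L]] <- c(sps[1], sps[2])
  }
  fstRows <- list(); geneTables <- list(); outlierList <- list()
  for (pr in pairs) {
    inSpecies <- all(pr %in% names(strata))
    ids1 <- if (inSpecies) strata[[pr[1]]] else
      which(meta$species == pr[1])
    ids2 <- if (inSpecies) strata[[pr[2]]] else
      which(meta$species == pr[2])
    lab <- paste(pr, collapse = "__vs__")
    glPair <- filterSites(subsetPileup(pileup, c(ids1, ids2)),
                          config$filters)
    if (nSites(glPair) < 10L) next
    fit <- fstFromGL(glPair, seq_along(ids1),
                     length(ids1) + seq_along(ids2))
    win <- windowedFst(fit$components, config$windowBp, config$stepBp,
                       chromLens)
    gw <- genomewideFst(fit$components, win)
    fstRows[[lab]] <- data.frame(
      comparison = lab, fst = gw$fst, mean_window_fst = gw$meanWindowFst,
      n_sites = gw$n_sites)
    out <- designateOutliers(win, config$outlierMultiplier)
    out$comparison <- lab
    outlierList[[lab]] <- out
    writeTsv(out, file.path(outDir, "fst", paste0("windows_", lab, ".tsv")))
    genes <- intersectGenes(out, gffPath)
    if (nrow(genes)) {
      genes$comparison <- lab
      geneTables[[lab]] <- genes
      writeTsv(genes, file.path(outDir, "fst", paste0("genes_", lab, ".tsv")))
    }
  }
  fstTable <- do.call(rbind, c(fstRows, make.row.names = FALSE))
  writeTsv(fstTable, file.path(outDir, "fst", "genomewide_fst.tsv"))
  geneTable <- if (length(geneTables))
    do.call(rbind, c(geneTables, make.row.names = FALSE)) else NULL
  counts$fst_comparisons <- nrow(fstTable)

  stage("[selection] Garud H scans")
  hscans <- list()
  for (st in names(strata)) {
    inds <- strata[[st]]
    hap <- rbind(truth@hapA[inds, , drop = FALSE],
                 truth@hapB[inds, , drop = FALSE])
    chroms <- as.character(seqnames(truth@sites))
    res <- list()
    for (chr in unique(chroms)) {
      onChr <- chroms == chr
      if (sum(onChr) < config$hWindowSnps) next
      res[[chr]] <- scanH(hap[, onChr, drop = FALSE],
                          start(truth@sites)[onChr], chr,
                          config$hWindowSnps)
    }
    sc <- do.call(rbind, c(res, make.row.names = FALSE))
    sc$stratum <- st
    hscans[[st]] <- sc
  }
  hscanTable <- do.call(rbind, c(hscans, make.row.names = FALSE))
  writeTsv(hscanTable, file.path(outDir, "selection", "hscan.tsv"))
  counts$hscan_windows <- nrow(hscanTable)

  stage("[structure] PCA, admixture, kinship")
  glAll <- filterSites(pileup, config$filters)
  keptInd <- filterIndividuals(glAll, 0.25)
  glAll <- keptInd$gl
  pcaSites <- as.character(seqnames(glSites(glAll))) == config$pcaChrom
  glPca <- if (any(pcaSites)) subsetGL(glAll, sites = which(pcaSites))
  else glAll
  writeBeagle(glPca, file.path(outDir, "structure", "pca_input.beagle.gz"))
  pca <- covariancePca(glPca)
  metaKept <- meta[match(glSamples(glAll), meta$sample_id), ]
  scores <- data.frame(sample_id = rownames(pca$scores),
                       metaKept[, c("species", "ecoregion", "site")],
                       pca$scores)
  writeTsv(scores, file.path(outDir, "structure", "pca_scores.tsv"))
  adm <- admixtureEm(glPca, config$admixtureK,
                     seed = childSeed(config$seed, 11L))
  Q <- data.frame(sample_id = glSamples(glPca), metaKept[, c("species",
                  "ecoregion")], adm@Q)
  writeTsv(Q, file.path(outDir, "structure", "admixture_Q.tsv"))

  mask <- NULL
  if (!is.null(config$sim@inversionBlock) &&
      nrow(config$sim@inversionBlock)) {
    ib <- config$sim@inversionBlock
    mask <- GRanges(ib$chrom, IRanges(ib$start, ib$end))
  }
  G <- callGenotypes(glAll)
  rownames(G) <- glSamples(glAll)
  kin <- kingKinship(G, sites = glSites(glAll), mask = mask)
  kin <- classifyRelationships(kin)
  writeTsv(kin, file.path(outDir, "kinship", "kinship.tsv"))
  counts$full_sib_pairs <- sum(kin$relationship == "full_sib",
                               na.rm = TRUE)

  stage("[ibd] Mantel tests and correlograms")
  phi <- attr(kin, "phiMatrix")
  ibdRows <- list(); correlogs <- list()
  for (sp in unique(metaKept$species)) {
    ii <- which(metaKept$species == sp)
    if (length(ii) < 4L) next
    gen <- 0.5 - phi[ii, ii]          # kinship as a distance
    diag(gen) <- 0
    geo <- geoDistanceMatrix(metaKept$lat[ii], metaKept$lon[ii],
                             metaKept$sample_id[ii])
    mt <- try(mantelTest(gen, geo, config$nPerm,
                         seed = childSeed(config$seed, 21L)), silent = TRUE)
    if (!inherits(mt, "try-error"))
      ibdRows[[sp]] <- data.frame(species = sp, r = mt$r, p = mt$p,
                                  n = length(ii))
    cg <- try(mantelCorrelogram(gen, geo, nPerm = config$nPerm,
                                seed = childSeed(config$seed, 22L)),
              silent = TRUE)
    if (!inherits(cg, "try-error")) {
      cg$species <- sp
      correlogs[[sp]] <- cg
    }
  }
  ibdTable <- do.call(rbind, c(ibdRows, make.row.names = FALSE))
  writeTsv(ibdTable, file.path(outDir, "ibd", "mantel.tsv"))
  if (length(correlogs))
    writeTsv(do.call(rbind, c(correlogs, make.row.names = FALSE)),
             file.path(outDir, "ibd", "correlogram.tsv"))

  manifest$row_counts <- counts
  manifest$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 1)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list(truth = truth, diversity = diversityTable,
              diversityWindows = do.call(rbind, c(divWindows,
                                                  make.row.names = FALSE)),
              fst = fstTable, outliers = outlierList, genes = geneTable,
              hscan = hscanTable, pca = pca, admixture = adm,
              kinship = kin, ibd = ibdTable,
              correlograms = if (length(correlogs))
                do.call(rbind, c(correlogs, make.row.names = FALSE))
              else NULL,
              meta = metaKept, outDir = outDir)
  stage("[done] pipeline complete in %.1f s", manifest$elapsed_sec)
  invisible(res)
}

#' Summary tables and figures for a pipeline run
#'
#' Regenerates the headline views from a [runPipeline()] result: the
#' per-stratum diversity table, the upper-triangular pairwise Fst
#' table, a Manhattan-style Fst scan, the H123 scan, a PCA scatter by
#' species/ecoregion, and the IBD correlogram; figures are written as
#' PDFs under \code{outDir/report}.
#'
#' @param res result list from [runPipeline()].
#' @param outDir output directory (default: the run directory).
#' @return invisibly, list(diversity, fstMatrix, files).
#' @export
summaryReport <- function(res, outDir = res$outDir) {
  repDir <- file.path(outDir, "report")
  dir.create(repDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  ## pairwise Fst as an upper-triangular table
  labs <- sort(unique(unlist(strsplit(res$fst$comparison, "__vs__"))))
  fm <- matrix(NA_real_, length(labs), length(labs),
               dimnames = list(labs, labs))
  for (i in seq_len(nrow(res$fst))) {
    pr <- strsplit(res$fst$comparison[i], "__vs__")[[1]]
    fm[pr[1], pr[2]] <- res$fst$fst[i]
  }
  writeTsv(data.frame(label = rownames(fm), fm, check.names = FALSE),
           file.path(repDir, "fst_matrix.tsv"))
  writeTsv(res$diversity, file.path(repDir, "diversity_table.tsv"))

  out <- do.call(rbind, c(res$outliers, make.row.names = FALSE))
  out <- out[!is.na(out$fst), ]
  p1 <- ggplot2::ggplot(out, ggplot2::aes(x = (start + end) / 2, y = fst,
                                          colour = is_outlier)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_grid(comparison ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "window Fst") +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  f <- file.path(repDir, "fst_scan.pdf")
  ggplot2::ggsave(f, p1, width = 9, height = 6); files <- c(files, f)

  p2 <- ggplot2::ggplot(res$hscan,
                        ggplot2::aes(x = (start_pos + end_pos) / 2,
                                     y = H123)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(stratum ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "Garud's H123") +
    ggplot2::theme_bw()
  f <- file.path(repDir, "h123_scan.pdf")
  ggplot2::ggsave(f, p2, width = 9, height = 6); files <- c(files, f)

  sc <- data.frame(res$meta, PC1 = res$pca$scores[, 1],
                   PC2 = res$pca$scores[, 2])
  p3 <- ggplot2::ggplot(sc, ggplot2::aes(PC1, PC2, colour = ecoregion,
                                         shape = species)) +
    ggplot2::geom_point() + ggplot2::theme_bw()
  f <- file.path(repDir, "pca.pdf")
  ggplot2::ggsave(f, p3, width = 6, height = 5); files <- c(files, f)

  if (!is.null(res$correlograms)) {
    cgPlot <- res$correlograms[!is.na(res$correlograms$r) &
                                 !is.na(res$correlograms$p_corrected), ]
    p4 <- ggplot2::ggplot(cgPlot,
                          ggplot2::aes(class_mid, r,
                                       colour = p_corrected <= 0.05)) +
      ggplot2::geom_point() + ggplot2::geom_line(colour = "grey50") +
      ggplot2::facet_wrap(~species) +
      ggplot2::labs(x = "distance class midpoint (km)", y = "Mantel r") +
      ggplot2::theme_bw()
    f <- file.path(repDir, "correlogram.pdf")
    ggplot2::ggsave(f, p4, width = 7, height = 4); files <- c(files, f)
  }
  invisible(list(diversity = res$diversity, fstMatrix = fm, files = files))
}
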