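test_that("genotype likelihoods match hand-computed closed forms", {
  ## 4 reads all equal to the major allele, e = 0.001
  e <- 0.001
  got <- genotypeLikelihoods(rep("A", 4), 30, "A", "C", normalize = FALSE)
  expect_equal(got[1], 4 * log(1 - e), tolerance = 1e-12)
  expect_equal(got[2], 4 * log(0.5 * (1 - e) + 0.5 * e / 3),
               tolerance = 1e-12)
  expect_equal(got[3], 4 * log(e / 3), tolerance = 1e-12)
  expect_equal(exp(got[1]), 0.999^4)

  ## no reads: flat triplet
  expect_equal(genotypeLikelihoods(character(), numeric(), "A", "C"),
               c(0, 0, 0))

  ## one minor read at tiny error: L(1) = L(2)/2, L(0) negligible
  got <- genotypeLikelihoods("C", 60, "A", "C", normalize = FALSE)
  expect_equal(exp(got[2]) / exp(got[3]), 0.5, tolerance = 1e-5)
  expect_lt(exp(got[1]), 1e-5)
})

test_that("normalized GLs are invariant to a constant likelihood scale", {
  got <- genotypeLikelihoods(c("A", "C", "A"), c(25, 32, 17), "A", "C")
  raw <- genotypeLikelihoods(c("A", "C", "A"), c(25, 32, 17), "A", "C",
                             normalize = FALSE)
  expect_equal(got, (raw + 7.3) - max(raw + 7.3))
  expect_equal(max(got), 0)
})

test_that("count-based and per-read GL paths agree", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 5, targetFst = 0, chroms = "1",
                   seqLength = 1e4, meanCoverage = 8, seed = 3)
  truth <- simulateFrequencies(cfg)
  pu <- simulateReads(truth)
  gl <- pileupGL(pu)
  s <- 5L; i <- 2L
  sites <- glSites(gl)
  ## reconstruct the read list for one individual-site
  origIdx <- match(GenomicRanges::start(sites)[s],
                   GenomicRanges::start(pu@sites))
  mm <- S4Vectors::mcols(sites)
  refBase <- S4Vectors::mcols(pu@sites)$ref[origIdx]
  altBase <- S4Vectors::mcols(pu@sites)$alt[origIdx]
  bases <- c(rep(refBase, pu@nRef[origIdx, i]),
             rep(altBase, pu@nAlt[origIdx, i]),
             rep(setdiff(c("A", "C", "G", "T"), c(refBase, altBase))[1],
                 pu@nOther[origIdx, i]))
  byHand <- genotypeLikelihoods(bases, pu@baseQual, mm$major[s], mm$minor[s])
  expect_equal(unname(glArray(gl)[s, i, ]), unname(byHand),
               tolerance = 1e-10)
})

test_that("ML allele frequency has the right analytic optima", {
  homMajor <- matrix(rep(c(0, -40, -80), each = 6), ncol = 3)
  expect_equal(estimateMaf(homMajor)$maf, 0, tolerance = 1e-6)
  hets <- matrix(rep(c(-40, 0, -40), each = 2), ncol = 3)
  expect_equal(estimateMaf(hets)$maf, 0.5, tolerance = 1e-6)
  allMissing <- matrix(0, 3, 3)
  expect_error(estimateMaf(allMissing), "missing")
})

test_that("EM frequency matches a fine grid-search oracle", {
  set.seed(7)
  worst <- 0
  for (rep in 1:20) {
    n <- 15
    gl <- matrix(log(runif(n * 3)), n, 3)
    gl <- gl - apply(gl, 1, max)
    em <- estimateMaf(gl)$maf
    grid <- oracleGridMaf(gl)
    worst <- max(worst, abs(em - grid))
  }
  expect_lt(worst, 1e-3)
})

test_that("the polymorphism LRT calibrates on simulated sites", {
  ## monomorphic sites should rarely be declared SNPs...
  nRep <- 500; nInd <- 50
  G0 <- matrix(0L, nInd, nRep)
  set.seed(5)
  e <- 10^(-30 / 10)
  mkGL <- function(G) {
    depth <- matrix(rpois(length(G), 15), nrow(G), ncol(G))
    tG <- t(G)
    tDepth <- t(depth)
    pAlt <- (tG / 2) * (1 - e) + (1 - tG / 2) * (e / 3)
    nAlt <- matrix(rbinom(length(tG), tDepth, pAlt), nrow(tG), ncol(tG))
    poplik:::glFromCounts(tDepth - nAlt, nAlt,
                          matrix(0L, nrow(tG), ncol(tG)), 30)
  }
  gl0 <- mkGL(G0)
  sites <- GenomicRanges::GRanges("1", IRanges::IRanges(1:nRep, 1:nRep),
                                  major = "A", minor = "C")
  glm0 <- poplik:::newGLMatrix(sites, gl0, sprintf("i%02d", 1:nInd))
  p0 <- snpLrt(glm0)$p_value
  expect_lte(mean(p0 <= 0.05), 0.06)
  ## ... and truly polymorphic sites (f = 0.2) should nearly always be
  Gp <- matrix(rbinom(nInd * nRep, 2, 0.2), nInd, nRep)
  glp <- mkGL(Gp)
  glmp <- poplik:::newGLMatrix(sites, glp, sprintf("i%02d", 1:nInd))
  pp <- snpLrt(glmp)$p_value
  expect_gte(mean(pp <= 0.05), 0.95)
})

test_that("site filters drop exactly the violating sites of a toy input", {
  ## 6 sites x 4 individuals; sites 3 (too deep) and 5 (monomorphic+MAF)
  ## violate one polymorphism-dependent rule each
  nRef <- matrix(5L, 6, 4)
  nAlt <- matrix(5L, 6, 4)
  nOther <- matrix(0L, 6, 4)
  nRef[3, ] <- 3000L; nAlt[3, ] <- 3000L       # depth 24000 > 6000
  nAlt[5, ] <- 0L                              # monomorphic
  sites <- GenomicRanges::GRanges("1", IRanges::IRanges(1:6 * 100, 1:6 * 100),
                                  ref = "A", alt = "C")
  pu <- new("ReadPileup", sites = sites, nRef = nRef, nAlt = nAlt,
            nOther = nOther, baseQual = 35, samples = paste0("i", 1:4))
  kept <- filterSites(pu, filterConfig())
  expect_equal(GenomicRanges::start(glSites(kept)), c(1, 2, 4, 6) * 100)
  lg <- attr(kept, "filterLog")
  expect_equal(unname(lg["maxDepth"]), 1)
  expect_equal(unname(lg["retained"]), 4)

  ## polymorphism filters off: only base-quality and minInd rules apply
  keptAll <- filterSites(pu, filterConfig(polymorphismFiltersOn = FALSE))
  expect_equal(nSites(keptAll), 6L)

  ## all reads below minQ: everything missing, dropped by minInd
  puLowQ <- new("ReadPileup", sites = sites, nRef = nRef, nAlt = nAlt,
                nOther = nOther, baseQual = 20, samples = paste0("i", 1:4))
  expect_warning(empty <- filterSites(puLowQ, filterConfig()),
                 "no sites survive")
  expect_equal(nSites(empty), 0L)
})

test_that("individual culling uses a strict 25% missingness rule", {
  G <- matrix(1L, 5, 100)
  gl <- certainGL(G)
  a <- glArray(gl)
  a[1:26, 2, ] <- 0                            # 26% missing: removed
  a[1:25, 3, ] <- 0                            # exactly 25%: retained
  gl2 <- poplik:::newGLMatrix(glSites(gl), a, glSamples(gl))
  res <- filterIndividuals(gl2, 0.25)
  expect_equal(res$removed, "ind002")
  expect_equal(nInd(res$gl), 4L)
  ## no missingness: identity
  res0 <- filterIndividuals(gl, 0.25)
  expect_equal(length(res0$removed), 0L)
  expect_equal(glArray(res0$gl), glArray(gl))
})

test_that("BEAGLE files round-trip losslessly", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 6, targetFst = 0, chroms = "1",
                   seqLength = 3e4, meanCoverage = 6, seed = 13)
  gl <- pileupGL(simulateReads(simulateFrequencies(cfg)))
  f <- tempfile(fileext = ".beagle.gz")
  writeBeagle(gl, f)
  gl2 <- readBeagle(f)
  expect_equal(glArray(gl2), glArray(gl), tolerance = 1e-5)
  expect_equal(S4Vectors::mcols(glSites(gl2))$major,
               S4Vectors::mcols(glSites(gl))$major)
  expect_equal(glSamples(gl2), glSamples(gl))

  ## empty matrix: header-only file
  empty <- subsetGL(gl, sites = integer())
  f2 <- tempfile(fileext = ".beagle")
  writeBeagle(empty, f2)
  expect_equal(length(readLines(f2)), 1L)

  ## column order contract: triplet written as AA, Aa, aa
  G <- matrix(c(0L, 1L), 2, 1)
  gl3 <- certainGL(G, pos = 500L)
  a <- glArray(gl3)
  a[1, 1, ] <- log(c(0.3, 0.6, 0.1) / 0.6)
  gl3 <- poplik:::newGLMatrix(glSites(gl3), a, glSamples(gl3))
  f3 <- tempfile(fileext = ".beagle")
  writeBeagle(gl3, f3)
  row <- strsplit(readLines(f3)[2], "\t")[[1]]
  expect_equal(row[1], "1_500")
  expect_equal(as.numeric(row[4:6]), c(0.3, 0.6, 0.1), tolerance = 1e-5)

  ## malformed rows are reported with their line number
  writeLines(c("marker\tallele1\tallele2\ti1\ti1\ti1",
               "1_10\tA\tC\t0.2\t0.5\t0.3",
               "1_xx\tA\tC\t0.2\t0.5\t0.3"), f3)
  expect_error(readBeagle(f3), "line 3")
})
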