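test_that("posterior dosages hit closed forms", {
  ## a certain het dosages to 1 regardless of the frequency prior
  G <- matrix(c(1L, 0L, 2L), 3, 4)
  gl <- certainGL(G)
  D <- posteriorDosages(gl, freqs = rep(0.3, 4))
  expect_equal(unname(D[1, ]), rep(1, 4), tolerance = 1e-10)
  ## a flat (missing) triplet dosages to 2f
  a <- glArray(gl)
  a[2, 1, ] <- 0
  gl2 <- poplik:::newGLMatrix(glSites(gl), a, glSamples(gl))
  D2 <- posteriorDosages(gl2, freqs = rep(0.3, 4))
  expect_equal(unname(D2[1, 2]), 0.6)
})

test_that("high-coverage dosages round to the true genotypes", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 12, targetFst = 0,
                   chroms = "1", seqLength = 2e5, meanCoverage = 25,
                   freqRange = c(0.05, 0.95), seed = 17)
  truth <- simulateFrequencies(cfg)
  gl <- pileupGL(simulateReads(truth))
  sameMinor <- S4Vectors::mcols(glSites(gl))$minor ==
    S4Vectors::mcols(truth@sites)$alt
  G <- truth@genotypes
  G[, !sameMinor] <- 2L - G[, !sameMinor]
  D <- posteriorDosages(gl)
  expect_gt(mean(round(D) == G), 0.99)
})

test_that("the GL covariance PCA separates diverged populations", {
  cfg <- simConfig(nPops = 2, nDipPerPop = 15, targetFst = 0.25,
                   chroms = "1", seqLength = 2e5, meanCoverage = 10,
                   seed = 29)
  truth <- simulateFrequencies(cfg)
  gl <- filterSites(simulateReads(truth), filterConfig())
  pca <- covariancePca(gl)
  pc1 <- pca$scores[, 1]
  between <- abs(mean(pc1[1:15]) - mean(pc1[16:30]))
  within <- max(stats::sd(pc1[1:15]), stats::sd(pc1[16:30]))
  expect_gt(between, 5 * within)
  expect_equal(pca$cov, t(pca$cov), tolerance = 1e-10)
})

test_that("PCA gives duplicates identical coordinates and permutes cleanly", {
  set.seed(31)
  G <- matrix(rbinom(6 * 300, 2, rep(runif(300, 0.2, 0.8), each = 6)),
              6, 300)
  G <- rbind(G, G[1, ])                          # duplicate of ind 1
  gl <- certainGL(G)
  ## (random draws can leave a few monomorphic columns, excluded with a
  ## warning that is not under test here)
  pca <- suppressWarnings(covariancePca(gl, nPcs = 4L))
  expect_equal(pca$scores[1, ], pca$scores[7, ], tolerance = 1e-8)
  ## permutation equivariance
  perm <- c(3, 1, 2, 7, 5, 6, 4)
  glp <- subsetGL(gl, individuals = perm)
  pcap <- suppressWarnings(covariancePca(glp, nPcs = 4L))
  expect_equal(abs(pcap$scores[, 1]), abs(pca$scores[perm, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## monomorphic sites excluded with a warning
  G2 <- cbind(G, 0L)
  expect_warning(covariancePca(certainGL(G2)), "monomorphic")
})

test_that("admixture EM has the analytic K=1 optimum and nested likelihoods", {
  cfg <- simConfig(nPops = 2, nDipPerPop = 8, targetFst = 0.15,
                   chroms = "1", seqLength = 1e5, meanCoverage = 10,
                   seed = 37)
  truth <- simulateFrequencies(cfg)
  gl <- filterSites(simulateReads(truth), filterConfig())
  fit1 <- admixtureEm(gl, 1, seed = 1, nStarts = 1L)
  expect_equal(unname(fit1@Q[, 1]), rep(1, nInd(gl)))
  fHat <- poplik:::estimateMafEM(glArray(gl))$freq
  expect_equal(unname(fit1@F[, 1]), fHat, tolerance = 1e-3)
  expect_true(all(diff(fit1@trace) > -1e-8))
  fit2 <- admixtureEm(gl, 2, seed = 1, nStarts = 2L)
  expect_gte(fit2@logLik, fit1@logLik - 1e-6)
  expect_true(all(diff(fit2@trace) > -1e-8))
  expect_equal(unname(rowSums(fit2@Q)), rep(1, nInd(gl)), tolerance = 1e-8)
  expect_error(admixtureEm(gl, nInd(gl) + 1L), "exceeds")
})

test_that("admixture and PCA are invariant to site order", {
  cfg <- simConfig(nPops = 2, nDipPerPop = 6, targetFst = 0.2,
                   chroms = "1", seqLength = 5e4, meanCoverage = 10,
                   seed = 41)
  truth <- simulateFrequencies(cfg)
  gl <- filterSites(simulateReads(truth), filterConfig())
  ## site order within a GLMatrix is canonical; shuffling the input
  ## sites must not change results once re-sorted
  shuf <- sample(nSites(gl))
  gl2 <- poplik:::newGLMatrix(glSites(gl)[shuf],
                              glArray(gl)[shuf, , , drop = FALSE],
                              glSamples(gl))
  expect_equal(glArray(gl2), glArray(gl))
  p1 <- covariancePca(gl); p2 <- covariancePca(gl2)
  expect_equal(p1$cov, p2$cov, tolerance = 1e-12)
})

test_that("KING kinship closed forms hold", {
  ## self-kinship = 0.5 on the phi matrix diagonal
  set.seed(43)
  G <- matrix(rbinom(4 * 500, 2, 0.4), 4, 500)
  rownames(G) <- paste0("i", 1:4)
  kin <- kingKinship(G)
  phi <- attr(kin, "phiMatrix")
  expect_equal(unname(diag(phi)), rep(0.5, 4))
  ## a pair with no shared hets, d opposite homozygotes, h total hets
  g1 <- c(rep(0L, 10), rep(1L, 6), rep(0L, 4))
  g2 <- c(rep(2L, 3), rep(0L, 7), rep(0L, 6), rep(1L, 4))
  kin2 <- kingKinship(rbind(a = g1, b = g2))
  expect_equal(kin2$n_both_het, 0)
  expect_equal(kin2$n_opposite_hom, 3)
  expect_equal(kin2$phi, -2 * 3 / (6 + 4))
  ## masked intervals are excluded
  sites <- GenomicRanges::GRanges("1", IRanges::IRanges(1:20 * 100,
                                                        1:20 * 100))
  mask <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 350))
  kin3 <- kingKinship(rbind(a = g1, b = g2), sites = sites, mask = mask)
  expect_equal(kin3$n_opposite_hom, 0)           # the 3 opp-homs masked
  expect_equal(kin3$n_sites, 17)
})

test_that("relationship classes follow the KING bins", {
  df <- data.frame(id1 = "a", id2 = "b",
                   n_sites = 100, n_both_het = 10,
                   n_opposite_hom = c(5, 0, 0, 0, 1),
                   n_het_1 = 10, n_het_2 = 10,
                   phi = c(0.25, 0.25, 0.40, 0.01, 0.12))
  out <- classifyRelationships(df)
  expect_equal(out$relationship,
               c("full_sib", "parent_offspring", "duplicate",
                 "unrelated", "second_degree"))
})

test_that("pedigree kinship separates sibs, parent-offspring and unrelated", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 24, targetFst = 0,
                   chroms = "1", seqLength = 2e6, mutDensity = 0.005,
                   nSibPairs = 2, seed = 47)
  truth <- simulateFrequencies(cfg)
  G <- truth@genotypes
  rownames(G) <- truth@meta$sample_id
  kin <- classifyRelationships(kingKinship(G))
  ped <- truth@pedigree
  sibPhi <- kin$phi[(kin$id1 == ped$offspring[1] &
                       kin$id2 == ped$offspring[2]) |
                      (kin$id1 == ped$offspring[3] &
                         kin$id2 == ped$offspring[4])]
  expect_true(all(sibPhi > 0.20 & sibPhi < 0.30))
  po <- kin[(kin$id1 %in% ped$parent1 & kin$id2 %in% ped$offspring) |
              (kin$id1 %in% ped$offspring & kin$id2 %in% ped$parent1), ]
  poPairs <- po[paste(po$id1, po$id2) %in%
                  c(paste(ped$parent1, ped$offspring),
                    paste(ped$offspring, ped$parent1)), ]
  expect_true(all(poPairs$n_opposite_hom == 0))
  expect_true(all(poPairs$phi > 0.15))
  unrel <- kin[!grepl("sib", kin$id1) & !grepl("sib", kin$id2), ]
  unrel <- unrel[!(unrel$id1 %in% c(ped$parent1, ped$parent2) &
                     unrel$id2 %in% c(ped$parent1, ped$parent2)), ]
  expect_true(stats::quantile(abs(unrel$phi), 0.99) < 0.06)
})
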