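test_that("Hudson/Bhatia components match closed forms", {
  ## fixed difference: alpha/beta = 1
  c1 <- fstComponents(1, 0, 1e6, 1e6)
  expect_equal(c1$alpha / c1$beta, 1, tolerance = 1e-5)
  ## identical intermediate frequencies: negative alpha retained
  c2 <- fstComponents(0.5, 0.5, 20, 20)
  expect_equal(c2$alpha, -2 * 0.25 / 19, tolerance = 1e-12)
  expect_equal(c2$beta, 0.5, tolerance = 1e-12)
  expect_error(fstComponents(0.5, 0.5, 1, 20), ">= 2")
})

test_that("windowed Fst is the ratio of sums and handles toys exactly", {
  comp <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                     alpha = c(0.1, 0.3, -0.1), beta = c(0.2, 0.4, 0.2))
  win <- windowedFst(comp, windowBp = 1000, stepBp = 1000,
                     chromLengths = c("1" = 1000))
  expect_equal(win$fst, 0.3 / 0.8)
  expect_equal(win$n_sites, 3L)
  ## genomewide equals the single spanning window
  gw <- genomewideFst(comp, win)
  expect_equal(gw$fst, 0.375)
  expect_equal(gw$meanWindowFst, 0.375)
})

test_that("ratio-of-sums Fst is invariant to window partitioning", {
  set.seed(4)
  comp <- data.frame(chrom = "1", pos = sort(sample(1e5, 400)),
                     alpha = rnorm(400, 0.01, 0.02),
                     beta = runif(400, 0.1, 0.5))
  gw <- genomewideFst(comp)$fst
  for (wb in c(5000, 20000, 1e5)) {
    win <- windowedFst(comp, wb, wb, c("1" = 1e5))
    ok <- !is.na(win$fst)
    expect_equal(sum(win$n_sites), 400L)
  }
  expect_equal(genomewideFst(comp)$fst, gw)
})

test_that("joint SFS handles degenerate and certain-genotype cases", {
  ## two pops fixed for opposite alleles at every site
  G1 <- matrix(0L, 3, 50); G2 <- matrix(2L, 3, 50)
  saf1 <- safLikelihoods(certainGL(G1))
  saf2 <- safLikelihoods(certainGL(G2))
  sfs2d <- jointSfs(saf1, saf2, tol = 1e-10)
  M <- sfsCounts(sfs2d)
  expect_equal(M[1, 7] / sum(M), 1, tolerance = 1e-6)
  ## EM trace non-decreasing
  expect_true(all(diff(attr(sfs2d, "trace")) > -1e-9))

  ## certain genotypes: equals the joint histogram
  set.seed(12)
  f <- runif(120, 0.1, 0.9)
  Ga <- matrix(rbinom(4 * 120, 2, rep(f, each = 4)), 4, 120)
  Gb <- matrix(rbinom(4 * 120, 2, rep(f, each = 4)), 4, 120)
  sa <- safLikelihoods(certainGL(Ga)); sb <- safLikelihoods(certainGL(Gb))
  s2 <- jointSfs(sa, sb, tol = 1e-10, maxIter = 3000L)
  hist2d <- matrix(0, 9, 9)
  for (s in seq_len(120)) {
    j1 <- sum(Ga[, s]); j2 <- sum(Gb[, s])
    hist2d[j1 + 1, j2 + 1] <- hist2d[j1 + 1, j2 + 1] + 1
  }
  expect_equal(sfsCounts(s2), hist2d, tolerance = 1e-3,
               ignore_attr = TRUE)

  ## mismatched site lists rejected
  expect_error(jointSfs(sa, safLikelihoods(certainGL(Gb[, 1:100]))),
               "site lists")
})

test_that("identical populations concentrate joint-SFS mass near the diagonal", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 16, targetFst = 0,
                   chroms = "1", seqLength = 2e5, meanCoverage = 12,
                   seed = 19)
  truth <- simulateFrequencies(cfg)
  gl <- filterSites(simulateReads(truth), filterConfig())
  fit <- fstFromGL(gl, 1:8, 9:16)
  M <- sfsCounts(fit$sfs2d) / sum(sfsCounts(fit$sfs2d))
  idx <- which(M > 0, arr.ind = TRUE)
  p1 <- (idx[, 1] - 1) / 16; p2 <- (idx[, 2] - 1) / 16
  vals <- M[idx]
  nearDiag <- sum(vals[abs(p1 - p2) <= 0.25])
  expect_gt(nearDiag, 0.9)
  corner <- M[1, 17] + M[17, 1]
  expect_lt(corner, 0.005)
  ## the resulting genomewide Fst is near zero
  expect_lt(abs(genomewideFst(fit$components)$fst), 0.03)
})

test_that("GL-path Fst agrees with a called-genotype oracle at high coverage", {
  cfg <- simConfig(nPops = 2, nDipPerPop = 20, targetFst = 0.1,
                   chroms = "1", seqLength = 4e5, meanCoverage = 30,
                   seed = 23)
  truth <- simulateFrequencies(cfg)
  gl <- filterSites(simulateReads(truth), filterConfig())
  fit <- fstFromGL(gl, 1:20, 21:40)
  glPath <- genomewideFst(fit$components)$fst
  ## oracle: textbook Hudson on independently called genotypes
  keep <- match(GenomicRanges::start(glSites(gl)),
                GenomicRanges::start(truth@sites))
  sameMinor <- S4Vectors::mcols(glSites(gl))$minor ==
    S4Vectors::mcols(truth@sites)$alt[keep]
  G <- truth@genotypes[, keep]
  G[, !sameMinor] <- 2L - G[, !sameMinor]
  oracle <- oracleHudsonFst(G[1:20, , drop = FALSE],
                            G[21:40, , drop = FALSE])
  expect_lt(abs(glPath - oracle), 0.005)
})

test_that("the mode-based outlier rule is exact on the hand toy", {
  w <- data.frame(chrom = "1", start = 0:5 * 1000, end = 1:6 * 1000,
                  fst = c(0.00, 0.01, 0.01, 0.01, 0.02, 0.05))
  out <- designateOutliers(w, minWindows = 1L)
  expect_equal(attr(out, "mode"), 0.01, tolerance = 2e-3)
  expect_equal(attr(out, "threshold"), 0.04, tolerance = 2e-3)
  expect_equal(out$fst[out$is_outlier], 0.05)

  ## all-equal windows: no outliers, with a warning
  wEq <- data.frame(chrom = "1", start = 0:39 * 1000, end = 1:40 * 1000,
                    fst = rep(0.02, 40))
  expect_warning(outEq <- designateOutliers(wEq), "equal")
  expect_false(any(outEq$is_outlier))

  ## too few windows rejected unless relaxed
  expect_error(designateOutliers(w), "minWindows")

  ## invariance to window order
  set.seed(2)
  wBig <- data.frame(chrom = "1", start = 0:199 * 1000,
                     end = 1:200 * 1000,
                     fst = c(rnorm(195, 0.05, 0.01), rep(0.4, 5)))
  o1 <- designateOutliers(wBig)
  shuf <- sample(nrow(wBig))
  o2 <- designateOutliers(wBig[shuf, ])
  expect_equal(attr(o1, "threshold"), attr(o2, "threshold"))
  expect_equal(o1$is_outlier[shuf], o2$is_outlier)
  expect_true(all(o1$fst[o1$is_outlier] > 0.3))
})

test_that("gene intersection reports overlapping genes ranked by peak Fst", {
  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(1000, 3000, 9000), c(2000, 4000, 9500)),
    type = "gene", ID = c("geneA", "geneB", "geneC"))
  w <- data.frame(chrom = "1", start = c(1500, 8900), end = c(2500, 9400),
                  fst = c(0.5, 0.8), is_outlier = c(TRUE, TRUE))
  tab <- intersectGenes(w, genes)
  expect_equal(tab$gene_id, c("geneC", "geneA"))   # sorted by peak Fst
  expect_false("geneB" %in% tab$gene_id)
  expect_equal(tab$peak_fst, c(0.8, 0.5))
  ## nothing flagged: empty table
  w$is_outlier <- FALSE
  expect_equal(nrow(intersectGenes(w, genes)), 0L)
})
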