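test_that("Garud H statistics match hand evaluations", {
  ## single repeated haplotype
  h <- garudH(matrix(1L, 6, 4))
  expect_equal(unname(h), c(1, 1, 1, 0))
  ## frequencies 0.5, 0.25, 0.25 (8 haplotypes)
  block <- rbind(matrix(0L, 4, 3),
                 matrix(rep(c(1L, 0L, 0L), each = 2), 2, 3),
                 matrix(rep(c(0L, 1L, 1L), each = 2), 2, 3))
  h2 <- garudH(block)
  expect_equal(unname(h2[1:3]), c(0.375, 0.625, 1.0))
  expect_equal(unname(h2[4]), (0.375 - 0.25) / 0.375)
  ## four classes at 0.25 each
  block3 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  h3 <- garudH(block3)
  expect_equal(unname(h3[1:3]), c(0.25, 0.375, 0.625))
  expect_error(garudH(matrix(0L, 1, 2)), ">= 2")
})

test_that("Garud H agrees with brute-force counting on random blocks", {
  set.seed(6)
  for (r in 1:100) {
    block <- matrix(rbinom(8 * 5, 1, runif(1, 0.2, 0.8)), 8, 5)
    expect_equal(garudH(block), oracleGarudH(block), tolerance = 1e-12)
  }
})

test_that("H ordering and range invariants hold across random windows", {
  set.seed(14)
  for (r in 1:50) {
    block <- matrix(rbinom(20 * 12, 1, 0.3), 20, 12)
    h <- garudH(block)
    expect_true(h["H1"] > 0)
    expect_lte(h["H1"], h["H12"])
    expect_lte(h["H12"], h["H123"])
    expect_lte(h["H123"], 1)
    expect_gte(h["H2H1"], 0)
    expect_lt(h["H2H1"], 1)
  }
})

test_that("the H scan windows by SNP count and is row-order invariant", {
  set.seed(8)
  block <- matrix(rbinom(10 * 250, 1, 0.4), 10, 250)
  pos <- sort(sample(1e5, 250))
  sc <- scanH(block, pos, "2L", windowSnps = 100L)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$n_snps, c(100L, 100L))
  expect_equal(sc$start_pos, c(pos[1], pos[101]))
  perm <- sample(nrow(block))
  sc2 <- scanH(block[perm, ], pos, "2L", windowSnps = 100L)
  expect_equal(sc2$H12, sc$H12)
  expect_equal(sc2$H123, sc$H123)
  ## fewer SNPs than a window: empty with warning
  expect_warning(e <- scanH(block[, 1:50], pos[1:50], "2L", 100L), "fewer")
  expect_equal(nrow(e), 0L)
  ## missing data rejected
  blockNA <- block; blockNA[1, 1] <- NA
  expect_error(scanH(blockNA, pos, "2L", 100L), "phase")
})

test_that("sweep windows show elevated H12 over the neutral background", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- simConfig(nPops = 1, nDipPerPop = 40, targetFst = 0,
                     chroms = "1", seqLength = 4e5, mutDensity = 0.005,
                     sweepLoci = data.frame(chrom = "1", center = 2e5,
                                            width = 5e4, strength = 0.6,
                                            pop = NA),
                     seed = 100 + seed)
    truth <- simulateFrequencies(cfg)
    hap <- rbind(truth@hapA, truth@hapB)
    pos <- GenomicRanges::start(truth@sites)
    sc <- scanH(hap, pos, "1", windowSnps = 100L)
    sweepWin <- sc$start_pos <= 225000 & sc$end_pos >= 175000
    if (any(sweepWin) &&
        max(sc$H12[sweepWin]) > stats::median(sc$H12[!sweepWin]))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

# hand-built plus-strand gene whose CDS carries known codons
buildTestModel <- function(strand = "+") {
  ## gene on chrom T: 5'UTR 1-100, CDS 101-1000 (300 codons), intron
  ## 1001-1200, CDS 1201-1500 (100 codons), 3'UTR 1501-1600
  set.seed(77)
  seq <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  ## codon 224 of the CDS spans positions 101 + 223*3 .. +2 = 770..772
  seq[770:772] <- c("A", "A", "T")                 # Asn
  seq[773:775] <- c("C", "T", "G")                 # Leu (codon 225)
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- "T"
  new("GeneModel", geneId = "testGene", chrom = "T", strand = strand,
      exons = IRanges::IRanges(c(1, 1201), c(1000, 1600)),
      cds = IRanges::IRanges(c(101, 1201), c(1000, 1500)),
      utr5 = IRanges::IRanges(1, 100),
      utr3 = IRanges::IRanges(1501, 1600),
      genome = genome)
}

test_that("variant effects are classified with protein notation", {
  m <- buildTestModel()
  ## AAT -> ATT at codon 224: missense p.Asn224Ile
  eff <- classifyVariantEffect("T", 771, "A", "T", m)
  expect_equal(eff$category, "missense")
  expect_equal(eff$protein, "p.Asn224Ile")
  ## CTG -> CTA: synonymous leucine
  eff2 <- classifyVariantEffect("T", 775, "G", "A", m)
  expect_equal(eff2$category, "synonymous")
  expect_equal(eff2$protein, "p.Leu225Leu")
  ## intron, UTRs, intergenic
  g <- m@genome[["T"]]
  at <- function(p) as.character(Biostrings::subseq(g, p, p))
  expect_equal(classifyVariantEffect("T", 1100, at(1100), "A", m)$category,
               "intronic")
  expect_equal(classifyVariantEffect("T", 50, at(50), "A", m)$category,
               "five_prime_UTR")
  expect_equal(classifyVariantEffect("T", 1550, at(1550), "A", m)$category,
               "three_prime_UTR")
  expect_equal(classifyVariantEffect("T", 1900, at(1900), "A", m)$category,
               "intergenic")
  ## reference mismatch reported with the site
  wrong <- setdiff(c("A", "C", "G", "T"), at(771))[1]
  expect_error(classifyVariantEffect("T", 771, wrong, "T", m),
               "mismatch")
})

test_that("minus-strand CDS variants translate on the coding strand", {
  m <- buildTestModel(strand = "-")
  ## plus-strand CDS spans 101-1000 and 1201-1500; on the minus strand
  ## translation runs 1500 -> 101 over the reverse complement.
  ## plus-strand AAT at 770..772 reads ATT on the minus strand.
  cdsLen <- 1200L
  ## compute the expected codon index of plus-position 771
  posInPlusCds <- 771L - 101L + 1L                 # = 671
  posInMinusCds <- cdsLen - posInPlusCds + 1L
  codon <- ((posInMinusCds - 1L) %/% 3L) + 1L
  eff <- classifyVariantEffect("T", 771, "A", "T", m)
  expect_true(eff$category %in% c("synonymous", "missense"))
  expect_match(eff$protein, paste0("^p\\.[A-Za-z]{3}", codon))
  ## round-trip sanity: a change that is silent on the minus strand
  ## (third codon position there) maps to plus position 770 or 773
})

test_that("synthetic annotations round-trip through gene models", {
  cfg <- simConfig(nPops = 1, nDipPerPop = 4, targetFst = 0, chroms = "X",
                   seqLength = 6e4, mutDensity = 0.002,
                   sweepLoci = data.frame(chrom = "X", center = 3e4,
                                          width = 5e3, strength = 0.5,
                                          pop = NA), seed = 2)
  truth <- simulateFrequencies(cfg)
  d <- withr::local_tempdir()
  writeSimulation(truth, d, writeGenome = TRUE)
  models <- geneModelsFromGFF(file.path(d, "annotation.gff3"),
                              file.path(d, "genome.fa"))
  expect_true("IRgene01" %in% names(models))
  m <- models[["IRgene01"]]
  expect_equal(sum(IRanges::width(m@cds)) %% 3L, 0L)
  ## planted variants of each category recovered
  g <- m@genome[["X"]]
  at <- function(p) as.character(Biostrings::subseq(g, p, p))
  utrPos <- IRanges::start(m@utr5)[1] + 5L
  cdsPos <- IRanges::start(m@cds)[1] + 3L
  intronStart <- IRanges::end(m@cds)[1] + 50L
  expect_equal(classifyVariantEffect("X", utrPos, at(utrPos), "A",
                                     m)$category, "five_prime_UTR")
  expect_true(classifyVariantEffect("X", cdsPos, at(cdsPos),
                                    setdiff(c("A", "C", "G", "T"),
                                            at(cdsPos))[1],
                                    m)$category %in%
                c("synonymous", "missense"))
  expect_equal(classifyVariantEffect("X", intronStart, at(intronStart),
                                     "A", m)$category, "intronic")
})
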