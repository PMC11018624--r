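# internal helpers shared across modules

# order sites by (chrom, pos) with chromosomes in first-appearance order
siteOrder <- function(gr) {
  chr <- as.character(seqnames(gr))
  order(match(chr, unique(chr)), start(gr))
}

# per-row maximum of a matrix without apply() overhead
rowMax <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

# linear-scale GL array from a normalized log-scale array
linearGL <- function(gl) {
  a <- exp(gl)
  a[is.na(a)] <- 0
  a
}

# flat (missing) individual-site indicator: sites x individuals logical
glMissing <- function(gl) {
  m <- gl[, , 1] == 0 & gl[, , 2] == 0 & gl[, , 3] == 0
  matrix(m, nrow = dim(gl)[1], ncol = dim(gl)[2])
}

# draw m values with density proportional to 1/f on [lo, hi]
rInvFreq <- function(m, lo, hi) lo * (hi / lo)^stats::runif(m)

# Balding-Nichols Beta draw around ancestral frequency f at divergence F
rBaldingNichols <- function(f, F) {
  if (F <= 0) return(f)
  a <- f * (1 - F) / F
  b <- (1 - f) * (1 - F) / F
  stats::rbeta(length(f), a, b)
}

# 0-based half-open windows covering [0, len); returns data.frame(start, end)
slidingWindows0 <- function(len, windowBp, stepBp) {
  starts <- seq(0, max(0, len - 1), by = stepBp)
  starts <- starts[starts < len]
  data.frame(start = starts, end = pmin(starts + windowBp, len))
}

# deterministic child seed derived from a base seed (kept well below 2^31)
childSeed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k) %% 2147483399)

`%||%` <- function(a, b) if (is.null(a)) b else a
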