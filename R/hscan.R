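#' Garud's haplotype-homozygosity statistics
#'
#' Distinct haplotype strings are counted and their frequencies sorted
#' descending, \eqn{p_1 \ge p_2 \ge \dots}. Then
#' \eqn{H_1 = \sum p_i^2},
#' \eqn{H_{12} = (p_1+p_2)^2 + \sum_{i \ge 3} p_i^2},
#' \eqn{H_{123} = (p_1+p_2+p_3)^2 + \sum_{i \ge 4} p_i^2}, and
#' \eqn{H_2/H_1 = (H_1 - p_1^2)/H_1}. With fewer than three distinct
#' haplotypes the absorbed classes have frequency 0.
#'
#' @param block haplotypes x SNPs binary matrix (rows are phased
#'   haplotypes).
#' @return named numeric: H1, H12, H123, H2H1.
#' @examples
#' # frequencies 0.5 / 0.25 / 0.25
#' block <- rbind(matrix(0, 2, 3), c(1, 0, 0), c(0, 1, 1))
#' garudH(block)
#' @export
garudH <- function(block) {
  if (is.null(dim(block)) || nrow(block) < 2L || ncol(block) < 1L)
    stop("need >= 2 haplotypes and >= 1 SNP")
  keys <- do.call(paste0, as.data.frame(block))
  p <- sort(as.vector(table(keys)) / nrow(block), decreasing = TRUE)
  p3 <- c(p, 0, 0, 0)[1:max(3L, length(p))]
  H1 <- sum(p^2)
  H12 <- (p3[1] + p3[2])^2 + sum(p3[-(1:2)]^2)
  H123 <- (p3[1] + p3[2] + p3[3])^2 + sum(p3[-(1:3)]^2)
  c(H1 = H1, H12 = H12, H123 = H123, H2H1 = (H1 - p3[1]^2) / H1)
}

#' Scan Garud's H statistics in fixed-SNP-count windows
#'
#' Consecutive windows of exactly \code{windowSnps} SNPs advancing by
#' \code{stepSnps} (default non-overlapping); a trailing partial window
#' is dropped. Input must be fully phased; windows with missing entries
#' are rejected with a message directing users to phase upstream.
#'
#' @param block haplotypes x SNPs binary matrix.
#' @param positions SNP bp positions (strictly increasing).
#' @param chrom chromosome label attached to the output.
#' @param windowSnps,stepSnps window size and step in SNPs.
#' @return data.frame(chrom, start_pos, end_pos, n_snps, H1, H12, H123,
#'   H2H1); empty (with a warning) when fewer SNPs than one window.
#' @export
scanH <- function(block, positions, chrom = "chr", windowSnps = 100L,
                  stepSnps = windowSnps) {
  stopifnot(ncol(block) == length(positions))
  if (any(is.na(block)))
    stop("unphased/missing entries present; phase haplotypes upstream")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  nSnp <- ncol(block)
  if (nSnp < windowSnps) {
    warning("fewer SNPs than one window; empty scan")
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      H1 = numeric(), H12 = numeric(), H123 = numeric(),
                      H2H1 = numeric()))
  }
  starts <- seq(1L, nSnp - windowSnps + 1L, by = stepSnps)
  res <- lapply(starts, function(s) {
    idx <- s:(s + windowSnps - 1L)
    h <- garudH(block[, idx, drop = FALSE])
    data.frame(chrom = chrom, start_pos = positions[idx[1]],
               end_pos = positions[idx[length(idx)]],
               n_snps = windowSnps, H1 = h["H1"], H12 = h["H12"],
               H123 = h["H123"], H2H1 = h["H2H1"])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build gene models from a GFF3 annotation and genome sequence
#'
#' One single-transcript model per gene: exon, CDS and UTR intervals
#' grouped under the gene's transcript, with the chromosome sequence
#' attached for codon extraction.
#'
#' @param gff GFF3 path or imported GRanges.
#' @param genome a Biostrings DNAStringSet (or FASTA path) with the
#'   chromosome sequences.
#' @return named list of [GeneModel] objects.
#' @export
geneModelsFromGFF <- function(gff, genome) {
  if (is.character(gff)) gff <- rtracklayer::import(gff, format = "gff3")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- gff[mcols(gff)$type == "gene"]
  ids <- as.character(mcols(genes)$ID)
  models <- lapply(seq_along(genes), function(i) {
    gid <- ids[i]
    isChildOfGene <- vapply(mcols(gff)$Parent, function(p)
      any(p == gid), TRUE)
    tx <- gff[isChildOfGene & mcols(gff)$type == "mRNA"]
    tid <- if (length(tx)) as.character(mcols(tx)$ID)[1] else gid
    kids <- gff[vapply(mcols(gff)$Parent, function(p)
      any(p %in% c(tid, gid)), TRUE)]
    pick <- function(type) {
      k <- kids[mcols(kids)$type == type]
      IRanges(start(k), end(k))
    }
    new("GeneModel", geneId = gid,
        chrom = as.character(seqnames(genes))[i],
        strand = as.character(GenomicRanges::strand(genes))[i],
        exons = pick("exon"), cds = pick("CDS"),
        utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"),
        genome = genome)
  })
  stats::setNames(models, ids)
}

# three-letter amino-acid code, with * for stop
aaThree <- function(aa) {
  code <- Biostrings::AMINO_ACID_CODE
  out <- unname(code[aa])
  out[aa == "*"] <- "Ter"
  out
}

#' Classify the functional effect of a SNP against a gene model
#'
#' Positions are mapped against the UTR/exon/intron/CDS structure
#' (strand-aware); CDS variants are translated with the standard codon
#' table and reported as synonymous or missense with
#' \code{p.RefPosAlt} three-letter notation. Positions outside the gene
#' are intergenic; inside the gene but outside exons, intronic.
#'
#' @param chrom,pos,ref,alt the variant (pos 1-based; ref/alt on the
#'   plus strand of the genome).
#' @param model a [GeneModel].
#' @return list(category, protein) where category is one of
#'   five_prime_UTR, three_prime_UTR, intronic, synonymous, missense,
#'   intergenic and protein is e.g. "p.Asn224Ile" for coding variants.
#' @export
classifyVariantEffect <- function(chrom, pos, ref, alt, model) {
  inRange <- function(rng) length(rng) > 0L &&
    any(pos >= start(rng) & pos <= end(rng))
  span <- if (length(model@exons)) model@exons else model@cds
  if (chrom != model@chrom ||
      !(pos >= min(start(span)) && pos <= max(end(span))))
    return(list(category = "intergenic", protein = NA_character_))
  chromSeq <- model@genome[[model@chrom]]
  refGenome <- as.character(Biostrings::subseq(chromSeq, pos, pos))
  if (refGenome != ref)
    stop(sprintf("reference mismatch at %s:%d (model %s, variant %s)",
                 chrom, pos, refGenome, ref))
  if (inRange(model@cds)) {
    cds <- model@cds[order(start(model@cds))]
    seqs <- lapply(seq_along(cds), function(i)
      as.character(Biostrings::subseq(chromSeq, start(cds)[i], end(cds)[i])))
    cdsSeq <- paste(unlist(seqs), collapse = "")
    offsets <- cumsum(c(0L, width(cds)))
    seg <- which(pos >= start(cds) & pos <= end(cds))
    posInCds <- offsets[seg] + (pos - start(cds)[seg]) + 1L
    altSeq <- cdsSeq
    substr(altSeq, posInCds, posInCds) <- alt
    if (model@strand == "-") {
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      cdsSeq <- rc(cdsSeq); altSeq <- rc(altSeq)
      posInCds <- nchar(cdsSeq) - posInCds + 1L
    }
    codonIdx <- (posInCds - 1L) %/% 3L
    refCodon <- substr(cdsSeq, 3L * codonIdx + 1L, 3L * codonIdx + 3L)
    altCodon <- substr(altSeq, 3L * codonIdx + 1L, 3L * codonIdx + 3L)
    ## no.init.codon: a codon extracted mid-CDS is never an initiator
    tr <- function(cod) as.character(
      Biostrings::translate(Biostrings::DNAString(cod),
                            no.init.codon = TRUE))
    refAA <- tr(refCodon); altAA <- tr(altCodon)
    if (refAA == altAA)
      return(list(category = "synonymous",
                  protein = sprintf("p.%s%d%s", aaThree(refAA),
                                    codonIdx + 1L, aaThree(altAA))))
    return(list(category = "missense",
                protein = sprintf("p.%s%d%s", aaThree(refAA),
                                  codonIdx + 1L, aaThree(altAA))))
  }
  utr5 <- model@utr5; utr3 <- model@utr3
  if (length(utr5) && inRange(utr5))
    return(list(category = "five_prime_UTR", protein = NA_character_))
  if (length(utr3) && inRange(utr3))
    return(list(category = "three_prime_UTR", protein = NA_character_))
  list(category = "intronic", protein = NA_character_)
}

#' Tabulate effects for a set of variants over gene models
#'
#' A minimal SNPEff-like report: each variant is classified against the
#' gene model it falls in (intergenic when none).
#'
#' @param variants data.frame(chrom, pos, ref, alt).
#' @param models list of [GeneModel] (from [geneModelsFromGFF()]).
#' @return the input with \code{gene_id}, \code{category},
#'   \code{protein} columns.
#' @export
variantEffects <- function(variants, models) {
  spans <- do.call(rbind, lapply(models, function(m) data.frame(
    gene = m@geneId, chrom = m@chrom,
    start = min(start(m@exons)), end = max(end(m@exons)))))
  res <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- which(spans$chrom == v$chrom & v$pos >= spans$start &
                   v$pos <= spans$end)
    if (!length(hit))
      return(data.frame(v, gene_id = NA_character_,
                        category = "intergenic", protein = NA_character_))
    eff <- classifyVariantEffect(v$chrom, v$pos, v$ref, v$alt,
                                 models[[hit[1]]])
    data.frame(v, gene_id = spans$gene[hit[1]], category = eff$category,
               protein = eff$protein)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
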