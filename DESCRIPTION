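Package: poplik
Title: Genotype-Likelihood Population Genomics for Low-Coverage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genomic inference from low-coverage whole-genome
    sequencing without hard genotype calls. Computes diallelic genotype
    likelihoods from read pileups with ANGSD-style site and individual
    filters, estimates folded site-frequency spectra by EM from site
    allele-frequency likelihoods, and derives nucleotide diversity,
    Watterson's theta, Tajima's D and Ne. Provides windowed Hudson/Bhatia
    Fst genome scans with mode-based outlier-window designation and gene
    intersection, Garud's H1/H12/H123 selective-sweep scans on phased
    haplotypes, genotype-likelihood PCA and admixture-proportion EM,
    KING-robust kinship with inversion masking, and Mantel tests and
    correlograms for isolation by distance. Includes a synthetic-data
    generator (Balding-Nichols differentiation, selective sweeps, sib
    pairs, Poisson low-coverage reads) so the whole pipeline is testable
    end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
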