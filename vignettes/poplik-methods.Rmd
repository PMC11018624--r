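---
title: "Genotype-likelihood population genomics with poplik: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-likelihood population genomics with poplik}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poplik` analyses low-coverage whole-genome sequencing without hard
genotype calls. This vignette is the package's account of its models and
the design decisions behind them: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the known
limitations lie. No empirical numbers are quoted here beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## 1. The genotype-likelihood model

At a diallelic site with alleles $a_1$ (major) and $a_2$ (minor), the
likelihood of the genotype carrying $g \in \{0,1,2\}$ copies of the
minor allele is the samtools-style product over reads

$$L(g) = \prod_i \Big[\tfrac{g}{2}\,P(b_i \mid a_2) +
 \big(1-\tfrac{g}{2}\big)\,P(b_i \mid a_1)\Big],\qquad
P(b \mid a) = \begin{cases}1-e_i & b=a\\ e_i/3 & b \ne a\end{cases}$$

with $e_i = 10^{-q_i/10}$ from the phred base quality. GLs are stored
log-scaled and per-individual max-normalized (the maximum of a triplet
is exactly 0); a missing individual-site is the flat triplet $(0,0,0)$,
which contributes only a constant to every downstream likelihood.
Assumptions: independent reads, symmetric base errors, no
mapping-quality weighting, no BAQ — the standard trade-offs of the GL
model family.

**Major/minor orientation.** The minor allele is defined by the
maximum-likelihood allele frequency (EM under Hardy–Weinberg
proportions): if the estimated frequency of the second allele exceeds
0.5, triplets and labels are swapped. This is a convention, not an
inference about ancestral state; all spectra downstream are folded.

**Allele-frequency EM.** The EM maximizing
$\sum_i \log \sum_g L_i(g)\,\mathrm{HWE}(g\mid f)$ runs to
$|\Delta f| < 10^{-8}$ with a 500-iteration cap and from three starts
(0.2, 0.5, 0.9), keeping the best likelihood per site. Two numerical
facts force this design: near-flat likelihoods make EM converge
sublinearly (a 100-iteration cap leaves errors of order $10^{-2}$), and
the HWE mixture likelihood can be multimodal for unusual GL triplets,
so a single start can land on the wrong mode. With these settings the
EM agrees with a $10^{-4}$-step grid search to better than $10^{-3}$
(tested).

**Filters.** The site filters mirror the ANGSD idiom and their defaults
are the field-standard values: total across-individual depth ≤ 6000
reads (catastrophic-mapping guard), base quality ≥ 30, ≥ 25% of
individuals with data, polymorphism likelihood-ratio p ≤ 0.05 against
$\chi^2_1$ (no boundary correction — the ANGSD convention; conservative
and anticonservative effects partially cancel and the test is only used
as a screen), and minor-allele frequency ≥ 0.05. The polymorphism,
depth and MAF rules are switched off for the diversity path, where
monomorphic sites must be retained so that window denominators are
meaningful. Filters are applied per analysis stratum (species ×
ecoregion), matching the per-population GL-calling convention;
individuals missing more than 25% of sites (strictly) are removed.

## 2. SAF, SFS and diversity

The site allele-frequency (SAF) likelihood of a population minor-allele
count $j$ among $2N$ chromosomes marginalizes genotypes under
hypergeometric allele assignment. It is computed by convolving
per-individual triplets weighted by genotype multiplicity $(1,2,1)$ and
dividing class $j$ by $\binom{2N}{j}$ — algebraically identical to the
brute-force sum over all $3^N$ genotype vectors, which the tests verify
for $N \le 4$ at $10^{-8}$. The convolution is carried out on all sites
simultaneously with periodic per-site rescaling to avoid underflow.

The SFS is estimated by EM over the simplex
($\max \sum_s \log \sum_j \mathrm{SFS}_j\,\mathrm{SAF}_s(j)$,
realSFS-style), folded at the SAF level by summing symmetric classes
before the EM; convergence at a log-likelihood gain below $10^{-6}$ or
500 iterations. The EM trace is non-decreasing (asserted in tests). One
caveat discovered in development and worth recording: with a *single*
site the ML solution is degenerate (all mass on the best-supported
class); the "SFS proportional to the site's SAF" intuition describes the
first EM step from a uniform start, not the optimum, and the tests
assert exactly that.

Per-site diversity uses the empirical-Bayes posterior
$P(j) \propto \mathrm{SFS}_j\,\mathrm{SAF}(j)$:
$E[\pi] = \sum_j P(j)\,2j(2N-j)/(2N(2N-1))$ and
$E[S] = P(\text{segregating})$, with $\theta_W = E[S]/a_1$. Windows
(default 10 kb / 5 kb step, 0-based half-open BED convention) sum
per-site expectations; Tajima's D uses the window totals with the
standard 1989 constants. Because no hard calls exist at low coverage,
$S$ is an *expected* count; windows where it is numerically zero
(< $10^{-8}$) report D as missing rather than 0. Both per-window D and
a genome-wide D from totals are reported, since either convention is
defensible. $N_e = \theta/(4\mu)$ requires a mutation rate; there is no
authoritative default for the target taxa, so `runConfig(mu = 3.5e-9)`
is an explicit, documented choice the user should override.

## 3. Differentiation and outlier windows

The 2D SFS is estimated by the same EM over the
$(2N_1+1)\times(2N_2+1)$ simplex, on SAFs sharing one site list and one
minor-allele polarization (folding would destroy the allele identity
Fst needs). Per-site frequencies are posterior means under that prior,
entering the Hudson estimator in Bhatia's formulation:

$$\alpha = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1},\qquad \beta = p_1(1-p_2)+p_2(1-p_1)$$

Window and genome-wide Fst are ratios of sums ($\sum\alpha/\sum\beta$),
which makes the genome-wide value invariant to window partitioning
(tested). Negative $\alpha$ is retained — clipping would bias the
threshold-relative outlier rule. Hudson is the default estimator
because it is robust to unequal sample sizes; the outlier rule is
threshold-relative, so the estimator choice mainly shifts the whole
distribution.

**Outlier rule.** With $d = \mathrm{mode} - \min$, windows with
$F_{st} > \mathrm{mode} + 3d$ on the right-hand side of the
distribution are flagged. The mode of a continuous-valued sample is not
well defined by a histogram (bin-width sensitivity), so it is estimated
deterministically by a Gaussian KDE with Silverman's bandwidth on a
512-point grid over $[\min,\max]$. Each population comparison gets its
own threshold, computed genome-wide by default (a per-chromosome option
exists); elevated-differentiation blocks such as inversions are
included by default, with a masking option. A minimum window count
(default 30) guards against meaningless modes. Genes are intersected
with outlier windows by ≥ 1 bp overlap (GFF3 1-based coordinates
converted to the BED convention internally) and ranked by peak window
Fst; picking "the" causal gene inside a peak remains a judgement call
and is deliberately not automated.

## 4. Sweeps and variant effects

Garud's statistics are computed on phased haplotypes in fixed-SNP
windows (default 100 SNPs, non-overlapping; step is configurable —
window-sized steps are the common scan default). $H_1 = \sum p_i^2$,
$H_{12}$ and $H_{123}$ pool the top two or three haplotype classes.
Missing or unphased entries are rejected with a pointer to phase
upstream — statistical phasing is out of scope. The effect classifier
handles single-transcript gene models: strand-aware codon extraction,
standard-table translation (with `no.init.codon`, since an extracted
codon is never an initiator — a subtle Biostrings default discovered in
testing), three-letter `p.Asn224Ile` notation, and UTR/intron/intergenic
categories by interval containment.

## 5. Structure and kinship

PCA uses the standardized GL covariance
$C_{ij} = S^{-1}\sum_s (E[g_{is}]-2f_s)(E[g_{js}]-2f_s)/(2f_s(1-f_s))$
with posterior-mean dosages, in the single-pass mode (fixed per-site
frequencies); an optional iterated mode re-estimates individual
frequencies from the top PCs. Monomorphic sites are excluded (the
denominator vanishes). Admixture proportions come from the
genotype-likelihood admixture model
$P(\text{data}_{is}) = \sum_g L_{is}(g)\binom{2}{g}\pi_{is}^g
(1-\pi_{is})^{2-g}$, $\pi = QF^\top$, fitted by EM with Dirichlet(1)
initial $Q$, frequency-jitter initial $F$, best of three seeded starts,
convergence at $\Delta\ell < 10^{-6}$ or 2000 iterations. The
log-likelihood is non-decreasing and $K=1$ reduces analytically to the
per-site ML frequencies (both tested).

Kinship uses hard calls (posterior argmax at an HWE prior, ≥ 0.95
posterior, else missing) rather than full GL integration — a documented
simplification; the kinship acceptance checks run on truth genotypes,
and at the pipeline's default coverage calls are nearly always
confident. KING-robust $\phi$ is computed per pair over mutually
non-missing sites, with inversion-like intervals masked first (inversion
polymorphism mimics relatedness). Relationship classes use KING's
powers-of-two bins, with first-degree pairs split into full sibs
(opposite homozygotes present) versus parent–offspring (essentially
none); on noisy calls a small opposite-homozygote count can mislabel a
parent–offspring pair as sibs — a known limitation at low coverage.

## 6. Isolation by distance

Geographic distances are WGS84 geodesics (`geosphere::distGeo`). The
Mantel test and correlogram are delegated to `vegan` (the package this
analysis family standardly uses): one-sided greater permutation test
with $p = (1+\#\{r^* \ge r\})/(1+n_{perm})$, and per-distance-class
indicator Mantel statistics with progressive Holm correction. Kinship
is converted to a distance as $0.5 - \phi$ (negative $\phi$ kept
as-is); classes with fewer than 10 pairs are flagged low-support.
Because the class indicators partition all pairs, a genuine short-range
similarity excess necessarily produces negative statistics in distant
classes — interpretation should focus on significantly *positive*
short-distance classes.

## 7. The synthetic-data generator

The generator emulates the structure of a two-species, multi-ecoregion
low-coverage field study: hierarchical Balding–Nichols differentiation
(species-level $F$ around a shared ancestral frequency, then
ecoregion-level $F$ within species), localized haplotype-copying
sweeps, one contiguous block with an elevated Beta variance parameter
(an "inversion" in its differentiation signature only), full-sib pairs
by Mendelian transmission with free recombination between SNPs, and
Poisson-depth reads with constant phred-scaled errors. Geographic
sampling sites sit on a grid spanning roughly 300 km with individuals
assigned round-robin — a stand-in layout, since real per-site
coordinates are study-specific; frequencies carry no explicit spatial
autocorrelation, so any IBD signal in the default study arises from the
spatial nesting of ecoregion strata.

**Ancestral frequencies.** Frequencies are drawn with density
$\propto 1/f$ — the neutral-SFS shape — truncated to
`freqRange = c(0.001, 0.999)`. The truncation bound matters more than
it looks: cutting at 0.05 removes the rare-variant classes entirely and
drives neutral Tajima's D to roughly +2, while a 0.001 bound reproduces
the neutral $1/j$ sample spectrum and mean D near 0 (established by a
true-genotype Monte-Carlo oracle before the estimators were built).
The default is therefore 0.001, exposed as a parameter.

**Sweep model.** A fraction `strength` of the target populations'
haplotypes in the window is replaced by copies of one randomly chosen
haplotype. This produces exactly the haplotype-homozygosity signal
H12/H123 measure, at a fraction of the cost of forward simulation; it
does not produce the flanking LD shoulders or the site-frequency skew
of a real sweep, so passing tests demonstrate sensitivity to haplotype
structure, not calibrated power on real sweeps. Sweeps are applied to
founders *before* sib transmission so pedigrees stay
Mendelian-consistent.

**Default study conditions** (`defaultStudyConfig()`): 2 species × 3
ecoregions × 12 diploids, within-species $F = 0.01$ and species-level
$F = 0.10$ (differentiation of the order seen between conspecific
ecoregions and between sibling species respectively), 3 chromosomes of
400 kb at 0.005 SNPs/bp, one species-wide sweep per species on the
X-like chromosome (strength 0.8), a 60-kb inversion block with
$+0.08\,F$ on 2L, 2 sib pairs, 14× coverage (the order of a typical
field study's median), Q30 errors. These sizes keep the full pipeline
under a couple of minutes on one CPU while leaving every signal
detectable; the acceptance analyses additionally use 50-diploid /
2-Mb neutral runs, 2 × 40-diploid / 5000-SNP Fst grids, and 500-replicate
Mantel calibrations.

## 8. What the generator does not emulate

Mapping artefacts, indels, multi-allelic sites, base-quality
recalibration structure, linkage disequilibrium beyond sweeps and
pedigree transmission, coalescent noise in the SFS (frequencies are
drawn i.i.d. across sites), and real phasing error (haplotypes are
emitted pre-phased; the pipeline accepts phased input and rejects
missingness). Results on synthetic data therefore validate the
estimators and their numerics, not the upstream read-processing
choices of any particular study.

## 9. Numerical conventions

Log-space throughout with max-subtraction; SAF convolution rescaled
every 8 individuals; EM tolerances as stated above ($10^{-8}$ allele
frequency, $10^{-6}$ SFS/2D-SFS/admixture log-likelihood);
haplotype-frequency ties broken lexicographically (H statistics depend
only on the multiset, so this affects nothing); window coordinates
0-based half-open everywhere, GFF3 converted on input; all stochastic
steps take explicit seeds, and a fixed configuration reproduces every
output byte-identically (tested).
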