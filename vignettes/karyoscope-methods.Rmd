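---
title: "Methods: chromosome painting, sex-chromosome inference and the synthetic genome generator"
author: "karyoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome painting and sex-chromosome inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscope)
```

# Scope and scientific background

Most nematodes determine sex by counting X chromosomes (XX females / X0
males), yet some filarial lineages carry heteromorphic XX/XY karyotypes.
Karyotype evidence suggests these Y chromosomes are not ancient,
gene-poor sex chromosomes but *neo-Y* chromosomes: when an X fuses with
an autosome, the unfused autosomal homologue becomes male-limited and
starts behaving as a Y. `karyoscope` implements the genomic analyses
that test this model on chromosome-level assemblies:

1. **Nigon painting** — assigning conserved single-copy orthologs
   (BUSCO markers) to the seven ancestral rhabditid linkage groups
   ("Nigon elements" A, B, C, D, E, N, X) and counting them in windows,
   to read each chromosome's ancestral composition and detect fusions.
2. **Sex-chromosome inference** — classifying chromosome ploidy per
   sex from windowed read depth normalised by the autosomal median, and
   identifying the X as the chromosome haploid in males.
3. **Shared-region calling** — finding the part of the X that is still
   diploid in males (covered by an alignable Y copy), using a
   ratio/merge/length rule on 100 kb bins.
4. **Divergence summaries** — windowed heterozygous SNP density in
   males, which measures X–Y gametolog divergence inside the shared
   region, plus alignment coverage and length-weighted identity of Y
   contigs against the X.
5. **Sequence features** — telomere-repeat counting and capped-end
   detection, softmask repeat density, and assembly metrics (span, N50,
   QV-to-error-spacing).
6. **A synthetic-data generator** that emulates all of these signals
   with known ground truth, so the full pipeline is testable without
   any sequencing data.

The package does not assemble genomes, call variants, align reads or
annotate repeats; it consumes the standard outputs of those tools
(FASTA, BUSCO full tables, windowed-depth bedGraph, VCF, alignment
tables) and implements the downstream comparative analyses.

# Coordinate conventions

In memory, every interval is a `GRanges` and therefore 1-based and
closed, the Bioconductor convention; all interval arithmetic goes
through `GenomicRanges`/`IRanges`. On disk, BED and bedGraph files are
0-based half-open, and `rtracklayer` performs the conversion in both
directions, so round-trips are exact. Window membership of a point
feature (a marker start, a SNP) follows half-open bin semantics: with
500 kb windows, a feature at 0-based position 500,000 belongs to the
second window. Human-readable region strings are rendered 1-based
inclusive (`chrX:22,300,001-24,943,668`), the style used in assembly
reports; note that a printed 0-based pair such as 22,300,000–24,943,668
denotes the same interval.

# Window grids

`makeWindows()` tiles each chromosome end to end with non-overlapping
windows of a nominal size; the final window per chromosome may be
short and is kept, because depth values are per-base means and
therefore remain comparable across window lengths. The analyses use the
window sizes their signals warrant: 100 kb for coverage and shared-region
bins, 500 kb for painting histograms, 50 kb for SNP density and
alignment coverage, 200 kb for repeat density, and 1 kb for telomere
motif counts.

# Nigon painting

`assignNigon()` labels markers with elements from an external
marker-to-element table; the element definitions themselves are an
input, not something the package re-derives. Fragmented BUSCO
placements are excluded from painting by default (their coordinates are
unreliable and their status is ambiguous); duplicated placements are
retained, each copy counting once, because duplication rates in the
assemblies this workflow targets are well under 1% and the choice is
configurable. A marker is binned by the window containing its start
coordinate — a single deterministic rule rather than a midpoint
convention.

`detectFusions()` calls a chromosome's ancestral components as every
element contributing at least 5% of its assigned markers *and* at least
10 markers. Both thresholds exist to ignore isolated mis-assigned
markers, which appear as stray colours on painted chromosomes; both are
arguments.

## Quantifying intermixing

Whether two fused partitions have blended is quantified with a
Wald–Wolfowitz runs statistic on the ordered element labels along the
chromosome: with $n_1$ and $n_2$ markers of the two elements, the
expected run count under random arrangement is
$E[R] = 1 + 2 n_1 n_2 / (n_1 + n_2)$ with variance
$\sigma^2 = \frac{2 n_1 n_2 (2 n_1 n_2 - n)}{n^2 (n - 1)}, \; n = n_1 + n_2,$
and $z = (R - E[R])/\sigma$. A fresh, un-rearranged fusion gives
exactly two runs and a strongly negative $z$ ("partitioned");
$|z| < 1.96$ is reported as "intermixed". The expected-runs formula is
verified in the test suite against exhaustive enumeration of all
orderings for $n \le 8$.

# Coverage normalisation and ploidy

Normalised coverage is $N = \text{depth} / \text{median autosomal
depth}$, so diploid regions sit at $N = 1$ and haploid regions at
$N = 0.5$. Because the divisor excludes the X but the X is not known a
priori, `inferX()` runs two passes: a provisional normalisation by the
global median over all windows identifies candidate X chromosomes
(haploid in all males), and a second pass recomputes the divisor over
autosomes only. The provisional pass is stable because the X
contributes a minority of windows and the median is robust.

Ploidy calls use median $N$ per chromosome with thresholds at 0.3 /
0.75 / 1.3 — midpoints between the expected haploid (0.5) and diploid
(1.0) levels, with slack on both sides; values outside the bands are
"ambiguous". All three thresholds are exposed as arguments.

A female X may legitimately sit below $N = 1$: gravid females of
viviparous filarial species carry many embryos of both sexes in utero,
and male embryos contribute haploid-X DNA. With embryo DNA fraction
$e$ and a 1:1 embryo sex ratio, the expected female X coverage is
$1 - e/4$ relative to autosomes — 0.8 at $e = 0.8$. The X caller does
not assume this dilution; it only tolerates it.

# Calling X–Y shared regions

The shared region is defined as a large, semi-contiguous region of the
X where no bins are female-dominated. Each 100 kb bin of the X is
classified as:

* **masked** if both sexes have $N$ below `lowCoverageN` (default
  0.25) — too little data to classify; this mechanises the manual
  exclusion of low-coverage intervals and is reported separately when a
  masked run exceeds the merge gap;
* **female-dominated** if the male-to-female $N$ ratio is below
  `ratioThreshold` (default 0.8); a bin with zero female coverage but
  adequate male coverage is *not* female-dominated (the ratio is
  effectively infinite);
* **qualifying** otherwise.

Qualifying bins separated by runs of non-qualifying bins spanning at
most `mergeGap` (default 200 kb, inclusive at exactly 200 kb) are
merged; merged intervals are trimmed to their first and last qualifying
bins and retained when at least `minRegionLength` long (default 1 Mb,
inclusive — where a verbal definition wavers between "greater than" and
"at least", the inclusive reading is used). Gap span is the summed
length of the skipped bins. The caller is verified against a
brute-force search over every candidate interval satisfying the
boundary/gap/length predicates, exhaustively for short classification
vectors and on random vectors of length 30. Region sizes are reported
in Mb rounded half-up to one decimal (`regionLengthMb()`), matching how
such regions are quoted; note that base R's `round()` is
round-half-even and is deliberately not used here.

# Divergence

In males, X–Y divergence inside the shared region is visible as
heterozygous SNPs: reads from the X and Y copies of formerly allelic
loci pile onto the X reference. `readHetSnps()` therefore keeps exactly
the biallelic single-nucleotide records with heterozygous genotypes,
dropping any record whose FILTER field contains the `RefCall` token
(matched as a whole, case-sensitive token — the label emitted by the
variant caller for non-variant sites). Density uses 50 kb windows;
region summaries report mean density and its reciprocal as "1 SNP every
N bp", N rounded half-up to an integer with thousands separators.

Y-contig alignments against the X are pre-filtered to one-to-one
alignments of at least 1 kb (inclusive). Windowed alignment coverage
uses the *union* of target intervals so overlaps are not
double-counted, while the length-weighted mean identity
$\sum_i p_i \ell_i / \sum_i \ell_i$ lets every alignment contribute its
full length — two deliberately separate summaries.

# Sequence features

Telomere counting scans for the nematode telomere motif TTAGGC and its
reverse complement, greedily and without overlap, case-insensitively;
counting both strands makes capped ends detectable regardless of
assembly orientation. An end is "capped" when at least 10 motif copies
fall within 10 kb of it (both arguments). Softmask repeat density is
the lowercase fraction per 200 kb window; because different repeat
finders mask very different fractions of the same genome (an
any-repeat finder can report an order of magnitude more masked sequence
than a transposable-element annotator), densities are only comparable
within one mask source, and FASTA reading for this purpose goes through
a case-preserving reader (`readFastaMasked()`). Assembly metrics
implement N50 by the descending prefix-sum definition and convert a
Phred-scaled consensus QV to an expected error spacing of
$10^{QV/10}$ bp; the conversion is reported exactly (QV 52.9 gives
194,984 bp ≈ 195 kb) rather than rounded to a headline figure.

# The synthetic-data generator

`presetConfig()` ships four karyotype architectures:

| preset | karyotype | X composition | male-diploid region | SNP rate |
|---|---|---|---|---|
| `litomosoides` | 5A + X, X0 | X+D (blended) | none | 0 |
| `dirofilaria` | 4A + XY | X+D+E | whole 15.2 Mb E partition | 1/2215 per bp |
| `onchocerca` | 3A + XY (A+N fused) | X+D+E | 3.4 Mb of the E partition | 1/314 per bp |
| `brugia` | 4A + XY | X+D+N (25 Mb X) | 2.6 Mb of the N partition | 1/2215, 7× boundary bin |

Element sizes are fixed per preset so that chromosome and region scales
match the corresponding published assemblies (e.g. a 25 Mb Brugia-like
X whose planted region spans 0-based 22,300,000–24,943,668). The
sex-linked geometry enforces the central biological claim: a planted
shared region must lie within the ancestrally autosomal (recently
fused) partition of the X, and the generator refuses configurations
that violate this.

**Karyotype construction.** Seven single-element chromosomes are merged
according to the fusion history; each fusion event appends one
chromosome's blocks to another's (optionally reversed). Random internal
inversions are then applied *within the ancient X+D partition only*,
reflecting the structure seen in real filarial X chromosomes: the old
fusion is blended while the recent fusion partition remains distinct.
Inversions pick two uniform breakpoints and reverse the intervening
fragment order; blocks are tracked exactly, so the emitted truth set
records the final physical arrangement.

A note on blending: a single inversion changes the marker run count by
at most two, so the number of inversions required for statistical
intermixing (runs z within ±1.96) grows roughly as $n \log n$ in the
number of markers on the fused partition. At the default marker density
(300 markers per element, matching the ~2,200 placed BUSCOs of a real
nematode assembly), the default 200 inversions produce visibly blended
but still statistically partitioned marker orders (z around −15);
near-complete statistical blending requires a few thousand inversions.
`intermixInversions` is a plain config knob for exploring this
continuum.

**Coverage.** Per-window read counts are drawn from a negative binomial
with mean `depthMean × factor × width / readLength` and size
`depthDispersion`, then converted to per-base mean depth. The factor is
1 for autosomes in both sexes, 0.5 on the male X outside the shared
region (1.0 inside, minus any degeneration strata), and $1 - e/4$ on
the female X. Parameterising dispersion at the read-count level keeps
the window-level coefficient of variation near the few-percent level
real short-read depth tracks show (defaults: 30× depth, size 500,
150 bp reads, ≈5% CV per 100 kb window); a window-level negative
binomial on the depth scale would be far too noisy at any moderate size
parameter. A window is treated as diploid when its midpoint falls in
the shared region, so planted boundaries are recoverable to ±1 bin.

**SNPs.** Heterozygous SNP positions are drawn as a Poisson process at
`snpRateShared` per bp uniformly over the male-diploid span, at
`boundaryMultiplier` times that rate in the bin immediately outside the
region's start (emulating the elevated divergence of the neighbouring,
degenerated stratum), and nowhere else. They are emitted as a minimal,
deterministic VCF with `0/1` genotypes that round-trips through the
package's own VCF reader.

**Determinism.** Every stochastic step derives its seed from the config
seed plus a fixed per-purpose offset, so `writeFixtureSet()` is
byte-reproducible: the same config yields an identical checksum
manifest, which the tests assert.

**What the generator does not emulate.** Real read mappability,
GC bias, collapsed repeats and copy-number variation (coverage noise is
i.i.d. across windows); gene structure or sequence evolution of the
marker loci (markers are coordinates, not sequences); recombination or
population variation; and continuous neo-Y decay (degeneration is
modelled as discrete haploid strata, matching how such strata are
described). Passing the recovery tests therefore demonstrates the
pipeline's logic and calibration, not robustness to every artefact of
real sequencing data.

# Problem sizes used by the tests

The checks in `tests/testthat` and `scripts/acceptance.R` run at the
scales the analyses are designed for: full-size coverage fixtures
(~81 Mb genomes, 100 kb bins, 25 Mb X) across 20 seeds for boundary
recovery; the caller-vs-oracle comparison exhaustively over all binary
classification vectors up to length 12 and all three-state vectors up
to length 8, plus 500 random three-state vectors of length 30, each
under three parameter settings; and sequence-level fixtures
(telomeres, painting round-trips) at 1/100 scale, where sequence
emission is cheap. Marker-density and SNP-rate calibrations use the
full preset values.

# Known limitations

* The seven-element ancestral alphabet is fixed; the package applies an
  external element definition and does not re-adjudicate disputes about
  the ancestral chromosome number.
* The shared-region caller is threshold-based by design (as the
  analyses it implements are); it performs no statistical test on
  coverage and no CNV modelling.
* Strata are an output of visual inspection in the source analyses;
  the package ships density tracks and planted-strata simulation but no
  changepoint inference.
* `repeatDensity()` is only as meaningful as the softmask it is given.
* The embryo-dilution model assumes a 1:1 embryo sex ratio and a single
  pooled DNA fraction `e`; `e` is a knob, never inferred.
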