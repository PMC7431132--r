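---
title: "Methods: coverage, enrichment and dependence calling for heritable heterochromatin ChIP-seq"
author: "heritChIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage, enrichment and dependence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(heritChIP))
```

## The analysis problem

Germline nuclear RNAi in *C. elegans* deposits repressive histone marks
(H3K23me3, H3K9me3) at dsRNA-targeted genes and at endogenous GRH/GRTS
loci, and the marks persist for several generations after the trigger is
removed.  Quantifying this from ChIP-seq requires a small but specific
chain of computations: fractionally weighted coverage that does not
discard multi-mapped reads (nuclear RNAi targets are enriched in repeats),
depth normalization so libraries are comparable, window-level enrichment
statistics over chromosome arms versus centers, mutant-versus-wild-type
dependence calls per gene, and set-overlap statistics among the dependent
gene sets.  heritChIP implements that chain and couples it to a synthetic
alignment generator with planted ground truth, so every stage can be
validated end to end without external data.

## Coverage model

Each alignment record carries the read's total number of equally good
alignments $n$; every record is weighted $1/n$, so a read always
contributes total mass 1 regardless of how many loci report it.  A record
is extended to a fixed fragment length $E$ (default 500 bp) from its
sequenced 5' end — the extension *replaces* the read span rather than
appending to it, the standard single-end approximation of fragment
coverage; fragments are clipped at chromosome ends and keep their partial
mass.  Per-base coverage is the sum of weights of fragments covering the
base.  Tracks store the *mean* per-base coverage within fixed bins
(25 bp for locus profiles, 1000 bp genome-wide), which makes values
independent of bin size, and scale by $10^6/\mathrm{depth}$
(reads per million), where depth is the number of distinct aligned reads.
Two invariants pin the implementation down and are enforced by tests:
total mass equals $\sum_i w_i \times$ clipped fragment length exactly, and
duplicating a library leaves the normalized track unchanged.

## Window statistics

The genome is tiled into fixed windows (1 kb by default; the last window
of a chromosome may be short).  Window signal is the exact per-base mean
over the window, computed from nested track bins; replicate tracks are
averaged.  Enrichment ratios (ChIP/input, mutant/WT) are pseudocounted:
$(x + c)/(y + c)$ with $c$ defaulting to the signal one read's fragment
deposits across one window at the library's depth
($c = \frac{10^6}{\mathrm{depth}} \cdot \frac{E}{\mathrm{window}}$) — a
scale-aware floor that sends empty-vs-empty windows to ratio 1.

Arm-versus-center comparison assigns each window by its midpoint
(unambiguous for boundary-straddling windows), reports quartiles and the
arm/center median ratio, and uses a two-sided rank (Wilcoxon) test — a
rank test matches the boxplot presentation of such comparisons and is
robust to the heavy right tail of ChIP coverage.  Because large window
counts make trivial differences significant, the summary flags
`negligible` when $p < 0.05$ but the median ratio lies within
$[1/1.1, 1.1]$: statistically detectable, biologically indifferent.
Between-mark correlation is plain Pearson on window ratios (untransformed
by default; `log2 = TRUE` exposed), with a scatter export carrying
two-fold guide columns.

## Dependence calling

A gene's signal is the mean normalized per-base depth over its body
(flank configurable, 0 by default), and its *mass* is the weighted
read-equivalent count: each fragment contributes its weight times the
fraction of the fragment inside the span, so masses sum to the library
depth genome-wide.  For each WT/mutant replicate pair (paired by index),
the fold change is computed on pseudocounted normalized signals and a
p-value from a depth-conditioned count test on masses: the gene's rounded
WT mass $x_1$ versus total $x_1 + x_2$ is referred to a binomial with
success probability $d_1/(d_1+d_2)$ (the depth share).  Masses are
fractional because of multimapper weights; they are rounded half-to-even
because exact tests need integers.  The test is a pluggable strategy
(`testFun`) since the choice of count model is a judgment call.  A gene is
*dependent* only when every replicate pair shows fold $\ge 2$ **and**
meets the significance criterion — the two-fold, consistent-in-both-
replicas rule.  Both a per-replicate p-value mode ($p < \alpha$) and a
BH-FDR mode ($q \le \alpha$, adjusted across genes within each pair) are
provided because different analyses in this literature use each; the
default is the p-value mode.  Monotonicity (relaxing either threshold
never shrinks the called set) and a WT-versus-WT null (per-replicate pass
fraction at most $\alpha$, reduced further by the two-replicate
requirement) are tested properties.

Gene-set overlaps use Fisher's exact test on the 2×2 table over a gene
universe (all annotated genes by default, configurable), one-sided for
enrichment since the scientific claim is that overlaps exceed chance.
Repeat composition counts a gene as repeat-containing when any repeat
interval intersects it by at least 1 bp (half-open convention: touching
intervals do not overlap), and summarizes repeat classes among the
repeat-containing genes; a gene may carry several classes.

## The synthetic-data generator

The generator works at the alignment level: sequence simulation and
alignment are deliberately skipped, because the analysis chain begins
after alignment (only perfect alignments, with per-read hit counts) and
an upstream aligner is not part of this package's contribution.

A toy genome (default: two 1 Mb chromosomes) is partitioned into arms and
center by an arm fraction (default 0.25 per arm).  GRH/GRTS regions
(default 8 + 8 of 2 kb) are placed uniformly on arms; genes (default 200
of 2 kb, of which 20 are nuclear-RNAi targets) are placed uniformly in the
remaining free space; repeat families (defaults: LTR 4 × 400 bp, DNA
6 × 300 bp, Low_complexity 8 × 200 bp) get one copy planted inside 60% of
target genes and the rest in intergenic space, all placements
non-overlapping and recorded in a truth table.

Read 5' starts are drawn from a piecewise-constant mixture over admissible
start positions: weight 1 everywhere, times the arm background fold
(default 3, ChIP only — the constitutive heterochromatin signal), times
the planted fold over each target feature,
$$f = 1 + (E_m - 1)\,\gamma_g\,d^{\,t},$$
with $E_m$ the mark's target enrichment (default 8), $\gamma_g$ the
genotype effect (defaults: WT 1; *hrde-1* 0; *set-32* 0.1;
*met-2 set-25* 0.7 — abolished, nearly abolished, partially retained,
matching the qualitative genetics of these factors for H3K23me3) and $d$
the per-generation decay (default 0.7).  Input libraries ignore all
enrichment.  Geometric decay in $(f-1)$ is the simplest monotone model of
persistence-then-decline; the underlying biology specifies no functional
form, so this is a modeling stand-in, not an inference.  A read falling
wholly inside a repeat copy is reported at every copy of its family at the
same offset, all records sharing the read id with $n$ = copy number —
reproducing exactly the situation the $1/n$ weighting exists for.  Strand
is uniform, read length fixed (50 bp), and every library contains exactly
`nReads` distinct reads.

What the generator does *not* emulate: sequencing errors, PCR
duplicates, fragment-length variation, mappability structure beyond the
planted repeat families, chromatin accessibility bias in input, and
between-replicate biological variability (replicates differ only by
sampling noise).  Passing tests therefore demonstrate correctness of the
computations and recoverability of planted effects under idealized noise,
not robustness to every artifact of real libraries.

## Numerical and design choices

* Coordinates are 0-based half-open in every file format and 1-based
  closed in memory (the Bioconductor convention); GFF is converted on
  read.
* Bin values are means, not sums, so tracks are comparable across
  resolutions; fractional-weight accumulation can leave $-10^{-17}$-scale
  round-off in per-base coverage, which is clamped to 0.
* Window membership is by midpoint; replicate pairing is by index;
  the Fisher universe is all annotated genes — each is configurable, and
  each default is stated where it is used.
* The per-library default seed is derived deterministically from the
  genome seed and the library coordinates (mark, genotype, role,
  replicate, generation), so a whole study design is reproducible from
  one integer while distinct libraries stay independent.
* Degenerate inputs fail loudly: empty libraries (depth 0), genomes too
  small for the requested placements (reported with counts), chromosomes
  lacking arm or center windows, inconsistent per-read hit counts.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to make planted effects estimable with
comfortable margins: mass-conservation checks on twenty random ≤100 kb
genomes; dependence recovery on a 2 Mb genome with 220 genes and
50,000-read libraries (two WT + two mutant replicates); arm/center
recovery at 100,000 reads; mark correlation at 200,000 reads; and a
five-generation heritable series (d = 0.7, initial fold 9) on a 200 kb
genome, ten seeded runs.  The corresponding published analyses used
whole-genome *C. elegans* data; the package reproduces their statistical
machinery, and its quantitative claims are about the synthetic
conditions.

## Limitations

Real ChIP-seq replicates vary biologically; the conditional binomial
treats masses as sampling counts and will be anticonservative under
overdispersion — the FDR mode and the pluggable `testFun` are the
escape hatches.  The arm/center statistic assumes the arm partition is
given (boundaries are a configuration input, not estimated).  Fold
estimates at planted regions are mildly compressed by depth
renormalization (enrichment elsewhere in the genome inflates the
denominator); the effect is a few percent at default settings and is
visible in the tests' tolerances.
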