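# heritChIP

ChIP-seq analysis of nuclear-RNAi-induced heterochromatin marks
(H3K23me3 / H3K9me3) in *C. elegans*-style genomes, with a synthetic-data
generator that plants known enrichment so the whole pipeline can be
validated end to end.

Germline nuclear RNAi deposits repressive histone marks at dsRNA-targeted
genes and at endogenous GRH/GRTS loci, and those marks are inherited for
several generations.  Quantifying this from ChIP-seq needs a specific
chain of computations, which this package implements for analysts working
on small-RNA-directed chromatin silencing:

* **Fractionally weighted coverage.**  Each alignment of a read reported
  at *n* loci is weighted 1/*n* (multimappers matter: nuclear-RNAi targets
  are repeat-rich), extended to a 500 bp fragment from its sequenced end,
  accumulated per base, binned as per-base means, and scaled to reads per
  million: value = mean per-base Σᵢ wᵢ × 10⁶ / depth.
* **Window statistics.**  1 kb genome windows; pseudocounted ChIP/input
  and mutant/WT ratios; chromosome arm-versus-center comparison (median
  ratio + two-sided Wilcoxon rank test, with a "significant but
  negligible" flag for tiny effects); Pearson correlation between marks.
* **Dependent-gene calling.**  A gene is dependent on a factor when its
  mark signal drops ≥ 2-fold in the mutant, significantly (depth-
  conditioned binomial count test, p < 0.05 or BH-FDR ≤ 0.05), in *every*
  replicate pair.
* **Set overlap and repeats.**  Venn intersection sizes of dependent-gene
  sets, one-sided Fisher's exact tests P(X ≥ overlap) under the
  hypergeometric null, and repeat-class composition of target genes
  (half-open interval intersection).
* **Transgenerational decay.**  Simulated heritable-RNAi series F0…Fg
  with planted fold f_t = 1 + (f₀ − 1)·d^t and estimation of the
  trigger-region enrichment per generation.

Everything runs on a planted-truth toy genome (`SimConfig` /
`buildToyGenome` / `simulateLibrary`), so sensitivity, false-positive
rates and estimator bias are measurable, not assumed.

## Worked example

```r
library(heritChIP)

cfg <- SimConfig(nReads = 50000L)      # 2 x 1 Mb genome, 200 genes,
gen <- buildToyGenome(cfg)             # 20 targets, 8+8 GRH/GRTS regions

wt  <- lapply(1:2, function(k) simulateLibrary(cfg, gen$truth,
              "H3K23me3", "WT", "chip", replicate = k))
mut <- lapply(1:2, function(k) simulateLibrary(cfg, gen$truth,
              "H3K23me3", "hrde-1", "chip", replicate = k))

calls <- callDependentGenes(wt, mut, gen$genes)
table(called = calls$dependent, truth = S4Vectors::mcols(gen$genes)$target)
#>        truth
#> called  FALSE TRUE
#>   FALSE   180    0
#>   TRUE      0   20

w   <- makeWindows(gen$layout, 1000)
trk <- computeCoverage(wt[[1]], binSize = 1000)
acc <- armCenterCompare(windowSignal(trk, w), w, gen$layout)
round(c(ratio = acc$overall$effect_ratio, p = acc$overall$p_value), 3)
#> ratio     p
#> 3.019 0.000
```

All 20 planted *hrde-1*-dependent genes are recovered with no false
positives among the 180 non-targets, and the arm/center median ratio
recovers the planted 3× heterochromatin background (the rank-test p-value
underflows to 0 at this window count).

A thin command-line wrapper is included
(`inst/scripts/heritchip`): `simulate`, `coverage`, `windows`,
`call-deps`, `overlap` and `report` subcommands over the same functions,
e.g. `heritchip report --config cfg.yaml --seed 1 --out out/`.

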