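## a library whose reads land exactly inside a 1 kb gene: each + read at the
## gene start with extension 500 deposits its full mass in the gene
geneAt <- function(chromLengths = c(chr = 100000L)) {
  g <- GRanges("chr", IRanges(1001, 2000),
               seqinfo = Seqinfo(names(chromLengths),
                                 seqlengths = chromLengths))
  mcols(g)$gene_id <- "g1"
  g
}

libWithGeneReads <- function(nIn, depth, chromLengths = c(chr = 100000L)) {
  nOut <- depth - nIn
  makeLib("chr",
          c(rep(1001, nIn), rep(50001, max(nOut, 0))),
          "+", 50, 1, sprintf("r%05d", seq_len(depth)), chromLengths,
          depth = depth)
}

test_that("gene signal and mass agree with hand arithmetic", {
  g <- geneAt()
  lib <- libWithGeneReads(4, 100)
  gs <- geneSignal(lib, g)
  # 4 reads x 500 bp inside a 1000 bp gene: mean unnorm depth 2
  expect_equal(gs$mass, 4)
  expect_equal(gs$signal, 2 * 1e6 / 100)
  # empty region
  g2 <- GenomicRanges::shift(geneAt(), 8000)
  expect_equal(geneSignal(lib, g2)$signal, 0)
  expect_equal(geneSignal(lib, g2)$mass, 0)
  # partial overlap contributes the overlapping fraction of the fragment
  g3 <- GenomicRanges::shift(geneAt(), 250)
  expect_equal(geneSignal(lib, g3)$mass, 4 * 250 / 500)
})

test_that("gene masses sum to the library depth genome-wide", {
  cfg <- smallConfig(nReads = 1000L)
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  whole <- GRanges(names(chromLengths(gen$layout)),
                   IRanges(1, chromLengths(gen$layout)))
  mcols(whole)$gene_id <- names(chromLengths(gen$layout))
  expect_equal(sum(geneSignal(lib, whole)$mass), seqDepth(lib),
               tolerance = 1e-9)
})

test_that("ChIP/input gene signal ratio recovers the planted fold", {
  cfg <- smallConfig(chromLengths = c(chr = 400000), nGenes = 20L,
                     nTargetGenes = 4L, nGRH = 0L, nGRTS = 0L,
                     backgroundArms = 1,
                     repeatFamilies = data.frame(class = character(0),
                                                 copies = integer(0),
                                                 length = integer(0)),
                     nReads = 60000L, geneLength = 2000L)
  gen <- buildToyGenome(cfg)
  chip <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  inp <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "input")
  tg <- mcols(gen$genes)$target
  ratio <- geneSignal(chip, gen$genes)$signal /
    geneSignal(inp, gen$genes)$signal
  # targets near the planted 8 (depth renormalization pulls it slightly
  # below), non-targets near 1
  expect_gt(median(ratio[tg]), 8 * 0.7)
  expect_lt(median(ratio[tg]), 8 * 1.3)
  expect_gt(median(ratio[!tg]), 0.75)
  expect_lt(median(ratio[!tg]), 1.3)
})

test_that("the worked two-sample count example is called dependent", {
  g <- geneAt()
  wt <- libWithGeneReads(100, 1000)
  mut <- libWithGeneReads(10, 1000)
  calls <- callDependentGenes(list(wt, wt), list(mut, mut), g)
  expect_true(calls$dependent[1])
  expect_gte(calls$fold[1, 1], 2)
  # p-value equals the exact two-sided binomial oracle at equal depths
  expect_equal(unname(calls$p[1, 1]), bruteBinomTwoSided(100, 110, 0.5),
               tolerance = 1e-12)
})

test_that("failing either criterion in any replicate blocks the call", {
  g <- geneAt()
  wt <- libWithGeneReads(100, 1000)
  mut <- libWithGeneReads(10, 1000)
  weak <- libWithGeneReads(67, 1000)   # fold ~1.5, p can be small
  calls <- callDependentGenes(list(wt, wt), list(mut, weak), g)
  expect_lt(calls$fold[1, 2], 2)
  expect_false(calls$dependent[1])
  # passes in replicate 1 only (replicate 2 identical to WT)
  same <- libWithGeneReads(100, 1000)
  calls2 <- callDependentGenes(list(wt, wt), list(mut, same), g)
  expect_false(calls2$dependent[1])
  # single-replicate comparison of the strong pair is dependent
  expect_true(callDependentGenes(list(wt), list(mut), g)$dependent[1])
})

test_that("replicate pairing is validated", {
  g <- geneAt()
  wt <- libWithGeneReads(10, 100)
  expect_error(callDependentGenes(list(), list(wt), g), "at least one")
  expect_error(callDependentGenes(list(wt, wt), list(wt), g),
               "pair by index")
})

test_that("relaxing thresholds never shrinks the dependent set", {
  cfg <- smallConfig(nReads = 4000L)
  gen <- buildToyGenome(cfg)
  wt <- lapply(1:2, function(k)
    simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip", replicate = k))
  mut <- lapply(1:2, function(k)
    simulateLibrary(cfg, gen$truth, "H3K23me3", "hrde-1", "chip",
                    replicate = k))
  strict <- callDependentGenes(wt, mut, gen$genes, foldThreshold = 2,
                               alpha = 0.05)
  looseFold <- callDependentGenes(wt, mut, gen$genes, foldThreshold = 1.5,
                                  alpha = 0.05)
  looseAlpha <- callDependentGenes(wt, mut, gen$genes, foldThreshold = 2,
                                   alpha = 0.2)
  expect_true(all(looseFold$dependent[strict$dependent]))
  expect_true(all(looseAlpha$dependent[strict$dependent]))
  # FDR mode also returns a full table with adjusted values
  fdr <- callDependentGenes(wt, mut, gen$genes, mode = "fdr")
  expect_equal(nrow(fdr), length(gen$genes))
  expect_true(all(fdr$padj >= fdr$p - 1e-12))
})

test_that("region class summary separates GRTS loss from the rest", {
  cfg <- smallConfig(chromLengths = c(chr = 300000), nGRH = 2L, nGRTS = 2L,
                     nGenes = 10L, nTargetGenes = 0L, nReads = 30000L,
                     regionLength = 3000L,
                     repeatFamilies = data.frame(class = character(0),
                                                 copies = integer(0),
                                                 length = integer(0)))
  gen <- buildToyGenome(cfg)
  w <- makeWindows(gen$layout, 1000)
  trk <- function(genotype) computeCoverage(
    simulateLibrary(cfg, gen$truth, "H3K23me3", genotype, "chip"),
    binSize = 1000)
  wt <- windowSignal(trk("WT"), w)
  mut <- windowSignal(trk("hrde-1"), w)
  pc <- 0.05 * 1e6 / 30000
  rcs <- regionClassSummary(ratioSignal(mut, wt, pc), w, gen$regions)
  smry <- as.data.frame(rcs$summary)
  expect_setequal(smry$class, c("GRH", "GRTS", "rest"))
  expect_lt(smry$median[smry$class == "GRTS"],
            smry$median[smry$class == "rest"])
  # identity comparison: all medians ~1
  rcsNull <- regionClassSummary(ratioSignal(wt, wt, pc), w, gen$regions)
  expect_true(all(abs(as.data.frame(rcsNull$summary)$median - 1) < 1e-12))
  # no annotation -> a single catch-all class
  rcs0 <- regionClassSummary(ratioSignal(mut, wt, pc), w, NULL)
  expect_equal(as.character(unique(rcs0$assignments)), "rest")
})
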