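test_that("arm partition follows the arm fraction arithmetic", {
  layout <- GenomeLayout(c(chrI = 1000000, chrII = 1000000),
                         armFraction = 0.25)
  a <- armDomains(layout)
  chrI <- a[as.character(seqnames(a)) == "chrI"]
  expect_equal(start(chrI) - 1L, c(0L, 250000L, 750000L))
  expect_equal(end(chrI), c(250000L, 750000L, 1000000L))
  expect_equal(mcols(chrI)$domain, c("left", "center", "right"))
})

test_that("toy genome respects counts, bounds and non-overlap", {
  cfg <- smallConfig()
  gen <- buildToyGenome(cfg)
  expect_length(gen$genes, cfg@nGenes)
  expect_equal(sum(mcols(gen$genes)$target), cfg@nTargetGenes)
  expect_length(gen$regions, cfg@nGRH + cfg@nGRTS)
  expect_equal(sum(cfg@repeatFamilies$copies), length(gen$repeats))
  # regions only on arms
  expect_true(all(overlapsAny(gen$regions, armRanges(gen$layout),
                              type = "within")))
  # genes and regions mutually non-overlapping
  feats <- c(granges(gen$genes), granges(gen$regions))
  expect_true(all(countOverlaps(feats, feats, ignore.strand = TRUE) == 1))
  # repeat copies non-overlapping and within bounds
  expect_true(all(countOverlaps(gen$repeats, gen$repeats) == 1))
  cl <- chromLengths(gen$layout)
  expect_true(all(end(gen$repeats) <=
                    cl[as.character(seqnames(gen$repeats))]))
})

test_that("zero GRTS regions yields an empty GRTS annotation", {
  gen <- buildToyGenome(smallConfig(nGRTS = 0L))
  expect_false(any(mcols(gen$regions)$class == "GRTS"))
  expect_equal(sum(mcols(gen$regions)$class == "GRH"), 2L)
})

test_that("genome construction is byte-identical given the seed", {
  cfg <- smallConfig()
  files <- function() {
    gen <- buildToyGenome(cfg)
    d <- withr::local_tempdir()
    writeChromSizes(gen$layout, file.path(d, "sizes"))
    writeArmsBed(gen$layout, file.path(d, "arms.bed"))
    writeBed(gen$genes, file.path(d, "genes.bed"),
             names = mcols(gen$genes)$gene_id)
    writeBed(gen$repeats, file.path(d, "repeats.bed"),
             names = mcols(gen$repeats)$class)
    writeTruthTable(gen$truth, file.path(d, "truth.tsv"))
    lapply(list.files(d, full.names = TRUE), readLines)
  }
  expect_identical(files(), files())
})

test_that("placement failure is reported with counts", {
  expect_error(buildToyGenome(smallConfig(
    chromLengths = c(chr = 10000), nGenes = 50L, geneLength = 1000L,
    nGRH = 1L, nGRTS = 1L)),
    "placement failure")
})

test_that("libraries carry exactly nReads distinct reads of unit weight", {
  cfg <- smallConfig()
  gen <- buildToyGenome(cfg)
  for (role in c("chip", "input")) {
    lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", role)
    ids <- mcols(alignments(lib))$readId
    expect_equal(length(unique(ids)), cfg@nReads)
    expect_equal(seqDepth(lib), cfg@nReads)
    # each read's records sum to weight 1
    w <- tapply(alignmentWeights(lib), ids, sum)
    expect_equal(max(abs(w - 1)), 0, tolerance = 1e-12)
  }
})

test_that("multimapped reads are reported at every family copy", {
  cfg <- smallConfig(nReads = 5000L)
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  r <- alignments(lib)
  multi <- r[mcols(r)$nHits > 1]
  expect_gt(length(multi), 0)
  expect_true(all(overlapsAny(multi, gen$repeats, type = "within",
                              ignore.strand = TRUE)))
  # record count per multimapped read equals its nHits
  tab <- table(mcols(multi)$readId)
  nh <- tapply(mcols(multi)$nHits, mcols(multi)$readId, `[`, 1)
  expect_equal(as.integer(tab), as.integer(nh[names(tab)]))
})

test_that("identical seeds reproduce a library; different seeds differ", {
  cfg <- smallConfig()
  gen <- buildToyGenome(cfg)
  a <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip", seed = 5)
  b <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip", seed = 5)
  c3 <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip", seed = 6)
  expect_identical(start(alignments(a)), start(alignments(b)))
  expect_false(identical(start(alignments(a)), start(alignments(c3))))
})

test_that("planted region enrichment matches the binomial expectation", {
  # one 2 kb target region at fold 8 on an otherwise flat 1 Mb genome
  cfg <- smallConfig(chromLengths = c(chr = 1000000), nGenes = 1L,
                     nTargetGenes = 0L, nGRH = 0L, nGRTS = 1L,
                     regionLength = 2000L, backgroundArms = 1,
                     targetEnrichment = c(H3K23me3 = 8),
                     repeatFamilies = data.frame(class = character(0),
                                                 copies = integer(0),
                                                 length = integer(0)),
                     nReads = 100000L)
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  region <- gen$regions[1]
  starts <- GRanges(seqnames(alignments(lib)),
                    IRanges(start(alignments(lib)), width = 1))
  obs <- sum(countOverlaps(region, starts))
  # exact mixture: start space has L - readLength + 1 positions, the
  # region contributes 8x its width
  Lp <- 1000000 - cfg@readLength + 1
  wRegion <- 8 * width(region)
  pExp <- wRegion / (Lp + 7 * width(region))
  expExp <- cfg@nReads * pExp
  sdExp <- sqrt(cfg@nReads * pExp * (1 - pExp))
  expect_lt(abs(obs - expExp), 4 * sdExp)
  # and the input library ignores the planted fold
  inp <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "input")
  startsI <- GRanges(seqnames(alignments(inp)),
                     IRanges(start(alignments(inp)), width = 1))
  obsI <- sum(countOverlaps(region, startsI))
  pI <- width(region) / Lp
  expect_lt(abs(obsI - cfg@nReads * pI),
            4 * sqrt(cfg@nReads * pI * (1 - pI)))
})

test_that("planted fold algebra follows 1 + (f0-1) * effect * d^g", {
  cfg <- smallConfig(targetEnrichment = c(H3K23me3 = 17),
                     generationDecay = 0.5)
  expect_equal(plantedFold(cfg, "H3K23me3", "WT", 4), 2)
  cfg2 <- smallConfig(generationDecay = 1)
  expect_equal(plantedFold(cfg2, "H3K23me3", "WT", 0),
               plantedFold(cfg2, "H3K23me3", "WT", 7))
  # a zero genotype effect collapses enrichment to background
  expect_equal(plantedFold(smallConfig(), "H3K23me3", "hrde-1", 0), 1)
  expect_error(plantedFold(cfg, "H3K4me3", "WT"), "unknown mark")
  expect_error(plantedFold(cfg, "H3K23me3", "nrde-2"), "unknown genotype")
})

test_that("unit effects and no decay reduce every condition to WT F0", {
  cfg <- smallConfig(genotypeEffects = c(WT = 1, "hrde-1" = 1),
                     generationDecay = 1)
  gen <- buildToyGenome(cfg)
  base <- plantedFolds(gen$truth, "H3K23me3", "WT", 0)
  for (g in c("WT", "hrde-1")) for (t in c(0, 3))
    expect_equal(plantedFolds(gen$truth, "H3K23me3", g, t)$fold, base$fold)
})

test_that("heritable series has one chip+input pair per generation", {
  cfg <- smallConfig(nReads = 500L)
  gen <- buildToyGenome(cfg)
  ser <- simulateHeritableSeries(cfg, gen$truth, "H3K23me3", 2)
  expect_named(ser, c("F0", "F1", "F2"))
  for (g in seq_along(ser)) {
    expect_s4_class(ser[[g]]$chip, "AlignmentLibrary")
    expect_equal(sampleInfo(ser[[g]]$chip)$generation, g - 1L)
    expect_equal(sampleInfo(ser[[g]]$input)$role, "input")
  }
})
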