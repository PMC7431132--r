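cl1 <- c(chr = 10000L)

test_that("extension anchors at the sequenced end and weights 1/nHits", {
  rec <- function(start, strand, nHits) {
    gr <- GRanges("chr", IRanges(start, width = 50), strand = strand,
                  seqinfo = Seqinfo("chr", 10000))
    mcols(gr)$readId <- "r1"
    mcols(gr)$nHits <- as.integer(nHits)
    gr
  }
  e <- extendAlignments(rec(1001, "+", 4))
  expect_equal(start(e), 1001)
  expect_equal(end(e), 1500)
  expect_equal(mcols(e)$weight, 0.25)

  # minus strand: window ends at the alignment's genomic end
  e <- extendAlignments(rec(2001, "-", 1))
  expect_equal(start(e), 1551)  # 0-based [1550, 2050)
  expect_equal(end(e), 2050)
  expect_equal(mcols(e)$weight, 1)

  # clipped at the chromosome end
  e <- extendAlignments(rec(10000L - 99L, "+", 1))
  expect_equal(width(e), 100)
  expect_equal(end(e), 10000)

  expect_error(extendAlignments(rec(1, "+", 1), extension = 0), "positive")
})

test_that("a single full-bin read gives unnormalized 1 and RPM 1e6", {
  lib <- makeLib("chr", 1, "+", 50, 1, "r1", c(chr = 1000L))
  trk <- computeCoverage(lib, binSize = 500)
  expect_equal(seqDepth(lib), 1)
  v <- trackValues(trk)$chr
  expect_equal(v / normFactor(trk), c(1, 0))  # unnormalized per-base mean
  expect_equal(v[1], 1e6)
})

test_that("empty libraries are rejected rather than divided by zero", {
  gr <- GRanges(seqinfo = Seqinfo("chr", 1000))
  mcols(gr)$readId <- character(0)
  mcols(gr)$nHits <- integer(0)
  lib <- AlignmentLibrary(gr)
  expect_error(computeCoverage(lib), "depth is 0")
})

test_that("duplicating every read leaves the normalized track unchanged", {
  cfg <- smallConfig()
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  r <- alignments(lib)
  r2 <- c(r, r)
  mcols(r2)$readId <- c(mcols(r)$readId, paste0(mcols(r)$readId, "_dup"))
  dup <- AlignmentLibrary(r2, depth = 2 * seqDepth(lib))
  t1 <- computeCoverage(lib, binSize = 100)
  t2 <- computeCoverage(dup, binSize = 100)
  for (chr in names(chromLengths(t1)))
    expect_equal(trackValues(t1)[[chr]], trackValues(t2)[[chr]],
                 tolerance = 1e-10)
})

test_that("coverage matches a brute-force per-base oracle exactly", {
  cfg <- smallConfig(chromLengths = c(chrA = 50000, chrB = 30000),
                     nReads = 1500L)
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  oracle <- naiveCoverage(lib)
  trk <- computeCoverage(lib, binSize = 1)
  for (chr in names(oracle)) {
    got <- trackValues(trk)[[chr]] / normFactor(trk)
    expect_equal(got, oracle[[chr]], tolerance = 1e-9)
  }
  # total mass identity: sum over bases == sum of weights x clipped lengths
  expect_equal(sum(unlist(oracle)), coverageMass(lib), tolerance = 1e-9)
})

test_that("a read with n alignments contributes total weight 1", {
  # same read reported at 3 loci
  lib <- makeLib(rep("chr", 3), c(100, 3000, 7000), "+", 50, 3,
                 rep("r1", 3), cl1)
  expect_equal(coverageMass(lib), 500)  # one read's worth of mass
  expect_equal(sum(alignmentWeights(lib)), 1)
})

test_that("genome-wide mass is invariant to bin refinement", {
  cfg <- smallConfig(nReads = 800L)
  gen <- buildToyGenome(cfg)
  lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
  mass <- function(binSize) {
    trk <- computeCoverage(lib, binSize = binSize)
    cl <- chromLengths(trk)
    sum(vapply(names(cl), function(chr) {
      v <- trackValues(trk)[[chr]] / normFactor(trk)
      nb <- length(v)
      lens <- c(rep(binSize, nb - 1), cl[[chr]] - (nb - 1) * binSize)
      sum(v * lens)
    }, 0))
  }
  expect_equal(mass(200), mass(100), tolerance = 1e-9)
  expect_equal(mass(100), coverageMass(lib), tolerance = 1e-9)
})

test_that("locus profiles slice track bins and keep track order", {
  t1 <- makeTrack(list(c(1, 2, 3, 4)), 25, c(chr = 100L))
  t2 <- makeTrack(list(c(10, 20, 30, 40)), 25, c(chr = 100L))
  # interval equal to one bin -> a single row
  p <- locusProfile(t1, "chr", 25, 50)
  expect_equal(nrow(p), 1)
  expect_equal(p$signal, 2)
  # two tracks -> two value columns in input order
  p2 <- locusProfile(list(a = t1, b = t2), "chr", 0, 100)
  expect_equal(names(p2)[4:5], c("a", "b"))
  expect_equal(p2$a, c(1, 2, 3, 4))
  expect_equal(p2$b, c(10, 20, 30, 40))
  expect_error(locusProfile(t1, "chrX", 0, 10), "unknown chromosome")
  expect_error(locusProfile(t1, "chr", 0, 500), "bounds")
})

test_that("profile ratio recovers a planted fold inside the region", {
  cfg <- smallConfig(chromLengths = c(chr = 200000), nGenes = 2L,
                     nTargetGenes = 0L, nGRH = 0L, nGRTS = 1L,
                     regionLength = 4000L, backgroundArms = 1,
                     targetEnrichment = c(H3K23me3 = 8),
                     repeatFamilies = data.frame(class = character(0),
                                                 copies = integer(0),
                                                 length = integer(0)),
                     nReads = 60000L)
  gen <- buildToyGenome(cfg)
  chip <- computeCoverage(
    simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip"),
    binSize = 1000)
  inp <- computeCoverage(
    simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "input"),
    binSize = 1000)
  reg <- gen$regions[1]
  # inner bins of the region (skip the extension-smeared edges)
  prof <- locusProfile(list(chip = chip, input = inp), "chr",
                       start(reg) + 999, end(reg) - 1000)
  expect_gt(length(prof$chip), 0)
  ratioIn <- mean(prof$chip) / mean(prof$input)
  expect_gt(ratioIn, 8 * 0.6)
  expect_lt(ratioIn, 8 * 1.4)
  # far from the region (the arm-free center) the ratio is ~1
  profOut <- locusProfile(list(chip = chip, input = inp), "chr",
                          60000, 90000)
  ratioOut <- mean(profOut$chip) / mean(profOut$input)
  expect_gt(ratioOut, 0.7)
  expect_lt(ratioOut, 1.4)
})
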