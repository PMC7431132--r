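suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## small, fast simulation setup shared across tests
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    chromLengths = c(chrA = 100000, chrB = 80000),
    nGenes = 20L, geneLength = 1000L, nTargetGenes = 4L,
    nGRH = 2L, nGRTS = 2L, regionLength = 1000L,
    repeatFamilies = data.frame(class = c("LTR", "DNA"),
                                copies = c(3L, 4L),
                                length = c(300L, 200L)),
    nReads = 3000L, seed = 11L)
  defaults[names(args)] <- args
  do.call(SimConfig, defaults)
}

## hand-built library from parallel vectors (1-based starts)
makeLib <- function(chrom, start, strand, readLen, nHits, readId,
                    chromLengths, depth = NULL, ...) {
  gr <- GRanges(chrom, IRanges(start, width = readLen), strand = strand,
                seqinfo = Seqinfo(names(chromLengths),
                                  seqlengths = chromLengths))
  mcols(gr)$readId <- readId
  mcols(gr)$nHits <- as.integer(nHits)
  AlignmentLibrary(gr, depth = depth, ...)
}

## hand-built coverage track with known bin values
makeTrack <- function(values, binSize, chromLengths, depth = 1e6,
                      extension = 500L) {
  vals <- S4Vectors::SimpleList(values)
  names(vals) <- names(chromLengths)
  new("CoverageTrack", binSize = as.integer(binSize), values = vals,
      chromLengths = stats::setNames(as.integer(chromLengths),
                                     names(chromLengths)),
      normFactor = 1e6 / depth, depth = depth,
      extension = as.integer(extension))
}

## brute-force per-base coverage oracle: accumulate each extended weighted
## interval into plain numeric vectors, one per chromosome
naiveCoverage <- function(library, extension = 500L) {
  cl <- GenomeInfoDb::seqlengths(alignments(library))
  acc <- lapply(as.list(cl), function(L) numeric(L))
  r <- alignments(library)
  for (i in seq_along(r)) {
    chr <- as.character(seqnames(r))[i]
    if (as.character(strand(r))[i] == "-") {
      e <- end(r)[i]; s <- e - extension + 1L
    } else {
      s <- start(r)[i]; e <- s + extension - 1L
    }
    s <- max(1L, s); e <- min(cl[[chr]], e)
    acc[[chr]][s:e] <- acc[[chr]][s:e] + 1 / mcols(r)$nHits[i]
  }
  acc
}

## exhaustive one-sided overlap p-value by enumerating every subset of the
## universe of size |B| (true brute force; universe must be small)
bruteFisherSubsets <- function(a, b, N, k) {
  if (b == 0 || N == 0) return(if (k <= 0) 1 else 0)
  inA <- seq_len(a)
  hits <- 0; total <- 0
  combos <- utils::combn(N, b, simplify = FALSE)
  for (B in combos) {
    total <- total + 1
    if (length(intersect(B, inA)) >= k) hits <- hits + 1
  }
  hits / total
}

## hypergeometric tail by explicit enumeration over overlap sizes
bruteFisherTail <- function(a, b, N, k) {
  js <- max(0, a + b - N):min(a, b)
  js <- js[js >= k]
  if (!length(js)) return(0)
  sum(choose(a, js) * choose(N - a, b - js)) / choose(N, b)
}

## two-sided exact binomial p-value by summing point probabilities
bruteBinomTwoSided <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

## region enrichment estimator: ChIP vs input share of reads in a region
estimateRegionFold <- function(chip, input, region, extension = 500L) {
  mcols(region)$gene_id <- "region"
  mc <- geneSignal(chip, region, extension)
  mi <- geneSignal(input, region, extension)
  (mc$mass / seqDepth(chip)) / (mi$mass / seqDepth(input))
}
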