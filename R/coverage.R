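#' Extend alignments to fragment intervals with fractional weights
#'
#' Each read is extended to \code{extension} bp from its sequenced (5') end:
#' a \code{+} read occupies \code{[start, start + extension)} and a \code{-}
#' read \code{[end - extension, end)} (0-based half-open terms), replacing
#' the read span.  Intervals are clipped to the chromosome and each carries
#' weight \code{1/nHits}, so a multi-mapped read contributes total weight 1.
#'
#' @param x An [AlignmentLibrary-class] or a \code{GRanges} of alignment
#'   records with \code{nHits} metadata and seqlengths.
#' @param extension Fragment length (bp), > 0.
#' @return \code{GRanges} with a numeric \code{weight} metadata column.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(1001, width = 50),
#'   strand = "+", readId = "r1", nHits = 4L,
#'   seqinfo = GenomeInfoDb::Seqinfo("chr", 10000))
#' extendAlignments(gr)  # [1001,1500], weight 0.25
#' @export
extendAlignments <- function(x, extension = 500L) {
  if (extension <= 0) stop("extension must be positive")
  gr <- if (is(x, "AlignmentLibrary")) alignments(x) else x
  ext <- as.integer(extension)
  minus <- as.logical(strand(gr) == "-")
  newStart <- ifelse(minus, end(gr) - ext + 1L, start(gr))
  newEnd <- newStart + ext - 1L
  sl <- seqlengths(gr)[as.character(seqnames(gr))]
  out <- GRanges(seqnames(gr),
                 IRanges(pmax(newStart, 1L), pmin(newEnd, sl)),
                 strand = strand(gr), seqinfo = seqinfo(gr))
  mcols(out)$weight <- 1 / mcols(gr)$nHits
  out
}

#' Total weighted coverage mass of a library
#'
#' The exact total per-base mass its extended, weighted fragments deposit:
#' \eqn{\sum_i w_i \times} clipped fragment length.  Equals the genome-wide
#' sum of the unnormalized per-base coverage (mass conservation).
#'
#' @param library An [AlignmentLibrary-class].
#' @param extension Fragment length (bp).
#' @return Scalar mass (base pairs of weighted coverage).
#' @export
coverageMass <- function(library, extension = 500L) {
  ext <- extendAlignments(library, extension)
  sum(mcols(ext)$weight * width(ext))
}

## base-resolution unnormalized coverage as an RleList
.baseCoverage <- function(library, extension) {
  ext <- extendAlignments(library, extension)
  coverage(ext, weight = mcols(ext)$weight)
}

## per-bin mean of an Rle over a chromosome of length L
.binMeans <- function(rle, L, binSize) {
  starts <- seq.int(1L, L, by = binSize)
  ends <- pmin(starts + binSize - 1L, L)
  as.numeric(viewMeans(Views(rle, start = starts, end = ends)))
}

#' Compute a depth-normalized coverage track
#'
#' Extends every alignment to \code{extension} bp from its sequenced end
#' with weight 1/(number of alignments), accumulates per-base coverage,
#' averages within \code{binSize} bins, and scales by \code{1e6 / depth}
#' (reads per million).  Bin values are per-base means, so they are
#' comparable across bin sizes, and the track is invariant to duplicating
#' the library.
#'
#' @param library An [AlignmentLibrary-class] with depth > 0.
#' @param binSize Bin width (bp); 25 suits locus profiles, 1000 genome-wide
#'   window analysis.
#' @param extension Fragment length (bp).
#' @return A [CoverageTrack-class].
#' @examples
#' cfg <- SimConfig(nReads = 2000)
#' gen <- buildToyGenome(cfg)
#' lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
#' trk <- computeCoverage(lib, binSize = 1000)
#' trk
#' @export
computeCoverage <- function(library, binSize = 25L, extension = 500L) {
  if (seqDepth(library) <= 0)
    stop("empty library: depth is 0, cannot normalize")
  cov <- .baseCoverage(library, extension)
  cl <- seqlengths(alignments(library))
  nf <- 1e6 / seqDepth(library)
  vals <- SimpleList(lapply(names(cl), function(chr) {
    # fractional weights accumulate tiny negative round-off; clamp at 0
    pmax(.binMeans(cov[[chr]], cl[[chr]], as.integer(binSize)), 0) * nf
  }))
  names(vals) <- names(cl)
  new("CoverageTrack", binSize = as.integer(binSize), values = vals,
      chromLengths = cl, normFactor = nf, depth = seqDepth(library),
      extension = as.integer(extension))
}

#' Named list of per-chromosome bin value vectors of a track
#' @param x A [CoverageTrack-class].
#' @return \code{SimpleList} of numeric vectors.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' Bin width of a coverage track (bp)
#' @param x A [CoverageTrack-class].
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

#' Depth normalization factor of a track (\code{1e6/depth})
#' @param x A [CoverageTrack-class].
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))

#' @export
setMethod("normFactor", "CoverageTrack", function(x) x@normFactor)

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf(
    "CoverageTrack: %d bp bins over %d chromosome(s), depth %g (normFactor %.4g), extension %d bp\n",
    object@binSize, length(object@chromLengths), object@depth,
    object@normFactor, object@extension))
})

#' Locus profile across one or more tracks
#'
#' Extracts the bins of each track intersecting an interval — the basis of
#' per-locus coverage panels (e.g. signal along a dsRNA-targeted gene, one
#' column per condition).
#'
#' @param tracks A [CoverageTrack-class] or named list of tracks sharing
#'   bin size and layout.
#' @param chrom Chromosome name.
#' @param start0,end Interval in 0-based half-open coordinates.
#' @return \code{data.frame} with \code{chrom}, \code{bin_start0},
#'   \code{bin_end} and one value column per track (input order).
#' @export
locusProfile <- function(tracks, chrom, start0, end) {
  if (is(tracks, "CoverageTrack")) tracks <- list(signal = tracks)
  t1 <- tracks[[1]]
  if (!chrom %in% names(chromLengths(t1)))
    stop("interval outside layout: unknown chromosome ", chrom)
  L <- chromLengths(t1)[[chrom]]
  if (start0 < 0 || end > L || start0 >= end)
    stop("interval outside layout bounds")
  b <- binSize(t1)
  first <- floor(start0 / b) + 1L
  last <- ceiling(end / b)
  starts0 <- (seq.int(first, last) - 1L) * b
  out <- data.frame(chrom = chrom, bin_start0 = starts0,
                    bin_end = pmin(starts0 + b, L))
  for (nm in names(tracks)) {
    trk <- tracks[[nm]]
    stopifnot(binSize(trk) == b)
    out[[nm]] <- trackValues(trk)[[chrom]][first:last]
  }
  out
}
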