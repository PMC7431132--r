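#' Construct an AlignmentLibrary
#'
#' @param reads \code{GRanges} of alignment records (1-based, width = read
#'   length, strand \code{+}/\code{-}) with metadata columns \code{readId}
#'   and \code{nHits}; seqlengths must be set (use
#'   \code{\link{layoutSeqinfo}}).
#' @param mark,genotype,role,sample Library metadata; \code{role} is
#'   \code{"chip"} or \code{"input"}.
#' @param replicate,generation Integer metadata.
#' @param depth Sequencing depth; defaults to the number of distinct
#'   \code{readId}s.
#' @return An [AlignmentLibrary-class].
#' @export
AlignmentLibrary <- function(reads, mark = "mark", genotype = "WT",
                             role = c("chip", "input"), replicate = 1L,
                             generation = 0L, sample = NULL, depth = NULL) {
  role <- match.arg(role)
  if (is.null(depth))
    depth <- length(unique(mcols(reads)$readId))
  if (is.null(sample))
    sample <- paste(mark, genotype, role,
                    paste0("rep", replicate), paste0("F", generation),
                    sep = "_")
  new("AlignmentLibrary", reads = reads, mark = mark, genotype = genotype,
      role = role, replicate = as.integer(replicate),
      generation = as.integer(generation), sample = sample,
      depth = as.numeric(depth))
}

#' The alignment records of a library as a \code{GRanges}
#' @param x An [AlignmentLibrary-class].
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @export
setMethod("alignments", "AlignmentLibrary", function(x) x@reads)

#' Sequencing depth (distinct reads) of a library or track
#' @param x An [AlignmentLibrary-class] or [CoverageTrack-class].
#' @export
setGeneric("seqDepth", function(x) standardGeneric("seqDepth"))

#' @export
setMethod("seqDepth", "AlignmentLibrary", function(x) x@depth)

#' @export
setMethod("seqDepth", "CoverageTrack", function(x) x@depth)

#' Library metadata as a named list
#' @param x An [AlignmentLibrary-class].
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @export
setMethod("sampleInfo", "AlignmentLibrary", function(x)
  list(sample = x@sample, mark = x@mark, genotype = x@genotype,
       role = x@role, replicate = x@replicate, generation = x@generation))

setMethod("show", "AlignmentLibrary", function(object) {
  cat(sprintf(
    "AlignmentLibrary '%s': %d records, depth %g (mark=%s genotype=%s role=%s rep=%d F%d)\n",
    object@sample, length(object@reads), object@depth, object@mark,
    object@genotype, object@role, object@replicate, object@generation))
})

#' Fractional alignment weights of a library
#'
#' Each record of a read reported at \code{n} loci receives weight
#' \code{1/n}, so a read always contributes total weight 1 to coverage.
#'
#' @param library An [AlignmentLibrary-class].
#' @return Numeric vector, one weight per record.
#' @export
alignmentWeights <- function(library) {
  1 / mcols(alignments(library))$nHits
}
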