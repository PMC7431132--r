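#' Construct a GenomeLayout
#'
#' Builds the coordinate frame of the pipeline from chromosome lengths plus
#' either a single arm fraction (each chromosome gets a left arm of
#' \code{floor(armFraction * length)} bp, a right arm of the same size, and
#' a center in between) or an explicit arm \code{GRanges} with a
#' \code{domain} column.
#'
#' @param chromLengths Named numeric/integer vector of chromosome lengths
#'   (bp).
#' @param arms Optional \code{GRanges} with metadata column \code{domain}
#'   (\code{"left"}, \code{"center"}, \code{"right"}) tiling each
#'   chromosome.  When missing, arms are derived from \code{armFraction}.
#' @param armFraction Fraction of each chromosome assigned to each arm.
#' @return A [GenomeLayout-class].
#' @examples
#' layout <- GenomeLayout(c(chrI = 1e6, chrII = 1e6), armFraction = 0.25)
#' armDomains(layout)
#' @export
GenomeLayout <- function(chromLengths, arms = NULL, armFraction = 0.25) {
  cl <- as.integer(chromLengths)
  names(cl) <- names(chromLengths)
  if (is.null(arms)) {
    stopifnot(armFraction > 0, armFraction <= 0.5)
    pieces <- lapply(names(cl), function(chr) {
      L <- cl[[chr]]
      a <- as.integer(floor(armFraction * L))
      starts <- c(1L, a + 1L, L - a + 1L)
      ends <- c(a, L - a, L)
      keep <- ends >= starts
      GRanges(factor(chr, levels = names(cl)),
              IRanges(starts[keep], ends[keep]),
              domain = c("left", "center", "right")[keep])
    })
    arms <- do.call(c, pieces)
  }
  sinfo <- Seqinfo(names(cl), seqlengths = cl)
  GenomeInfoDb::seqlevels(arms) <- names(cl)
  GenomeInfoDb::seqinfo(arms) <- sinfo
  new("GenomeLayout", chromLengths = cl, arms = arms)
}

#' Named integer chromosome lengths
#' @param x A [GenomeLayout-class], [CoverageTrack-class] or [SimConfig-class].
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@chromLengths)

#' @export
setMethod("chromLengths", "CoverageTrack", function(x) x@chromLengths)

#' @export
setMethod("chromLengths", "SimConfig", function(x) x@chromLengths)

#' Arm/center domain intervals as a \code{GRanges} with a \code{domain} column
#' @param x A [GenomeLayout-class].
#' @export
setGeneric("armDomains", function(x) standardGeneric("armDomains"))

#' @export
setMethod("armDomains", "GenomeLayout", function(x) x@arms)

#' Arm (left + right) intervals of a layout
#' @param layout A [GenomeLayout-class].
#' @return \code{GRanges} of the heterochromatic arm domains.
#' @export
armRanges <- function(layout) {
  a <- armDomains(layout)
  a[mcols(a)$domain %in% c("left", "right")]
}

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chromLengths), "chromosome(s),",
      sum(as.numeric(object@chromLengths)), "bp total\n")
  for (chr in names(object@chromLengths)) {
    a <- object@arms[as.character(seqnames(object@arms)) == chr]
    cat(sprintf("  %s (%d bp): %s\n", chr, object@chromLengths[[chr]],
                paste(sprintf("%s [%d,%d)", mcols(a)$domain,
                              start(a) - 1L, end(a)), collapse = " ")))
  }
})

#' Seqinfo of a layout
#' @param layout A [GenomeLayout-class].
#' @return A \code{Seqinfo}.
#' @export
layoutSeqinfo <- function(layout) {
  Seqinfo(names(chromLengths(layout)), seqlengths = chromLengths(layout))
}

## align a GRanges to a Seqinfo (set seqlevels, then seqinfo)
.setSeqinfo <- function(gr, sinfo) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(sinfo)
  GenomeInfoDb::seqinfo(gr) <- sinfo
  gr
}
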