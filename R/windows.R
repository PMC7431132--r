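#' Tile the genome into fixed-size windows
#'
#' Contiguous, non-overlapping windows covering every chromosome; the last
#' window of a chromosome may be short.  1 kb windows are the unit of the
#' genome-wide enrichment, arm-versus-center and correlation analyses.
#'
#' @param layout A [GenomeLayout-class].
#' @param windowSize Window width (bp), > 0.
#' @return \code{GRanges} of windows (sorted by chromosome, then start).
#' @examples
#' makeWindows(GenomeLayout(c(chr = 10500)), 1000)  # 11 windows, last 500 bp
#' @export
makeWindows <- function(layout, windowSize = 1000L) {
  stopifnot(windowSize > 0)
  windowSize <- as.integer(windowSize)
  cl <- chromLengths(layout)
  pieces <- lapply(names(cl), function(chr) {
    starts <- seq.int(1L, cl[[chr]], by = windowSize)
    GRanges(factor(chr, levels = names(cl)),
            IRanges(starts, pmin(starts + windowSize - 1L, cl[[chr]])))
  })
  out <- do.call(c, pieces)
  out <- .setSeqinfo(out, layoutSeqinfo(layout))
  out
}

#' Mean window signal of one or more coverage tracks
#'
#' Mean normalized per-base depth per window, computed exactly from the
#' track bins (the track's bin size must divide the window size so bins
#' nest inside windows).  When several replicate tracks are given, their
#' window signals are averaged — genome-wide scatter analyses use averaged
#' replicate values.
#'
#' @param tracks A [CoverageTrack-class] or list of tracks on the same
#'   layout with the same bin size.
#' @param windows \code{GRanges} from [makeWindows()].
#' @return Numeric vector, one value per window.
#' @export
windowSignal <- function(tracks, windows) {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  mat <- vapply(tracks, function(trk) {
    cl <- chromLengths(trk)
    b <- binSize(trk)
    ws <- max(width(windows))
    if (ws %% b != 0L)
      stop(sprintf(
        "bin size %d does not divide window size %d; recompute the track at a compatible bin size",
        b, ws))
    out <- numeric(length(windows))
    for (chr in names(cl)) {
      idx <- which(as.character(seqnames(windows)) == chr)
      if (!length(idx)) next
      v <- trackValues(trk)[[chr]]
      nb <- length(v)
      lens <- c(rep(b, nb - 1L), cl[[chr]] - (nb - 1L) * b)
      rle <- S4Vectors::Rle(v, lens)
      out[idx] <- as.numeric(viewMeans(
        Views(rle, start = start(windows)[idx], end = end(windows)[idx])))
    }
    out
  }, numeric(length(windows)))
  rowMeans(mat)
}

#' Pseudocounted elementwise ratio of two signal vectors
#'
#' \code{(num + pseudocount) / (den + pseudocount)}: the enrichment ratio
#' used for ChIP/input and mutant/WT window comparisons.  The pseudocount
#' floors empty windows at ratio 1 instead of 0/0.
#'
#' @param num,den Equal-length numeric vectors.
#' @param pseudocount Positive scalar; see [defaultPseudocount()] for a
#'   depth-aware default.
#' @return Numeric ratio vector with attributes \code{pseudocount}.
#' @export
ratioSignal <- function(num, den, pseudocount) {
  if (length(num) != length(den))
    stop("numerator and denominator differ in length")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure((num + pseudocount) / (den + pseudocount),
            pseudocount = pseudocount)
}

#' Depth-aware default pseudocount for window ratios
#'
#' The normalized per-base signal one read's extended fragment deposits
#' when spread over one window at the track's depth:
#' \code{normFactor * extension / windowSize}.  A scale-aware floor — one
#' read's worth of signal — rather than an arbitrary constant.
#'
#' @param track A [CoverageTrack-class].
#' @param windowSize Window width (bp).
#' @return Positive scalar.
#' @export
defaultPseudocount <- function(track, windowSize = 1000L) {
  normFactor(track) * track@extension / windowSize
}

#' Compare window signal between chromosome arms and centers
#'
#' Assigns every window to \code{arm} or \code{center} by its midpoint,
#' then reports quartiles, the arm/center median ratio, and a two-sided
#' rank-based (Wilcoxon) p-value, per chromosome and overall.  Echoing the
#' caution that statistically significant but tiny differences have little
#' biological meaning, the summary flags \code{negligible} when p < 0.05
#' yet the effect ratio lies within \code{[1/1.1, 1.1]}.
#'
#' @param signal Numeric vector from [windowSignal()].
#' @param windows Matching \code{GRanges} from [makeWindows()].
#' @param layout The [GenomeLayout-class] providing the arm partition.
#' @return List with \code{overall} (list: \code{n_arm}, \code{n_center},
#'   quartile vectors, \code{effect_ratio}, \code{statistic},
#'   \code{p_value}, \code{significant}, \code{negligible}) and
#'   \code{perChromosome} (\code{DataFrame}, one row per chromosome).
#' @export
armCenterCompare <- function(signal, windows, layout) {
  stopifnot(length(signal) == length(windows))
  mids <- GRanges(seqnames(windows),
                  IRanges(floor((start(windows) + end(windows)) / 2),
                          width = 1L))
  dom <- armDomains(layout)
  ov <- findOverlaps(mids, dom, ignore.strand = TRUE)
  grp <- rep(NA_character_, length(windows))
  grp[S4Vectors::queryHits(ov)] <-
    ifelse(mcols(dom)$domain[S4Vectors::subjectHits(ov)] == "center",
           "center", "arm")
  one <- function(keep, label) {
    a <- signal[keep & grp == "arm"]
    ce <- signal[keep & grp == "center"]
    if (!length(a) || !length(ce))
      stop(sprintf("%s has no %s windows", label,
                   if (!length(a)) "arm" else "center"))
    if (length(unique(c(a, ce))) == 1L) {
      p <- 1; stat <- NA_real_
    } else {
      wt <- stats::wilcox.test(a, ce, exact = FALSE)
      p <- wt$p.value; stat <- unname(wt$statistic)
    }
    ratio <- stats::median(a) / stats::median(ce)
    list(n_arm = length(a), n_center = length(ce),
         arm_quartiles = stats::quantile(a, c(0.25, 0.5, 0.75)),
         center_quartiles = stats::quantile(ce, c(0.25, 0.5, 0.75)),
         effect_ratio = ratio, statistic = stat, p_value = p,
         significant = p < 0.05,
         negligible = p < 0.05 && ratio >= 1 / 1.1 && ratio <= 1.1)
  }
  overall <- one(rep(TRUE, length(windows)), "genome")
  chroms <- names(chromLengths(layout))
  per <- lapply(chroms, function(chr)
    one(as.character(seqnames(windows)) == chr, chr))
  perDF <- DataFrame(
    chrom = chroms,
    n_arm = vapply(per, `[[`, 0L, "n_arm"),
    n_center = vapply(per, `[[`, 0L, "n_center"),
    arm_median = vapply(per, function(x) x$arm_quartiles[[2]], 0),
    center_median = vapply(per, function(x) x$center_quartiles[[2]], 0),
    effect_ratio = vapply(per, `[[`, 0, "effect_ratio"),
    p_value = vapply(per, `[[`, 0, "p_value"),
    negligible = vapply(per, `[[`, TRUE, "negligible"))
  list(overall = overall, perChromosome = perDF)
}

#' Pearson correlation between two mark signals
#'
#' Product-moment correlation of window-level signals (optionally
#' log2-transformed), plus a scatter table with two-fold guide columns for
#' plotting.
#'
#' @param signalA,signalB Equal-length numeric vectors over the same
#'   windows (>= 3 finite values).
#' @param log2 Transform both signals with \code{log2} first.
#' @return List with \code{r}, \code{n}, and \code{scatter} (a
#'   \code{data.frame} with \code{x}, \code{y}, \code{twofold_up},
#'   \code{twofold_down}).
#' @export
correlateMarks <- function(signalA, signalB, log2 = FALSE) {
  stopifnot(length(signalA) == length(signalB))
  if (log2) {
    signalA <- base::log2(signalA)
    signalB <- base::log2(signalB)
  }
  keep <- is.finite(signalA) & is.finite(signalB)
  if (sum(keep) < 3) stop("need at least 3 windows with finite values")
  a <- signalA[keep]; b <- signalB[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a signal vector")
  list(r = stats::cor(a, b), n = sum(keep),
       scatter = data.frame(x = a, y = b,
                            twofold_up = if (log2) a + 1 else 2 * a,
                            twofold_down = if (log2) a - 1 else a / 2))
}
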