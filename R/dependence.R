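#' Per-gene signal and weighted read mass
#'
#' For each gene span (optionally flank-extended, clipped to the
#' chromosome) returns (a) the mean per-base depth-normalized signal and
#' (b) the unnormalized weighted read mass: the sum over extended,
#' 1/nHits-weighted fragments of the fraction of the fragment inside the
#' span.  Mass is in read-equivalents (a fully contained read contributes
#' its weight) and sums to the library depth genome-wide, which makes it
#' the natural count for depth-conditioned testing.
#'
#' @param library An [AlignmentLibrary-class].
#' @param genes \code{GRanges} with a \code{gene_id} metadata column.
#' @param extension Fragment length (bp).
#' @param flank Extra bp added to both gene ends before measuring.
#' @return \code{DataFrame} with \code{gene_id}, \code{signal} (normalized
#'   mean per-base depth), \code{mass} (weighted read-equivalents).
#' @export
geneSignal <- function(library, genes, extension = 500L, flank = 0L) {
  sl <- seqlengths(alignments(library))
  if (!all(as.character(seqnames(genes)) %in% names(sl)))
    stop("gene outside layout: unknown chromosome")
  spans <- GRanges(seqnames(genes),
                   IRanges(pmax(start(genes) - flank, 1L),
                           pmin(end(genes) + flank,
                                sl[as.character(seqnames(genes))])))
  cov <- .baseCoverage(library, extension)
  sig <- numeric(length(spans))
  for (chr in unique(as.character(seqnames(spans)))) {
    idx <- which(as.character(seqnames(spans)) == chr)
    sig[idx] <- as.numeric(viewMeans(Views(cov[[chr]],
                                           start = start(spans)[idx],
                                           end = end(spans)[idx])))
  }
  ext <- extendAlignments(library, extension)
  ov <- findOverlaps(ext, spans, ignore.strand = TRUE)
  mass <- numeric(length(spans))
  if (length(ov)) {
    inter <- pintersect(ext[S4Vectors::queryHits(ov)],
                        spans[S4Vectors::subjectHits(ov)],
                        ignore.strand = TRUE)
    contrib <- mcols(ext)$weight[S4Vectors::queryHits(ov)] *
      width(inter) / width(ext)[S4Vectors::queryHits(ov)]
    agg <- tapply(contrib, S4Vectors::subjectHits(ov), sum)
    mass[as.integer(names(agg))] <- as.numeric(agg)
  }
  DataFrame(gene_id = mcols(genes)$gene_id,
            signal = sig * 1e6 / seqDepth(library), mass = mass)
}

## conditional binomial two-sample count test: is the gene's share of
## library 1 consistent with the depth ratio?  Masses are rounded
## half-to-even because exact tests need integers.
.countTestBinomial <- function(mass1, mass2, depth1, depth2) {
  x1 <- round(mass1); x2 <- round(mass2)
  if (x1 + x2 == 0) return(1)
  stats::binom.test(x1, x1 + x2, p = depth1 / (depth1 + depth2))$p.value
}

#' Call genes whose mark signal depends on a factor
#'
#' Mutant-versus-WT dependent-gene calling: for each replicate pair
#' (WT rep k vs mutant rep k), the fold change is computed on
#' depth-normalized gene signals with a pseudocount, and a p-value from a
#' depth-conditioned two-sample count test on the raw weighted read masses.
#' A gene is called dependent only if \emph{every} replicate pair shows
#' fold >= \code{foldThreshold} \emph{and} meets the significance
#' criterion — the two-fold, significant-in-both-replicas rule.
#'
#' @param wt,mut Lists of [AlignmentLibrary-class] replicates, paired by
#'   index; equal, positive lengths.
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param foldThreshold Minimum WT/mutant fold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param mode \code{"p"}: per-replicate p < alpha; \code{"fdr"}:
#'   Benjamini-Hochberg adjusted value <= alpha (adjusted across genes
#'   within each replicate pair).
#' @param pseudocount Added to both normalized signals before the ratio;
#'   default is one read's normalized signal over the gene span at the
#'   pair's mean depth (scale-aware floor).
#' @param extension,flank Passed to [geneSignal()].
#' @param testFun Pluggable significance strategy
#'   \code{function(mass1, mass2, depth1, depth2) -> p}; default is the
#'   conditional binomial test on half-to-even rounded masses.
#' @return \code{DataFrame}, one row per gene: \code{gene_id}; matrix
#'   columns \code{wtSignal}, \code{mutSignal}, \code{fold}, \code{p},
#'   \code{padj} (one column per replicate pair); logical
#'   \code{dependent}.  The full table is returned, not just the called
#'   set.
#' @export
callDependentGenes <- function(wt, mut, genes, foldThreshold = 2,
                               alpha = 0.05, mode = c("p", "fdr"),
                               pseudocount = NULL, extension = 500L,
                               flank = 0L, testFun = .countTestBinomial) {
  mode <- match.arg(mode)
  if (is(wt, "AlignmentLibrary")) wt <- list(wt)
  if (is(mut, "AlignmentLibrary")) mut <- list(mut)
  if (length(wt) == 0L || length(mut) == 0L)
    stop("need at least one WT and one mutant replicate")
  if (length(wt) != length(mut))
    stop("WT and mutant replicate lists must pair by index (equal lengths)")
  nPairs <- length(wt)
  nG <- length(genes)
  spanW <- pmin(end(genes) + flank,
                seqlengths(alignments(wt[[1]]))[
                  as.character(seqnames(genes))]) -
    pmax(start(genes) - flank, 1L) + 1L
  wtS <- mutS <- fold <- p <- padj <- matrix(NA_real_, nG, nPairs)
  for (k in seq_len(nPairs)) {
    sw <- geneSignal(wt[[k]], genes, extension, flank)
    sm <- geneSignal(mut[[k]], genes, extension, flank)
    pc <- pseudocount
    if (is.null(pc))
      pc <- extension * 1e6 /
        (spanW * (seqDepth(wt[[k]]) + seqDepth(mut[[k]])) / 2)
    wtS[, k] <- sw$signal
    mutS[, k] <- sm$signal
    fold[, k] <- (sw$signal + pc) / (sm$signal + pc)
    p[, k] <- mapply(testFun, sw$mass, sm$mass,
                     MoreArgs = list(depth1 = seqDepth(wt[[k]]),
                                     depth2 = seqDepth(mut[[k]])))
    padj[, k] <- stats::p.adjust(p[, k], method = "BH")
  }
  sigOK <- if (mode == "p") p < alpha else padj <= alpha
  dependent <- rowSums(fold >= foldThreshold & sigOK) == nPairs
  repNames <- paste0("rep", seq_len(nPairs))
  colnames(wtS) <- colnames(mutS) <- colnames(fold) <- colnames(p) <-
    colnames(padj) <- repNames
  DataFrame(gene_id = mcols(genes)$gene_id, wtSignal = I(wtS),
            mutSignal = I(mutS), fold = I(fold), p = I(p), padj = I(padj),
            dependent = dependent)
}

#' Summarize mutant/WT window ratios by region class
#'
#' Assigns each window (by midpoint) to GRH, GRTS or \code{rest}, and
#' summarizes the ratio distribution per class with quartiles — the basis
#' of class-wise boxplots of whole-genome mutant/WT coverage.
#'
#' @param ratios Numeric window ratio vector (e.g. from [ratioSignal()]).
#' @param windows Matching \code{GRanges} from [makeWindows()].
#' @param regions \code{GRanges} of region classes with a \code{class}
#'   metadata column (\code{"GRH"}/\code{"GRTS"}); may be empty or missing.
#' @return List with \code{assignments} (factor per window),
#'   \code{summary} (\code{DataFrame}: class, n, q25, median, q75) and
#'   \code{table} (long \code{data.frame} of per-window ratios for
#'   boxplot export).  Empty classes are reported with n = 0.
#' @export
regionClassSummary <- function(ratios, windows, regions = NULL) {
  stopifnot(length(ratios) == length(windows))
  cls <- rep("rest", length(windows))
  if (!is.null(regions) && length(regions)) {
    mids <- GRanges(seqnames(windows),
                    IRanges(floor((start(windows) + end(windows)) / 2),
                            width = 1L))
    ov <- findOverlaps(mids, regions, ignore.strand = TRUE)
    cls[S4Vectors::queryHits(ov)] <-
      mcols(regions)$class[S4Vectors::subjectHits(ov)]
  }
  lev <- "rest"
  if (!is.null(regions) && length(regions))
    lev <- c(unique(as.character(mcols(regions)$class)), "rest")
  assignments <- factor(cls, levels = lev)
  smry <- do.call(rbind, lapply(levels(assignments), function(cl) {
    v <- ratios[assignments == cl]
    if (!length(v))
      return(data.frame(class = cl, n = 0L, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(class = cl, n = length(v), q25 = q[[1]], median = q[[2]],
               q75 = q[[3]])
  }))
  list(assignments = assignments, summary = DataFrame(smry),
       table = data.frame(class = as.character(assignments), ratio = ratios))
}
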