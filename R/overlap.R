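#' Fisher's exact test for gene-set overlap
#'
#' Builds the 2x2 contingency table (in A / not in A) x (in B / not in B)
#' over a gene universe and tests one-sided enrichment of the overlap:
#' \eqn{P(X \ge |A \cap B|)} under the hypergeometric null.
#'
#' @param setA,setB Character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe Character vector of all eligible gene ids (the natural
#'   maximal choice is all annotated protein-coding genes).
#' @return List with \code{p_value}, \code{odds_ratio} (conditional MLE),
#'   \code{overlap} and \code{table} (the 2x2 matrix).
#' @examples
#' fisherOverlap(c("a", "b"), c("a", "b"), c("a", "b", "c", "d"))$p_value
#' # 1/6: both pairs drawn together out of choose(4, 2) arrangements
#' @export
fisherOverlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  out <- union(setdiff(setA, universe), setdiff(setB, universe))
  if (length(out))
    stop("set element(s) outside universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  k <- length(intersect(setA, setB))
  a <- length(setA); b <- length(setB); N <- length(universe)
  tab <- matrix(c(k, a - k, b - k, N - a - b + k), nrow = 2,
                dimnames = list(inA = c("yes", "no"),
                                inB = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       overlap = k, table = tab)
}

#' Venn analysis of 2-3 labeled gene sets
#'
#' Exact single, pairwise and (for three sets) triple intersection sizes
#' over a universe — the layout-ready size list of a proportional Venn
#' diagram — plus Fisher's exact enrichment test for every pair.
#'
#' @param sets Named list of 2 or 3 character vectors, each a subset of
#'   \code{universe}.
#' @param universe Character vector of all eligible gene ids.
#' @return List of class \code{"VennResult"}: \code{labels},
#'   \code{sizes} (named by label combinations joined with \code{"&"}),
#'   \code{universe_size}, and \code{tests} (\code{DataFrame} with one row
#'   per pair: labels, overlap, odds ratio, Fisher p-value).
#' @export
vennSets <- function(sets, universe) {
  stopifnot(length(sets) %in% 2:3, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  labs <- names(sets)
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(labs, k, simplify = FALSE)), recursive = FALSE)
  sizes <- vapply(combos, function(cm)
    length(Reduce(intersect, sets[cm])), 0L)
  names(sizes) <- vapply(combos, paste, "", collapse = "&")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    ft <- fisherOverlap(sets[[pr[1]]], sets[[pr[2]]], universe)
    data.frame(setA = pr[1], setB = pr[2], overlap = ft$overlap,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }))
  structure(list(labels = labs, sizes = sizes,
                 universe_size = length(unique(universe)),
                 tests = DataFrame(tests)),
            class = "VennResult")
}

#' @export
print.VennResult <- function(x, ...) {
  cat("VennResult over", x$universe_size, "genes\n  sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %s vs %s: overlap %d, OR %.3g, Fisher p = %.3g\n",
                x$tests$setA[i], x$tests$setB[i], x$tests$overlap[i],
                x$tests$odds_ratio[i], x$tests$p_value[i]))
  invisible(x)
}

#' Repeat composition of a gene set
#'
#' A gene "contains" a repeat iff their intervals intersect by at least
#' 1 bp (half-open convention: touching intervals do not overlap).
#' Reports the fraction of repeat-containing genes and, among those, the
#' per-repeat-class composition (a gene may contain several classes, so
#' class counts can exceed the number of repeat-containing genes) — the
#' pie-chart view of which repeat classes populate dependent genes.
#'
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param repeats \code{GRanges} with a \code{class} metadata column (e.g.
#'   \code{"LTR"}, \code{"DNA"}, \code{"Low_complexity"}).
#' @return List with \code{composition} (list: \code{n_genes},
#'   \code{n_genes_with_repeat}, \code{fraction_with_repeat}),
#'   \code{classTable} (\code{DataFrame}: class, n_genes, fraction among
#'   repeat-containing genes) and \code{perGene} (\code{DataFrame}:
#'   gene_id, n_repeats, classes).
#' @export
annotateRepeats <- function(genes, repeats) {
  if (any(start(genes) > end(genes)) ||
      (length(repeats) && any(start(repeats) > end(repeats))))
    stop("malformed intervals")
  ov <- findOverlaps(genes, repeats, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nGenes <- length(genes)
  hasRep <- logical(nGenes)
  hasRep[unique(qh)] <- TRUE
  classesPerGene <- lapply(seq_len(nGenes), function(i)
    unique(as.character(mcols(repeats)$class[sh[qh == i]])))
  perGene <- DataFrame(
    gene_id = mcols(genes)$gene_id,
    n_repeats = tabulate(qh, nGenes),
    classes = vapply(classesPerGene, paste, "", collapse = ","))
  nWith <- sum(hasRep)
  allClasses <- sort(unique(unlist(classesPerGene)))
  classTable <- DataFrame(
    class = allClasses,
    n_genes = vapply(allClasses, function(cl)
      sum(vapply(classesPerGene, function(x) cl %in% x, TRUE)), 0L),
    fraction = rep(NA_real_, length(allClasses)))
  if (nWith > 0) classTable$fraction <- classTable$n_genes / nWith
  list(composition = list(n_genes = nGenes, n_genes_with_repeat = nWith,
                          fraction_with_repeat = nWith / nGenes),
       classTable = classTable, perGene = perGene)
}
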