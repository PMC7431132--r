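## All files are plain text.  Intervals are written 0-based half-open
## (chrom-sizes TSV, BED, bedGraph, alignment TSV); GRanges are 1-based
## internally and converted at the boundary.  GFF input is 1-based closed
## and converted on read by rtracklayer.

#' @importFrom rtracklayer import export
NULL

.writeLines <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Write / read chromosome sizes
#'
#' Two-column tab-separated \code{chrom<TAB>length} file.
#'
#' @param layout A [GenomeLayout-class].
#' @param path File path.
#' @return \code{readChromSizes} returns a named integer vector.
#' @export
writeChromSizes <- function(layout, path) {
  cl <- chromLengths(layout)
  .writeLines(paste(names(cl), cl, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeChromSizes
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$length, df$chrom)
}

#' Write / read the arm/center partition as BED
#'
#' BED6 with the domain (\code{left}/\code{center}/\code{right}) in the
#' name field, 0-based half-open.
#'
#' @param layout A [GenomeLayout-class].
#' @param path File path.
#' @param sizesPath Chrom-sizes file accompanying the arm BED.
#' @return \code{readGenomeLayout} returns a [GenomeLayout-class]; when
#'   \code{armsPath} is NULL the arms are derived from \code{armFraction}.
#' @param armsPath,armFraction See Details.
#' @export
writeArmsBed <- function(layout, path) {
  a <- armDomains(layout)
  writeBed(a, path, names = mcols(a)$domain)
}

#' @rdname writeArmsBed
#' @export
readGenomeLayout <- function(sizesPath, armsPath = NULL, armFraction = 0.25) {
  cl <- readChromSizes(sizesPath)
  arms <- NULL
  if (!is.null(armsPath)) {
    arms <- readBed(armsPath)
    mcols(arms)$domain <- mcols(arms)$name
    mcols(arms)$name <- NULL
  }
  GenomeLayout(cl, arms = arms, armFraction = armFraction)
}

#' Write / read BED6 interval files
#'
#' Thin wrappers around \pkg{rtracklayer}: intervals on disk are 0-based
#' half-open; the in-memory \code{GRanges} is 1-based.  The name field
#' carries feature ids or repeat classes.
#'
#' @param gr \code{GRanges} to write.
#' @param path File path.
#' @param names Character vector for the BED name field.
#' @param scores Integer vector for the BED score field.
#' @return \code{readBed} returns a \code{GRanges} with \code{name} and
#'   \code{score} metadata columns.
#' @export
writeBed <- function(gr, path, names = NULL, scores = NULL) {
  out <- granges(gr)
  mcols(out)$name <- if (is.null(names)) mcols(gr)$name else names
  mcols(out)$score <- if (is.null(scores)) 0L else scores
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read gene annotations from GFF
#'
#' Imports a GFF file (1-based closed coordinates, converted by
#' \pkg{rtracklayer}), keeps \code{gene}/\code{mRNA} features only, and
#' takes the \code{ID} attribute as the \code{gene_id}.
#'
#' @param path GFF file path.
#' @return \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readGenesGFF <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF")
  gr <- gr[as.character(gr$type) %in% c("gene", "mRNA")]
  out <- granges(gr)
  mcols(out)$gene_id <- as.character(mcols(gr)$ID)
  out
}

.metaLine <- function(lib) {
  info <- sampleInfo(lib)
  enc <- function(x) gsub(" ", "%20", x)
  sprintf("sample=%s mark=%s genotype=%s role=%s replicate=%d generation=%d depth=%g",
          enc(info$sample), enc(info$mark), enc(info$genotype),
          info$role, info$replicate, info$generation, seqDepth(lib))
}

.parseMeta <- function(line) {
  kv <- strsplit(strsplit(sub("^[#@]\\S*\\s*", "", line), " ")[[1]], "=")
  vals <- lapply(kv, function(x) gsub("%20", " ", x[2]))
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Write an alignment library
#'
#' Two on-disk dialects:
#' \describe{
#'   \item{\code{tsv}}{6 columns \code{read_id, chrom, start0, strand,
#'     read_len, n_hits} (0-based half-open starts), preceded by
#'     \code{#}-comment lines carrying the library metadata and chromosome
#'     sizes.}
#'   \item{\code{sam}}{minimal SAM: \code{@HD}/\code{@SQ}/\code{@CO}
#'     header, then \code{QNAME FLAG RNAME POS(1-based) MAPQ=255
#'     CIGAR=<len>M * 0 0 * *} plus an \code{NH:i:} hit-count tag.  Only
#'     those fields are interpreted on read; unmapped records (FLAG 0x4)
#'     are skipped with a logged count.}
#' }
#' A write-then-read round trip reproduces the library exactly.
#'
#' @param library An [AlignmentLibrary-class].
#' @param path File path.
#' @param format \code{"tsv"} or \code{"sam"} (inferred from the extension
#'   by \code{readAlignments} when \code{"auto"}).
#' @return \code{readAlignments} returns an [AlignmentLibrary-class].
#' @export
writeAlignments <- function(library, path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  r <- alignments(library)
  cl <- seqlengths(r)
  if (format == "tsv") {
    head <- c("#heritChIP alignments v1",
              paste0("#meta ", .metaLine(library)),
              paste("#sq", names(cl), cl, sep = "\t"),
              paste(c("read_id", "chrom", "start0", "strand", "read_len",
                      "n_hits"), collapse = "\t"))
    body <- paste(mcols(r)$readId, as.character(seqnames(r)),
                  start(r) - 1L, as.character(strand(r)), width(r),
                  mcols(r)$nHits, sep = "\t")
    .writeLines(c(head, body), path)
  } else {
    head <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(cl), "\tLN:", cl),
              paste0("@CO\theritChIP ", .metaLine(library)))
    flag <- ifelse(as.character(strand(r)) == "-", 16L, 0L)
    body <- paste(mcols(r)$readId, flag, as.character(seqnames(r)),
                  start(r), 255L, paste0(width(r), "M"), "*", 0L, 0L,
                  "*", "*", paste0("NH:i:", mcols(r)$nHits), sep = "\t")
    .writeLines(c(head, body), path)
  }
  invisible(path)
}

#' @rdname writeAlignments
#' @export
readAlignments <- function(path, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  lines <- readLines(path)
  if (format == "tsv") {
    metaLine <- grep("^#meta ", lines, value = TRUE)
    sqLines <- grep("^#sq\t", lines, value = TRUE)
    body <- lines[!grepl("^#", lines)]
    body <- body[-1L]  # column header
    f <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(f, `[`, "", 2)
    gr <- GRanges(chrom,
                  IRanges(as.integer(vapply(f, `[`, "", 3)) + 1L,
                          width = as.integer(vapply(f, `[`, "", 5))),
                  strand = vapply(f, `[`, "", 4))
    mcols(gr)$readId <- vapply(f, `[`, "", 1)
    mcols(gr)$nHits <- as.integer(vapply(f, `[`, "", 6))
    sq <- strsplit(sqLines, "\t", fixed = TRUE)
    cl <- stats::setNames(as.integer(vapply(sq, `[`, "", 3)),
                          vapply(sq, `[`, "", 2))
    meta <- .parseMeta(metaLine[1])
  } else {
    hdr <- lines[grepl("^@", lines)]
    body <- lines[!grepl("^@", lines)]
    f <- strsplit(body, "\t", fixed = TRUE)
    flags <- as.integer(vapply(f, `[`, "", 2))
    unmapped <- bitwAnd(flags, 4L) != 0L
    if (any(unmapped))
      message(sum(unmapped), " unmapped record(s) skipped")
    f <- f[!unmapped]; flags <- flags[!unmapped]
    cig <- vapply(f, `[`, "", 6)
    if (!all(grepl("^[0-9]+M$", cig)))
      stop("unsupported CIGAR (only <len>M is interpreted)")
    gr <- GRanges(vapply(f, `[`, "", 3),
                  IRanges(as.integer(vapply(f, `[`, "", 4)),
                          width = as.integer(sub("M", "", cig))),
                  strand = ifelse(bitwAnd(flags, 16L) != 0L, "-", "+"))
    mcols(gr)$readId <- vapply(f, `[`, "", 1)
    nh <- vapply(f, function(x) {
      tag <- grep("^NH:i:", x[-(1:11)], value = TRUE)
      if (length(tag)) as.integer(sub("NH:i:", "", tag[1])) else 1L
    }, 0L)
    mcols(gr)$nHits <- nh
    sqh <- hdr[grepl("^@SQ", hdr)]
    cl <- stats::setNames(
      as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sqh)),
      sub(".*\tSN:(\\S+).*", "\\1", sqh))
    coLine <- grep("^@CO\theritChIP ", hdr, value = TRUE)
    meta <- if (length(coLine)) .parseMeta(coLine[1]) else
      list(sample = NULL, mark = "mark", genotype = "WT", role = "chip",
           replicate = "1", generation = "0", depth = NULL)
  }
  gr <- .setSeqinfo(gr, Seqinfo(names(cl), seqlengths = cl))
  # per-read consistency: all records of a read share nHits and their
  # count equals nHits
  tab <- table(mcols(gr)$readId)
  nh1 <- tapply(mcols(gr)$nHits, mcols(gr)$readId, function(x) x[1])
  bad <- names(tab)[tab != nh1[names(tab)]]
  if (length(bad))
    stop("n_hits inconsistent with record count for read(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  AlignmentLibrary(gr, mark = meta$mark, genotype = meta$genotype,
                   role = meta$role, replicate = as.integer(meta$replicate),
                   generation = as.integer(meta$generation),
                   sample = meta$sample,
                   depth = if (is.null(meta$depth)) NULL else
                     as.numeric(meta$depth))
}

#' Write / read a coverage track as bedGraph
#'
#' Standard bedGraph body (\code{chrom start0 end value}, 0-based
#' half-open) with adjacent equal-value bins merged; the track parameters
#' (bin size, normalization factor, depth, extension, chromosome sizes)
#' travel in \code{#}-comment header lines so a write-then-read round trip
#' reproduces the [CoverageTrack-class] (values to 10 significant digits).
#'
#' @param track A [CoverageTrack-class].
#' @param path File path.
#' @param keepZeros Emit zero-valued intervals (default drops them; either
#'   way the reader restores zeros from the chromosome sizes).
#' @return \code{readTrack} returns a [CoverageTrack-class].
#' @export
writeTrack <- function(track, path, keepZeros = FALSE) {
  cl <- chromLengths(track)
  head <- c(sprintf(
    "#heritChIP bedGraph binSize=%d normFactor=%.15g depth=%g extension=%d",
    binSize(track), normFactor(track), seqDepth(track), track@extension),
    paste("#sq", names(cl), cl, sep = "\t"))
  body <- character(0)
  b <- binSize(track)
  for (chr in names(cl)) {
    v <- trackValues(track)[[chr]]
    r <- rle(v)
    ends0 <- cumsum(r$lengths) * b
    starts0 <- c(0, ends0[-length(ends0)])
    ends0 <- pmin(ends0, cl[[chr]])
    keep <- if (keepZeros) rep(TRUE, length(r$values)) else r$values != 0
    if (any(keep))
      body <- c(body, paste(chr, starts0[keep], ends0[keep],
                            sprintf("%.10g", r$values[keep]), sep = "\t"))
  }
  .writeLines(c(head, body), path)
  invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) {
  lines <- readLines(path)
  metaLine <- grep("^#heritChIP bedGraph", lines, value = TRUE)[1]
  meta <- strsplit(sub("^#heritChIP bedGraph ", "", metaLine), " ")[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  b <- as.integer(vals[["binSize"]])
  sq <- strsplit(grep("^#sq\t", lines, value = TRUE), "\t", fixed = TRUE)
  cl <- stats::setNames(as.integer(vapply(sq, `[`, "", 3)),
                        vapply(sq, `[`, "", 2))
  body <- lines[!grepl("^#", lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, "", 1)
  s0 <- as.numeric(vapply(f, `[`, "", 2))
  val <- as.numeric(vapply(f, `[`, "", 4))
  e0 <- as.numeric(vapply(f, `[`, "", 3))
  valsList <- SimpleList(lapply(names(cl), function(chr) {
    nb <- ceiling(cl[[chr]] / b)
    v <- numeric(nb)
    idx <- which(chrom == chr)
    for (i in idx) {
      first <- s0[i] / b + 1L
      last <- ceiling(e0[i] / b)
      v[first:last] <- val[i]
    }
    v
  }))
  names(valsList) <- names(cl)
  new("CoverageTrack", binSize = b, values = valsList, chromLengths = cl,
      normFactor = as.numeric(vals[["normFactor"]]),
      depth = as.numeric(vals[["depth"]]),
      extension = as.integer(vals[["extension"]]))
}

#' Write the ground-truth table of a synthetic genome
#'
#' Tab-separated, 0-based half-open: one row per planted gene, GRH/GRTS
#' region and repeat copy, with class/target flags and family copy
#' numbers.  Planted folds per condition are obtained with
#' [plantedFolds()].
#'
#' @param truth A [SimTruth-class].
#' @param path File path.
#' @export
writeTruthTable <- function(truth, path) {
  g <- truth@genes; r <- truth@regions; p <- truth@repeats
  df <- rbind(
    data.frame(type = "gene", id = mcols(g)$gene_id,
               chrom = as.character(seqnames(g)), start0 = start(g) - 1L,
               end = end(g), class = ifelse(mcols(g)$target, "target", "."),
               copy = NA_integer_, copies = NA_integer_),
    if (length(r)) data.frame(type = "region", id = mcols(r)$region_id,
               chrom = as.character(seqnames(r)), start0 = start(r) - 1L,
               end = end(r), class = mcols(r)$class,
               copy = NA_integer_, copies = NA_integer_),
    if (length(p)) data.frame(type = "repeat", id = mcols(p)$family,
               chrom = as.character(seqnames(p)), start0 = start(p) - 1L,
               end = end(p), class = mcols(p)$class,
               copy = mcols(p)$copy, copies = mcols(p)$copies))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
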