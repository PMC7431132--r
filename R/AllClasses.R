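#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges Views viewMeans
#' @importFrom GenomicRanges GRanges granges findOverlaps pintersect seqnames
#'   start end width strand strand<- coverage
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importFrom BiocGenerics sort
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' Genome layout: chromosome sizes and arm/center partition
#'
#' A \code{GenomeLayout} holds the coordinate frame for the whole pipeline:
#' the ordered chromosomes with their lengths, and the partition of each
#' chromosome into a left arm, a center, and a right arm.  In
#' \emph{C. elegans}, the autosome arms are constitutive heterochromatin
#' domains; the arm boundaries here are a configuration input (either derived
#' from a single arm fraction or read from an arm BED file).
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot arms \code{GRanges} with metadata column \code{domain} in
#'   \code{c("left", "center", "right")}; the intervals of each chromosome
#'   tile \code{[1, length]} exactly, in order, without overlap (zero-width
#'   domains are dropped).
#'
#' @seealso [GenomeLayout()] for construction, [armDomains()],
#'   [chromLengths()].
#' @export
setClass("GenomeLayout",
  representation(chromLengths = "integer", arms = "GRanges"))

setValidity("GenomeLayout", function(object) {
  cl <- object@chromLengths
  if (length(cl) == 0L) return("no chromosomes")
  if (is.null(names(cl)) || anyDuplicated(names(cl)))
    return("chromLengths must be uniquely named")
  if (any(cl <= 0L)) return("chromosome lengths must be positive")
  arms <- object@arms
  if (!all(as.character(seqnames(arms)) %in% names(cl)))
    return("arm intervals on unknown chromosomes")
  if (!all(mcols(arms)$domain %in% c("left", "center", "right")))
    return("arm domain must be left/center/right")
  for (chr in names(cl)) {
    a <- arms[as.character(seqnames(arms)) == chr]
    a <- a[order(start(a))]
    if (length(a) == 0L) return(sprintf("chromosome %s has no domains", chr))
    if (start(a)[1] != 1L || end(a)[length(a)] != cl[[chr]])
      return(sprintf("domains of %s do not span the chromosome", chr))
    if (length(a) > 1L && any(start(a)[-1] != end(a)[-length(a)] + 1L))
      return(sprintf("domains of %s overlap or leave gaps", chr))
  }
  TRUE
})

#' Simulation configuration for the synthetic genome and read generator
#'
#' Full parameterization of the toy genome and the ChIP/input alignment
#' generator.  Enrichment is planted multiplicatively: chromosome arms carry
#' a constitutive heterochromatin background fold
#' (\code{backgroundArms}), and target features (GRH/GRTS regions and target
#' genes) carry, for a mark \eqn{m}, genotype \eqn{g} and generation
#' \eqn{t}, the planted fold
#' \deqn{f = 1 + (E_m - 1)\,\gamma_g\,d^{\,t}}
#' where \eqn{E_m} is \code{targetEnrichment[m]}, \eqn{\gamma_g} is
#' \code{genotypeEffects[g]} and \eqn{d} is \code{generationDecay}.
#'
#' @slot chromLengths Named integer vector, bp.
#' @slot armFraction Fraction of each chromosome assigned to each arm
#'   (0 to 0.5).
#' @slot nGenes,geneLength Number of genes and their common length (bp).
#' @slot nTargetGenes Number of genes planted as nuclear-RNAi targets
#'   (enriched in ChIP, lost in deficient genotypes).
#' @slot nGRH,nGRTS,regionLength Counts and common length (bp) of GRH and
#'   GRTS target regions; regions are placed on arms only.
#' @slot repeatFamilies \code{data.frame} with columns \code{class},
#'   \code{copies}, \code{length}: each family has \code{copies} identical
#'   copies of \code{length} bp; reads falling wholly inside a copy are
#'   reported at every copy (multimapping).
#' @slot backgroundArms Arm heterochromatin background fold (>= 1), applied
#'   to ChIP libraries only.
#' @slot targetEnrichment Named numeric, mark -> fold (>= 1) at target
#'   features in wild type at generation 0.
#' @slot genotypeEffects Named numeric, genotype -> multiplier in [0, 1]
#'   applied to (fold - 1).
#' @slot generationDecay Geometric decay factor d in [0, 1] applied to
#'   (fold - 1) per generation.
#' @slot nReads,readLength Reads per library and fixed read length (bp).
#' @slot targetRepeatFraction Fraction of target genes planted with a repeat
#'   copy inside the gene body.
#' @slot seed Integer seed governing genome construction.
#'
#' @seealso [SimConfig()], [buildToyGenome()], [simulateLibrary()].
#' @export
setClass("SimConfig",
  representation(
    chromLengths = "integer", armFraction = "numeric",
    nGenes = "integer", geneLength = "integer", nTargetGenes = "integer",
    nGRH = "integer", nGRTS = "integer", regionLength = "integer",
    repeatFamilies = "data.frame",
    backgroundArms = "numeric", targetEnrichment = "numeric",
    genotypeEffects = "numeric", generationDecay = "numeric",
    nReads = "integer", readLength = "integer",
    targetRepeatFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(length(object@chromLengths) > 0 && all(object@chromLengths > 0) &&
        !is.null(names(object@chromLengths)),
      "chromLengths must be positive and named")
  chk(object@armFraction > 0 && object@armFraction <= 0.5,
      "armFraction must be in (0, 0.5]")
  chk(all(c(object@nGenes, object@geneLength, object@regionLength,
            object@nReads, object@readLength) > 0),
      "counts and lengths must be positive")
  chk(object@nTargetGenes >= 0 && object@nTargetGenes <= object@nGenes,
      "nTargetGenes must be in [0, nGenes]")
  chk(object@nGRH >= 0 && object@nGRTS >= 0, "region counts must be >= 0")
  rf <- object@repeatFamilies
  chk(all(c("class", "copies", "length") %in% names(rf)),
      "repeatFamilies needs columns class, copies, length")
  if (nrow(rf) > 0)
    chk(all(rf$copies >= 1) && all(rf$length >= 1),
        "repeat copies and lengths must be positive")
  chk(object@backgroundArms >= 1, "backgroundArms fold must be >= 1")
  chk(length(object@targetEnrichment) > 0 &&
        all(object@targetEnrichment >= 1) &&
        !is.null(names(object@targetEnrichment)),
      "targetEnrichment must be a named map mark -> fold >= 1")
  chk(all(object@genotypeEffects >= 0 & object@genotypeEffects <= 1) &&
        !is.null(names(object@genotypeEffects)),
      "genotypeEffects must be a named map genotype -> [0,1]")
  chk(object@generationDecay >= 0 && object@generationDecay <= 1,
      "generationDecay must be in [0,1]")
  chk(object@targetRepeatFraction >= 0 && object@targetRepeatFraction <= 1,
      "targetRepeatFraction must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic genome
#'
#' Records where every annotated feature was planted and with what base
#' enrichment, so downstream calls can be scored against truth.  The planted
#' fold of any feature under a given (mark, genotype, generation) condition
#' is obtained with [plantedFolds()].
#'
#' @slot genes \code{GRanges} with \code{gene_id} and logical \code{target}.
#' @slot regions \code{GRanges} with \code{region_id} and \code{class}
#'   (\code{"GRH"} or \code{"GRTS"}).
#' @slot repeats \code{GRanges} with \code{family}, \code{class},
#'   \code{copy} (index) and \code{copies} (family copy number).
#' @slot config The [SimConfig-class] the genome was built from.
#'
#' @export
setClass("SimTruth",
  representation(genes = "GRanges", regions = "GRanges",
                 repeats = "GRanges", config = "SimConfig"))

#' A library of single-end alignment records
#'
#' One sequencing library after alignment: each record is one reported
#' alignment of a read (position, strand, read length), together with the
#' read's total number of equally good alignments \code{nHits} — the basis
#' of the 1/(number of alignments) fractional weighting.  A read reported at
#' \code{n} loci appears as \code{n} records sharing its \code{readId}, each
#' later weighted \code{1/n}, so every read contributes total weight 1.
#'
#' @slot reads \code{GRanges} (1-based, width = read length, strand set,
#'   seqlengths set) with metadata columns \code{readId} and \code{nHits}.
#' @slot mark,genotype,role,sample Character metadata; \code{role} is
#'   \code{"chip"} or \code{"input"}.
#' @slot replicate,generation Integer metadata.
#' @slot depth Number of distinct reads (the sequencing depth used for
#'   normalization).
#'
#' @seealso [AlignmentLibrary()], [readAlignments()], [computeCoverage()].
#' @export
setClass("AlignmentLibrary",
  representation(reads = "GRanges", mark = "character", genotype = "character",
                 role = "character", replicate = "integer",
                 generation = "integer", sample = "character",
                 depth = "numeric"))

setValidity("AlignmentLibrary", function(object) {
  r <- object@reads
  if (length(r)) {
    if (is.null(mcols(r)$readId) || is.null(mcols(r)$nHits))
      return("reads need readId and nHits metadata columns")
    if (any(mcols(r)$nHits < 1L)) return("nHits must be >= 1")
    sl <- seqlengths(r)
    if (any(is.na(sl))) return("reads must carry seqlengths")
    if (any(start(r) < 1L) || any(end(r) > sl[as.character(seqnames(r))]))
      return("read alignments outside chromosome bounds")
    tab <- table(mcols(r)$readId)
    nh <- tapply(mcols(r)$nHits, mcols(r)$readId, function(x) x[1])
    bad <- names(tab)[tab != nh[names(tab)]]
    if (length(bad))
      return(paste0("record count != nHits for read(s): ",
                    paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!object@role %in% c("chip", "input"))
    return("role must be 'chip' or 'input'")
  if (object@depth < 0) return("depth must be >= 0")
  TRUE
})

#' Binned, depth-normalized coverage track
#'
#' Per-chromosome vectors of mean per-base weighted coverage within fixed
#' bins, scaled to reads-per-million sequencing depth: each alignment is
#' extended to a fixed fragment length from its sequenced end, weighted
#' 1/(number of alignments), accumulated per base, averaged within bins and
#' multiplied by \code{normFactor = 1e6 / depth}.
#'
#' @slot binSize Bin width (bp).
#' @slot values Named \code{SimpleList} of numeric vectors, one per
#'   chromosome, length \code{ceiling(length / binSize)}.
#' @slot chromLengths Named integer vector (bp).
#' @slot normFactor \code{1e6 / depth}.
#' @slot depth Library sequencing depth (distinct reads).
#' @slot extension Fragment extension used (bp).
#'
#' @seealso [computeCoverage()], [writeTrack()], [windowSignal()].
#' @export
setClass("CoverageTrack",
  representation(binSize = "integer", values = "SimpleList",
                 chromLengths = "integer", normFactor = "numeric",
                 depth = "numeric", extension = "integer"))

setValidity("CoverageTrack", function(object) {
  if (object@binSize < 1L) return("binSize must be >= 1")
  if (!identical(names(object@values), names(object@chromLengths)))
    return("values and chromLengths must cover the same chromosomes")
  for (chr in names(object@values)) {
    v <- object@values[[chr]]
    if (length(v) != ceiling(object@chromLengths[[chr]] / object@binSize))
      return(sprintf("wrong number of bins on %s", chr))
    if (any(v < 0)) return("coverage values must be >= 0")
  }
  TRUE
})
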