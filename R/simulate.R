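#' Construct a simulation configuration
#'
#' Returns a [SimConfig-class] describing a toy multi-chromosome genome with
#' heterochromatic arm domains, GRH/GRTS nuclear-RNAi target regions,
#' protein-coding genes (a subset planted as targets), repeat families whose
#' copies induce multimapping, and the generative model for ChIP and input
#' alignment libraries.  Defaults emulate the experimental design of a
#' germline nuclear-RNAi ChIP study: two 1 Mb autosome-like chromosomes with
#' 25% arms at 3-fold heterochromatin background, 8-fold target enrichment
#' for both marks, genotypes that retain (\code{WT}), abolish
#' (\code{hrde-1}), nearly abolish (\code{set-32}) or partially retain
#' (\code{met-2 set-25}) target enrichment, and geometric transgenerational
#' decay of 0.7 per generation.
#'
#' @param chromLengths Named chromosome lengths (bp).
#' @param armFraction Fraction of each chromosome per arm.
#' @param nGenes,geneLength,nTargetGenes Gene complement.
#' @param nGRH,nGRTS,regionLength GRH/GRTS regions (placed on arms).
#' @param repeatFamilies \code{data.frame(class, copies, length)}.
#' @param backgroundArms Arm background fold (ChIP only).
#' @param targetEnrichment Named mark -> fold map.
#' @param genotypeEffects Named genotype -> multiplier map.
#' @param generationDecay Geometric decay d per generation.
#' @param nReads,readLength Library size and read length.
#' @param targetRepeatFraction Fraction of target genes containing a planted
#'   repeat copy.
#' @param seed Integer seed for genome construction.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- SimConfig(nReads = 1000)
#' cfg
#' @export
SimConfig <- function(chromLengths = c(chrI = 1000000, chrII = 1000000),
                      armFraction = 0.25,
                      nGenes = 200L, geneLength = 2000L,
                      nTargetGenes = 20L,
                      nGRH = 8L, nGRTS = 8L, regionLength = 2000L,
                      repeatFamilies = data.frame(
                        class = c("LTR", "DNA", "Low_complexity"),
                        copies = c(4L, 6L, 8L),
                        length = c(400L, 300L, 200L)),
                      backgroundArms = 3,
                      targetEnrichment = c(H3K23me3 = 8, H3K9me3 = 8),
                      genotypeEffects = c("WT" = 1, "hrde-1" = 0,
                                          "set-32" = 0.1,
                                          "met-2 set-25" = 0.7),
                      generationDecay = 0.7,
                      nReads = 50000L, readLength = 50L,
                      targetRepeatFraction = 0.6,
                      seed = 1L) {
  cl <- as.integer(chromLengths); names(cl) <- names(chromLengths)
  new("SimConfig", chromLengths = cl, armFraction = armFraction,
      nGenes = as.integer(nGenes), geneLength = as.integer(geneLength),
      nTargetGenes = as.integer(nTargetGenes), nGRH = as.integer(nGRH),
      nGRTS = as.integer(nGRTS), regionLength = as.integer(regionLength),
      repeatFamilies = repeatFamilies, backgroundArms = backgroundArms,
      targetEnrichment = targetEnrichment, genotypeEffects = genotypeEffects,
      generationDecay = generationDecay, nReads = as.integer(nReads),
      readLength = as.integer(readLength),
      targetRepeatFraction = targetRepeatFraction, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d chromosome(s) (%g bp), %d genes (%d targets), %d GRH + %d GRTS regions\n",
    length(object@chromLengths), sum(as.numeric(object@chromLengths)),
    object@nGenes, object@nTargetGenes, object@nGRH, object@nGRTS))
  cat(sprintf("  arms %.0f%% @ %gx; marks: %s; genotypes: %s\n",
              100 * object@armFraction, object@backgroundArms,
              paste(sprintf("%s=%gx", names(object@targetEnrichment),
                            object@targetEnrichment), collapse = ", "),
              paste(sprintf("%s=%g", names(object@genotypeEffects),
                            object@genotypeEffects), collapse = ", ")))
  cat(sprintf("  decay d=%g; %d reads x %d bp; seed %d\n",
              object@generationDecay, object@nReads, object@readLength,
              object@seed))
})

## Sequentially allocate non-overlapping intervals of fixed length inside
## the free space (a per-chromosome list of IRanges), optionally restricted
## to a GRanges mask.  Sampling is uniform over all admissible start
## positions.  Mutates nothing; returns list(placed = GRanges, free = list).
.placeIntervals <- function(free, n, len, what, mask = NULL) {
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- lapply(names(free), function(chr) {
      sp <- free[[chr]]
      if (!is.null(mask)) {
        m <- IRanges::ranges(mask[as.character(seqnames(mask)) == chr])
        sp <- IRanges::intersect(sp, m)
      }
      sp[IRanges::width(sp) >= len]
    })
    names(cand) <- names(free)
    caps <- unlist(lapply(cand, function(x) IRanges::width(x) - len + 1L),
                   use.names = FALSE)
    chrOf <- rep(names(cand), vapply(cand, length, 1L))
    if (length(caps) == 0L || sum(caps) == 0L)
      stop(sprintf(
        "placement failure: no room for %s %d of %d (length %d bp)",
        what, i, n, len))
    k <- sample.int(length(caps), 1L, prob = caps)
    sp <- unlist(lapply(cand, function(x) start(x)), use.names = FALSE)
    s <- sp[k] + sample.int(caps[k], 1L) - 1L
    placed[[i]] <- GRanges(factor(chrOf[k], levels = names(free)),
                           IRanges(s, width = len))
    free[[chrOf[k]]] <-
      IRanges::setdiff(free[[chrOf[k]]], IRanges(s, width = len))
  }
  list(placed = if (n > 0) do.call(c, placed) else GRanges(), free = free)
}

#' Build a toy genome with planted annotations and ground truth
#'
#' Deterministically (given \code{config@seed}) constructs the genome
#' layout, places GRH/GRTS regions on the arms, genes genome-wide, and
#' repeat-family copies both inside a fraction of target genes and in free
#' space, all mutually non-overlapping (repeat copies may lie inside target
#' genes by design).  Every placement is recorded in a [SimTruth-class].
#'
#' @param config A [SimConfig-class].
#' @return A list with elements \code{layout} ([GenomeLayout-class]),
#'   \code{genes}, \code{repeats}, \code{regions} (annotation
#'   \code{GRanges}) and \code{truth} ([SimTruth-class]).
#' @examples
#' gen <- buildToyGenome(SimConfig(nReads = 1000))
#' gen$layout
#' head(gen$genes)
#' @export
buildToyGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  layout <- GenomeLayout(config@chromLengths, armFraction = config@armFraction)
  sinfo <- layoutSeqinfo(layout)
  free <- lapply(as.list(config@chromLengths),
                 function(L) IRanges(1L, L))

  # GRH/GRTS target regions live on arms only
  arms <- armRanges(layout)
  nR <- config@nGRH + config@nGRTS
  regions <- GRanges(seqinfo = sinfo)
  if (nR > 0) {
    pl <- .placeIntervals(free, nR, config@regionLength,
                          "GRH/GRTS region", mask = arms)
    free <- pl$free
    regions <- pl$placed
    regions <- .setSeqinfo(regions, sinfo)
    cls <- c(rep("GRH", config@nGRH), rep("GRTS", config@nGRTS))
    mcols(regions)$region_id <- sprintf("%s_%02d", cls,
                                        c(seq_len(config@nGRH),
                                          seq_len(config@nGRTS)))
    mcols(regions)$class <- cls
  }

  pl <- .placeIntervals(free, config@nGenes, config@geneLength, "gene")
  free <- pl$free
  genes <- pl$placed
  genes <- .setSeqinfo(genes, sinfo)
  genes <- BiocGenerics::sort(genes)
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
  target <- logical(length(genes))
  targetIdx <- sample.int(config@nGenes, config@nTargetGenes)
  target[targetIdx] <- TRUE
  mcols(genes)$target <- target
  strand(genes) <- sample(c("+", "-"), length(genes), replace = TRUE)

  # repeat copies: a fraction of target genes get one copy planted inside
  # the gene body; the rest of each family goes to intergenic free space
  rf <- config@repeatFamilies
  repeats <- GRanges(seqinfo = sinfo)
  if (nrow(rf) > 0 && sum(rf$copies) > 0) {
    queue <- do.call(rbind, lapply(seq_len(max(rf$copies)), function(k) {
      has <- rf$copies >= k
      data.frame(family = which(has), copy = k)
    }))
    nInGene <- round(config@targetRepeatFraction * config@nTargetGenes)
    fits <- rf$length[queue$family] <= config@geneLength
    inGeneRows <- utils::head(which(fits), nInGene)
    if (length(inGeneRows) < nInGene)
      stop(sprintf(
        "placement failure: %d repeat copies fit inside genes, %d requested",
        length(inGeneRows), nInGene))
    hostGenes <- genes[sample(targetIdx, nInGene)]
    entries <- vector("list", nrow(queue))
    for (r in seq_along(inGeneRows)) {
      qr <- queue[inGeneRows[r], ]
      len <- rf$length[qr$family]
      g <- hostGenes[r]
      s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
      entries[[inGeneRows[r]]] <-
        GRanges(seqnames(g), IRanges(s, width = len))
    }
    freeRows <- setdiff(seq_len(nrow(queue)), inGeneRows)
    for (r in freeRows) {
      qr <- queue[r, ]
      pl <- .placeIntervals(free, 1L, rf$length[qr$family],
                            sprintf("repeat copy (%s)", rf$class[qr$family]))
      free <- pl$free
      entries[[r]] <- pl$placed
    }
    repeats <- do.call(c, entries)
    repeats <- .setSeqinfo(repeats, sinfo)
    mcols(repeats)$family <- rf$class[queue$family]
    mcols(repeats)$class <- rf$class[queue$family]
    mcols(repeats)$copy <- queue$copy
    mcols(repeats)$copies <- rf$copies[queue$family]
  }

  truth <- new("SimTruth", genes = genes, regions = regions,
               repeats = repeats, config = config)
  list(layout = layout, genes = genes, repeats = repeats,
       regions = regions, truth = truth)
}

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d genes (%d targets), %d GRH/GRTS regions, %d repeat copies\n",
    length(object@genes), sum(mcols(object@genes)$target),
    length(object@regions), length(object@repeats)))
})

#' Planted enrichment fold for one condition
#'
#' The generative model plants, at every target feature of mark \eqn{m} in
#' genotype \eqn{g} at generation \eqn{t},
#' \deqn{f = 1 + (E_m - 1)\,\gamma_g\,d^{\,t}.}
#' Input libraries and non-target features have fold 1.
#'
#' @param config A [SimConfig-class].
#' @param mark,genotype Keys into the config maps.
#' @param generation Non-negative integer.
#' @return The scalar planted fold.
#' @export
plantedFold <- function(config, mark, genotype, generation = 0L) {
  if (!mark %in% names(config@targetEnrichment))
    stop("unknown mark: ", mark)
  if (!genotype %in% names(config@genotypeEffects))
    stop("unknown genotype: ", genotype)
  1 + (config@targetEnrichment[[mark]] - 1) *
    config@genotypeEffects[[genotype]] *
    config@generationDecay^generation
}

#' Truth table of planted folds for one condition
#'
#' Expands the ground truth into one row per annotated gene and region with
#' its planted enrichment fold under the given (mark, genotype, generation).
#'
#' @param truth A [SimTruth-class].
#' @param mark,genotype,generation Condition keys.
#' @return A \code{DataFrame} with columns \code{feature_id}, \code{type}
#'   (\code{gene}, \code{GRH}, \code{GRTS}), \code{chrom}, \code{start0},
#'   \code{end} (0-based half-open) and \code{fold}.
#' @export
plantedFolds <- function(truth, mark, genotype, generation = 0L) {
  f <- plantedFold(truth@config, mark, genotype, generation)
  g <- truth@genes
  r <- truth@regions
  DataFrame(
    feature_id = c(mcols(g)$gene_id, mcols(r)$region_id),
    type = c(rep("gene", length(g)), mcols(r)$class),
    chrom = c(as.character(seqnames(g)), as.character(seqnames(r))),
    start0 = c(start(g), start(r)) - 1L,
    end = c(end(g), end(r)),
    fold = c(ifelse(mcols(g)$target, f, 1), rep(f, length(r))))
}

## deterministic per-library seed derived from the config seed and the
## library coordinates; kept below 2^31
.librarySeed <- function(config, mark, genotype, role, replicate, generation) {
  h <- sum(utf8ToInt(paste(mark, genotype, role, sep = "|")))
  (abs(config@seed) * 97L + h * 131L + as.integer(replicate) * 7919L +
     as.integer(generation) * 104729L) %% 2147483647L
}

#' Simulate one ChIP or input alignment library
#'
#' Draws \code{config@nReads} read 5' start positions from a mixture of
#' uniform background and planted excess: ChIP libraries multiply the
#' sampling weight by \code{backgroundArms} on arm domains and by the
#' planted fold (see [plantedFold()]) over each target feature; input
#' libraries are pure background.  Reads falling wholly inside a repeat
#' copy are reported at every copy of the family (one record per copy, all
#' sharing the read id, with \code{nHits} = family copy number); all other
#' reads have \code{nHits = 1}.  Strand is uniform.
#'
#' @param config A [SimConfig-class].
#' @param truth The matching [SimTruth-class] from [buildToyGenome()].
#' @param mark,genotype Condition keys (must exist in the config maps).
#' @param role \code{"chip"} or \code{"input"}.
#' @param replicate,generation Integers recorded in the metadata and mixed
#'   into the default seed.
#' @param seed Integer seed for this library; defaults to a deterministic
#'   value derived from the config seed and the library coordinates.
#' @return An [AlignmentLibrary-class] with exactly \code{nReads} distinct
#'   reads.
#' @examples
#' cfg <- SimConfig(nReads = 2000)
#' gen <- buildToyGenome(cfg)
#' lib <- simulateLibrary(cfg, gen$truth, "H3K23me3", "WT", "chip")
#' lib
#' @export
simulateLibrary <- function(config, truth, mark, genotype,
                            role = c("chip", "input"), replicate = 1L,
                            generation = 0L, seed = NULL) {
  role <- match.arg(role)
  if (config@nReads <= 0L) stop("nReads must be positive")
  if (!genotype %in% names(config@genotypeEffects))
    stop("unknown genotype: ", genotype)
  if (!mark %in% names(config@targetEnrichment))
    stop("unknown mark: ", mark)
  if (is.null(seed))
    seed <- .librarySeed(config, mark, genotype, role, replicate, generation)
  set.seed(seed)
  rl <- config@readLength
  cl <- config@chromLengths
  layout <- GenomeLayout(cl, armFraction = config@armFraction)
  sinfo <- layoutSeqinfo(layout)

  # per-chromosome sampling weight over admissible start positions
  weights <- lapply(names(cl), function(chr) {
    Lp <- cl[[chr]] - rl + 1L
    w <- rep(1, Lp)
    if (role == "chip") {
      boost <- function(gr, fold) {
        keep <- as.character(seqnames(gr)) == chr
        gr <- gr[keep]
        fold <- fold[keep]
        for (i in seq_along(gr)) {
          s <- max(1L, start(gr)[i]); e <- min(Lp, end(gr)[i])
          if (s <= e) w[s:e] <<- w[s:e] * fold[i]
        }
      }
      a <- armRanges(layout)
      boost(a, rep(config@backgroundArms, length(a)))
      pf <- plantedFolds(truth, mark, genotype, generation)
      feat <- GRanges(pf$chrom, IRanges(pf$start0 + 1L, pf$end))
      boost(feat, pf$fold)
    }
    w
  })
  names(weights) <- names(cl)

  totals <- vapply(weights, sum, 0)
  nPer <- as.vector(stats::rmultinom(1, config@nReads, prob = totals))
  pieces <- lapply(seq_along(weights), function(ci) {
    n <- nPer[ci]
    if (n == 0L) return(GRanges(seqinfo = sinfo))
    rle <- S4Vectors::Rle(weights[[ci]])
    rlens <- S4Vectors::runLength(rle)
    rvals <- S4Vectors::runValue(rle)
    rstarts <- cumsum(c(1L, rlens[-length(rlens)]))
    run <- sample.int(length(rlens), n, replace = TRUE,
                      prob = rlens * rvals)
    off <- pmin(as.integer(floor(stats::runif(n) * rlens[run])),
                rlens[run] - 1L)
    pos <- rstarts[run] + off
    GRanges(names(weights)[ci], IRanges(pos, width = rl),
            strand = sample(c("+", "-"), n, replace = TRUE),
            seqinfo = sinfo)
  })
  reads <- do.call(c, pieces)
  mcols(reads)$readId <- sprintf("r%07d", seq_along(reads))
  mcols(reads)$nHits <- rep(1L, length(reads))

  # multimapping: a read wholly inside a repeat copy is reported at every
  # copy of its family, at the same offset
  reps <- truth@repeats
  if (length(reps)) {
    ov <- findOverlaps(reads, reps, type = "within", ignore.strand = TRUE)
    if (length(ov)) {
      hitQ <- S4Vectors::queryHits(ov)
      hitS <- S4Vectors::subjectHits(ov)
      extra <- vector("list", length(hitQ))
      for (k in seq_along(hitQ)) {
        i <- hitQ[k]; j <- hitS[k]
        fam <- mcols(reps)$family[j]
        copies <- reps[mcols(reps)$family == fam]
        offs <- start(reads)[i] - start(reps)[j]
        gr <- GRanges(seqnames(copies),
                      IRanges(start(copies) + offs, width = rl),
                      strand = rep(strand(reads)[i], length(copies)),
                      seqinfo = sinfo)
        mcols(gr)$readId <- rep(mcols(reads)$readId[i], length(copies))
        mcols(gr)$nHits <- rep(length(copies), length(copies))
        extra[[k]] <- gr
      }
      reads <- c(reads[-hitQ], do.call(c, extra))
    }
  }
  lib <- AlignmentLibrary(reads, mark = mark, genotype = genotype,
                          role = role, replicate = replicate,
                          generation = generation, depth = config@nReads)
  validObject(lib)
  lib
}

#' Simulate a heritable RNAi generation series
#'
#' One ChIP and one input library per generation F0..Fg; the planted fold at
#' target features follows \eqn{f_t = 1 + (f_0 - 1) d^{\,t}}, emulating an
#' exogenous trigger whose mark persists and decays over generations after
#' dsRNA feeding stops.
#'
#' @param config,truth As for [simulateLibrary()].
#' @param mark Mark key.
#' @param generations Last generation index (>= 1); F0..F(generations) are
#'   produced.
#' @param genotype Genotype key (default \code{"WT"}).
#' @param seed Base seed; generation \code{t} uses \code{seed + 2t} (ChIP)
#'   and \code{seed + 2t + 1} (input).
#' @return Named list \code{F0..Fg}, each element
#'   \code{list(chip =, input =)} of [AlignmentLibrary-class].
#' @export
simulateHeritableSeries <- function(config, truth, mark, generations,
                                    genotype = "WT", seed = config@seed) {
  stopifnot(generations >= 1)
  out <- lapply(0:generations, function(g) {
    list(chip = simulateLibrary(config, truth, mark, genotype, "chip",
                                generation = g, seed = seed + 2L * g),
         input = simulateLibrary(config, truth, mark, genotype, "input",
                                 generation = g, seed = seed + 2L * g + 1L))
  })
  names(out) <- paste0("F", 0:generations)
  out
}
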