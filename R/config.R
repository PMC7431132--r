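#' Read a pipeline run configuration
#'
#' YAML configuration merged over defaults.  Analysis parameters default to
#' the pipeline's canonical values: read extension 500 bp, 1 kb windows,
#' two-fold threshold, alpha 0.05, per-replicate p-value mode, flank 0.
#' The \code{sim} section parameterizes [SimConfig()]
#' (\code{targetEnrichment}/\code{genotypeEffects} as maps,
#' \code{repeatFamilies} as a list of \code{class/copies/length} rows).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Named list (a run configuration).
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    extension = 500L, windowSize = 1000L, binSize = 1000L,
    locusBinSize = 25L, foldThreshold = 2, alpha = 0.05, mode = "p",
    flank = 0L, pseudocount = NULL, replicates = 2L, seed = 1L,
    marks = NULL, genotypes = NULL, outputDir = "heritchip_out",
    sim = list())
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Build a SimConfig from a run configuration
#'
#' @param runConfig List from [readRunConfig()].
#' @return A [SimConfig-class]; the run seed is used unless the \code{sim}
#'   section sets its own.
#' @export
simConfigFromRun <- function(runConfig) {
  sim <- runConfig$sim
  if (!is.null(sim$chromLengths)) sim$chromLengths <- unlist(sim$chromLengths)
  if (!is.null(sim$targetEnrichment))
    sim$targetEnrichment <- unlist(sim$targetEnrichment)
  if (!is.null(sim$genotypeEffects))
    sim$genotypeEffects <- unlist(sim$genotypeEffects)
  if (!is.null(sim$repeatFamilies) && !is.data.frame(sim$repeatFamilies))
    sim$repeatFamilies <- do.call(rbind,
      lapply(sim$repeatFamilies, as.data.frame))
  if (is.null(sim$seed)) sim$seed <- runConfig$seed
  do.call(SimConfig, sim)
}
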