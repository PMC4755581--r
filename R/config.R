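#' Pipeline configuration
#'
#' All tunables of the segmentation pipeline with their defaults. Emitting
#' lengths \code{lc0 = 30} and \code{lc1 = 5} pixels parameterize the
#' anisotropic ray length bound; \code{angularStep} is the ray fan
#' resolution; \code{stableWindow} (w, px), \code{stabilityThreshold} and
#' \code{stableSlices} (M) drive the stable-edge test; \code{zStep} and
#' \code{xyPixel} are the voxel dimensions in micrometres.
#'
#' @slot lc0 maximal emitting length scale, px.
#' @slot lc1 minimal emitting length, px.
#' @slot clampRayLength use the clamped ray-length bound (TRUE) or the
#'   literal unclamped form (FALSE).
#' @slot angularStep ray fan step, degrees.
#' @slot gapMinRun minimal consecutive hitless rays forming a gap.
#' @slot trunkHalfAngle trunk sector half-width around the normal to the
#'   cell vector, degrees.
#' @slot extendedRayTol parallelism tolerance that triggers extended rays
#'   from skeleton endpoints, degrees.
#' @slot cannySigma Gaussian sigma for edge detection, px.
#' @slot cannyLow,cannyHigh hysteresis thresholds as fractions of the
#'   gradient dynamic range.
#' @slot diffusionIters coherence-filter iterations.
#' @slot minSpur spur length pruned during edge cleanup, px.
#' @slot rayGroupWidth ray group width for Laplace-verified PCA, degrees.
#' @slot pcaWindow sampling window for Laplace-verified PCA, px.
#' @slot stableWindow neighbor window width w, px.
#' @slot stabilityThreshold stable-point ratio above which an edge is
#'   stable.
#' @slot stableSlices number of neighboring slices M.
#' @slot maxDisplacement per-point displacement cap between slices, px.
#' @slot slicesPerNucleus target slice count spanned by one nucleus.
#' @slot zStep z spacing, micrometres.
#' @slot xyPixel in-plane pixel size, micrometres.
#' @slot contrastNormalize optional per-slice contrast normalization.
#' @slot seed integer seed for any stochastic step.
#' @export
setClass("PipelineConfig",
  representation(lc0 = "numeric", lc1 = "numeric", clampRayLength = "logical",
                 angularStep = "numeric", gapMinRun = "integer",
                 trunkHalfAngle = "numeric", extendedRayTol = "numeric",
                 cannySigma = "numeric", cannyLow = "numeric",
                 cannyHigh = "numeric", diffusionIters = "integer",
                 minSpur = "integer", rayGroupWidth = "numeric",
                 pcaWindow = "integer", stableWindow = "numeric",
                 stabilityThreshold = "numeric", stableSlices = "integer",
                 maxDisplacement = "numeric", slicesPerNucleus = "integer",
                 zStep = "numeric", xyPixel = "numeric",
                 contrastNormalize = "logical", seed = "integer"),
  validity = function(object) {
    pos <- c(lc0 = object@lc0, lc1 = object@lc1,
             angularStep = object@angularStep, cannySigma = object@cannySigma,
             stableWindow = object@stableWindow, zStep = object@zStep,
             xyPixel = object@xyPixel, maxDisplacement = object@maxDisplacement)
    if (any(pos <= 0))
      return(paste("non-positive:", paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@lc0 <= object@lc1) return("lc0 must exceed lc1")
    if (object@cannyHigh <= object@cannyLow)
      return("cannyHigh must exceed cannyLow")
    if (object@stabilityThreshold < 0 || object@stabilityThreshold > 1)
      return("stabilityThreshold must be in [0, 1]")
    TRUE
  })

#' Create a pipeline configuration
#'
#' @param ... named overrides of any \linkS4class{PipelineConfig} slot.
#' @return A \linkS4class{PipelineConfig} with defaults where not
#'   overridden.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@lc0   # 30 px
#' @export
pipelineConfig <- function(...) {
  defaults <- list(lc0 = 30, lc1 = 5, clampRayLength = TRUE,
                   angularStep = 1, gapMinRun = 3L, trunkHalfAngle = 60,
                   extendedRayTol = 15, cannySigma = 1.5, cannyLow = 0.1,
                   cannyHigh = 0.2, diffusionIters = 5L, minSpur = 3L,
                   rayGroupWidth = 7, pcaWindow = 5L, stableWindow = 5,
                   stabilityThreshold = 0.30, stableSlices = 3L,
                   maxDisplacement = 3, slicesPerNucleus = 14L,
                   zStep = 0.25, xyPixel = 0.412,
                   contrastNormalize = FALSE, seed = 1L)
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  ints <- c("gapMinRun", "diffusionIters", "minSpur", "pcaWindow",
            "stableSlices", "slicesPerNucleus", "seed")
  for (f in ints) defaults[[f]] <- as.integer(defaults[[f]])
  do.call(new, c(list("PipelineConfig"), defaults))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, paste(slot(object, s), collapse = ", ")))
})

#' Write a configuration to a YAML file
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path YAML file written by \code{\link{writePipelineConfig}} (or by
#'   hand).
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}
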