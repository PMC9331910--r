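#' Pipeline configuration
#'
#' Bundles every tunable of the view-to-report pipeline. The configuration
#' round-trips losslessly through JSON (\code{\link{writePipelineConfig}} /
#' \code{\link{readPipelineConfig}}); unknown keys are rejected.
#'
#' @param unit input unit scale to cm (1 = cm, 100 = m).
#' @param cropBox a \linkS4class{CropBox} applied to each raw view.
#' @param segmentation a \linkS4class{RegionGrowingParams}; NULL skips
#'   per-view segmentation (for pre-segmented input).
#' @param icp an \linkS4class{ICPParams}.
#' @param mls an \linkS4class{MLSParams}.
#' @param downsampleEdge voxel edge for model downsampling (cm).
#' @param alpha alpha-shape radius (cm).
#' @param voxelEdge voxel-volume edge (cm).
#' @param poisson a \linkS4class{PoissonParams}.
#' @param methods volume estimators to run.
#' @param seed master seed for every stochastic stage.
#' @param verbose print stage progress.
#' @return A named list of class \code{bunchmetricConfig}.
#' @export
pipelineConfig <- function(unit = 1,
                           cropBox = bunchmetric::cropBox(xRange = c(-8, 8),
                                                          yRange = c(-11, 11)),
                           segmentation = regionGrowingParams(),
                           icp = icpParams(),
                           mls = mlsParams(),
                           downsampleEdge = 0.3,
                           alpha = 2,
                           voxelEdge = 0.2,
                           poisson = poissonParams(),
                           methods = c("gm", "ch", "as", "vb", "pb"),
                           seed = 1L,
                           verbose = FALSE) {
  cfg <- list(unit = unit, cropBox = cropBox, segmentation = segmentation,
              icp = icp, mls = mls, downsampleEdge = downsampleEdge,
              alpha = alpha, voxelEdge = voxelEdge, poisson = poisson,
              methods = methods, seed = as.integer(seed), verbose = verbose)
  class(cfg) <- "bunchmetricConfig"
  cfg
}

.CONFIG_KEYS <- c("unit", "cropBox", "segmentation", "icp", "mls",
                  "downsampleEdge", "alpha", "voxelEdge", "poisson",
                  "methods", "seed", "verbose")

#' Write a pipeline configuration as JSON
#'
#' @param config a \code{bunchmetricConfig}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  s4ToList <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    out <- lapply(slotNames(x), function(nm) slot(x, nm))
    names(out) <- slotNames(x)
    out
  }
  ser <- list(
    unit = config$unit,
    cropBox = s4ToList(config$cropBox),
    segmentation = if (is.null(config$segmentation)) NULL
                   else s4ToList(config$segmentation),
    icp = s4ToList(config$icp),
    mls = s4ToList(config$mls),
    downsampleEdge = config$downsampleEdge,
    alpha = config$alpha,
    voxelEdge = config$voxelEdge,
    poisson = s4ToList(config$poisson),
    methods = config$methods,
    seed = config$seed,
    verbose = config$verbose)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path a JSON file written by \code{\link{writePipelineConfig}} (or
#'   hand-authored with the same schema). Unknown keys raise an error.
#' @return A \code{bunchmetricConfig}.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  cb <- raw$cropBox
  seg <- raw$segmentation
  pipelineConfig(
    unit = raw$unit,
    cropBox = cropBox(xRange = num(cb$xRange), yRange = num(cb$yRange),
                      zRange = num(cb$zRange)),
    segmentation = if (is.null(seg)) NULL else
      regionGrowingParams(k = seg$k, angleThreshold = seg$angleThreshold,
                          curvatureThreshold = seg$curvatureThreshold,
                          minClusterSize = seg$minClusterSize),
    icp = icpParams(maxIterations = raw$icp$maxIterations,
                    translationTolerance = raw$icp$translationTolerance,
                    rotationTolerance = raw$icp$rotationTolerance,
                    maxCorrespondenceDistance = raw$icp$maxCorrespondenceDistance,
                    downsampleEdge = raw$icp$downsampleEdge),
    mls = mlsParams(radius = raw$mls$radius, h = raw$mls$h,
                    polynomialOrder = raw$mls$polynomialOrder),
    downsampleEdge = raw$downsampleEdge,
    alpha = raw$alpha,
    voxelEdge = raw$voxelEdge,
    poisson = poissonParams(gridResolution = raw$poisson$gridResolution,
                            gaussianWidth = if (is.null(raw$poisson$gaussianWidth))
                              NA_real_ else as.numeric(raw$poisson$gaussianWidth),
                            isoOffset = raw$poisson$isoOffset),
    methods = raw$methods,
    seed = raw$seed,
    verbose = isTRUE(raw$verbose))
}

#' Run the full view-to-report pipeline
#'
#' Stages: per-view segmentation (crop + region growing), hierarchical view
#' merging (PCA coarse alignment + ICP), voxel-grid downsampling, MLS
#' smoothing, then size extraction and the configured volume estimators.
#'
#' @param views either a character vector of cloud file paths (one per
#'   view) or a list of \linkS4class{PointCloud}s.
#' @param config a \code{bunchmetricConfig}.
#' @param vTrue optional reference volume to carry into the report.
#' @param sampleId report label.
#' @return List with \code{report} (a \linkS4class{VolumeReport}),
#'   \code{model} (the final \linkS4class{PointCloud}), and \code{log}
#'   (per-stage records: timings, point counts, registration RMSEs).
#' @export
runPipeline <- function(views, config = pipelineConfig(), vTrue = NA_real_,
                        sampleId = "sample") {
  log <- list()
  note <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    log[[length(log) + 1]] <<- rec
    if (isTRUE(config$verbose))
      message(sprintf("[%s] %s", stage,
                      paste(names(rec)[-1], unlist(rec[-1]), sep = "=",
                            collapse = " ")))
  }
  t0 <- proc.time()["elapsed"]
  if (is.character(views)) {
    missing <- views[!file.exists(views)]
    if (length(missing)) stop("missing view file(s): ",
                              paste(missing, collapse = ", "))
    views <- lapply(views, readCloud, unit = config$unit)
  }
  note("load", views = length(views),
       points = sum(vapply(views, nPoints, 1L)))
  if (!is.null(config$segmentation)) {
    views <- lapply(seq_along(views), function(i) {
      seg <- segmentBunch(views[[i]], box = config$cropBox,
                          params = config$segmentation)
      seg$cloud
    })
    note("segment", points = sum(vapply(views, nPoints, 1L)))
  }
  merged <- mergeViews(views, params = config$icp)
  note("merge", points = nPoints(merged$cloud),
       meanRmse = mean(merged$log$rmse))
  model <- downsampleCloud(merged$cloud, config$downsampleEdge)
  note("downsample", points = nPoints(model))
  model <- mlsSmooth(model, config$mls)
  note("mls", points = nPoints(model))
  report <- measureAll(model, alpha = config$alpha,
                       voxelEdge = config$voxelEdge,
                       poisson = config$poisson, methods = config$methods,
                       vTrue = vTrue, sampleId = sampleId)
  note("measure", seconds = round(proc.time()["elapsed"] - t0, 2))
  list(report = report, model = model,
       log = list(stages = log, registration = merged$log))
}
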