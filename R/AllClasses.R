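#' @import methods
#' @importFrom stats rnorm runif sd lm coef cor
#' @importFrom utils head tail
#' @useDynLib bunchmetric, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PointCloud: 3D points with optional normals and curvatures
#'
#' The central container of the package. Coordinates are held in centimetres
#' internally. Normals, when present, are unit vectors; curvatures are the
#' surface-variation statistic (smallest local covariance eigenvalue over the
#' eigenvalue sum), which lies in [0, 1/3].
#'
#' @slot points numeric matrix (n x 3) of coordinates, cm.
#' @slot normals optional numeric matrix (n x 3) of unit normals.
#' @slot curvatures optional numeric vector of per-point surface variation.
#' @export
setClass("PointCloud",
  representation(points = "matrix", normals = "matrixOrNULL",
                 curvatures = "numericOrNULL"),
  prototype(normals = NULL, curvatures = NULL))

setValidity("PointCloud", function(object) {
  p <- object@points
  if (ncol(p) != 3) return("points must have 3 columns")
  if (nrow(p) > 0 && !all(is.finite(p))) return("all coordinates must be finite")
  if (!is.null(object@normals)) {
    nm <- object@normals
    if (!all(dim(nm) == dim(p))) return("normals must match points in shape")
    if (nrow(nm) > 0) {
      len <- sqrt(rowSums(nm^2))
      if (any(abs(len - 1) > 1e-6)) return("normals must have unit length (tol 1e-6)")
    }
  }
  if (!is.null(object@curvatures)) {
    cv <- object@curvatures
    if (length(cv) != nrow(p)) return("curvatures must match point count")
    if (length(cv) > 0 && (any(!is.finite(cv)) || any(cv < 0) || any(cv > 1)))
      return("curvatures must lie in [0, 1]")
  }
  TRUE
})

#' TriangleMesh: indexed triangle surface
#'
#' @slot vertices numeric matrix (n x 3), cm.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices,
#'   counter-clockwise when viewed from outside.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must have 3 columns")
  f <- object@faces
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(f) > 0) {
    if (any(f < 1) || any(f > nrow(object@vertices)))
      return("face indices out of range")
  }
  TRUE
})

#' RigidTransform: rotation plus translation
#'
#' Maps coordinates from one frame into another: x' = R x + t.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation length-3 numeric, cm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (length(object@translation) != 3) return("translation must have length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (tol 1e-9)")
  if (det(R) < 0) return("rotation must have determinant +1")
  TRUE
})

#' VoxelGrid: occupancy grid of a point cloud
#'
#' @slot origin length-3 numeric, grid origin (cm).
#' @slot edge positive voxel edge length (cm).
#' @slot occupied integer matrix (m x 3) of unique occupied cell indices.
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", edge = "numeric", occupied = "matrix"))

setValidity("VoxelGrid", function(object) {
  if (length(object@origin) != 3) return("origin must have length 3")
  if (length(object@edge) != 1 || object@edge <= 0) return("edge must be a positive scalar")
  occ <- object@occupied
  if (ncol(occ) != 3) return("occupied must have 3 columns")
  if (anyDuplicated(occ)) return("occupied indices must be unique")
  TRUE
})

#' PCAFrame: object-intrinsic coordinate frame
#'
#' Centroid plus orthonormal axes from the eigendecomposition of the point
#' covariance, columns ordered by descending eigenvalue.
#'
#' @slot centroid length-3 numeric (cm).
#' @slot axes 3x3 orthonormal matrix, det +1, columns ordered by variance.
#' @slot eigenvalues non-negative, descending.
#' @export
setClass("PCAFrame",
  representation(centroid = "numeric", axes = "matrix", eigenvalues = "numeric"))

setValidity("PCAFrame", function(object) {
  A <- object@axes
  if (!all(dim(A) == c(3, 3))) return("axes must be 3x3")
  if (max(abs(crossprod(A) - diag(3))) > 1e-9) return("axes must be orthonormal (tol 1e-9)")
  if (det(A) < 0) return("axes must form a right-handed frame")
  ev <- object@eigenvalues
  if (length(ev) != 3 || any(ev < -1e-12)) return("eigenvalues must be 3 non-negatives")
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  TRUE
})

#' Bunch: ground-truth berry geometry of a synthetic grape bunch
#'
#' @slot centers numeric matrix (b x 3) of berry centers (cm).
#' @slot radii per-berry radii (cm), all positive.
#' @export
setClass("Bunch", representation(centers = "matrix", radii = "numeric"))

setValidity("Bunch", function(object) {
  if (ncol(object@centers) != 3) return("centers must have 3 columns")
  if (length(object@radii) != nrow(object@centers)) return("radii must match centers")
  if (any(object@radii <= 0)) return("all radii must be positive")
  TRUE
})

#' BunchSpec: recipe for a synthetic grape bunch
#'
#' @slot berryCount number of berries.
#' @slot radiusMean,radiusSd berry radius distribution (cm), truncated normal;
#'   the mean must exceed three standard deviations.
#' @slot bunchHeight vertical extent of the berry-center envelope (cm).
#' @slot rachisProfile function mapping relative height in [0,1] to the
#'   envelope radius (cm) around the vertical rachis (cluster taper).
#' @slot packingOverlap allowed berry interpenetration as a fraction of
#'   radius, in [0, 0.5).
#' @slot seed integer; the same spec always generates the identical bunch.
#' @export
setClass("BunchSpec",
  representation(berryCount = "integer", radiusMean = "numeric",
                 radiusSd = "numeric", bunchHeight = "numeric",
                 rachisProfile = "function", packingOverlap = "numeric",
                 seed = "integer"))

setValidity("BunchSpec", function(object) {
  if (object@berryCount < 1) return("berryCount must be positive")
  if (!(object@radiusMean > 3 * object@radiusSd && object@radiusSd > 0))
    return("need radiusMean > 3*radiusSd > 0")
  if (object@bunchHeight <= 0) return("bunchHeight must be positive")
  if (object@packingOverlap < 0 || object@packingOverlap >= 0.5)
    return("packingOverlap must lie in [0, 0.5)")
  TRUE
})

#' ScanSpec: simulated turntable acquisition settings
#'
#' Defaults mirror the acquisition protocol the package emulates: 12 views
#' 30 degrees apart about the vertical Y axis, a depth camera 100 cm away
#' with 0.2 cm noise, an optional background board plus 1 percent uniform
#' outliers.
#'
#' @slot views number of views; views * stepDeg must equal 360 for full
#'   coverage.
#' @slot stepDeg turntable step about the vertical Y axis, degrees.
#' @slot noiseSd isotropic Gaussian sensor noise (cm).
#' @slot pointsPerView target number of bunch surface points per view.
#' @slot background add a planar board and uniform outliers.
#' @slot cameraDistance camera distance from the bunch (cm).
#' @slot seed integer driving all scan randomness.
#' @export
setClass("ScanSpec",
  representation(views = "integer", stepDeg = "numeric", noiseSd = "numeric",
                 pointsPerView = "integer", background = "logical",
                 cameraDistance = "numeric", seed = "integer"))

setValidity("ScanSpec", function(object) {
  if (object@views < 1) return("views must be positive")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (abs(object@views * object@stepDeg - 360) > 1e-9)
    return("views * stepDeg must equal 360 for full coverage")
  if (object@cameraDistance <= 0) return("cameraDistance must be positive")
  TRUE
})

#' RegionGrowingParams: thresholds for curvature-seeded region growing
#'
#' @slot k neighborhood size for normal/curvature estimation (>= 4).
#' @slot angleThreshold degrees, in (0, 90): a neighbor joins a region when
#'   the angle between its normal and the current seed normal is below this.
#' @slot curvatureThreshold dimensionless, in (0, 1): a joined point becomes
#'   a new seed only when its surface variation is below this.
#' @slot minClusterSize clusters smaller than this are discarded.
#' @export
setClass("RegionGrowingParams",
  representation(k = "integer", angleThreshold = "numeric",
                 curvatureThreshold = "numeric", minClusterSize = "integer"))

setValidity("RegionGrowingParams", function(object) {
  if (object@k < 4) return("k must be >= 4")
  if (object@angleThreshold <= 0 || object@angleThreshold >= 90)
    return("angleThreshold must lie in (0, 90)")
  if (object@curvatureThreshold <= 0 || object@curvatureThreshold >= 1)
    return("curvatureThreshold must lie in (0, 1)")
  if (object@minClusterSize < 1) return("minClusterSize must be positive")
  TRUE
})

#' CropBox: axis-aligned coordinate-range filter
#'
#' Each range is an optional closed interval (min, max) in cm; absent ranges
#' leave that axis unconstrained.
#'
#' @slot xRange,yRange,zRange optional length-2 numeric (min, max).
#' @export
setClass("CropBox",
  representation(xRange = "numericOrNULL", yRange = "numericOrNULL",
                 zRange = "numericOrNULL"),
  prototype(xRange = NULL, yRange = NULL, zRange = NULL))

setValidity("CropBox", function(object) {
  for (nm in c("xRange", "yRange", "zRange")) {
    r <- slot(object, nm)
    if (!is.null(r)) {
      if (length(r) != 2) return(paste(nm, "must have length 2"))
      if (r[1] >= r[2]) return(paste(nm, "must satisfy min < max"))
    }
  }
  TRUE
})

#' ICPParams: iterative-closest-point settings
#'
#' @slot maxIterations iteration cap.
#' @slot translationTolerance cm; converged when the per-iteration
#'   translation update falls below this (jointly with rotationTolerance).
#' @slot rotationTolerance degrees.
#' @slot maxCorrespondenceDistance cm; matches farther than this are dropped.
#' @slot downsampleEdge cm; 0 disables pre-registration downsampling.
#' @export
setClass("ICPParams",
  representation(maxIterations = "integer", translationTolerance = "numeric",
                 rotationTolerance = "numeric",
                 maxCorrespondenceDistance = "numeric",
                 downsampleEdge = "numeric"))

setValidity("ICPParams", function(object) {
  if (object@maxIterations < 1) return("maxIterations must be positive")
  if (object@translationTolerance <= 0) return("translationTolerance must be positive")
  if (object@rotationTolerance <= 0) return("rotationTolerance must be positive")
  if (object@maxCorrespondenceDistance <= 0)
    return("maxCorrespondenceDistance must be positive")
  if (object@downsampleEdge < 0) return("downsampleEdge must be >= 0")
  TRUE
})

#' MLSParams: moving-least-squares smoothing settings
#'
#' @slot radius neighborhood radius for the local plane fit (cm).
#' @slot h Gaussian weight bandwidth (cm); radius >= h > 0.
#' @slot polynomialOrder only order 1 (plane) is supported.
#' @export
setClass("MLSParams",
  representation(radius = "numeric", h = "numeric", polynomialOrder = "integer"))

setValidity("MLSParams", function(object) {
  if (!(object@radius >= object@h && object@h > 0))
    return("need radius >= h > 0")
  if (object@polynomialOrder != 1L) return("only polynomialOrder = 1 is supported")
  TRUE
})

#' AlphaShapeParams: circumsphere radius bound for the alpha complex
#'
#' @slot alpha positive length (cm): tetrahedra with circumsphere radius
#'   above alpha are removed from the Delaunay complex.
#' @export
setClass("AlphaShapeParams", representation(alpha = "numeric"))

setValidity("AlphaShapeParams", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0) return("alpha must be positive")
  TRUE
})

#' PoissonParams: indicator-function reconstruction settings
#'
#' @slot gridResolution cells along the longest bounding-box axis (>= 32).
#' @slot gaussianWidth bandwidth of the smoothing filter (cm); NA selects
#'   1.5 times the mean nearest-neighbor spacing of the input cloud.
#' @slot isoOffset added to the extraction isovalue (which defaults to the
#'   mean indicator value interpolated at the input samples).
#' @export
setClass("PoissonParams",
  representation(gridResolution = "integer", gaussianWidth = "numeric",
                 isoOffset = "numeric"))

setValidity("PoissonParams", function(object) {
  if (object@gridResolution < 32) return("gridResolution must be >= 32")
  if (!is.na(object@gaussianWidth) && object@gaussianWidth <= 0)
    return("gaussianWidth must be positive (or NA for automatic)")
  TRUE
})

#' SizeTriple: length, width and height of a bunch (cm)
#'
#' @slot l,w,h positive extents measured in the bunch's own principal-axis
#'   frame.
#' @export
setClass("SizeTriple", representation(l = "numeric", w = "numeric", h = "numeric"))

setValidity("SizeTriple", function(object) {
  if (any(c(object@l, object@w, object@h) <= 0)) return("l, w, h must be positive")
  TRUE
})

setClassUnion("SizeTripleOrNULL", c("SizeTriple", "NULL"))

#' VolumeReport: one bunch's measured sizes and volumes
#'
#' Mirrors a per-sample record of sizes and the five volume estimates plus
#' the true (reference) volume. Absent quantities are NA.
#'
#' @slot sampleId identifier.
#' @slot size SizeTriple or NULL when size extraction failed.
#' @slot vTrue,vGM,vCH,vAS,vVB,vPB volumes in cubic cm (NA when absent).
#' @slot notes named character vector of per-estimator warnings.
#' @export
setClass("VolumeReport",
  representation(sampleId = "character", size = "SizeTripleOrNULL",
                 vTrue = "numeric", vGM = "numeric", vCH = "numeric",
                 vAS = "numeric", vVB = "numeric", vPB = "numeric",
                 notes = "character"),
  prototype(size = NULL, vTrue = NA_real_, vGM = NA_real_, vCH = NA_real_,
            vAS = NA_real_, vVB = NA_real_, vPB = NA_real_,
            notes = character(0)))

setValidity("VolumeReport", function(object) {
  for (nm in c("vTrue", "vGM", "vCH", "vAS", "vVB", "vPB")) {
    v <- slot(object, nm)
    if (!is.na(v) && v <= 0) return(paste(nm, "must be positive when present"))
  }
  TRUE
})

#' PairedSeries: truth/estimate pairs for accuracy statistics
#'
#' @slot truth reference values y.
#' @slot estimate estimated values y-hat, same length.
#' @slot unit measurement unit label.
#' @export
setClass("PairedSeries",
  representation(truth = "numeric", estimate = "numeric", unit = "character"))

setValidity("PairedSeries", function(object) {
  if (length(object@truth) != length(object@estimate))
    return("truth and estimate must have equal length")
  if (length(object@truth) < 2) return("need at least 2 pairs")
  if (!all(is.finite(object@truth)) || !all(is.finite(object@estimate)))
    return("values must be finite")
  TRUE
})
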