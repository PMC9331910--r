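#' Create a PointCloud
#'
#' @param points numeric matrix (n x 3), coordinates in cm.
#' @param normals optional numeric matrix (n x 3) of unit normals.
#' @param curvatures optional numeric vector of surface-variation values.
#' @return A \linkS4class{PointCloud}.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), ncol = 3))
#' nPoints(pc)
#' @export
pointCloud <- function(points, normals = NULL, curvatures = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
  }
  new("PointCloud", points = points, normals = normals, curvatures = curvatures)
}

#' @describeIn pointCloud number of points
#' @param cloud a PointCloud.
#' @export
nPoints <- function(cloud) nrow(cloud@points)

#' @describeIn pointCloud coordinate matrix accessor
#' @export
cloudPoints <- function(cloud) cloud@points

#' @describeIn pointCloud normals accessor (NULL when absent)
#' @export
cloudNormals <- function(cloud) cloud@normals

#' @describeIn pointCloud curvature accessor (NULL when absent)
#' @export
cloudCurvatures <- function(cloud) cloud@curvatures

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points (cm)%s%s\n", nrow(object@points),
              if (!is.null(object@normals)) ", with normals" else "",
              if (!is.null(object@curvatures)) ", with curvatures" else ""))
  if (nrow(object@points) > 0) {
    rng <- apply(object@points, 2, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                rng[1,1], rng[2,1], rng[1,2], rng[2,2], rng[1,3], rng[2,3]))
  }
})

#' Create a TriangleMesh
#'
#' @param vertices numeric matrix (n x 3), cm.
#' @param faces integer matrix (m x 3), 1-based vertex indices with
#'   counter-clockwise outward winding.
#' @return A \linkS4class{TriangleMesh}.
#' @export
triangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' @describeIn triangleMesh vertex matrix accessor
#' @param mesh a TriangleMesh.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn triangleMesh face index matrix accessor
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' Create a RigidTransform
#'
#' The rotation is projected onto SO(3) (closest orthonormal matrix by SVD)
#' so that compositions of many transforms cannot drift out of validity.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric (cm).
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  s <- svd(rotation)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  new("RigidTransform", rotation = R, translation = as.numeric(translation))
}

#' Apply a rigid transform to points or a cloud
#'
#' Rotates normals (when present) without translating them.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param x a PointCloud or an n x 3 matrix.
#' @return Object of the same kind as \code{x}.
#' @export
applyTransform <- function(transform, x) {
  R <- transform@rotation
  t <- transform@translation
  if (is(x, "PointCloud")) {
    p <- x@points %*% t(R)
    p <- sweep(p, 2, t, "+")
    nm <- x@normals
    if (!is.null(nm)) nm <- nm %*% t(R)
    pointCloud(p, normals = nm, curvatures = x@curvatures)
  } else {
    sweep(as.matrix(x) %*% t(R), 2, t, "+")
  }
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first, then \code{a}.
#'
#' @param a,b RigidTransforms.
#' @return The composed \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#'
#' @param transform a RigidTransform.
#' @return The inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Rotation about a coordinate axis
#'
#' @param axis "x", "y" or "z".
#' @param degrees rotation angle.
#' @return A \linkS4class{RigidTransform} with zero translation.
#' @export
axisRotation <- function(axis = c("y", "x", "z"), degrees) {
  axis <- match.arg(axis)
  a <- degrees * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
  rigidTransform(R, c(0, 0, 0))
}

#' Rotation angle of a rigid transform
#'
#' @param transform a RigidTransform.
#' @return Angle in degrees of the axis-angle decomposition of the rotation.
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) cm\n",
              rotationAngle(object), object@translation[1], object@translation[2],
              object@translation[3]))
})

#' @describeIn pcaFrame centroid accessor
#' @export
frameCentroid <- function(frame) frame@centroid

#' @describeIn pcaFrame axes accessor (columns by descending variance)
#' @export
frameAxes <- function(frame) frame@axes

#' @describeIn pcaFrame eigenvalues accessor (descending)
#' @export
frameEigenvalues <- function(frame) frame@eigenvalues

setMethod("show", "PCAFrame", function(object) {
  cat(sprintf("PCAFrame: centroid (%.2f, %.2f, %.2f), eigenvalues %.3g / %.3g / %.3g\n",
              object@centroid[1], object@centroid[2], object@centroid[3],
              object@eigenvalues[1], object@eigenvalues[2], object@eigenvalues[3]))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: edge %.3f cm, %d occupied cells\n",
              object@edge, nrow(object@occupied)))
})

setMethod("show", "Bunch", function(object) {
  cat(sprintf("Bunch: %d berries, radius %.2f-%.2f cm\n",
              length(object@radii), min(object@radii), max(object@radii)))
})

#' Create a BunchSpec
#'
#' Defaults describe a red table-grape bunch: berry radius 1.3 +/- 0.1 cm
#' (berries 2.5-3 cm across), a roughly cylindrical envelope about 18 cm
#' tall that tapers toward the tip, and moderate berry interpenetration
#' where neighbors press against each other.
#'
#' @param berryCount number of berries.
#' @param radiusMean,radiusSd berry radius distribution (cm).
#' @param bunchHeight vertical extent of the berry-center envelope (cm).
#' @param rachisProfile function of relative height u in [0,1] (0 = top)
#'   giving the envelope radius (cm).
#' @param packingOverlap allowed interpenetration fraction, in [0, 0.5).
#' @param seed integer seed.
#' @return A \linkS4class{BunchSpec}.
#' @export
bunchSpec <- function(berryCount = 60, radiusMean = 1.3, radiusSd = 0.1,
                      bunchHeight = 18,
                      rachisProfile = function(u) 4.6 * sqrt(pmax(0, 1 - 0.6 * u^2)),
                      packingOverlap = 0.4, seed = 1L) {
  new("BunchSpec", berryCount = as.integer(berryCount), radiusMean = radiusMean,
      radiusSd = radiusSd, bunchHeight = bunchHeight,
      rachisProfile = rachisProfile, packingOverlap = packingOverlap,
      seed = as.integer(seed))
}

setMethod("show", "BunchSpec", function(object) {
  cat(sprintf("BunchSpec: %d berries, radius %.2f +/- %.2f cm, height %.1f cm, seed %d\n",
              object@berryCount, object@radiusMean, object@radiusSd,
              object@bunchHeight, object@seed))
})

#' Create a ScanSpec
#'
#' @param views number of turntable views.
#' @param stepDeg turntable step (degrees about the vertical Y axis).
#' @param noiseSd sensor noise (cm); default 0.2 cm (a 2 mm depth camera).
#' @param pointsPerView target bunch points per view.
#' @param background include a planar board and 1 percent uniform outliers.
#' @param cameraDistance camera distance (cm).
#' @param seed integer seed.
#' @return A \linkS4class{ScanSpec}.
#' @export
scanSpec <- function(views = 12, stepDeg = 30, noiseSd = 0.2,
                     pointsPerView = 15000, background = FALSE,
                     cameraDistance = 100, seed = 1L) {
  new("ScanSpec", views = as.integer(views), stepDeg = stepDeg,
      noiseSd = noiseSd, pointsPerView = as.integer(pointsPerView),
      background = background, cameraDistance = cameraDistance,
      seed = as.integer(seed))
}

#' Create RegionGrowingParams
#'
#' Defaults were calibrated on generator-labelled synthetic scenes (see the
#' methods vignette): k = 50, angle 30 degrees, curvature 0.3, minimum
#' cluster 500 points. The curvature threshold is deliberately far above
#' the surface variation a 2 mm-noise scan induces on berry surfaces, so
#' berry points can seed region growth; separation from the background
#' board comes from spatial disconnection and the angle test.
#'
#' @param k neighborhood size.
#' @param angleThreshold degrees.
#' @param curvatureThreshold surface-variation bound for new seeds.
#' @param minClusterSize minimum surviving cluster size.
#' @return A \linkS4class{RegionGrowingParams}.
#' @export
regionGrowingParams <- function(k = 50, angleThreshold = 30,
                                curvatureThreshold = 0.3,
                                minClusterSize = 500) {
  new("RegionGrowingParams", k = as.integer(k), angleThreshold = angleThreshold,
      curvatureThreshold = curvatureThreshold,
      minClusterSize = as.integer(minClusterSize))
}

#' Create a CropBox
#'
#' @param xRange,yRange,zRange optional (min, max) in cm.
#' @return A \linkS4class{CropBox}.
#' @export
cropBox <- function(xRange = NULL, yRange = NULL, zRange = NULL) {
  num <- function(r) if (is.null(r)) NULL else as.numeric(r)
  new("CropBox", xRange = num(xRange), yRange = num(yRange), zRange = num(zRange))
}

#' Create ICPParams
#'
#' @param maxIterations iteration cap.
#' @param translationTolerance cm.
#' @param rotationTolerance degrees.
#' @param maxCorrespondenceDistance cm.
#' @param downsampleEdge cm (0 = no downsampling before registration).
#' @return An \linkS4class{ICPParams}.
#' @export
icpParams <- function(maxIterations = 100, translationTolerance = 1e-4,
                      rotationTolerance = 1e-3,
                      maxCorrespondenceDistance = 2,
                      downsampleEdge = 0.3) {
  new("ICPParams", maxIterations = as.integer(maxIterations),
      translationTolerance = translationTolerance,
      rotationTolerance = rotationTolerance,
      maxCorrespondenceDistance = maxCorrespondenceDistance,
      downsampleEdge = downsampleEdge)
}

#' Create MLSParams
#'
#' @param radius plane-fit neighborhood radius (cm).
#' @param h Gaussian bandwidth (cm).
#' @param polynomialOrder fit order; only 1 (plane) supported.
#' @return An \linkS4class{MLSParams}.
#' @export
mlsParams <- function(radius = 1.0, h = 0.5, polynomialOrder = 1L) {
  new("MLSParams", radius = radius, h = h,
      polynomialOrder = as.integer(polynomialOrder))
}

#' Create AlphaShapeParams
#'
#' @param alpha circumsphere radius bound (cm).
#' @return An \linkS4class{AlphaShapeParams}.
#' @export
alphaShapeParams <- function(alpha) new("AlphaShapeParams", alpha = alpha)

#' Create PoissonParams
#'
#' @param gridResolution cells along the longest axis (default 128).
#' @param gaussianWidth smoothing bandwidth (cm); NA = 1.5 x mean
#'   nearest-neighbor spacing.
#' @param isoOffset isovalue offset (default 0).
#' @return A \linkS4class{PoissonParams}.
#' @export
poissonParams <- function(gridResolution = 128, gaussianWidth = NA_real_,
                          isoOffset = 0) {
  new("PoissonParams", gridResolution = as.integer(gridResolution),
      gaussianWidth = gaussianWidth, isoOffset = isoOffset)
}

#' Create a SizeTriple
#'
#' @param l,w,h extents in cm.
#' @return A \linkS4class{SizeTriple}.
#' @export
sizeTriple <- function(l, w, h) new("SizeTriple", l = l, w = w, h = h)

setMethod("show", "SizeTriple", function(object) {
  cat(sprintf("SizeTriple: l %.2f x w %.2f x h %.2f cm\n",
              object@l, object@w, object@h))
})

#' Create a PairedSeries
#'
#' @param truth reference values.
#' @param estimate estimated values.
#' @param unit unit label.
#' @return A \linkS4class{PairedSeries}.
#' @export
pairedSeries <- function(truth, estimate, unit = "cm^3") {
  new("PairedSeries", truth = as.numeric(truth), estimate = as.numeric(estimate),
      unit = unit)
}

setMethod("show", "VolumeReport", function(object) {
  cat(sprintf("VolumeReport '%s'\n", object@sampleId))
  if (!is.null(object@size))
    cat(sprintf("  size: l %.2f  w %.2f  h %.2f cm\n",
                object@size@l, object@size@w, object@size@h))
  v <- c(true = object@vTrue, GM = object@vGM, CH = object@vCH,
         AS = object@vAS, VB = object@vVB, PB = object@vPB)
  for (nm in names(v))
    if (!is.na(v[[nm]])) cat(sprintf("  V_%s = %.2f cm^3\n", nm, v[[nm]]))
  if (length(object@notes))
    cat("  notes:", paste(names(object@notes), object@notes, sep = ": ",
                          collapse = "; "), "\n")
})

# one integer sub-seed per named pipeline stage, all derived from a master
# seed so stage outputs are independently reproducible
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
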