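#' Length, width and height in the bunch's own frame
#'
#' The cloud is expressed in its principal-axis frame; h is the extent along
#' the largest-eigenvalue axis (bunches are elongated vertically along the
#' rachis), and the remaining two extents are assigned l >= w. With
#' \code{frame = "lab"} the extents are taken along the laboratory x
#' (length), y (width) and z (height) axes instead.
#'
#' @param cloud a non-degenerate \linkS4class{PointCloud}.
#' @param frame "pca" (default) or "lab".
#' @return A \linkS4class{SizeTriple} (cm).
#' @export
sizeExtent <- function(cloud, frame = c("pca", "lab")) {
  frame <- match.arg(frame)
  stopifnot(is(cloud, "PointCloud"))
  p <- cloud@points
  if (frame == "pca") {
    f <- pcaFrame(cloud)
    local <- sweep(p, 2, f@centroid) %*% f@axes
    ext <- apply(local, 2, max) - apply(local, 2, min)
    h <- ext[1]                       # largest-variance axis
    l <- max(ext[2], ext[3])
    w <- min(ext[2], ext[3])
  } else {
    ext <- apply(p, 2, max) - apply(p, 2, min)
    l <- ext[1]; w <- ext[2]; h <- ext[3]
  }
  sizeTriple(l, w, h)
}

#' Bounding-cylinder (geometric model) volume
#'
#' The bunch is replaced by a cylinder: the larger of width and length is
#' the diameter 2r, the height is h, and the volume is pi r^2 h. A crude
#' envelope that systematically overestimates a real bunch.
#'
#' @param size a \linkS4class{SizeTriple}.
#' @return Volume in cubic cm.
#' @export
volumeGM <- function(size) {
  stopifnot(is(size, "SizeTriple"))
  r <- max(size@l, size@w) / 2
  pi * r^2 * size@h
}

#' Convex-hull volume
#'
#' Quickhull facets with outward winding; the volume is the signed-
#' tetrahedron sum over the hull mesh. Every cloud point lies inside or on
#' the hull (within 1e-6).
#'
#' @param cloud a \linkS4class{PointCloud} with at least 4 affinely
#'   independent points.
#' @return List with \code{mesh} (\linkS4class{TriangleMesh}) and
#'   \code{volume} (cubic cm).
#' @export
volumeConvexHull <- function(cloud) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  p <- unique(p)
  if (nrow(p) < 4) stop("degenerate geometry: need at least 4 distinct points")
  res <- .convex_hull_cpp(p)
  mesh <- triangleMesh(p, res$faces)
  list(mesh = mesh, volume = meshVolume(mesh, check = TRUE))
}

#' Alpha-shape volume
#'
#' Delaunay tetrahedralization filtered by circumsphere radius: tetrahedra
#' whose circumsphere radius exceeds alpha are removed; the volume is the
#' sum of the kept tetrahedron volumes and the surface is the outward-wound
#' boundary of the kept complex. As alpha grows the shape fills in and
#' converges to the convex hull.
#'
#' @param cloud a \linkS4class{PointCloud} with at least 4 points.
#' @param params an \linkS4class{AlphaShapeParams} (alpha in cm; Inf gives
#'   the convex hull).
#' @return List with \code{mesh}, \code{volume} (cubic cm) and
#'   \code{keptTetrahedra}.
#' @export
volumeAlphaShape <- function(cloud, params) {
  stopifnot(is(params, "AlphaShapeParams"))
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  p <- unique(p)
  if (nrow(p) < 4) stop("degenerate geometry: need at least 4 distinct points")
  dt <- .delaunayOf(p)
  keep <- which(dt$circumradius <= params@alpha)
  if (length(keep) == 0)
    stop("alpha too small: no tetrahedron has circumsphere radius <= ",
         params@alpha)
  vol <- sum(dt$volume[keep])
  tets <- dt$tets[keep, , drop = FALSE]
  # boundary faces: occur in exactly one kept tetrahedron
  faceIdx <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                   tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  sorted <- t(apply(faceIdx, 1, sort))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  cnt <- table(key)
  onBoundary <- cnt[key] == 1
  bFaces <- faceIdx[onBoundary, , drop = FALSE]
  bOpp <- opp[onBoundary]
  # orient outward: normal away from the kept tet's opposite vertex
  a <- p[bFaces[, 1], , drop = FALSE]
  b <- p[bFaces[, 2], , drop = FALSE]
  cc <- p[bFaces[, 3], , drop = FALSE]
  d <- p[bOpp, , drop = FALSE]
  u <- b - a; v <- cc - a; w <- d - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  swap <- nx * w[, 1] + ny * w[, 2] + nz * w[, 3] > 0
  tmp <- bFaces[swap, 2]
  bFaces[swap, 2] <- bFaces[swap, 3]
  bFaces[swap, 3] <- tmp
  list(mesh = triangleMesh(p, bFaces), volume = vol,
       keptTetrahedra = length(keep))
}

# Delaunay with a deterministic symbolic-perturbation jitter (1e-9 of the
# bounding-box diagonal) to break exact cosphericity; retried coarser if the
# incremental insertion still hits a degeneracy
.delaunayOf <- function(p) {
  rng <- apply(p, 2, range)
  diag_ <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  for (mag in c(1e-9, 1e-7, 1e-5)) {
    jit <- .hashJitter(nrow(p)) * mag * max(diag_, 1e-12)
    dt <- tryCatch(.delaunay_cpp(p + jit), error = function(e) NULL)
    if (!is.null(dt)) return(dt)
  }
  stop("Delaunay tetrahedralization failed (degenerate input)")
}

# deterministic pseudo-random matrix in [-1, 1], no RNG state touched
.hashJitter <- function(n) {
  i <- seq_len(n)
  m <- cbind((sin(i * 12.9898) * 43758.5453) %% 1,
             (sin(i * 78.2330) * 24634.6345) %% 1,
             (sin(i * 39.3468) * 11369.8723) %% 1)
  2 * m - 1
}

#' Voxel-occupancy volume
#'
#' Voxelizes the cloud and returns occupied-cell count times edge^3. On
#' surface-only samples this measures the occupied shell, not the enclosed
#' solid.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param edge voxel edge (cm), > 0.
#' @param origin optional fixed grid origin.
#' @return Volume in cubic cm.
#' @export
volumeVoxel <- function(cloud, edge, origin = NULL) {
  grid <- voxelize(cloud, edge, origin = origin)
  nrow(grid@occupied) * edge^3
}

#' Poisson indicator-function surface reconstruction
#'
#' The oriented samples are splatted with a Gaussian filter into a regular
#' grid to form a smoothed gradient field of the indicator function; its
#' divergence is taken by central differences and the discrete Poisson
#' equation is solved by conjugate gradients (homogeneous Dirichlet
#' boundary). The isosurface at the mean indicator value over the input
#' samples (plus \code{isoOffset}) is extracted by marching tetrahedra and
#' the largest connected component is returned. The result is watertight or
#' an error is raised.
#'
#' Normals must be consistently oriented; a cloud whose mean normal points
#' inward (negative mean dot product with the centroid-to-point direction)
#' is flipped automatically.
#'
#' @param cloud a \linkS4class{PointCloud} with normals.
#' @param params a \linkS4class{PoissonParams}.
#' @return A watertight \linkS4class{TriangleMesh}.
#' @export
reconstructPoisson <- function(cloud, params = poissonParams()) {
  stopifnot(is(cloud, "PointCloud"), is(params, "PoissonParams"))
  if (is.null(cloud@normals))
    stop("Poisson reconstruction needs oriented normals")
  p <- cloud@points
  nrm <- cloud@normals
  ctr <- colMeans(p)
  if (mean(rowSums(nrm * sweep(p, 2, ctr))) < 0) nrm <- -nrm
  sigma <- params@gaussianWidth
  if (is.na(sigma)) {
    nn <- RANN::nn2(p, p, k = 2)
    sigma <- 1.5 * mean(nn$nn.dists[, 2])
  }
  ext <- apply(p, 2, max) - apply(p, 2, min)
  h <- max(ext) / params@gridResolution
  pad <- 4 * sigma + 3 * h
  lo <- apply(p, 2, min) - pad
  dims <- as.integer(ceiling((ext + 2 * pad) / h)) + 1L
  if (prod(as.numeric(dims)) > 4e7)
    stop("Poisson grid too large (", paste(dims, collapse = "x"),
         "); lower gridResolution or gaussianWidth")
  field <- .poisson_field_cpp(p, nrm, lo, h, dims, sigma,
                              tol = 1e-6, maxit = 4L * max(dims))
  atSamples <- .trilinear_cpp(field, lo, h, dims, p)
  iso <- mean(atSamples) + params@isoOffset * (max(field) - min(field))
  mt <- .marching_tets_cpp(field, iso, lo, h, dims)
  if (nrow(mt$faces) == 0)
    stop("reconstruction failed: empty isosurface; raise gridResolution")
  mesh <- largestMeshComponent(triangleMesh(mt$vertices, mt$faces))
  if (!isWatertight(mesh))
    stop("reconstruction failed: extracted surface is not watertight; ",
         "raise gridResolution")
  mesh
}

#' Poisson-reconstruction volume
#'
#' @param cloud a \linkS4class{PointCloud} with normals.
#' @param params a \linkS4class{PoissonParams}.
#' @return List with \code{mesh} and \code{volume} (cubic cm).
#' @export
volumePB <- function(cloud, params = poissonParams()) {
  mesh <- reconstructPoisson(cloud, params)
  list(mesh = mesh, volume = meshVolume(mesh, check = FALSE))
}

#' Run size extraction and all five volume estimators
#'
#' Individual estimator failures are recorded in the report's notes rather
#' than aborting the run.
#'
#' @param cloud the registered, smoothed bunch \linkS4class{PointCloud}.
#' @param alpha alpha-shape radius (cm).
#' @param voxelEdge voxel edge (cm).
#' @param poisson a \linkS4class{PoissonParams}.
#' @param methods subset of c("gm", "ch", "as", "vb", "pb").
#' @param vTrue optional reference volume (cubic cm).
#' @param sampleId report label.
#' @return A \linkS4class{VolumeReport}.
#' @export
measureAll <- function(cloud, alpha = 2, voxelEdge = 0.2,
                       poisson = poissonParams(),
                       methods = c("gm", "ch", "as", "vb", "pb"),
                       vTrue = NA_real_, sampleId = "sample") {
  stopifnot(is(cloud, "PointCloud"))
  notes <- character(0)
  size <- tryCatch(sizeExtent(cloud), error = function(e) {
    notes <<- c(notes, size = conditionMessage(e)); NULL
  })
  run <- function(tag, f) {
    if (!(tag %in% methods)) return(NA_real_)
    tryCatch(f(), error = function(e) {
      notes <<- c(notes, stats::setNames(conditionMessage(e), tag))
      warning("estimator '", tag, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  }
  vGM <- run("gm", function() if (is.null(size)) stop("no size") else volumeGM(size))
  vCH <- run("ch", function() volumeConvexHull(cloud)$volume)
  vAS <- run("as", function() volumeAlphaShape(cloud, alphaShapeParams(alpha))$volume)
  vVB <- run("vb", function() volumeVoxel(cloud, voxelEdge))
  vPB <- run("pb", function() volumePB(cloud, poisson)$volume)
  new("VolumeReport", sampleId = sampleId, size = size, vTrue = vTrue,
      vGM = vGM, vCH = vCH, vAS = vAS, vVB = vVB, vPB = vPB, notes = notes)
}
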