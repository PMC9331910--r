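#' Crop a point cloud to coordinate ranges
#'
#' Retains exactly the points whose coordinates satisfy every present axis
#' range (closed intervals); point order, normals and curvatures are
#' preserved. An empty result is allowed.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param box a \linkS4class{CropBox}.
#' @return The cropped \linkS4class{PointCloud}.
#' @export
cropCloud <- function(cloud, box) {
  stopifnot(is(cloud, "PointCloud"), is(box, "CropBox"))
  p <- cloud@points
  keep <- rep(TRUE, nrow(p))
  if (!is.null(box@xRange))
    keep <- keep & p[, 1] >= box@xRange[1] & p[, 1] <= box@xRange[2]
  if (!is.null(box@yRange))
    keep <- keep & p[, 2] >= box@yRange[1] & p[, 2] <= box@yRange[2]
  if (!is.null(box@zRange))
    keep <- keep & p[, 3] >= box@zRange[1] & p[, 3] <= box@zRange[2]
  subsetCloud(cloud, keep)
}

#' Subset a cloud by index or logical mask
#'
#' @param cloud a PointCloud.
#' @param i logical mask or integer indices.
#' @return The subset \linkS4class{PointCloud}.
#' @export
subsetCloud <- function(cloud, i) {
  pointCloud(cloud@points[i, , drop = FALSE],
             normals = if (!is.null(cloud@normals))
               cloud@normals[i, , drop = FALSE] else NULL,
             curvatures = if (!is.null(cloud@curvatures))
               cloud@curvatures[i] else NULL)
}

#' Concatenate point clouds
#'
#' Normals/curvatures are kept only when present on every input.
#'
#' @param ... PointClouds.
#' @return The concatenated \linkS4class{PointCloud}.
#' @export
concatClouds <- function(...) {
  cls <- list(...)
  if (length(cls) == 1 && is.list(cls[[1]]) && !is(cls[[1]], "PointCloud"))
    cls <- cls[[1]]
  p <- do.call(rbind, lapply(cls, function(c) c@points))
  nrms <- lapply(cls, function(c) c@normals)
  crv <- lapply(cls, function(c) c@curvatures)
  pointCloud(p,
             normals = if (all(!vapply(nrms, is.null, TRUE)))
               do.call(rbind, nrms) else NULL,
             curvatures = if (all(!vapply(crv, is.null, TRUE)))
               do.call(c, crv) else NULL)
}

#' Estimate per-point normals and curvature
#'
#' Eigendecomposes the covariance of each point's k nearest neighbors. The
#' normal is the eigenvector of the smallest eigenvalue, sign-flipped toward
#' the +Z camera half-space; the curvature is the surface variation
#' (smallest eigenvalue over the eigenvalue sum), which lies in [0, 1/3] and
#' is near 0 on planes.
#'
#' @param cloud a \linkS4class{PointCloud} with at least k points.
#' @param k neighborhood size.
#' @return The cloud with normals and curvatures filled.
#' @export
estimateNormalsCurvature <- function(cloud, k = 30) {
  stopifnot(is(cloud, "PointCloud"))
  n <- nrow(cloud@points)
  if (k > n) stop("k (", k, ") exceeds cloud size (", n, ")")
  nn <- RANN::nn2(cloud@points, cloud@points, k = k)
  res <- .local_pca_cpp(cloud@points, nn$nn.idx)
  nrm <- res$normals
  # orient toward the +Z camera half-space; normals lying exactly in the
  # camera plane get a deterministic lexicographic sign (eigenvector signs
  # are otherwise arbitrary, which would fracture region growing)
  eps <- 1e-6
  flip <- nrm[, 3] < -eps |
    (abs(nrm[, 3]) <= eps & nrm[, 2] < -eps) |
    (abs(nrm[, 3]) <= eps & abs(nrm[, 2]) <= eps & nrm[, 1] < 0)
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / len
  pointCloud(cloud@points, normals = nrm,
             curvatures = pmin(1, pmax(0, res$curvature)))
}

#' Curvature-seeded region growing
#'
#' Classic region growing: repeatedly seed at the unassigned point of
#' minimum curvature (ties broken by lowest index); a neighbor joins the
#' region when the angle between its normal and the current seed's normal is
#' below \code{angleThreshold}; a joined point becomes a new seed when its
#' curvature is below \code{curvatureThreshold}. Clusters smaller than
#' \code{minClusterSize} are discarded.
#'
#' @param cloud a \linkS4class{PointCloud} with normals and curvatures.
#' @param params a \linkS4class{RegionGrowingParams}.
#' @return List of integer index vectors (clusters), largest first.
#' @export
regionGrow <- function(cloud, params = regionGrowingParams()) {
  stopifnot(is(cloud, "PointCloud"))
  if (is.null(cloud@normals) || is.null(cloud@curvatures))
    stop("region growing needs normals and curvatures; run estimateNormalsCurvature first")
  n <- nrow(cloud@points)
  k <- min(params@k, n)
  nn <- RANN::nn2(cloud@points, cloud@points, k = k)$nn.idx
  nrm <- cloud@normals
  curv <- cloud@curvatures
  cosThr <- cos(params@angleThreshold * pi / 180)
  assigned <- integer(n)
  seedOrder <- order(curv, seq_len(n))
  clusters <- list()
  cid <- 0L
  ptr <- 1L
  while (ptr <= n) {
    s <- seedOrder[ptr]
    ptr <- ptr + 1L
    if (assigned[s]) next
    cid <- cid + 1L
    assigned[s] <- cid
    region <- s
    queue <- s
    qHead <- 1L
    while (qHead <= length(queue)) {
      q <- queue[qHead]
      qHead <- qHead + 1L
      nb <- nn[q, ]
      nb <- nb[assigned[nb] == 0L]
      if (length(nb) == 0) next
      dotp <- nrm[nb, , drop = FALSE] %*% nrm[q, ]
      ok <- nb[dotp >= cosThr]
      if (length(ok) == 0) next
      assigned[ok] <- cid
      region <- c(region, ok)
      newSeeds <- ok[curv[ok] < params@curvatureThreshold]
      if (length(newSeeds)) queue <- c(queue, newSeeds)
    }
    clusters[[cid]] <- region
  }
  clusters <- clusters[vapply(clusters, length, 1L) >= params@minClusterSize]
  clusters[order(vapply(clusters, length, 1L), decreasing = TRUE)]
}

#' Segment the bunch from a raw single-view cloud
#'
#' Pipeline: crop to the configured coordinate ranges, estimate normals and
#' curvature, run region growing, return the largest cluster as the bunch.
#'
#' @param cloud the raw \linkS4class{PointCloud}.
#' @param box a \linkS4class{CropBox}.
#' @param params a \linkS4class{RegionGrowingParams}.
#' @return List with \code{cloud} (the bunch \linkS4class{PointCloud}) and
#'   \code{indices} (positions in the input cloud).
#' @export
segmentBunch <- function(cloud, box = cropBox(), params = regionGrowingParams()) {
  stopifnot(is(cloud, "PointCloud"))
  p <- cloud@points
  keep <- rep(TRUE, nrow(p))
  if (!is.null(box@xRange))
    keep <- keep & p[, 1] >= box@xRange[1] & p[, 1] <= box@xRange[2]
  if (!is.null(box@yRange))
    keep <- keep & p[, 2] >= box@yRange[1] & p[, 2] <= box@yRange[2]
  if (!is.null(box@zRange))
    keep <- keep & p[, 3] >= box@zRange[1] & p[, 3] <= box@zRange[2]
  idxCrop <- which(keep)
  if (length(idxCrop) < params@k)
    stop("segmentation failed: crop left too few points (", length(idxCrop), ")")
  cropped <- subsetCloud(cloud, idxCrop)
  enriched <- estimateNormalsCurvature(cropped, k = params@k)
  clusters <- regionGrow(enriched, params)
  if (length(clusters) == 0)
    stop("segmentation failed: no cluster reached minClusterSize = ",
         params@minClusterSize)
  sel <- clusters[[1]]
  list(cloud = subsetCloud(enriched, sel), indices = idxCrop[sel])
}
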