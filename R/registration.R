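#' Principal-axis frame of a point cloud
#'
#' Centroid plus the SVD eigenvectors of the mean-centered 3x3 covariance,
#' columns ordered by descending eigenvalue. Sign convention: each of the
#' first two axes is flipped so its largest-magnitude component is positive;
#' the third is their cross product, guaranteeing a right-handed frame.
#'
#' @param cloud a \linkS4class{PointCloud} with at least 4 non-collinear
#'   points.
#' @return A \linkS4class{PCAFrame}.
#' @export
pcaFrame <- function(cloud) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  n <- nrow(p)
  if (n < 4) stop("degenerate geometry: need at least 4 points")
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  C <- crossprod(x) / n
  s <- svd(C)
  ev <- s$d
  if (ev[2] <= 1e-12 * max(ev[1], .Machine$double.eps))
    stop("degenerate geometry: point cloud is collinear")
  A <- s$u
  for (j in 1:2) {
    big <- which.max(abs(A[, j]))
    if (A[big, j] < 0) A[, j] <- -A[, j]
  }
  A[, 3] <- c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
              A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
              A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])
  new("PCAFrame", centroid = as.numeric(ctr), axes = A,
      eigenvalues = pmax(ev, 0))
}

#' Coarse alignment by principal-axis frames
#'
#' Maps the source's PCA frame onto the target's (centroid to centroid,
#' axes to axes). Among the four right-handed axis-sign combinations, the
#' transform minimizing the summed nearest-neighbor distance of a 500-point
#' source subsample against the target is returned.
#'
#' For near-cylindrical objects (a bunch is one) the two horizontal
#' principal axes are weakly determined and the frame-to-frame azimuth can
#' be badly wrong; \code{azimuthSearch} additionally scans rotations about
#' the target's primary axis in steps of that many degrees, scoring each
#' candidate the same way.
#'
#' @param source,target \linkS4class{PointCloud}s admitting a PCA frame.
#' @param azimuthSearch step (degrees) of the optional azimuth scan about
#'   the primary axis; 0 disables it.
#' @return A \linkS4class{RigidTransform} mapping source into the target
#'   frame.
#' @export
coarseAlign <- function(source, target, azimuthSearch = 0) {
  fs <- pcaFrame(source)
  ft <- pcaFrame(target)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- .evenSubsample(source@points, 500L)
  best <- NULL
  bestCost <- Inf
  score <- function(tr) {
    moved <- applyTransform(tr, sub)
    sum(RANN::nn2(target@points, moved, k = 1)$nn.dists)
  }
  for (sg in signs) {
    R <- ft@axes %*% diag(sg) %*% t(fs@axes)
    tr <- rigidTransform(R, ft@centroid - as.numeric(R %*% fs@centroid))
    cost <- score(tr)
    if (cost < bestCost) { bestCost <- cost; best <- tr }
  }
  if (azimuthSearch > 0) {
    axis <- ft@axes[, 1]
    base <- best@rotation
    for (a in seq(azimuthSearch, 360 - azimuthSearch, by = azimuthSearch)) {
      R <- .axisAngleRotation(axis, a) %*% base
      tr <- rigidTransform(R, ft@centroid - as.numeric(R %*% fs@centroid))
      cost <- score(tr)
      if (cost < bestCost) { bestCost <- cost; best <- tr }
    }
  }
  best
}

# Multi-start pose disambiguation. Partial turntable shells of a
# near-cylindrical object admit wrong nestings whose point-to-point RMSE
# beats the true pose, and the PCA frame's axis signs can be outright
# flipped, so every combination of the four right-handed sign choices and
# an azimuth scan about the primary axis is polished by a few ICP
# iterations. Candidates are scored by inlier RMSE inflated by normal
# disagreement at the matched points: wrong nestings interleave surfaces of
# different orientation and lose on that score even when positions match.
.multiStartAzimuth <- function(ps, pt, init, params, stepDeg) {
  fs <- pcaFrame(ps)
  ft <- pcaFrame(pt)
  axis <- ft@axes[, 1]
  short <- new("ICPParams", maxIterations = 8L,
               translationTolerance = params@translationTolerance,
               rotationTolerance = params@rotationTolerance,
               maxCorrespondenceDistance = params@maxCorrespondenceDistance,
               downsampleEdge = max(params@downsampleEdge, 0.5))
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- init
  bestCost <- Inf
  for (sg in signs) {
    R0 <- ft@axes %*% diag(sg) %*% t(fs@axes)
    t0 <- ft@centroid - as.numeric(R0 %*% fs@centroid)
    for (a in seq(0, 360 - stepDeg, by = stepDeg)) {
      Raz <- .axisAngleRotation(axis, a)
      cand <- rigidTransform(Raz %*% R0,
                             as.numeric(Raz %*% (t0 - ft@centroid)) +
                               ft@centroid)
      polished <- tryCatch(icp(ps, pt, init = cand, params = short),
                           error = function(e) NULL)
      if (is.null(polished)) next
      cost <- .poseScore(ps, pt, polished$transform, polished$rmse)
      if (cost < bestCost) {
        bestCost <- cost
        best <- polished$transform
      }
    }
  }
  best
}

# inlier RMSE inflated by (2 - mean normal agreement) over the best 70% of
# matches; reduces to plain RMSE when either cloud lacks normals
.poseScore <- function(ps, pt, transform, rmse) {
  if (is.null(ps@normals) || is.null(pt@normals)) return(rmse)
  moved <- applyTransform(transform, ps)
  nn <- RANN::nn2(pt@points, moved@points, k = 1)
  inl <- nn$nn.dists[, 1] <= stats::quantile(nn$nn.dists[, 1], 0.7)
  agree <- mean(rowSums(moved@normals[inl, , drop = FALSE] *
                        pt@normals[nn$nn.idx[inl, 1], , drop = FALSE]))
  rmse * (2 - agree)
}

# Rodrigues rotation about a unit axis by an angle in degrees
.axisAngleRotation <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  a <- degrees * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

.evenSubsample <- function(p, nMax) {
  n <- nrow(p)
  if (n <= nMax) return(p)
  p[round(seq(1, n, length.out = nMax)), , drop = FALSE]
}

#' Iterative closest point registration
#'
#' Point-to-point ICP with a hard correspondence cutoff: each iteration
#' transforms the source by the current estimate, matches every source
#' point to its nearest target point (dropping pairs beyond
#' \code{maxCorrespondenceDistance}), and applies the closed-form
#' least-squares rigid update from the SVD of the correspondence
#' cross-covariance (reflection-guarded). Stops when the per-iteration
#' translation and rotation updates fall below the tolerances, or at
#' \code{maxIterations}.
#'
#' @param source,target non-empty \linkS4class{PointCloud}s.
#' @param init initial \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{coarseAlign}}).
#' @param params an \linkS4class{ICPParams}.
#' @return List with \code{transform} (source-to-target
#'   \linkS4class{RigidTransform}), \code{rmse} (inlier RMSE, cm),
#'   \code{iterations}, and \code{rmseTrace}.
#' @export
icp <- function(source, target, init = rigidTransform(),
                params = icpParams()) {
  stopifnot(is(source, "PointCloud"), is(target, "PointCloud"))
  if (nrow(source@points) == 0 || nrow(target@points) == 0)
    stop("ICP needs non-empty clouds")
  src <- source
  tgt <- target
  if (params@downsampleEdge > 0) {
    src <- downsampleCloud(src, params@downsampleEdge)
    tgt <- downsampleCloud(tgt, params@downsampleEdge)
  }
  s0 <- src@points
  tp <- tgt@points
  Tcur <- init
  rmse <- NA_real_
  trace <- numeric(0)
  iterations <- 0L
  for (it in seq_len(params@maxIterations)) {
    iterations <- it
    moved <- sweep(s0 %*% t(Tcur@rotation), 2, Tcur@translation, "+")
    nn <- RANN::nn2(tp, moved, k = 1)
    # annealed cutoff: starts at the configured maximum and tightens toward
    # the residual scale, which suppresses the partial-overlap edge drag of
    # point-to-point ICP on turntable shells
    cutoff <- min(params@maxCorrespondenceDistance,
                  max(3 * stats::median(nn$nn.dists[, 1]),
                      0.05 * params@maxCorrespondenceDistance))
    inl <- which(nn$nn.dists[, 1] <= cutoff)
    if (length(inl) == 0)
      stop("no overlap: zero inlier correspondences within ",
           params@maxCorrespondenceDistance, " cm")
    a <- moved[inl, , drop = FALSE]
    b <- tp[nn$nn.idx[inl, 1], , drop = FALSE]
    rmse <- sqrt(mean(nn$nn.dists[inl, 1]^2))
    trace <- c(trace, rmse)
    am <- colMeans(a)
    bm <- colMeans(b)
    H <- crossprod(sweep(a, 2, am), sweep(b, 2, bm))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rd <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    td <- bm - as.numeric(Rd %*% am)
    delta <- rigidTransform(Rd, td)
    Tcur <- composeTransforms(delta, Tcur)
    if (rotationAngle(delta) < params@rotationTolerance &&
        sqrt(sum(td^2)) < params@translationTolerance) break
  }
  list(transform = Tcur, rmse = rmse, iterations = iterations,
       rmseTrace = trace)
}

#' Merge turntable views into a complete model
#'
#' Consecutive triples of views are registered pairwise (coarse alignment
#' plus ICP, middle view as the reference) and concatenated into quarter
#' models; the quarter models are then registered sequentially into one
#' cloud. Works for any view count divisible into groups of 3 (or, failing
#' that, 4). Every pairwise step is logged with its RMSE.
#'
#' Pairwise correspondences are estimated on voxel-downsampled,
#' MLS-smoothed proxies of the views (sensor noise at the 2 mm scale
#' otherwise biases point-to-point ICP on partial shells); the resulting
#' transforms are applied to the original, unsmoothed points.
#'
#' @param views list of \linkS4class{PointCloud}s ordered by acquisition
#'   angle.
#' @param params an \linkS4class{ICPParams}.
#' After the hierarchical merge, the per-view poses are polished by
#' \code{refinementSweeps} rounds in which each view is re-registered
#' against the model formed by the other views (a lightweight analogue of
#' global pose refinement that distributes the sequential drift).
#'
#' @param registrationSmoothing register on smoothed proxies (recommended
#'   for noisy scans).
#' @param azimuthSearch degrees; step of the multi-start azimuth
#'   disambiguation for pairwise registrations (0 disables).
#' @param refinementSweeps rounds of per-view re-registration against the
#'   model of the remaining views (0 disables).
#' @return List with \code{cloud} (the merged model), \code{log}
#'   (data.frame of pairwise RMSE/iterations), and \code{poses} (list of
#'   per-view \linkS4class{RigidTransform}s into the merged frame).
#' @export
mergeViews <- function(views, params = icpParams(),
                       registrationSmoothing = TRUE, azimuthSearch = 15,
                       refinementSweeps = 4) {
  n <- length(views)
  if (n %% 3 == 0) grp <- 3L
  else if (n %% 4 == 0) grp <- 4L
  else stop("view count (", n, ") must be divisible into groups of 3 or 4")
  lapply(views, function(v) stopifnot(is(v, "PointCloud")))
  proxy <- function(cl) {
    if (!registrationSmoothing) return(cl)
    ds <- downsampleCloud(cl, max(params@downsampleEdge, 0.25))
    if (nPoints(ds) < 10) return(ds)
    mlsSmooth(ds, mlsParams(radius = 0.8, h = 0.4))
  }
  log <- list()
  poses <- vector("list", n)
  registerPair <- function(src, tgt, label) {
    res <- tryCatch({
      ps <- proxy(src)
      pt <- proxy(tgt)
      init <- coarseAlign(ps, pt)
      if (azimuthSearch > 0)
        init <- .multiStartAzimuth(ps, pt, init, params, azimuthSearch)
      icp(ps, pt, init = init, params = params)
    }, error = function(e)
      stop("merge failed at ", label, ": ", conditionMessage(e), call. = FALSE))
    log[[length(log) + 1]] <<- data.frame(pair = label, rmse = res$rmse,
                                          iterations = res$iterations)
    res$transform
  }
  nGroups <- n %/% grp
  quarters <- vector("list", nGroups)
  qPose <- vector("list", n)   # per original view: pose into its quarter frame
  for (g in seq_len(nGroups)) {
    idx <- ((g - 1) * grp + 1):(g * grp)
    ref <- idx[ceiling(grp / 2)]
    parts <- list()
    for (i in idx) {
      if (i == ref) {
        qPose[[i]] <- rigidTransform()
        parts[[length(parts) + 1]] <- views[[i]]
      } else {
        tr <- registerPair(views[[i]], views[[ref]],
                           sprintf("view %d -> view %d", i, ref))
        qPose[[i]] <- tr
        parts[[length(parts) + 1]] <- applyTransform(tr, views[[i]])
      }
    }
    quarters[[g]] <- concatClouds(parts)
  }
  # Sequential group merging. A wide-baseline group-to-model registration is
  # not identifiable from point-to-point cost alone (wrong nestings of two
  # near-cylindrical shells can score better than the truth), so the group
  # pose is initialized through a bridge registration of the two adjacent
  # boundary views (30 degrees apart, same well-posed problem as the
  # in-group pairs) and only refined locally against the growing model.
  merged <- quarters[[1]]
  gPose <- vector("list", nGroups)
  gPose[[1]] <- rigidTransform()
  if (nGroups > 1) {
    for (g in 2:nGroups) {
      first <- (g - 1) * grp + 1      # first view of group g
      last <- (g - 1) * grp           # last view of group g-1
      bridge <- registerPair(views[[first]], views[[last]],
                             sprintf("bridge view %d -> view %d", first, last))
      init <- composeTransforms(
        composeTransforms(gPose[[g - 1]],
                          composeTransforms(qPose[[last]], bridge)),
        invertTransform(qPose[[first]]))
      res <- tryCatch(
        icp(proxy(quarters[[g]]), proxy(merged), init = init, params = params),
        error = function(e)
          stop("merge failed at group ", g, " -> merged: ",
               conditionMessage(e), call. = FALSE))
      log[[length(log) + 1]] <- data.frame(
        pair = sprintf("group %d -> merged", g),
        rmse = res$rmse, iterations = res$iterations)
      gPose[[g]] <- res$transform
      merged <- concatClouds(list(merged,
                                  applyTransform(res$transform, quarters[[g]])))
    }
  }
  for (i in seq_len(n)) {
    g <- (i - 1) %/% grp + 1
    poses[[i]] <- composeTransforms(gPose[[g]], qPose[[i]])
  }
  if (refinementSweeps > 0) {
    vproxy <- lapply(views, proxy)
    posed <- lapply(seq_len(n), function(i)
      applyTransform(poses[[i]], vproxy[[i]]))
    for (sweep in seq_len(refinementSweeps)) {
      sweepRmse <- numeric(n)
      for (i in seq_len(n)) {
        model <- concatClouds(posed[-i])
        r <- tryCatch(icp(vproxy[[i]], model, init = poses[[i]],
                          params = params),
                      error = function(e)
                        stop("merge failed at refinement of view ", i, ": ",
                             conditionMessage(e), call. = FALSE))
        poses[[i]] <- r$transform
        posed[[i]] <- applyTransform(poses[[i]], vproxy[[i]])
        sweepRmse[i] <- r$rmse
      }
      log[[length(log) + 1]] <- data.frame(
        pair = sprintf("refinement sweep %d", sweep),
        rmse = mean(sweepRmse), iterations = NA_integer_)
    }
    merged <- concatClouds(lapply(seq_len(n), function(i)
      applyTransform(poses[[i]], views[[i]])))
  }
  list(cloud = merged,
       log = do.call(rbind, log),
       poses = poses)
}

#' Voxel-grid downsampling
#'
#' One output point per occupied voxel: the centroid of the voxel's members.
#' Normals, when present, are averaged and renormalized.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param edge voxel edge (cm), > 0.
#' @return The downsampled \linkS4class{PointCloud}.
#' @export
downsampleCloud <- function(cloud, edge) {
  stopifnot(is(cloud, "PointCloud"))
  if (edge <= 0) stop("edge must be positive")
  p <- cloud@points
  if (nrow(p) == 0) return(cloud)
  origin <- apply(p, 2, min)
  ijk <- floor(sweep(p, 2, origin) / edge)
  dims <- apply(ijk, 2, max) + 1
  key <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  grpIdx <- match(key, unique(key))
  cnt <- tabulate(grpIdx)
  ctr <- rowsum(p, grpIdx, reorder = FALSE) / cnt
  nrm <- NULL
  if (!is.null(cloud@normals)) {
    nrm <- rowsum(cloud@normals, grpIdx, reorder = FALSE)
    len <- sqrt(rowSums(nrm^2))
    # degenerate averages fall back to the first member's normal
    degen <- len < 1e-9
    if (any(degen)) {
      first <- match(unique(key), key)
      nrm[degen, ] <- cloud@normals[first[degen], , drop = FALSE]
      len[degen] <- 1
    }
    nrm <- nrm / sqrt(rowSums(nrm^2))
  }
  pointCloud(ctr, normals = nrm)
}

#' Moving-least-squares smoothing
#'
#' Per point, a local reference plane minimizing the Gaussian-weighted sum
#' of squared plane distances over neighbors within \code{radius} is fitted
#' (weights theta(d) = exp(-d^2 / h^2), recentred once on the projection),
#' and the point is projected onto it. Removes the doubled-surface
#' ("ghosting") artifact left by imperfect multi-view registration. Points
#' with fewer than 4 neighbors pass through unchanged and are flagged in
#' the \code{smoothed} attribute of the result.
#'
#' @param cloud a \linkS4class{PointCloud} with at least 10 points.
#' @param params an \linkS4class{MLSParams}.
#' @return The smoothed \linkS4class{PointCloud} (normals refitted,
#'   sign-matched to the input normals when present), with a logical
#'   attribute \code{smoothed}.
#' @export
mlsSmooth <- function(cloud, params = mlsParams()) {
  stopifnot(is(cloud, "PointCloud"))
  n <- nrow(cloud@points)
  if (n < 10) stop("MLS smoothing needs at least 10 points")
  k <- min(64L, n)
  nn <- RANN::nn2(cloud@points, cloud@points, k = k)
  res <- .mls_cpp(cloud@points, nn$nn.idx, nn$nn.dists, params@radius, params@h)
  nrm <- res$normals
  passThrough <- !res$smoothed
  if (!is.null(cloud@normals)) {
    flip <- !passThrough & rowSums(nrm * cloud@normals) < 0
    nrm[flip, ] <- -nrm[flip, , drop = FALSE]
    nrm[passThrough, ] <- cloud@normals[passThrough, , drop = FALSE]
  } else if (any(passThrough)) {
    nrm[passThrough, ] <- matrix(rep(c(0, 0, 1), each = sum(passThrough)),
                                 ncol = 3)
  }
  len <- sqrt(rowSums(nrm^2))
  out <- pointCloud(res$points, normals = nrm / len)
  attr(out, "smoothed") <- res$smoothed
  out
}
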