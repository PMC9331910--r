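#' Generate a synthetic grape bunch of known geometry
#'
#' Berries are spheres placed in rings around a vertical (Y) rachis inside
#' the taper envelope given by the spec's \code{rachisProfile}, with radii
#' drawn from a truncated normal. A bounded pairwise relaxation then pushes
#' berries apart until no pair interpenetrates by more than
#' \code{packingOverlap * (r_i + r_j) / 2}, while keeping the bunch
#' connected. The result is deterministic in the spec's seed.
#'
#' @param spec a \linkS4class{BunchSpec}.
#' @return A \linkS4class{Bunch}.
#' @export
generateBunch <- function(spec) {
  stopifnot(is(spec, "BunchSpec"))
  n <- spec@berryCount
  rng <- .withSeed(stageSeed(spec@seed, "generate_bunch"), {
    # truncated normal radii (within 3 sd)
    radii <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        r <- rnorm(1, spec@radiusMean, spec@radiusSd)
        if (abs(r - spec@radiusMean) <= 3 * spec@radiusSd) break
      }
      radii[i] <- r
    }
    if (n == 1) {
      centers <- matrix(0, 1, 3)
    } else {
      rbar <- spec@radiusMean
      h <- spec@bunchHeight
      # Real bunches are internally dense (berries fill the volume, not just
      # a shell) but irregular in outline: the envelope is modulated by
      # low-order azimuthal lobes so the convex hull stays well above the
      # berry-union volume, as it is for real fruit. Candidate positions
      # fill the lobed envelope from the shoulder downward, outer circles
      # first, with angular/radial jitter so no artificial symmetry remains.
      lobePhase <- runif(2, 0, 2 * pi)
      lobeAmp <- c(runif(1, 0.12, 0.22), runif(1, 0.06, 0.12))
      envMod <- function(theta) 1 + lobeAmp[1] * sin(2 * theta + lobePhase[1]) +
        lobeAmp[2] * sin(3 * theta + lobePhase[2])
      candidates <- function(scale) {
        hs <- h * scale
        nRings <- max(2, round(hs / (1.45 * rbar)))
        u <- seq(0, 1, length.out = nRings)     # 0 = top
        yRing <- hs / 2 - u * hs
        out <- matrix(NA_real_, 0, 3)
        for (k in seq_len(nRings)) {
          re <- max(0, spec@rachisProfile(u[k]) * scale - rbar)
          rc <- re
          while (rc > 0.3 * rbar) {
            m <- max(1, floor(2 * pi * rc / (1.65 * rbar)))
            ang <- runif(1, 0, 2 * pi) + seq_len(m) / m * 2 * pi +
                   runif(m, -0.35, 0.35) * 2 * pi / m
            rad <- rc * runif(m, 0.88, 1) * envMod(ang)
            out <- rbind(out, cbind(rad * cos(ang),
                                    yRing[k] + rnorm(m, 0, 0.3 * rbar),
                                    rad * sin(ang)))
            rc <- rc - 1.6 * rbar
          }
          out <- rbind(out, cbind(rnorm(1, 0, 0.2 * rbar), yRing[k],
                                  rnorm(1, 0, 0.2 * rbar)))
        }
        out
      }
      # the envelope scales with berry count so small bunches keep the
      # elongated aspect of real clusters instead of becoming squat
      capacity <- nrow(candidates(1))
      scale <- ((n + 2) / capacity)^(1 / 3)
      centers <- candidates(scale)
      tries <- 0
      while (nrow(centers) < n && tries < 6) {
        scale <- scale * 1.07
        centers <- candidates(scale)
        tries <- tries + 1
      }
      if (nrow(centers) < n)
        stop("berryCount exceeds the envelope capacity (", nrow(centers),
             "); enlarge rachisProfile/bunchHeight or reduce berryCount")
      centers <- centers[seq_len(n), , drop = FALSE]
      # damped pairwise relaxation toward the allowed interpenetration
      allow <- outer(radii, radii, "+") * (1 - spec@packingOverlap / 2)
      for (iter in 1:400) {
        d <- as.matrix(dist(centers))
        diag(d) <- Inf
        viol <- which(d < allow - 1e-9, arr.ind = TRUE)
        viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
        if (nrow(viol) == 0) break
        for (v in seq_len(nrow(viol))) {
          i <- viol[v, 1]; j <- viol[v, 2]
          dir <- centers[j, ] - centers[i, ]
          len <- sqrt(sum(dir^2))
          if (len < 1e-9) { dir <- c(runif(3) - 0.5); len <- sqrt(sum(dir^2)) }
          dir <- dir / len
          push <- (allow[i, j] - len) / 2 * 0.6
          centers[i, ] <- centers[i, ] - dir * push
          centers[j, ] <- centers[j, ] + dir * push
        }
      }
      d <- as.matrix(dist(centers))
      diag(d) <- Inf
      if (max((allow - d) / allow) > 0.05)
        stop("packing relaxation did not converge; try a smaller berryCount")
      centers <- sweep(centers, 2, colMeans(centers))
    }
    list(centers = centers, radii = radii)
  })
  b <- new("Bunch", centers = rng$centers, radii = rng$radii)
  if (n > 1 && !.bunchConnected(b, spec@packingOverlap))
    stop("generated bunch is disconnected; try a smaller berryCount or larger packingOverlap")
  b
}

.bunchConnected <- function(bunch, overlap) {
  d <- as.matrix(dist(bunch@centers))
  thr <- outer(bunch@radii, bunch@radii, "+") * (1 + overlap)
  adj <- d <= thr
  seen <- logical(nrow(d))
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# evaluate expr with a local RNG state, restoring the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Monte-Carlo reference volume of a bunch
#'
#' Plays the role of the physical water-displacement measurement: the volume
#' of the union of berry spheres is estimated by uniform sampling of the
#' bounding box, reported with its binomial standard error so downstream
#' tolerances can be principled.
#'
#' @param bunch a \linkS4class{Bunch}.
#' @param samples number of Monte-Carlo samples (>= 1e4).
#' @param seed integer seed.
#' @return List with \code{volume} and \code{standardError} (cubic cm).
#' @export
trueVolume <- function(bunch, samples = 1e6, seed = 1L) {
  stopifnot(is(bunch, "Bunch"))
  if (samples < 1e4) stop("samples must be at least 1e4")
  lo <- apply(bunch@centers - bunch@radii, 2, min)
  hi <- apply(bunch@centers + bunch@radii, 2, max)
  vbox <- prod(hi - lo)
  m <- nrow(bunch@centers)
  hits <- 0
  .withSeed(stageSeed(seed, "true_volume"), {
    left <- as.integer(samples)
    chunk <- 200000L
    while (left > 0) {
      nc <- min(chunk, left)
      left <- left - nc
      q <- cbind(runif(nc, lo[1], hi[1]), runif(nc, lo[2], hi[2]),
                 runif(nc, lo[3], hi[3]))
      inside <- rep(FALSE, nc)
      for (j in seq_len(m)) {
        dj <- (q[, 1] - bunch@centers[j, 1])^2 +
              (q[, 2] - bunch@centers[j, 2])^2 +
              (q[, 3] - bunch@centers[j, 3])^2
        inside <- inside | (dj < bunch@radii[j]^2)
      }
      hits <- hits + sum(inside)
    }
  })
  p <- hits / samples
  list(volume = p * vbox,
       standardError = vbox * sqrt(p * (1 - p) / samples))
}

#' Sample the exposed surface of a bunch
#'
#' Uniform samples on each berry sphere; samples falling strictly inside any
#' other berry are discarded, so the result is the boundary of the union.
#' Outward analytic normals are attached.
#'
#' @param bunch a \linkS4class{Bunch}.
#' @param density points per square cm of sphere area.
#' @param seed integer seed.
#' @return A \linkS4class{PointCloud} with normals.
#' @export
sampleSurface <- function(bunch, density = 10, seed = 1L) {
  stopifnot(is(bunch, "Bunch"))
  if (density <= 0) stop("density must be positive")
  m <- nrow(bunch@centers)
  .withSeed(stageSeed(seed, "sample_surface"), {
    pts <- vector("list", m)
    nrm <- vector("list", m)
    for (j in seq_len(m)) {
      r <- bunch@radii[j]
      nPts <- max(1L, as.integer(ceiling(density * 4 * pi * r^2)))
      g <- matrix(rnorm(3 * nPts), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      p <- sweep(g * r, 2, bunch@centers[j, ], "+")
      keep <- rep(TRUE, nPts)
      for (i in seq_len(m)) {
        if (i == j) next
        d2 <- (p[, 1] - bunch@centers[i, 1])^2 +
              (p[, 2] - bunch@centers[i, 2])^2 +
              (p[, 3] - bunch@centers[i, 3])^2
        keep <- keep & (d2 >= (bunch@radii[i] - 1e-9)^2)
      }
      pts[[j]] <- p[keep, , drop = FALSE]
      nrm[[j]] <- g[keep, , drop = FALSE]
    }
    pointCloud(do.call(rbind, pts), normals = do.call(rbind, nrm))
  })
}

#' Simulate a turntable scan of a bunch
#'
#' For each view the bunch is rotated about the vertical Y axis by the
#' accumulated turntable step and observed by a camera on the +Z axis.
#' Surface samples that are back-facing or occluded (a berry intersects the
#' segment from the point to the camera; the point's own berry counts only
#' beyond a surface tolerance) are removed, isotropic Gaussian noise is
#' added, and, optionally, a planar background board plus 1 percent uniform
#' outliers are appended. Each view's ground-truth pose maps view
#' coordinates back into bunch coordinates.
#'
#' @param bunch a \linkS4class{Bunch}.
#' @param scan a \linkS4class{ScanSpec}.
#' @return List of per-view lists with elements \code{cloud}
#'   (\linkS4class{PointCloud}), \code{pose} (\linkS4class{RigidTransform})
#'   and \code{labels} (character: "bunch", "background" or "outlier").
#' @export
scanViews <- function(bunch, scan) {
  stopifnot(is(bunch, "Bunch"), is(scan, "ScanSpec"))
  cam <- c(0, 0, scan@cameraDistance)
  totalArea <- sum(4 * pi * bunch@radii^2)
  density <- 3 * scan@pointsPerView / totalArea
  out <- vector("list", scan@views)
  for (v in seq_len(scan@views)) {
    rot <- axisRotation("y", (v - 1) * scan@stepDeg)
    rb <- new("Bunch",
              centers = applyTransform(rot, bunch@centers),
              radii = bunch@radii)
    surf <- sampleSurface(rb, density,
                          seed = stageSeed(scan@seed, paste0("view_surface_", v)))
    vis <- .visibleFromCamera(surf@points, rb, cam)
    p <- surf@points[vis, , drop = FALSE]
    nrm <- surf@normals[vis, , drop = FALSE]
    .withSeed(stageSeed(scan@seed, paste0("view_noise_", v)), {
      if (nrow(p) > scan@pointsPerView) {
        sel <- sort(sample.int(nrow(p), scan@pointsPerView))
        p <- p[sel, , drop = FALSE]
        nrm <- nrm[sel, , drop = FALSE]
      }
      labels <- rep("bunch", nrow(p))
      if (scan@background) {
        # board behind the bunch plus sparse uniform outliers
        zBoard <- min(rb@centers[, 3] - rb@radii) - 8
        half <- 30
        bCount <- as.integer(round(scan@pointsPerView *
                                     (2 * half)^2 / (totalArea / 2)))
        bCount <- min(bCount, 2L * scan@pointsPerView)
        bp <- cbind(runif(bCount, -half, half), runif(bCount, -half, half),
                    rep(zBoard, bCount))
        bn <- matrix(rep(c(0, 0, 1), each = bCount), ncol = 3)
        oCount <- max(1L, as.integer(round(0.01 * scan@pointsPerView)))
        op <- cbind(runif(oCount, -half, half), runif(oCount, -half, half),
                    runif(oCount, zBoard, max(rb@centers[, 3]) + 5))
        on_ <- matrix(rnorm(3 * oCount), ncol = 3)
        on_ <- on_ / sqrt(rowSums(on_^2))
        p <- rbind(p, bp, op)
        nrm <- rbind(nrm, bn, on_)
        labels <- c(labels, rep("background", bCount), rep("outlier", oCount))
      }
      if (scan@noiseSd > 0)
        p <- p + matrix(rnorm(length(p), 0, scan@noiseSd), ncol = 3)
      out[[v]] <- list(cloud = pointCloud(p, normals = nrm),
                       pose = invertTransform(rot),
                       labels = labels)
    })
  }
  out
}

# visibility of surface points from a camera: a point survives iff no berry
# sphere intersects the open segment from it to the camera (its own berry is
# tested only beyond a small parameter tolerance, which also culls
# back-facing points)
.visibleFromCamera <- function(p, bunch, cam, epsT = 1e-6) {
  n <- nrow(p)
  d <- matrix(rep(cam, each = n), ncol = 3) - p
  a <- rowSums(d^2)
  blocked <- rep(FALSE, n)
  for (j in seq_len(nrow(bunch@centers))) {
    f <- sweep(p, 2, bunch@centers[j, ])
    b <- 2 * rowSums(f * d)
    cc <- rowSums(f^2) - bunch@radii[j]^2
    disc <- b^2 - 4 * a * cc
    has <- disc > 0
    sq <- sqrt(pmax(0, disc))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    hit1 <- has & t1 > epsT & t1 < 1
    hit2 <- has & t2 > epsT & t2 < 1
    blocked <- blocked | hit1 | hit2
  }
  !blocked
}
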