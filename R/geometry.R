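#' k-nearest neighbors between two clouds
#'
#' Exact Euclidean k-nearest-neighbor search (kd-tree). For each query point
#' the \code{count} closest reference points are returned in ascending
#' distance order, ties broken by lower reference index.
#'
#' @param query a \linkS4class{PointCloud} (or n x 3 matrix).
#' @param reference a non-empty \linkS4class{PointCloud} (or matrix).
#' @param count number of neighbors, at most the reference size.
#' @return List with integer matrix \code{index} (n x count) and numeric
#'   matrix \code{distance} (n x count).
#' @export
nearestNeighbors <- function(query, reference, count) {
  q <- if (is(query, "PointCloud")) query@points else as.matrix(query)
  r <- if (is(reference, "PointCloud")) reference@points else as.matrix(reference)
  if (nrow(r) == 0) stop("reference cloud is empty")
  if (count < 1 || count > nrow(r))
    stop("count must be between 1 and the reference size (", nrow(r), ")")
  res <- RANN::nn2(r, q, k = count)
  # RANN breaks exact-distance ties arbitrarily; enforce lower-index-first
  idx <- res$nn.idx
  d <- res$nn.dists
  if (count > 1) {
    for (i in seq_len(nrow(idx))) {
      o <- order(d[i, ], idx[i, ])
      idx[i, ] <- idx[i, o]
      d[i, ] <- d[i, o]
    }
  }
  list(index = idx, distance = d)
}

#' Enclosed volume of a watertight triangle mesh
#'
#' Sums the signed volumes (1/6) (v1 x v2) . v3 of the tetrahedra spanned by
#' each face and the coordinate origin, and returns the absolute value. The
#' result is translation-invariant for watertight meshes with consistent
#' winding.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param check audit watertightness first (every edge shared by exactly two
#'   faces); disable only for meshes already audited.
#' @return Volume in cubic cm.
#' @export
meshVolume <- function(mesh, check = TRUE) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (check) {
    bad <- .boundaryEdges(mesh)
    if (nrow(bad) > 0)
      stop(sprintf("mesh is not watertight: edge (%d, %d) is on %d face(s)",
                   bad[1, 1], bad[1, 2], bad[1, 3]))
  }
  V <- mesh@vertices
  F <- mesh@faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  abs(sum(cx * v3[, 1] + cy * v3[, 2] + cz * v3[, 3]) / 6)
}

# edges not shared by exactly two faces: matrix (edge v1, v2, multiplicity)
.boundaryEdges <- function(mesh) {
  F <- mesh@faces
  if (nrow(F) == 0) return(matrix(integer(0), 0, 3))
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2]
  if (length(bad) == 0) return(matrix(integer(0), 0, 3))
  parts <- do.call(rbind, strsplit(bad, " "))
  cbind(as.integer(parts[, 1]), as.integer(parts[, 2]),
        as.integer(tab[bad]))
}

#' Is a mesh watertight?
#'
#' @param mesh a TriangleMesh.
#' @return TRUE when every edge is shared by exactly two faces.
#' @export
isWatertight <- function(mesh) nrow(.boundaryEdges(mesh)) == 0

#' Largest connected component of a mesh
#'
#' Components are connected through shared vertices. Vertices are reindexed.
#'
#' @param mesh a TriangleMesh.
#' @return A \linkS4class{TriangleMesh} containing only the largest component.
#' @export
largestMeshComponent <- function(mesh) {
  if (nrow(mesh@faces) == 0) return(mesh)
  lab <- .vertex_components_cpp(mesh@faces, nrow(mesh@vertices))
  faceLab <- lab[mesh@faces[, 1]]
  sizes <- table(lab)
  big <- as.integer(names(sizes)[which.max(sizes)])
  keepF <- mesh@faces[faceLab == big, , drop = FALSE]
  usedV <- sort(unique(as.vector(keepF)))
  remap <- integer(nrow(mesh@vertices))
  remap[usedV] <- seq_along(usedV)
  triangleMesh(mesh@vertices[usedV, , drop = FALSE],
               matrix(remap[keepF], ncol = 3))
}

#' Voxelize a point cloud
#'
#' Cell index of a point p is floor((p - origin) / edge) per axis; the grid
#' origin defaults to the per-axis minimum of the cloud and can be
#' overridden (useful for convergence studies on a fixed grid).
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param edge voxel edge length k (cm), > 0.
#' @param origin optional fixed grid origin (default: cloud minimum).
#' @return A \linkS4class{VoxelGrid}.
#' @export
voxelize <- function(cloud, edge, origin = NULL) {
  stopifnot(is(cloud, "PointCloud"))
  if (edge <= 0) stop("edge must be positive")
  p <- cloud@points
  if (nrow(p) == 0) stop("cannot voxelize an empty cloud")
  if (is.null(origin)) origin <- apply(p, 2, min)
  ijk <- floor(sweep(p, 2, origin) / edge)
  storage.mode(ijk) <- "integer"
  occ <- unique(ijk)
  dimnames(occ) <- NULL
  new("VoxelGrid", origin = as.numeric(origin), edge = edge, occupied = occ)
}

#' Axis-aligned box mesh
#'
#' 12 outward-wound triangles; handy as an exactly-known watertight fixture.
#'
#' @param min,max opposite box corners (length-3).
#' @return A \linkS4class{TriangleMesh}.
#' @export
boxMesh <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  lo <- as.numeric(min); hi <- as.numeric(max)
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # vertex order: (x fastest) 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  #               5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = hi, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = lo, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = hi, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = lo, normal -x
    c(2, 4, 6), c(4, 8, 6))   # x = hi, normal +x
  triangleMesh(v, f)
}

#' Subdivided icosahedron sphere mesh
#'
#' @param radius sphere radius (cm).
#' @param subdivisions number of 4-way triangle subdivisions.
#' @param center sphere center.
#' @return A watertight \linkS4class{TriangleMesh} inscribed in the sphere.
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midCache <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midCache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      midCache[[key]] <- id
      id
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, c_); ca <- getMid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  triangleMesh(sweep(v * radius, 2, as.numeric(center), "+"), f)
}
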