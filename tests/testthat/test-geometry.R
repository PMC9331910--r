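test_that("cloud I/O round-trips through every dialect", {
  set.seed(3)
  p <- matrix(rnorm(60), ncol = 3)
  nrm <- matrix(rnorm(60), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cl <- pointCloud(p, normals = nrm)
  plain <- pointCloud(p)
  for (case in list(list(cl, "ply", FALSE), list(cl, "ply", TRUE),
                    list(cl, "pcd", FALSE), list(cl, "xyz", FALSE),
                    list(plain, "ply", TRUE), list(plain, "xyz", FALSE))) {
    path <- tempfile(fileext = paste0(".", case[[2]]))
    writeCloud(case[[1]], path, binary = case[[3]])
    back <- readCloud(path)
    expect_equal(cloudPoints(back), cloudPoints(case[[1]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    if (is.null(cloudNormals(case[[1]]))) {
      expect_null(cloudNormals(back))
    } else {
      expect_equal(cloudNormals(back), cloudNormals(case[[1]]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    unlink(path)
  }
})

test_that("binary PLY round trip is bit-exact", {
  set.seed(4)
  cl <- pointCloud(matrix(rnorm(300), ncol = 3))
  path <- tempfile(fileext = ".ply")
  writeCloud(cl, path, binary = TRUE)
  expect_identical(unname(cloudPoints(readCloud(path))),
                   unname(cloudPoints(cl)))
  unlink(path)
})

test_that("a hand-written ASCII PLY is read in file order", {
  path <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0 0", "0 1 0"), path)
  cl <- readCloud(path)
  expect_equal(unname(cloudPoints(cl)),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  unlink(path)
})

test_that("XYZ files with six columns populate checked normals", {
  path <- tempfile(fileext = ".xyz")
  writeLines(c("1 2 3 0 0 1", "4 5 6 1 0 0"), path)
  cl <- readCloud(path)
  expect_equal(unname(cloudNormals(cl)), rbind(c(0, 0, 1), c(1, 0, 0)))
  # non-unit normals must be rejected by the PointCloud invariant
  writeLines(c("1 2 3 0 0 9"), path)
  expect_error(readCloud(path), "unit length")
  unlink(path)
})

test_that("malformed and empty files raise informative errors", {
  path <- tempfile(fileext = ".ply")
  file.create(path)
  expect_error(readCloud(path), "empty")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "not numbers here"), path)
  expect_error(readCloud(path), "malformed")
  unlink(path)
  expect_error(readCloud(tempfile()), "not found")
  expect_error(writeCloud(pointCloud(matrix(0, 0, 3)), tempfile(fileext = ".ply")),
               "empty")
})

test_that("nearestNeighbors matches a brute-force oracle", {
  expect_equal(nearestNeighbors(matrix(0, 1, 3),
                                rbind(c(1, 0, 0), c(2, 0, 0)), 1),
               list(index = matrix(1L, 1, 1), distance = matrix(1, 1, 1)),
               ignore_attr = TRUE)
  set.seed(11)
  ref <- matrix(runif(300), ncol = 3)
  q <- rbind(matrix(runif(150), ncol = 3), ref[7, , drop = FALSE])
  for (k in c(1, 5, 10)) {
    got <- nearestNeighbors(q, ref, k)
    for (i in seq_len(nrow(q))) {
      d <- sqrt(colSums((t(ref) - q[i, ])^2))
      ord <- order(d, seq_along(d))[seq_len(k)]
      expect_equal(got$index[i, ], ord)
      expect_equal(got$distance[i, ], d[ord], tolerance = 1e-12)
    }
  }
  # a query equal to a reference point comes back first at distance zero
  got <- nearestNeighbors(ref[7, , drop = FALSE], ref, 3)
  expect_equal(got$index[1, 1], 7L)
  expect_equal(got$distance[1, 1], 0)
  expect_error(nearestNeighbors(q, ref, 1000), "count")
})

test_that("meshVolume is exact on boxes and translation-invariant", {
  cube <- boxMesh()
  expect_identical(meshVolume(cube), 1)
  moved <- triangleMesh(sweep(meshVertices(cube), 2, c(100, -50, 7), "+"),
                        meshFaces(cube))
  expect_equal(meshVolume(moved), 1, tolerance = 1e-12)
  box <- boxMesh(c(-1, -2, -3), c(1, 0, 1))
  expect_equal(meshVolume(box), 2 * 2 * 4, tolerance = 1e-12)
})

test_that("meshVolume approaches the analytic sphere volume", {
  ic <- icosphereMesh(radius = 3, subdivisions = 4)
  expect_true(isWatertight(ic))
  expect_lt(relErr(meshVolume(ic), 4 / 3 * pi * 27), 0.005)
})

test_that("meshVolume is invariant under rigid transforms", {
  set.seed(21)
  ic <- icosphereMesh(radius = 2, subdivisions = 2)
  v0 <- meshVolume(ic)
  for (i in 1:5) {
    ax <- rnorm(3)
    R <- bunchmetric:::.axisAngleRotation(ax / sqrt(sum(ax^2)), runif(1, 0, 360))
    moved <- triangleMesh(sweep(meshVertices(ic) %*% t(R), 2, rnorm(3, 0, 50), "+"),
                          meshFaces(ic))
    expect_lt(abs(meshVolume(moved) - v0) / v0, 1e-9)
  }
})

test_that("meshVolume of disjoint components adds up", {
  a <- boxMesh(c(0, 0, 0), c(1, 1, 1))
  b <- boxMesh(c(5, 5, 5), c(6, 7, 8))
  both <- triangleMesh(rbind(meshVertices(a), meshVertices(b)),
                       rbind(meshFaces(a), meshFaces(b) + nrow(meshVertices(a))))
  expect_equal(meshVolume(both), meshVolume(a) + meshVolume(b),
               tolerance = 1e-12)
})

test_that("non-watertight meshes are rejected with the offending edge", {
  cube <- boxMesh()
  leaky <- triangleMesh(meshVertices(cube), meshFaces(cube)[-1, ])
  expect_error(meshVolume(leaky), "not watertight: edge")
  expect_false(isWatertight(leaky))
  expect_true(isWatertight(cube))
})

test_that("voxelize counts cells exactly", {
  expect_equal(nrow(voxelize(pointCloud(matrix(c(.5, .5, .5), 1)), 1)@occupied), 1)
  two <- pointCloud(rbind(c(.1, .1, .1), c(.2, .2, .2)))
  expect_equal(nrow(voxelize(two, 1)@occupied), 1)
  g <- expand.grid(x = 1:10, y = 1:10, z = 1:10)
  lattice <- pointCloud(as.matrix(g) - 0.5)
  expect_equal(nrow(voxelize(lattice, 1)@occupied), 1000)
  expect_error(voxelize(two, 0), "positive")
  expect_error(voxelize(two, -1), "positive")
})

test_that("occupied count is non-increasing in the voxel edge", {
  set.seed(9)
  cl <- pointCloud(matrix(runif(3000, 0, 10), ncol = 3))
  origin <- c(0, 0, 0)
  counts <- vapply(c(0.5, 1, 2, 4),
                   function(k) nrow(voxelize(cl, k, origin = origin)@occupied), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("largestMeshComponent keeps the bigger shell", {
  a <- icosphereMesh(2, 2)
  b <- boxMesh(c(10, 10, 10), c(11, 11, 11))
  both <- triangleMesh(rbind(meshVertices(a), meshVertices(b)),
                       rbind(meshFaces(a), meshFaces(b) + nrow(meshVertices(a))))
  keep <- largestMeshComponent(both)
  expect_equal(nrow(meshFaces(keep)), nrow(meshFaces(a)))
  expect_true(isWatertight(keep))
})

test_that("rigid transforms compose, invert and stay in SO(3)", {
  set.seed(2)
  a <- axisRotation("y", 37)
  b <- rigidTransform(bunchmetric:::.axisAngleRotation(c(1, 1, 1) / sqrt(3), 55),
                      c(1, -2, 3))
  ab <- composeTransforms(a, b)
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(applyTransform(ab, p), applyTransform(a, applyTransform(b, p)),
               tolerance = 1e-12)
  roundtrip <- composeTransforms(invertTransform(ab), ab)
  expect_lt(rotationAngle(roundtrip), 1e-5)  # acos() floor near identity
  expect_lt(sqrt(sum(roundtrip@translation^2)), 1e-9)
  expect_error(new("RigidTransform", rotation = diag(3) * 2,
                   translation = c(0, 0, 0)), "orthonormal")
})
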