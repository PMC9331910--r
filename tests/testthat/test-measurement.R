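test_that("size extents match an axis-aligned box up to labelling", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 0.5), y = seq(0, 8, 0.5),
                             z = seq(0, 20, 0.5)))
  st <- sizeExtent(pointCloud(g))
  expect_equal(st@h, 20, tolerance = 0.02)
  expect_equal(st@l, 10, tolerance = 0.02)
  expect_equal(st@w, 8, tolerance = 0.02)
})

test_that("size extents are rotation-invariant", {
  set.seed(1)
  g <- as.matrix(expand.grid(x = seq(0, 10, 0.5), y = seq(0, 8, 0.5),
                             z = seq(0, 20, 0.5)))
  R <- bunchmetric:::.axisAngleRotation(rnorm(3) |> (\(v) v / sqrt(sum(v^2)))(),
                                        37)
  st <- sizeExtent(pointCloud(g %*% t(R)))
  expect_equal(st@h, 20, tolerance = 0.2)
  expect_equal(st@l, 10, tolerance = 0.1)
  expect_equal(st@w, 8, tolerance = 0.1)
})

test_that("a dense sphere has three equal extents of one diameter", {
  s <- sphereCloud(20000, 5, seed = 2)
  st <- sizeExtent(s)
  for (v in c(st@l, st@w, st@h)) expect_lt(relErr(v, 10), 0.02)
})

test_that("the cylinder model volume follows the formula", {
  expect_equal(volumeGM(sizeTriple(10, 8, 12)), pi * 25 * 12)
  expect_equal(volumeGM(sizeTriple(4, 4, 7)), pi * 4 * 7)
  # the bounding cylinder of a sphere overestimates its volume
  s <- sphereCloud(20000, 5, seed = 3)
  gm <- volumeGM(sizeExtent(s))
  expect_equal(gm, pi * 25 * 10, tolerance = 0.05 * pi * 250)
  expect_gt(gm, 4 / 3 * pi * 125)
})

test_that("the convex hull of a cube's corners has unit volume", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  res <- volumeConvexHull(pointCloud(corners))
  expect_equal(res$volume, 1, tolerance = 1e-12)
  expect_true(isWatertight(res$mesh))
})

test_that("the hull of dense sphere samples approaches the ball volume", {
  s <- sphereCloud(20000, 5, seed = 4)
  res <- volumeConvexHull(s)
  expect_lte(res$volume, 4 / 3 * pi * 125 + 1e-9)   # inscribed
  expect_lt(relErr(res$volume, 4 / 3 * pi * 125), 0.01)
})

test_that("every point lies inside or on the hull", {
  set.seed(5)
  cl <- pointCloud(matrix(rnorm(900), ncol = 3))
  res <- volumeConvexHull(cl)
  V <- meshVertices(res$mesh)
  F <- meshFaces(res$mesh)
  ctr <- colMeans(V)
  p <- cloudPoints(cl)
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c_ <- V[F[f, 3], ]
    n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
           (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
           (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    expect_lte(max(p %*% n) - sum(n * a), 1e-6 * sqrt(sum(n^2)))
  }
  expect_error(volumeConvexHull(pointCloud(cbind(1:9, (1:9) * 2, 0))),
               "degenerate|coplanar")
})

test_that("the alpha complex of a regular tetrahedron is exact", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  res <- volumeAlphaShape(pointCloud(v), alphaShapeParams(0.62))
  expect_equal(res$volume, 1 / (6 * sqrt(2)), tolerance = 1e-4)
  expect_equal(res$keptTetrahedra, 1)
  # below the circumradius (~0.6124) nothing survives
  expect_error(volumeAlphaShape(pointCloud(v), alphaShapeParams(0.5)),
               "alpha too small")
})

test_that("alpha to infinity reproduces the convex hull", {
  set.seed(6)
  for (cl in list(pointCloud(matrix(runif(600), ncol = 3)),
                  sphereCloud(3000, 5, seed = 7))) {
    as_ <- volumeAlphaShape(cl, alphaShapeParams(Inf))
    ch <- volumeConvexHull(cl)
    expect_lt(relErr(as_$volume, ch$volume), 1e-6)
  }
})

test_that("alpha-shape volume is monotone in alpha and below the hull", {
  sc <- smallBunchViews(seed = 8, berries = 25, pointsPerView = 3000)
  cl <- downsampleCloud(sc$views[[1]]$cloud, 0.4)
  vols <- vapply(c(1, 1.6, 3, 8),
                 function(a) volumeAlphaShape(cl, alphaShapeParams(a))$volume, 0)
  expect_true(all(diff(vols) >= -1e-9))
  expect_lte(vols[length(vols)],
             volumeConvexHull(cl)$volume * (1 + 1e-6))
})

test_that("two well-separated dense spheres alpha-shape to twice one sphere", {
  a <- sphereCloud(6000, 5, center = c(0, 0, 0), seed = 9)
  b <- sphereCloud(6000, 5, center = c(30, 0, 0), seed = 10)
  both <- concatClouds(pointCloud(cloudPoints(a)), pointCloud(cloudPoints(b)))
  res <- volumeAlphaShape(both, alphaShapeParams(6))
  expect_lt(relErr(res$volume, 2 * 4 / 3 * pi * 125), 0.05)
})

test_that("voxel volume counts cells times cell volume", {
  one <- pointCloud(matrix(c(0.5, 0.5, 0.5), 1))
  expect_equal(volumeVoxel(one, 2), 8)
  # sampling must be dense relative to the finest grid (about 33,500 cells
  # at edge 0.25) or empty-cell misses dominate the boundary excess
  ball <- ballCloud(400000, 5, seed = 11)
  v5 <- volumeVoxel(ball, 0.5)
  v25 <- volumeVoxel(ball, 0.25)
  ref <- 4 / 3 * pi * 125
  expect_lt(relErr(v5, ref), 0.2)   # boundary-cell excess at coarse edges
  expect_lt(relErr(v25, ref), relErr(v5, ref))
})

test_that("voxel volume of a hollow shell is far below the solid", {
  shell <- sphereCloud(20000, 5, seed = 12)
  expect_lt(volumeVoxel(shell, 0.35), 0.5 * 4 / 3 * pi * 125)
})

test_that("Poisson reconstruction of a sphere is watertight and accurate", {
  s <- sphereCloud(15000, 5, seed = 13)
  res <- volumePB(s, poissonParams(gridResolution = 96))
  expect_true(isWatertight(res$mesh))
  expect_lt(relErr(res$volume, 4 / 3 * pi * 125), 0.05)
})

test_that("Poisson reconstruction preserves the topology of a torus", {
  set.seed(14)
  n <- 30000
  u <- runif(n, 0, 2 * pi)
  v <- runif(n, 0, 2 * pi)
  keep <- runif(n) < (5 + 2 * cos(v)) / 7
  u <- u[keep]; v <- v[keep]
  pts <- cbind((5 + 2 * cos(v)) * cos(u), (5 + 2 * cos(v)) * sin(u),
               2 * sin(v))
  nrm <- cbind(cos(v) * cos(u), cos(v) * sin(u), sin(v))
  mesh <- reconstructPoisson(pointCloud(pts, normals = nrm),
                             poissonParams(gridResolution = 96))
  expect_true(isWatertight(mesh))
  euler <- nrow(meshVertices(mesh)) - 3 * nrow(meshFaces(mesh)) / 2 +
    nrow(meshFaces(mesh))
  expect_equal(euler, 0)
  expect_lt(relErr(meshVolume(mesh, check = FALSE), 2 * pi^2 * 5 * 4), 0.05)
})

test_that("Poisson reconstruction closes a missing cap", {
  s <- sphereCloud(20000, 5, seed = 15)
  keep <- cloudPoints(s)[, 3] < 0.6 * 5
  holed <- subsetCloud(s, keep)
  res <- volumePB(holed, poissonParams(gridResolution = 96, gaussianWidth = 1))
  expect_true(isWatertight(res$mesh))
  expect_lt(relErr(res$volume, 4 / 3 * pi * 125), 0.08)
})

test_that("inward-oriented normals are flipped automatically", {
  s <- sphereCloud(8000, 5, seed = 16)
  inward <- pointCloud(cloudPoints(s), normals = -cloudNormals(s))
  res <- volumePB(inward, poissonParams(gridResolution = 64))
  expect_lt(relErr(res$volume, 4 / 3 * pi * 125), 0.05)
  expect_error(reconstructPoisson(pointCloud(cloudPoints(s))), "normals")
})

test_that("volume estimators are invariant under rigid motion within 1%", {
  set.seed(17)
  sc <- smallBunchViews(seed = 18, berries = 25, pointsPerView = 3000)
  cl <- downsampleCloud(sc$views[[1]]$cloud, 0.4)
  R <- bunchmetric:::.axisAngleRotation(c(2, 1, 2) / 3, 53)
  tr <- rigidTransform(R, c(11, -4, 6))
  moved <- applyTransform(tr, cl)
  expect_lt(relErr(volumeConvexHull(moved)$volume,
                   volumeConvexHull(cl)$volume), 0.01)
  expect_lt(relErr(volumeAlphaShape(moved, alphaShapeParams(1.6))$volume,
                   volumeAlphaShape(cl, alphaShapeParams(1.6))$volume), 0.01)
  expect_lt(relErr(volumeVoxel(moved, 0.3), volumeVoxel(cl, 0.3)), 0.03)
})

test_that("measureAll fills a report and survives estimator failures", {
  s <- sphereCloud(8000, 5, seed = 19)
  rep <- suppressWarnings(
    measureAll(s, alpha = 0.01, voxelEdge = 0.5,
               poisson = poissonParams(gridResolution = 64),
               vTrue = 523.6, sampleId = "sphere"))
  expect_true(is.na(rep@vAS))              # alpha too small -> recorded
  expect_true("as" %in% names(rep@notes))
  expect_equal(rep@vTrue, 523.6)
  # analytic ordering on the sphere: GM > CH ~ PB ~ analytic
  expect_gt(rep@vGM, rep@vCH)
  expect_lt(relErr(rep@vCH, 523.6), 0.02)
  expect_lt(relErr(rep@vPB, 523.6), 0.05)
})
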