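test_that("bunch generation is deterministic and respects the packing bound", {
  spec <- bunchSpec(berryCount = 40, seed = 7)
  b1 <- generateBunch(spec)
  b2 <- generateBunch(spec)
  expect_identical(b1@centers, b2@centers)
  expect_identical(b1@radii, b2@radii)
  # all-pairs interpenetration check against the allowed fraction
  d <- as.matrix(dist(b1@centers))
  diag(d) <- Inf
  rsum <- outer(b1@radii, b1@radii, "+")
  depth <- (rsum - d) / (rsum / 2)     # interpenetration over (ri+rj)/2
  expect_lte(max(depth), spec@packingOverlap * 1.05 + 1e-9)
})

test_that("a one-berry spec yields a single sphere at the origin", {
  b <- generateBunch(bunchSpec(berryCount = 1, seed = 3))
  expect_equal(nrow(b@centers), 1)
  expect_equal(unname(b@centers[1, ]), c(0, 0, 0))
  expect_lt(abs(b@radii[1] - 1.3), 0.3)
})

test_that("generated bunches are connected", {
  for (s in c(2, 9)) {
    b <- generateBunch(bunchSpec(berryCount = 60, seed = s))
    expect_true(bunchmetric:::.bunchConnected(b, 0.4))
  }
})

test_that("Monte-Carlo volume matches analytic references", {
  one <- new("Bunch", centers = matrix(0, 1, 3), radii = 5)
  tv <- trueVolume(one, 1e6, seed = 1)
  expect_lt(abs(tv$volume - 4 / 3 * pi * 125), 4 * tv$standardError)
  expect_lt(relErr(tv$volume, 523.599), 0.01)

  apart <- new("Bunch", centers = rbind(c(0, 0, 0), c(30, 0, 0)),
               radii = c(5, 5))
  tv2 <- trueVolume(apart, 1e6, seed = 2)
  expect_lt(abs(tv2$volume - 2 * 4 / 3 * pi * 125), 4 * tv2$standardError)

  overlapping <- new("Bunch", centers = rbind(c(0, 0, 0), c(5, 0, 0)),
                     radii = c(5, 5))
  tv3 <- trueVolume(overlapping, 1e6, seed = 3)
  expect_lt(abs(tv3$volume - twoSphereUnionVolume(5, 5)),
            3 * tv3$standardError)
  expect_error(trueVolume(one, 100), "1e4")
})

test_that("Monte-Carlo standard error scales like 1/sqrt(samples)", {
  b <- generateBunch(bunchSpec(berryCount = 20, seed = 4))
  se4 <- trueVolume(b, 1e4, seed = 5)$standardError
  se6 <- trueVolume(b, 1e6, seed = 5)$standardError
  expect_equal(se4 / se6, 10, tolerance = 0.15)
})

test_that("union volume never exceeds the sum of sphere volumes", {
  for (s in 1:3) {
    b <- generateBunch(bunchSpec(berryCount = 30, seed = s))
    tv <- trueVolume(b, 2e5, seed = s)
    expect_lt(tv$volume, sum(4 / 3 * pi * b@radii^3) + 4 * tv$standardError)
  }
})

test_that("surface samples lie on the union boundary with radial normals", {
  one <- new("Bunch", centers = matrix(0, 1, 3), radii = 5)
  s <- sampleSurface(one, 3, seed = 2)
  r <- sqrt(rowSums(cloudPoints(s)^2))
  expect_lt(max(abs(r - 5)), 1e-9)
  radial <- cloudPoints(s) / r
  expect_lt(max(abs(radial - cloudNormals(s))), 1e-9)

  two <- new("Bunch", centers = rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(5, 5))
  s2 <- sampleSurface(two, 3, seed = 3)
  p <- cloudPoints(s2)
  d1 <- sqrt(rowSums(p^2))
  d2 <- sqrt(rowSums(sweep(p, 2, c(5, 0, 0))^2))
  expect_gte(min(pmax(d1, d2)), 5 - 1e-7)  # no point strictly inside a berry
})

test_that("surface point count scales with density", {
  b <- generateBunch(bunchSpec(berryCount = 10, seed = 6))
  n1 <- nPoints(sampleSurface(b, 4, seed = 1))
  n2 <- nPoints(sampleSurface(b, 8, seed = 1))
  expect_lt(abs(n2 / n1 - 2), 0.2)
})

test_that("a single-sphere view keeps only the camera-facing hemisphere", {
  one <- new("Bunch", centers = matrix(0, 1, 3), radii = 5)
  v <- scanViews(one, scanSpec(views = 1, stepDeg = 360, noiseSd = 0,
                               pointsPerView = 2000, seed = 5))[[1]]
  expect_gte(min(cloudPoints(v$cloud)[, 3]), -1e-6)
})

test_that("noiseless scan points lie exactly on a berry surface", {
  b <- generateBunch(bunchSpec(berryCount = 20, seed = 8))
  v <- scanViews(b, scanSpec(views = 1, stepDeg = 360, noiseSd = 0,
                             pointsPerView = 3000, seed = 9))[[1]]
  p <- cloudPoints(v$cloud)
  resid <- rep(Inf, nrow(p))
  for (j in seq_len(nrow(b@centers))) {
    dj <- abs(sqrt(rowSums(sweep(p, 2, b@centers[j, ])^2)) - b@radii[j])
    resid <- pmin(resid, dj)
  }
  expect_lt(max(resid), 1e-9)
})

test_that("ground-truth poses map two opposite views back onto the object", {
  # convex case: only the thin grazing band at the terminator is lost, so
  # two opposite views reassemble essentially the whole surface
  one <- new("Bunch", centers = matrix(0, 1, 3), radii = 5)
  vs <- scanViews(one, scanSpec(views = 2, stepDeg = 180, noiseSd = 0,
                                pointsPerView = 5000, seed = 11))
  merged <- concatClouds(lapply(vs, function(v)
    applyTransform(v$pose, v$cloud)))
  full <- sampleSurface(one, 3, seed = 12)
  nn <- nearestNeighbors(full, merged, 1)
  expect_gte(mean(nn$distance < 0.6), 0.95)
})

test_that("scans are reproducible under a fixed seed", {
  b <- generateBunch(bunchSpec(berryCount = 15, seed = 13))
  sc <- scanSpec(views = 3, stepDeg = 120, seed = 14, background = TRUE,
                 pointsPerView = 2000)
  v1 <- scanViews(b, sc)
  v2 <- scanViews(b, sc)
  for (i in seq_along(v1)) {
    expect_identical(cloudPoints(v1[[i]]$cloud), cloudPoints(v2[[i]]$cloud))
    expect_identical(v1[[i]]$labels, v2[[i]]$labels)
  }
})

test_that("scan spec invariants are enforced", {
  expect_error(scanSpec(views = 12, stepDeg = 20), "360")
  expect_error(scanSpec(noiseSd = -1), "noiseSd")
  expect_error(bunchSpec(radiusMean = 0.2, radiusSd = 0.1), "3\\*radiusSd")
  expect_error(bunchSpec(packingOverlap = 0.7), "packingOverlap")
})
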