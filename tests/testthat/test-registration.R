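test_that("the PCA frame recovers a dominant axis", {
  set.seed(1)
  n <- 500
  p <- cbind(runif(n, -10, 10), rnorm(n, 0, 0.01), rnorm(n, 0, 0.01))
  f <- pcaFrame(pointCloud(p))
  expect_gt(abs(frameAxes(f)[1, 1]), cos(1 * pi / 180))
  expect_equal(frameCentroid(f), colMeans(p), tolerance = 1e-9)
  expect_equal(det(frameAxes(f)), 1, tolerance = 1e-9)
})

test_that("PCA axes are equivariant under a known rotation", {
  set.seed(2)
  p <- cbind(rnorm(800, 0, 5), rnorm(800, 0, 2), rnorm(800, 0, 0.5))
  f0 <- pcaFrame(pointCloud(p))
  R <- bunchmetric:::.axisAngleRotation(c(1, 2, 3) / sqrt(14), 40)
  f1 <- pcaFrame(pointCloud(p %*% t(R)))
  for (j in 1:3) {
    # recovered axes equal the rotated originals up to the sign convention
    expect_gt(abs(sum(f1@axes[, j] * (R %*% f0@axes[, j]))), 0.999)
  }
  expect_equal(f1@eigenvalues, f0@eigenvalues, tolerance = 1e-6)
})

test_that("an isotropic blob yields close eigenvalues without crashing", {
  set.seed(3)
  f <- pcaFrame(pointCloud(matrix(rnorm(3e4), ncol = 3)))
  ev <- frameEigenvalues(f)
  expect_lt((ev[1] - ev[3]) / ev[1], 0.1)
})

test_that("degenerate clouds are rejected", {
  line <- cbind(1:10, 0, 0)
  expect_error(pcaFrame(pointCloud(line)), "collinear")
  expect_error(pcaFrame(pointCloud(line[1:3, ])), "4 points")
})

test_that("coarse alignment is the identity for identical clouds", {
  sc <- smallBunchViews(seed = 6, berries = 30, pointsPerView = 3000)
  cl <- sc$views[[1]]$cloud
  tr <- coarseAlign(cl, cl)
  expect_lt(rotationAngle(tr), 1e-4)
  expect_lt(sqrt(sum(tr@translation^2)), 1e-6)
})

test_that("coarse alignment recovers a 30-degree turn of a full cloud", {
  b <- generateBunch(bunchSpec(berryCount = 40, seed = 7))
  full <- sampleSurface(b, 4, seed = 8)
  rot <- axisRotation("y", 30)
  moved <- applyTransform(rot, full)
  tr <- coarseAlign(moved, full)   # should be the inverse rotation
  err <- composeTransforms(tr, rot)
  expect_lt(rotationAngle(err), 5)
})

test_that("coarse alignment picks the cheapest of the four sign candidates", {
  sc <- smallBunchViews(seed = 9, berries = 30, pointsPerView = 3000)
  src <- sc$views[[1]]$cloud
  tgt <- sc$views[[2]]$cloud
  got <- coarseAlign(src, tgt)
  fs <- pcaFrame(src)
  ft <- pcaFrame(tgt)
  sub <- bunchmetric:::.evenSubsample(cloudPoints(src), 500L)
  costs <- vapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                  function(sg) {
    R <- frameAxes(ft) %*% diag(sg) %*% t(frameAxes(fs))
    tr <- rigidTransform(R, frameCentroid(ft) - as.numeric(R %*% frameCentroid(fs)))
    moved <- applyTransform(tr, sub)
    sum(nearestNeighbors(moved, tgt, 1)$distance)
  }, 0)
  moved <- applyTransform(got, sub)
  gotCost <- sum(nearestNeighbors(moved, tgt, 1)$distance)
  expect_equal(gotCost, min(costs), tolerance = 1e-9)
})

test_that("ICP is immediately converged on identical clouds", {
  sc <- smallBunchViews(seed = 10, berries = 25, pointsPerView = 2500,
                        noiseSd = 0)
  cl <- sc$views[[1]]$cloud
  r <- icp(cl, cl, params = icpParams(downsampleEdge = 0))
  expect_lte(r$iterations, 2)
  expect_lt(r$rmse, 1e-9)
  expect_lt(rotationAngle(r$transform), 1e-6)
})

test_that("ICP with coarse init recovers the pose of noiseless views", {
  b <- generateBunch(bunchSpec(berryCount = 40, seed = 11))
  views <- scanViews(b, scanSpec(views = 12, noiseSd = 0,
                                 pointsPerView = 6000, seed = 12))
  v1 <- views[[1]]$cloud
  v2 <- views[[2]]$cloud
  trueRel <- composeTransforms(invertTransform(views[[2]]$pose),
                               views[[1]]$pose)
  init <- bunchmetric:::.multiStartAzimuth(v1, v2, coarseAlign(v1, v2),
                                           icpParams(), 15)
  r <- icp(v1, v2, init = init, params = icpParams())
  d <- composeTransforms(invertTransform(r$transform), trueRel)
  expect_lt(rotationAngle(d), 2)
  expect_lt(sqrt(sum(d@translation^2)), 0.2)
})

test_that("a grossly wrong fixed init ends worse than the multi-start path", {
  b <- generateBunch(bunchSpec(berryCount = 40, seed = 11))
  views <- scanViews(b, scanSpec(views = 12, noiseSd = 0,
                                 pointsPerView = 6000, seed = 12))
  v1 <- views[[1]]$cloud
  v2 <- views[[2]]$cloud
  init <- bunchmetric:::.multiStartAzimuth(v1, v2, coarseAlign(v1, v2),
                                           icpParams(), 15)
  good <- icp(v1, v2, init = init, params = icpParams())
  flipped <- composeTransforms(axisRotation("x", 180), init)
  bad <- icp(v1, v2, init = flipped,
             params = icpParams(maxIterations = 30))
  expect_gt(bad$rmse, good$rmse)
})

test_that("ICP fails loudly when clouds cannot overlap", {
  a <- sphereCloud(500, 2, seed = 13)
  b <- pointCloud(sweep(cloudPoints(sphereCloud(500, 2, seed = 14)),
                        2, c(1000, 0, 0), "+"))
  expect_error(icp(a, b, params = icpParams(downsampleEdge = 0)),
               "no overlap")
})

test_that("mergeViews rejects view counts without a 3/4 grouping", {
  views <- replicate(11, sphereCloud(100, 2), simplify = FALSE)
  expect_error(mergeViews(views), "divisible")
})

test_that("pre-aligned views merge as a near-no-op", {
  b <- generateBunch(bunchSpec(berryCount = 30, seed = 15))
  views <- scanViews(b, scanSpec(pointsPerView = 5000, seed = 16))
  aligned <- lapply(views, function(v) applyTransform(v$pose, v$cloud))
  m <- mergeViews(aligned, icpParams())
  pairwise <- m$log[grepl("view|bridge", m$log$pair), ]
  expect_lt(max(pairwise$rmse), 0.2 * 2)   # < 2x the 0.2 cm sensor noise
  # relative poses stay near the identity (the global frame is a gauge
  # freedom of the refinement sweeps)
  for (i in 1:11) {
    rel <- composeTransforms(invertTransform(m$poses[[i]]), m$poses[[i + 1]])
    expect_lt(rotationAngle(rel), 2)
    expect_lt(sqrt(sum(rel@translation^2)), 0.2)
  }
})

test_that("a noiseless 12-view merge lands on the true berry surfaces", {
  b <- generateBunch(bunchSpec(berryCount = 30, seed = 17))
  views <- scanViews(b, scanSpec(noiseSd = 0, pointsPerView = 5000,
                                 seed = 18))
  m <- mergeViews(lapply(views, function(v) v$cloud), icpParams(),
                  registrationSmoothing = FALSE)
  # express the merged model in bunch coordinates; the global pose is a
  # gauge, so align it by the best-fitting per-view correction
  best <- Inf
  for (i in 1:12) {
    toBunch <- composeTransforms(views[[i]]$pose,
                                 invertTransform(m$poses[[i]]))
    q <- cloudPoints(applyTransform(toBunch, m$cloud))
    resid <- rep(Inf, nrow(q))
    for (j in seq_len(nrow(b@centers))) {
      dj <- abs(sqrt(rowSums(sweep(q, 2, b@centers[j, ])^2)) - b@radii[j])
      resid <- pmin(resid, dj)
    }
    best <- min(best, quantile(resid, 0.99))
  }
  expect_lt(best, 0.1)
})

test_that("downsampling collapses voxels to centroids", {
  cl <- pointCloud(matrix(rep(c(1, 2, 3), each = 1000), ncol = 3))
  got <- downsampleCloud(cl, 0.5)
  expect_equal(unname(cloudPoints(got)), rbind(c(1, 2, 3)))
  g <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5)) - 0.5
  lattice <- pointCloud(g)
  expect_equal(nPoints(downsampleCloud(lattice, 1)), 125)
  set.seed(19)
  cl2 <- pointCloud(matrix(runif(3000, 0, 7), ncol = 3))
  expect_equal(nPoints(downsampleCloud(cl2, 0.8)),
               nrow(voxelize(cl2, 0.8)@occupied))
})

test_that("MLS is a fixed point on an exact plane", {
  pl <- planeCloud(25, 25, 0.2)
  sm <- mlsSmooth(pl, mlsParams(radius = 1, h = 0.5))
  expect_lt(max(abs(cloudPoints(sm) - cloudPoints(pl))), 1e-9)
})

test_that("MLS halves the residual of a noisy plane", {
  set.seed(20)
  pl <- planeCloud(40, 40, 0.25)
  noisy <- pointCloud(cloudPoints(pl) +
                        cbind(0, 0, rnorm(nPoints(pl), 0, 0.2)))
  sm <- mlsSmooth(noisy, mlsParams(radius = 1.2, h = 0.6))
  rms <- function(cl) sqrt(mean(cloudPoints(cl)[, 3]^2))
  expect_lt(rms(sm), 0.5 * rms(noisy))
})

test_that("MLS collapses two ghost sheets into one", {
  set.seed(21)
  a <- planeCloud(40, 40, 0.25)@points
  b <- sweep(a, 2, c(0.07, 0.11, 0.3), "+")  # offset replica: ghosting
  ghost <- pointCloud(rbind(a, b))
  sm <- mlsSmooth(ghost, mlsParams(radius = 1.5, h = 0.75))
  thick0 <- sd(cloudPoints(ghost)[, 3])
  thick1 <- sd(cloudPoints(sm)[, 3])
  inner <- cloudPoints(ghost)[, 1] > 1 & cloudPoints(ghost)[, 1] < 9 &
           cloudPoints(ghost)[, 2] > 1 & cloudPoints(ghost)[, 2] < 9
  expect_lt(sd(cloudPoints(sm)[inner, 3]) / sd(cloudPoints(ghost)[inner, 3]),
            1 / 4)
  expect_lt(abs(mean(cloudPoints(sm)[inner, 3]) - 0.15), 0.05)
})

test_that("MLS never moves a point beyond its neighborhood radius", {
  sc <- smallBunchViews(seed = 22, berries = 25, pointsPerView = 3000)
  cl <- sc$views[[1]]$cloud
  sm <- mlsSmooth(cl, mlsParams(radius = 1, h = 0.5))
  shift <- sqrt(rowSums((cloudPoints(sm) - cloudPoints(cl))^2))
  expect_lte(max(shift), 1 + 1e-9)
})

test_that("ICP residuals do not increase along a run", {
  sc <- smallBunchViews(seed = 23, berries = 30, pointsPerView = 4000)
  v1 <- sc$views[[1]]$cloud
  v2 <- sc$views[[2]]$cloud
  init <- bunchmetric:::.multiStartAzimuth(v1, v2, coarseAlign(v1, v2),
                                           icpParams(), 30)
  r <- icp(v1, v2, init = init, params = icpParams())
  expect_true(all(diff(r$rmseTrace) <= 0.02 * r$rmseTrace[-length(r$rmseTrace)]))
})
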