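test_that("crop keeps exactly the in-range points in order", {
  cl <- pointCloud(rbind(c(0, 0, 0), c(5, 0, 0)))
  got <- cropCloud(cl, cropBox(xRange = c(-1, 1)))
  expect_equal(unname(cloudPoints(got)), rbind(c(0, 0, 0)))
  expect_equal(cloudPoints(cropCloud(cl, cropBox())), cloudPoints(cl))
  set.seed(5)
  big <- pointCloud(matrix(runif(3000), ncol = 3))
  box <- cropBox(xRange = c(0, 0.5), zRange = c(0.25, 0.9))
  got <- cropCloud(big, box)
  keep <- big@points[, 1] >= 0 & big@points[, 1] <= 0.5 &
          big@points[, 3] >= 0.25 & big@points[, 3] <= 0.9
  expect_equal(cloudPoints(got), cloudPoints(big)[keep, ], ignore_attr = TRUE)
  expect_error(cropBox(xRange = c(2, 1)), "min < max")
})

test_that("normals and curvature are exact on a plane", {
  pl <- planeCloud(30, 30, 0.25)
  e <- estimateNormalsCurvature(pl, 20)
  expect_lt(max(abs(abs(cloudNormals(e)[, 3]) - 1)), 1e-9)
  expect_lt(max(cloudCurvatures(e)), 1e-9)
})

test_that("normals on a dense sphere are near-radial with higher curvature", {
  s <- sphereCloud(8000, 5, seed = 2)
  e <- estimateNormalsCurvature(s, 20)
  radial <- cloudPoints(s) / 5
  agree <- abs(rowSums(cloudNormals(e) * radial))
  expect_gte(mean(agree > cos(5 * pi / 180)), 0.99)
  pl <- estimateNormalsCurvature(planeCloud(30, 30), 20)
  expect_gt(median(cloudCurvatures(e)), 100 * max(median(cloudCurvatures(pl)), 1e-12))
})

test_that("duplicated points do not break the local eigendecomposition", {
  p <- rbind(planeCloud(5, 5)@points, c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  e <- estimateNormalsCurvature(pointCloud(p), 6)
  expect_true(all(is.finite(cloudNormals(e))))
  expect_true(all(is.finite(cloudCurvatures(e))))
  expect_error(estimateNormalsCurvature(planeCloud(3, 3), 100), "exceeds")
})

test_that("region growing separates two distant parallel planes", {
  a <- planeCloud(20, 20, 0.25)
  b <- pointCloud(sweep(planeCloud(20, 20, 0.25)@points, 2, c(0, 0, 10), "+"))
  cl <- concatClouds(a, b)
  e <- estimateNormalsCurvature(cl, 10)
  cls <- regionGrow(e, regionGrowingParams(k = 10, minClusterSize = 50))
  expect_equal(length(cls), 2)
  expect_setequal(cls[[1]], 1:400)
  expect_setequal(cls[[2]], 401:800)
})

test_that("region growing splits at a sharp crease", {
  # a horizontal and a vertical plane meeting at an edge: the 90-degree
  # normal jump far exceeds the 20-degree threshold
  flat <- planeCloud(30, 20, 0.25)@points
  up <- cbind(flat[, 1], 0, flat[, 2] + 0.25)
  cl <- pointCloud(rbind(flat, up))
  e <- estimateNormalsCurvature(cl, 8)
  cls <- regionGrow(e, regionGrowingParams(k = 8, angleThreshold = 20,
                                           curvatureThreshold = 0.3,
                                           minClusterSize = 100))
  expect_equal(length(cls), 2)
  pure <- vapply(cls, function(ix) max(mean(ix <= 600), mean(ix > 600)), 0)
  expect_gte(min(pure), 0.98)
})

test_that("a single flat plane grows into one cluster", {
  e <- estimateNormalsCurvature(planeCloud(25, 25), 10)
  cls <- regionGrow(e, regionGrowingParams(k = 10, minClusterSize = 100))
  expect_equal(length(cls), 1)
  expect_equal(sort(cls[[1]]), 1:625)
})

test_that("clusters are disjoint subsets of the input", {
  sc <- smallBunchViews(seed = 3, berries = 30, pointsPerView = 4000)
  e <- estimateNormalsCurvature(sc$views[[1]]$cloud, 30)
  cls <- regionGrow(e, regionGrowingParams(k = 30, minClusterSize = 100))
  all_ <- unlist(cls)
  expect_equal(anyDuplicated(all_), 0)
  expect_true(all(all_ >= 1 & all_ <= nPoints(e)))
})

test_that("region growing requires normals and curvatures", {
  expect_error(regionGrow(planeCloud(10, 10)), "normals")
})

test_that("the bunch is segmented out of a labelled background scene", {
  b <- generateBunch(bunchSpec(berryCount = 60, seed = 1))
  v <- scanViews(b, scanSpec(seed = 301, background = TRUE))[[1]]
  seg <- segmentBunch(v$cloud, box = cropBox(xRange = c(-8, 8),
                                             yRange = c(-11, 11)))
  isBunch <- v$labels == "bunch"
  precision <- mean(isBunch[seg$indices])
  recall <- sum(isBunch[seg$indices]) / sum(isBunch)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
  expect_lte(mean(v$labels[seg$indices] == "background"), 0.01)
})

test_that("a bunch-only cloud is retained almost completely", {
  sc <- smallBunchViews(seed = 4, berries = 40, pointsPerView = 8000)
  cl <- sc$views[[1]]$cloud
  seg <- segmentBunch(cl)
  expect_gte(length(seg$indices) / nPoints(cl), 0.95)
})

test_that("an empty crop fails loudly", {
  cl <- pointCloud(matrix(rnorm(300), ncol = 3))
  expect_error(segmentBunch(cl, box = cropBox(xRange = c(100, 101))),
               "segmentation failed")
})
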