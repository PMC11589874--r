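vertical_line_cloud <- function(seed = 1) {
  set.seed(seed)
  z <- seq(0, 2, by = 0.01)
  PointCloud(data.frame(x = rnorm(length(z), 0, 0.002),
                        y = rnorm(length(z), 0, 0.002), z = z))
}

test_that("local-PCA classification flags vertical lines, not sheets or blobs", {
  dtm <- flat_dtm(extent = 10, z = 0, res = 0.5)
  cfg <- stemDetectionConfig()

  vert <- vertical_line_cloud()
  mask <- classifyStemPoints(vert, dtm, cfg)
  interior <- pointData(vert)$z > 0.5 & pointData(vert)$z < 1.5
  expect_true(all(mask[interior]))

  horiz <- PointCloud(data.frame(x = pointData(vert)$z,
                                 y = pointData(vert)$y,
                                 z = pointData(vert)$x))
  expect_identical(sum(classifyStemPoints(horiz, dtm, cfg)), 0L)

  set.seed(2)
  blob <- PointCloud(data.frame(x = rnorm(400, 0, 0.2),
                                y = rnorm(400, 0, 0.2),
                                z = rnorm(400, 1, 0.2)))
  expect_identical(sum(classifyStemPoints(blob, dtm, cfg)), 0L)
})

test_that("frame mismatch between cloud and DTM is detected", {
  dtm <- flat_dtm(extent = 5, center = c(1000, 1000))
  expect_error(classifyStemPoints(vertical_line_cloud(), dtm,
                                  stemDetectionConfig()), "frame mismatch")
})

test_that("cylinder fit recovers radius and axis on exact and noisy samples", {
  pts <- cylinder_points(400, radius = 0.10, zlim = c(0, 3), seed = 3)
  cyl <- fitCylinder(pts, c(0, 0, 1))
  expect_equal(cyl@radius, 0.10, tolerance = 1e-6)
  tilt <- acos(abs(cyl@axisDirection[3])) * 180 / pi
  expect_lt(tilt, 0.01)
  expect_lt(cyl@inlierRMSE, 1e-9)

  radii <- vapply(1:20, function(s) {
    fitCylinder(cylinder_points(400, radius = 0.10, zlim = c(0, 3),
                                seed = s, radial_sd = 0.005))@radius
  }, numeric(1))
  expect_true(all(abs(radii - 0.10) < 0.01))
  # consistency: radius error shrinks with the noise
  err <- vapply(c(0.004, 0.001, 0), function(sg)
    abs(fitCylinder(cylinder_points(800, radius = 0.10, zlim = c(0, 3),
                                    seed = 31, radial_sd = sg))@radius -
          0.10), numeric(1))
  expect_true(all(diff(err) <= 1e-6))

  expect_error(fitCylinder(pts[1:5, ]), ">= 6")
  line <- cbind(rep(0, 10), rep(0, 10), seq(0, 1, length.out = 10))
  expect_error(fitCylinder(line), "collinear")
})

test_that("stem clustering finds planted stems and nothing on bare ground", {
  scene <- small_scene(seed = 5, nTrees = 3, res = 0.15)
  geo <- applyHelmert(rectify(scene$cloud), scene$truth$helmert)
  cfg <- stemDetectionConfig()
  mask <- classifyStemPoints(geo, scene$truth$dtm, cfg)
  sm <- clusterStems(geo, mask, scene$truth$dtm, cfg,
                     scannerPosition = scene$truth$helmert@translation)
  vis <- visibleTrees(scene, cfg)
  m <- matchStems(sm, scene$truth$trees[vis, c("x", "y")], gate = 0.25)
  expect_identical(nrow(m$pairs), sum(vis))
  expect_identical(m$unmatched_detected, 0L)
  expect_gte(sum(vis), 2L)

  bare <- cached_scene("bare", function()
    generateScene(sceneConfig(nTrees = 0, seed = 3),
                  scannerPose(angularResDeg = 0.25)))
  geo0 <- applyHelmert(rectify(bare$cloud), bare$truth$helmert)
  mask0 <- classifyStemPoints(geo0, bare$truth$dtm, cfg)
  sm0 <- clusterStems(geo0, mask0, bare$truth$dtm, cfg,
                      scannerPosition = bare$truth$helmert@translation)
  expect_identical(length(sm0), 0L)
})

test_that("stems beyond the maximum range are discarded", {
  dtm <- flat_dtm(extent = 220, res = 2)
  pts <- cylinder_points(600, center = c(210, 0), radius = 0.15,
                         zlim = c(0, 4), seed = 6)
  pc <- PointCloud(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  mask <- rep(TRUE, npoints(pc))
  cfg <- stemDetectionConfig()
  near <- clusterStems(pc, mask, dtm, cfg,
                       scannerPosition = c(210, 0, 30))   # 30 m away: kept
  expect_identical(length(near), 1L)
  far <- clusterStems(pc, mask, dtm, cfg,
                      scannerPosition = c(0, 0, 30))      # ~212 m: dropped
  expect_identical(length(far), 0L)
})

test_that("coarse buffers are inclusive at 3.5 m and may overlap", {
  sm <- StemMap(data.frame(stem_id = c(1L, 2L), x = c(0, 4), y = 0,
                           ground_z = 0, n_points = 100L),
                list(NULL, NULL))
  pc <- PointCloud(data.frame(x = c(3.0, 3.5, 4.0, 2.0), y = 0,
                              z = c(1, 1, 1, 1)))
  bufs <- coarseSegment(pc, sm, stemDetectionConfig())
  expect_identical(npoints(bufs[["1"]]), 3L)      # 3.0, 3.5 in; 4.0 out...
  expect_equal(sort(pointData(bufs[["1"]])$x), c(2.0, 3.0, 3.5))
  # the point at x = 2 is 2 m from each stem: present in both buffers
  expect_true(2.0 %in% pointData(bufs[["2"]])$x)
  # brute-force membership check
  for (i in 1:2) {
    d <- sqrt((pointData(pc)$x - stems(sm)$x[i])^2 +
                (pointData(pc)$y - stems(sm)$y[i])^2)
    expect_identical(npoints(bufs[[as.character(i)]]), sum(d <= 3.5))
  }
  expect_identical(coarseSegment(pc, StemMap(data.frame(
    stem_id = integer(), x = numeric(), y = numeric(),
    ground_z = numeric(), n_points = integer()), list()),
    stemDetectionConfig()), list())
})

test_that("height normalization subtracts local ground and inverts exactly", {
  dtm <- flat_dtm(extent = 10, z = 100, res = 0.5)
  pc <- PointCloud(data.frame(x = 0.1, y = 0.2, z = 105))
  out <- normalizeHeights(pc, dtm)
  expect_equal(pointData(out)$z, 5)
  pc2 <- random_cloud(200, seed = 12, extent = 8)
  d <- pointData(pc2); d$x <- abs(d$x); d$y <- abs(d$y)
  pc2 <- PointCloud(d)
  back <- denormalizeHeights(normalizeHeights(pc2, dtm), dtm)
  expect_equal(coords(back), coords(pc2), tolerance = 1e-9)

  far <- PointCloud(data.frame(x = 500, y = 500, z = 1))
  expect_error(normalizeHeights(far, dtm), "DTM support")
})

test_that("ground returns normalize to zero on a sloped synthetic scene", {
  scene <- cached_scene("sloped", function()
    generateScene(sceneConfig(nTrees = 2, terrain = "sloped",
                              slope = c(0.08, 0.03), areaSize = 20,
                              areaCenter = c(30, 0), outlierFraction = 0,
                              seed = 4),
                  scannerPose(angularResDeg = 0.3)))
  geo <- applyHelmert(rectify(scene$cloud), scene$truth$helmert)
  norm <- normalizeHeights(geo, scene$truth$dtm)
  gz <- pointData(norm)$z[pointData(norm)$ptclass == 0]
  expect_gt(mean(abs(gz) <= 0.05), 0.99)
})
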