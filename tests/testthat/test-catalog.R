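test_that("the completeness level mapping is total and exact", {
  expect_identical(assignQuality(FALSE, FALSE), 4L)
  expect_identical(assignQuality(TRUE, FALSE), 3L)
  expect_identical(assignQuality(FALSE, TRUE), 2L)
  expect_identical(assignQuality(TRUE, TRUE), 1L)
  for (com in c(TRUE, FALSE))
    for (om in c(TRUE, FALSE))
      expect_identical(assignQuality(com, om, segFailed = TRUE), 0L)
  # bijection over the five cases
  levels <- c(assignQuality(FALSE, FALSE), assignQuality(TRUE, FALSE),
              assignQuality(FALSE, TRUE), assignQuality(TRUE, TRUE),
              assignQuality(FALSE, FALSE, TRUE))
  expect_identical(sort(levels), 0:4)
})

test_that("tree height uses the interpolated 99.95th percentile above local ground", {
  dtm <- flat_dtm(extent = 10, z = 100, res = 0.5)
  flat <- PointCloud(data.frame(x = 0.1, y = 0.1, z = rep(105, 50)))
  expect_equal(estimateTreeHeight(flat, dtm, c(0, 0)), 5)

  dtm0 <- flat_dtm(extent = 10, z = 0, res = 0.5)
  ladder <- PointCloud(data.frame(x = 0, y = 0, z = seq(0, 10, by = 0.01)))
  expect_equal(estimateTreeHeight(ladder, dtm0, c(0, 0)), 9.995)

  # monotone: adding a point above the maximum never lowers the estimate
  h0 <- estimateTreeHeight(ladder, dtm0, c(0, 0))
  d <- rbind(pointData(ladder), data.frame(x = 0, y = 0, z = 12))
  expect_gte(estimateTreeHeight(PointCloud(d), dtm0, c(0, 0)), h0)

  low <- PointCloud(data.frame(x = 0, y = 0, z = 90))
  expect_warning(h <- estimateTreeHeight(low, dtm, c(0, 0)), "clamped")
  expect_identical(h, 0)
  expect_error(estimateTreeHeight(PointCloud(data.frame(
    x = numeric(), y = numeric(), z = numeric())), dtm, c(0, 0)), "empty")
})

test_that("synthetic tree height is recovered within a decimetre", {
  scene <- cached_scene("height12", function()
    generateScene(sceneConfig(nTrees = 1, areaSize = 8,
                              areaCenter = c(45, 0),
                              heightRange = list(pine = c(12, 12),
                                                 spruce = c(12, 12),
                                                 birch = c(12, 12),
                                                 unidentified = c(12, 12)),
                              seed = 2),
                  scannerPose(angularResDeg = 0.05)))
  geo <- applyHelmert(rectify(scene$cloud), scene$truth$helmert)
  tt <- scene$truth$trees
  tree <- geo[pointData(geo)$label == tt$tree_id[1]]
  h <- estimateTreeHeight(tree, scene$truth$dtm, c(tt$x[1], tt$y[1]))
  expect_lt(abs(h - tt$height_m[1]), 0.1)
  expect_lt(abs(h - 12), 0.1)
})

test_that("scanner distances are plain 3-D distances to crown top and stem base", {
  dtm <- flat_dtm(extent = 50, z = 0, res = 1)
  tree <- PointCloud(data.frame(x = c(40, 40), y = 0, z = c(2, 10)))
  d <- scannerDistances(tree, c(0, 0, 30), c(40, 0), dtm)
  expect_equal(unname(d["stem_base_m"]), 50)   # 3-4-5 scaled
  expect_equal(unname(d["crown_top_m"]), sqrt(40^2 + 20^2))

  below <- PointCloud(data.frame(x = 0, y = 0, z = 10))
  d2 <- scannerDistances(below, c(0, 0, 30), c(0, 0), dtm)
  expect_equal(unname(d2["crown_top_m"]), 20)
})

test_that("point density is count over the planimetric hull area", {
  set.seed(17)
  sq <- PointCloud(data.frame(x = runif(400, 0, 2), y = runif(400, 0, 2),
                              z = runif(400, 0, 5)))
  dens <- pointDensity(sq)
  expect_lt(abs(dens - 100) / 100, 0.1)
  # scaling x, y by 2 divides the density by 4
  d <- pointData(sq); d$x <- 2 * d$x; d$y <- 2 * d$y
  expect_equal(pointDensity(PointCloud(d)), dens / 4, tolerance = 1e-9)
  expect_true(is.na(pointDensity(PointCloud(data.frame(
    x = c(0, 1), y = c(0, 1), z = 0)))))
  expect_true(is.na(pointDensity(PointCloud(data.frame(
    x = c(0, 1, 2), y = c(0, 1, 2), z = 0)))))  # collinear
})

test_that("scan selection enforces strict weather bounds", {
  w <- data.frame(timestamp = c("ok", "wind", "rh", "rain", "snow"),
                  wind = c(2.0, 3.0, 2.0, 1.0, 1.0),
                  precipitation = c(0, 0, 0, 0.2, 0),
                  snow = c(0, 0, 0, 0, 1),
                  rh = c(85, 85, 90.0, 50, 50))
  expect_identical(selectScans(w), "ok")
  expect_error(selectScans(w[, -2]), "wind")
})

test_that("tree file names follow the pattern and round-trip", {
  t1 <- as.POSIXct("2020-04-06 01:23:45", tz = "UTC")
  expect_identical(makeTreeFilename(t1, 17, 4), "200406_012345_17_4.laz")
  t2 <- as.POSIXct("2021-09-30 23:59:59", tz = "UTC")
  expect_identical(makeTreeFilename(t2, 458, 0), "210930_235959_458_0.laz")
  p <- parseTreeFilename("200406_012345_17_4.laz")
  expect_identical(p$tree_id, 17L)
  expect_identical(p$quality, 4L)
  expect_equal(p$timestamp, t1)
  expect_error(parseTreeFilename("nope.laz"), "not a tree file")
})

catalog_records <- function(n) {
  ii <- seq_len(n)
  data.frame(tree_id = ii, species_index = rep_len(1:3, n),
             e = 100 + ii, n = 200 + ii, h = rep(10, n),
             height_m = 15 + ii, quality = rep(4L, n),
             dist_crown_top_m = rep(50, n), dist_stem_base_m = rep(60, n),
             point_density_per_m2 = rep(1000, n))
}

test_that("the JSON catalogue is valid, recoverable and byte-deterministic", {
  f <- withr::local_tempfile(fileext = ".json")
  writeCatalog(buildCatalog(catalog_records(0)), f)
  empty <- readCatalog(f)
  expect_identical(empty$type, "FeatureCollection")
  expect_identical(length(empty$features), 0L)

  cat3 <- buildCatalog(catalog_records(3))
  writeCatalog(cat3, f)
  back <- readCatalog(f)
  expect_identical(length(back$features), 3L)
  expect_identical(vapply(back$features, function(x) x$id, 1L), 1:3)
  expect_identical(back$features[[2]]$properties$species_name,
                   "Norway spruce")

  f2 <- withr::local_tempfile(fileext = ".json")
  writeCatalog(buildCatalog(catalog_records(3)), f2)
  expect_identical(readBin(f, "raw", file.info(f)$size),
                   readBin(f2, "raw", file.info(f2)$size))

  dup <- catalog_records(2); dup$tree_id <- c(1L, 1L)
  expect_error(buildCatalog(dup), "duplicate")
})
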