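test_that("LAS write/read round-trip preserves coordinates and attributes", {
  pc <- random_cloud(100, seed = 11)
  crs(pc) <- "EPSG:3067"
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(pc, f)
  back <- readPointCloud(f)
  expect_lte(max(abs(coords(back) - coords(pc))), 0.0005)
  for (a in c("intensity", "reflectance", "deviation", "return_number",
              "number_of_returns", "label"))
    expect_equal(pointData(back)[[a]], pointData(pc)[[a]], tolerance = 0,
                 ignore_attr = TRUE)
  expect_identical(crs(back), "EPSG:3067")
})

test_that("round-trip is lossless up to the coordinate quantum on large random clouds", {
  pc <- random_cloud(1e5, seed = 2, extent = 300)
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(pc, f)
  back <- readPointCloud(f)
  expect_lte(max(abs(coords(back) - coords(pc))), 0.0005)
  d <- pointData(back)
  expect_true(all(lengths(d) == npoints(back)))
})

test_that("a missing required attribute is an error naming the attribute", {
  pc <- PointCloud(data.frame(x = 1:3, y = 1:3, z = 1:3, intensity = 0))
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(pc, f)
  expect_error(readPointCloud(f, requiredAttrs = "deviation"), "deviation")
  expect_silent(readPointCloud(f, requiredAttrs = "intensity"))
})

test_that("invalid return-number combinations are rejected at load", {
  pc <- PointCloud(data.frame(x = 1, y = 1, z = 1, intensity = 0,
                              return_number = 2L, number_of_returns = 2L))
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(pc, f)
  # patch the flag byte of the first (only) point record to
  # return_number = 3, number_of_returns = 2
  raw <- readBin(f, "raw", file.info(f)$size)
  raw[375 + 15] <- as.raw(3 + 2 * 16)
  writeBin(raw, f)
  expect_error(readPointCloud(f), "return_number")
})

test_that("empty and attribute-less clouds round-trip", {
  empty <- PointCloud(data.frame(x = numeric(), y = numeric(),
                                 z = numeric()))
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(empty, f)
  expect_warning(back <- readPointCloud(f), "zero points")
  expect_identical(npoints(back), 0L)

  bare <- PointCloud(data.frame(x = c(1, 2), y = c(3, 4), z = c(5, 6),
                                intensity = c(7, 8)))
  writePointCloud(bare, f)
  back <- readPointCloud(f)
  # no extra-byte records: only the standard columns come back
  expect_setequal(names(pointData(back)), c("x", "y", "z", "intensity"))
})

test_that("LAZ-compressed input is rejected with a clear message", {
  pc <- PointCloud(data.frame(x = 1, y = 1, z = 1))
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(pc, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  raw[105] <- as.raw(bitwOr(as.integer(raw[105]), 128L))  # compression bit
  writeBin(raw, f)
  expect_error(readPointCloud(f), "LAZ")
})

test_that("DTM and control point readers populate their types", {
  # 10 x 10 grid at 0.2 m spacing written as LAS
  g <- expand.grid(x = seq(0, 1.8, by = 0.2), y = seq(0, 1.8, by = 0.2))
  f <- withr::local_tempfile(fileext = ".las")
  writePointCloud(PointCloud(data.frame(x = g$x, y = g$y, z = 100)), f)
  dtm <- readDTM(f)
  expect_identical(nrow(dtm@points), 100L)
  expect_equal(dtm@resolution, 0.2, tolerance = 1e-9)

  gcp <- data.frame(sx = rnorm(8), sy = rnorm(8), sz = rnorm(8),
                    tx = rnorm(8), ty = rnorm(8), tz = rnorm(8))
  fc <- withr::local_tempfile(fileext = ".csv")
  write.csv(gcp, fc, row.names = FALSE)
  expect_identical(nrow(readControlPoints(fc)), 8L)

  write.csv(gcp[1:2, ], fc, row.names = FALSE)
  expect_error(readControlPoints(fc), ">= 3")
})

test_that("PointCloud validity enforces the declared invariants", {
  expect_error(PointCloud(data.frame(x = 1, y = 1, z = NaN)), "non-finite")
  expect_error(PointCloud(data.frame(x = 1, y = 1, z = 1,
                                     return_number = 3L,
                                     number_of_returns = 2L)),
               "return_number")
  expect_error(PointCloud(data.frame(x = 1, y = 1, z = 1, range = -2)),
               "range")
  pc <- PointCloud(data.frame(x = 1, y = 1, z = 1))
  expect_false(hasAttribute(pc, "reflectance"))
})
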