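test_that("stem matching pairs greedily within the gate", {
  ref <- data.frame(x = c(0, 10), y = c(0, 0))
  det <- data.frame(x = c(0.3, 10), y = c(0.4, 1.0))
  m <- matchStems(det, ref, gate = 2)
  expect_identical(nrow(m$pairs), 2L)
  expect_equal(sort(m$pairs$distance), c(0.5, 1.0))
  expect_identical(m$unmatched_detected, 0L)

  # identical maps: everything matches at distance zero
  m0 <- matchStems(ref, ref)
  expect_identical(nrow(m0$pairs), 2L)
  expect_equal(m0$pairs$distance, c(0, 0))

  # stray detection outside the gate stays unmatched
  det2 <- rbind(det, data.frame(x = 5, y = 5))
  m2 <- matchStems(det2, ref, gate = 2)
  expect_identical(m2$unmatched_detected, 1L)
  expect_identical(nrow(m2$pairs), 2L)
})

test_that("matching is symmetric under swapping the two maps", {
  set.seed(30)
  a <- data.frame(x = runif(6, 0, 20), y = runif(6, 0, 20))
  b <- data.frame(x = runif(8, 0, 20), y = runif(8, 0, 20))
  mab <- matchStems(a, b, gate = 5)
  mba <- matchStems(b, a, gate = 5)
  expect_identical(nrow(mab$pairs), nrow(mba$pairs))
  key_ab <- sort(paste(mab$pairs$detected_id, mab$pairs$reference_id))
  key_ba <- sort(paste(mba$pairs$reference_id, mba$pairs$detected_id))
  expect_identical(key_ab, key_ba)
  expect_identical(mab$unmatched_detected, mba$unmatched_reference)
})

test_that("planimetric accuracy reproduces the worked example", {
  ref <- data.frame(x = c(0, 10), y = c(0, 0))
  det <- data.frame(x = c(0.3, 10), y = c(0.4, 1.0))
  acc <- planimetricAccuracy(matchStems(det, ref, gate = 2))
  expect_equal(acc$mean_planimetric_m, 0.75)
  expect_equal(acc$rmse_e_m, sqrt((0.3^2 + 0) / 2), tolerance = 1e-9)
  expect_equal(round(acc$rmse_e_m, 4), 0.2121)
  expect_equal(acc$rmse_n_m, sqrt((0.4^2 + 1) / 2), tolerance = 1e-9)
  expect_equal(round(acc$rmse_n_m, 4), 0.7616)

  zero <- planimetricAccuracy(matchStems(ref, ref))
  expect_identical(zero$mean_planimetric_m, 0)
  expect_identical(zero$rmse_e_m, 0)

  one <- planimetricAccuracy(data.frame(de = 1, dn = 0, distance = 1))
  expect_equal(one$mean_planimetric_m, 1)
  expect_equal(one$rmse_e_m, 1)
  expect_equal(one$rmse_n_m, 0)
  expect_error(planimetricAccuracy(matchStems(
    data.frame(x = 0, y = 0), data.frame(x = 50, y = 50))), "no matched")
})

test_that("cloud-to-cloud distances behave on the translated-grid example", {
  g <- expand.grid(x = seq(0, 9), y = seq(0, 9))
  a <- PointCloud(data.frame(x = g$x, y = g$y, z = 0))
  bd <- pointData(a); bd$x <- bd$x + 0.10
  b <- PointCloud(bd)
  same <- cloudToCloud(a, a)
  expect_identical(same$mean_distance_m, 0)
  expect_identical(same$fraction_within_threshold, 1)

  r <- cloudToCloud(a, b, threshold = 0.15)
  expect_equal(r$mean_distance_m, 0.10, tolerance = 1e-9)
  expect_identical(r$fraction_within_threshold, 1)
  expect_identical(cloudToCloud(a, b, threshold = 0.05)$
                     fraction_within_threshold, 0)

  # translation covariance: shifting both clouds changes nothing
  shift <- function(pc, v) {
    d <- pointData(pc); d$x <- d$x + v[1]; d$y <- d$y + v[2]
    PointCloud(d)
  }
  r2 <- cloudToCloud(shift(a, c(100, -7)), shift(b, c(100, -7)),
                     threshold = 0.15)
  expect_equal(r2$mean_distance_m, r$mean_distance_m, tolerance = 1e-9)

  # symmetric variant reports the worse direction
  asym <- PointCloud(data.frame(x = c(0, 50), y = 0, z = 0))
  sym <- cloudToCloud(a, asym, threshold = 0.15, symmetric = TRUE)
  expect_gte(sym$mean_distance_m,
             cloudToCloud(a, asym, threshold = 0.15)$mean_distance_m)
  expect_error(cloudToCloud(a, PointCloud(data.frame(
    x = numeric(), y = numeric(), z = numeric()))), "empty")
})

test_that("automatic completeness scoring reproduces the level mapping", {
  truth <- rep(c(1L, 2L), each = 100)
  perfect <- truth
  expect_identical(scoreCompleteness(perfect, truth, 1)$quality, 4L)

  # 20% foreign points mixed in, nothing missing: commission only -> 3
  mixed <- truth
  mixed[101:125] <- 1L                 # 25 foreign of 125 assigned = 20%
  sc <- scoreCompleteness(mixed, truth, 1)
  expect_identical(sc$quality, 3L)
  expect_true(sc$commission)
  expect_false(sc$omission)
  expect_equal(sc$commission_fraction, 0.2)

  # omission only -> 2
  partial <- truth
  partial[1:30] <- 0L
  expect_identical(scoreCompleteness(partial, truth, 1)$quality, 2L)

  # nothing assigned -> segmentation failed, level 0
  none <- rep(0L, 200)
  expect_identical(scoreCompleteness(none, truth, 1)$quality, 0L)
  expect_error(scoreCompleteness(perfect, truth, 7), "absent")

  # zero tolerances reduce to strict set equality
  almost <- truth
  almost[1] <- 0L
  expect_identical(scoreCompleteness(almost, truth, 1, 0, 0)$quality, 2L)
  expect_identical(scoreCompleteness(truth, truth, 1, 0, 0)$quality, 4L)
})
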