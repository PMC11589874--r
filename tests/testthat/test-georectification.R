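# Independent oracle for the Euler composition: each factor written as an
# axis-angle (Rodrigues) rotation rather than the explicit trig matrices
# used by the implementation.
rodrigues <- function(axis, deg) {
  th <- deg * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("rotation matrix matches the axis-angle composition oracle", {
  expect_equal(rotationMatrix(0, 0, 0), diag(3), tolerance = 1e-15)
  oracle <- rodrigues(c(0, 0, 1), 90) %*% rodrigues(c(0, 1, 0), 60) %*%
    rodrigues(c(1, 0, 0), 0)
  expect_equal(rotationMatrix(0, 60, 90), oracle, tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    ang <- runif(3, -180, 180)
    R <- rotationMatrix(ang[1], ang[2], ang[3])
    oracle <- rodrigues(c(0, 0, 1), ang[3]) %*%
      rodrigues(c(0, 1, 0), ang[2]) %*% rodrigues(c(1, 0, 0), ang[1])
    expect_equal(R, oracle, tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    v <- rnorm(3)
    expect_equal(sqrt(sum((R %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("rectify is an isometry that leaves attributes untouched", {
  pc <- random_cloud(500, seed = 3)
  out <- rectify(pc, c(10, 60, 90))
  expect_equal(pointData(out)$reflectance, pointData(pc)$reflectance)
  idx <- cbind(sample(500, 200, TRUE), sample(500, 200, TRUE))
  d0 <- sqrt(rowSums((coords(pc)[idx[, 1], ] - coords(pc)[idx[, 2], ])^2))
  d1 <- sqrt(rowSums((coords(out)[idx[, 1], ] - coords(out)[idx[, 2], ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_equal(coords(rectify(pc, c(0, 0, 0))), coords(pc))
})

test_that("default rectification levels the synthetic ground at -30 m", {
  scene <- small_scene(seed = 5, nTrees = 2, res = 0.3)
  rc <- rectify(scene$cloud)
  gz <- pointData(rc)$z[pointData(rc)$ptclass == 0]
  expect_gt(mean(gz > -31 & gz < -29), 0.99)
})

test_that("scan attributes follow the spherical convention", {
  pc <- PointCloud(data.frame(x = c(0, 3), y = c(0, 4), z = c(-30, 0)))
  out <- pointData(computeScanAttributes(pc))
  expect_equal(out$range, c(30, 5))
  expect_equal(out$theta, c(180, 90))
  expect_equal(out$phi_az[2], 53.130, tolerance = 1e-4)
  expect_warning(out0 <- computeScanAttributes(
    PointCloud(data.frame(x = 0, y = 0, z = 0))), "origin")
  expect_equal(unlist(pointData(out0)[, c("range", "theta", "phi_az")]),
               c(range = 0, theta = 0, phi_az = 0))
})

test_that("ranges are invariant under rectification", {
  pc <- random_cloud(200, seed = 8)
  r0 <- pointData(computeScanAttributes(pc))$range
  r1 <- pointData(computeScanAttributes(rectify(pc, c(5, 60, 90))))$range
  expect_equal(r1, r0, tolerance = 1e-9)
})

make_pairs <- function(n = 8, seed = 7, mu = 1.0005, tr = c(105, 220, 5.5),
                       ang = c(0.3, -0.2, 1.4), sigma = 0) {
  set.seed(seed)
  S <- matrix(runif(3 * n, -50, 50), n, 3)
  R <- rotationMatrix(ang[1], ang[2], ang[3])
  T <- t(tr + mu * R %*% t(S)) + matrix(rnorm(3 * n, 0, sigma), n, 3)
  data.frame(sx = S[, 1], sy = S[, 2], sz = S[, 3],
             tx = T[, 1], ty = T[, 2], tz = T[, 3])
}

test_that("Helmert parameters are recovered exactly from noise-free pairs", {
  p <- make_pairs()
  h <- fitHelmert(p)
  expect_lt(max(abs(h@translation - c(105, 220, 5.5))), 1e-9)
  expect_lt(abs(h@scale - 1.0005), 1e-9)
  expect_lt(max(abs(h@rotation - rotationMatrix(0.3, -0.2, 1.4))), 1e-9)
  expect_lt(h@fitRMSE, 1e-9)
  expect_equal(unname(helmertAngles(h)), c(0.3, -0.2, 1.4),
               tolerance = 1e-9)

  id <- data.frame(sx = c(0, 1, 0, 0), sy = c(0, 0, 1, 0),
                   sz = c(0, 0, 0, 1))
  id[c("tx", "ty", "tz")] <- id[c("sx", "sy", "sz")]
  h0 <- fitHelmert(id)
  expect_equal(h0@translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(h0@rotation, diag(3), tolerance = 1e-12)
  expect_equal(h0@scale, 1, tolerance = 1e-12)
})

test_that("fit RMSE under Gaussian noise sits in the expected band", {
  sigma <- 0.01
  rmse <- vapply(1:100, function(s)
    fitHelmert(make_pairs(seed = s, sigma = sigma))@fitRMSE, numeric(1))
  expect_true(all(rmse >= 0.5 * sigma & rmse <= 2 * sigma))
})

test_that("fitted transform generalizes exactly to held-out pairs", {
  p9 <- make_pairs(n = 9, seed = 21)
  h <- fitHelmert(p9[1:8, ])
  pred <- applyHelmert(as.matrix(p9[9, c("sx", "sy", "sz")]), h)
  expect_lt(max(abs(pred - as.matrix(p9[9, c("tx", "ty", "tz")]))), 1e-8)
})

test_that("apply then inverse is the identity; errors on degenerate input", {
  pc <- random_cloud(50, seed = 4)
  h <- fitHelmert(make_pairs())
  back <- applyHelmert(applyHelmert(pc, h), invertHelmert(h))
  expect_equal(coords(back), coords(pc), tolerance = 1e-9)
  expect_equal(coords(applyHelmert(pc, HelmertTransform())), coords(pc))

  collinear <- data.frame(sx = 1:4, sy = 2 * (1:4), sz = 3 * (1:4),
                          tx = 1:4, ty = 2 * (1:4), tz = 3 * (1:4))
  expect_error(fitHelmert(collinear), "degenerate|collinear")
  expect_error(fitHelmert(make_pairs()[1:2, ]), ">= 3")
})

test_that("gimbal lock reports kappa = 0 by convention", {
  ang <- helmertAngles(rotationMatrix(25, 90, 40))
  expect_equal(unname(ang["kappa"]), 0)
  expect_equal(unname(ang["phi"]), 90)
  # reconstructed matrix must agree even at the singular pose
  expect_equal(rotationMatrix(unname(ang["omega"]), unname(ang["phi"]),
                              unname(ang["kappa"])),
               rotationMatrix(25, 90, 40), tolerance = 1e-9,
               ignore_attr = TRUE)
})
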