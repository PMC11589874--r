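test_that("layer slicing partitions the cloud with half-open intervals", {
  pc <- PointCloud(data.frame(x = 0, y = 0, z = c(0.1, 0.6, 1.1)))
  layers <- sliceLayers(pc, 0.5)
  expect_identical(lengths(layers), c(`0` = 1L, `1` = 1L, `2` = 1L))

  pc2 <- PointCloud(data.frame(x = 0, y = 0, z = c(0.49, 0.5)))
  layers2 <- sliceLayers(pc2, 0.5)
  expect_identical(layers2[["0"]], 1L)   # 0.49 below the boundary
  expect_identical(layers2[["1"]], 2L)   # exactly 0.5: upper layer

  rnd <- random_cloud(500, seed = 14)
  layers3 <- sliceLayers(rnd, 0.5)
  expect_identical(sum(lengths(layers3)), 500L)
  expect_identical(sort(unlist(layers3, use.names = FALSE)), 1:500)
  expect_error(sliceLayers(pc, 0), "> 0")
})

test_that("DBSCAN agrees with the brute-force reachability oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 2 * sample(15:100, 1)
    # mixed clusters and sparse noise
    xy <- rbind(matrix(rnorm(n, 0, 0.15), ncol = 2),
                matrix(rnorm(n, 5, 0.15), ncol = 2),
                matrix(runif(n, -3, 8), ncol = 2))
    got <- clusterLayer(xy, eps = 0.4, minSamples = 5)
    want <- brute_dbscan(xy, eps = 0.4, min_pts = 5)
    expect_true(same_partition(got, want))
  }
})

test_that("DBSCAN handles isolated, duplicated and well-separated points", {
  two <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
               matrix(rnorm(100, 5, 0.1), ncol = 2))
  lab <- clusterLayer(two, eps = 0.4, minSamples = 5)
  expect_identical(length(setdiff(unique(lab), 0L)), 2L)
  expect_true(same_partition(lab, brute_dbscan(two, 0.4, 5)))

  lone <- rbind(c(0, 0), matrix(rnorm(20, 5, 0.01), ncol = 2))
  expect_identical(clusterLayer(lone, 0.4, 5)[1], 0L)  # noise

  dup <- matrix(rep(c(1.5, 2.5), each = 6), ncol = 2, byrow = FALSE)
  dup <- cbind(rep(1.5, 6), rep(2.5, 6))
  expect_identical(unique(clusterLayer(dup, 0.4, 5)), 1L)
})

test_that("fuzzy k-NN memberships follow the inverse-distance weight rule", {
  u <- fknnMembership(c(0, 0, 0), rbind(c(1, 0, 0), c(-1, 0, 0)),
                      c(1, 2), k = 2, m = 2)
  expect_equal(unname(u), c(0.5, 0.5))
  u <- fknnMembership(c(0, 0, 0), rbind(c(1, 0, 0), c(2, 0, 0)),
                      c(1, 2), k = 2, m = 2)
  expect_equal(unname(u), c(0.8, 0.2))
  u <- fknnMembership(c(2, 0, 0), rbind(c(1, 0, 0), c(2, 0, 0)),
                      c(1, 3), k = 2, m = 2)
  expect_equal(unname(u), 1)
  expect_identical(names(u), "3")
  expect_error(fknnMembership(c(0, 0, 0),
                              matrix(numeric(), ncol = 3), integer()),
               "empty")
})

test_that("memberships sum to one and are label-permutation equivariant", {
  set.seed(20)
  for (i in 1:20) {
    pos <- matrix(rnorm(30), ncol = 3)
    lab <- sample(1:3, 10, replace = TRUE)
    q <- rnorm(3)
    u <- fknnMembership(q, pos, lab, k = 7, m = 2)
    expect_equal(sum(u), 1, tolerance = 1e-12)
    perm <- c(2L, 3L, 1L)
    u2 <- fknnMembership(q, pos, perm[lab], k = 7, m = 2)
    expect_equal(unname(u2[order(as.integer(names(u2)))]),
                 unname(u[order(perm[as.integer(names(u))])]),
                 tolerance = 1e-12)
  }
})

two_tree_buffer <- function() {
  scene <- cached_scene("twotree", function()
    generateScene(sceneConfig(nTrees = 2, areaSize = 10,
                              areaCenter = c(30, 0), minSpacing = 4,
                              seed = 5),
                  scannerPose(angularResDeg = 0.15)))
  geo <- applyHelmert(rectify(scene$cloud), scene$truth$helmert)
  tt <- scene$truth$trees
  ctr <- c(mean(tt$x), mean(tt$y))
  d <- pointData(geo)
  buf <- geo[(d$x - ctr[1])^2 + (d$y - ctr[2])^2 <= 5^2]
  list(buffer = normalizeHeights(buf, scene$truth$dtm),
       truth_label = pointData(buf)$label, trees = tt)
}

test_that("tree detection seeds the planted trees and gates understory", {
  tb <- two_tree_buffer()
  seeds <- detectTrees(tb$buffer, layerSegConfig())
  expect_identical(length(seeds), 2L)
  # seeds sit at the planted locations (ids ordered by apex height)
  for (s in seeds) {
    dmin <- min(sqrt((tb$trees$x - s$apex_xy[1])^2 +
                       (tb$trees$y - s$apex_xy[2])^2))
    expect_lt(dmin, 0.25)
  }
  expect_identical(vapply(seeds, `[[`, 1L, "tree_id"), 1:2)

  # a flat blob spanning a single layer never becomes a tree
  set.seed(9)
  blob <- PointCloud(data.frame(x = rnorm(300, 0, 0.3),
                                y = rnorm(300, 0, 0.3),
                                z = runif(300, 0.5, 0.9)))
  expect_identical(detectTrees(blob, layerSegConfig()), list())
})

test_that("the fuzzy k-NN sweep labels a two-tree buffer at 95%+ accuracy", {
  tb <- two_tree_buffer()
  cfg <- layerSegConfig()
  seeds <- detectTrees(tb$buffer, cfg)
  seg <- segmentLayers(tb$buffer, seeds, cfg)
  lab <- pointData(seg)$label
  expect_true(all(lab %in% c(0L, vapply(seeds, `[[`, 1L, "tree_id"))))
  # map seed ids to truth ids by apex proximity
  map <- vapply(seeds, function(s)
    tb$trees$tree_id[which.min((tb$trees$x - s$apex_xy[1])^2 +
                                 (tb$trees$y - s$apex_xy[2])^2)], 1L)
  lab2 <- ifelse(lab > 0, map[pmax(lab, 1L)], 0L)
  expect_gt(mean(lab2 == tb$truth_label), 0.95)
  # deterministic: identical labels on a re-run
  seg2 <- segmentLayers(tb$buffer, detectTrees(tb$buffer, cfg), cfg)
  expect_identical(pointData(seg2)$label, lab)
})

test_that("points beyond the assignment gate stay unassigned", {
  d <- data.frame(x = c(rep(0, 60), 10), y = c(rep(0, 60), 0),
                  z = c(seq(0.31, 3.5, length.out = 60), 1))
  pc <- PointCloud(d)
  seeds <- list(list(tree_id = 1L, apex_xy = c(0, 0),
                     seed_point_indices = 1:60))
  seg <- segmentLayers(pc, seeds, layerSegConfig(maxAssignDist = 1.5))
  expect_identical(pointData(seg)$label[61], 0L)
  expect_true(all(pointData(seg)$label[1:60] == 1L))
  expect_error(segmentLayers(pc, list(), layerSegConfig()), "seed")
})
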