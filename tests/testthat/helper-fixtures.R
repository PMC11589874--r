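# Shared fixtures and independent oracles.

# random attribute-rich cloud
random_cloud <- function(n, seed = 1, extent = 10) {
  set.seed(seed)
  PointCloud(data.frame(
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    z = runif(n, -extent, extent),
    intensity = round(runif(n, 0, 65535)),
    reflectance = rnorm(n, -10, 3),
    deviation = runif(n, 0, 200),
    return_number = rep(1L, n), number_of_returns = rep(2L, n),
    label = sample(0:9, n, replace = TRUE)))
}

# independent voxel-occupancy oracle: count distinct floor-index triples
voxel_count_oracle <- function(cloud, size, origin) {
  xyz <- coords(cloud)
  key <- paste(floor((xyz[, 1] - origin[1]) / size),
               floor((xyz[, 2] - origin[2]) / size),
               floor((xyz[, 3] - origin[3]) / size))
  length(unique(key))
}

# brute-force O(n^2) DBSCAN oracle: cores from full distance matrix,
# clusters = connected components of cores under eps-reachability seeded in
# ascending index order; border points claimed by the earliest-created
# cluster among their core neighbours
brute_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  dd <- as.matrix(stats::dist(xy))
  core <- rowSums(dd <= eps) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (!core[p]) next
      nb <- which(dd[p, ] <= eps & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  labels
}

# partitions equal up to label renaming (noise label 0 fixed)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  if (!any(ok)) return(TRUE)
  identical(as.integer(match(a[ok], unique(a[ok]))),
            as.integer(match(b[ok], unique(b[ok]))))
}

# points sampled on a cylinder surface
cylinder_points <- function(n, center = c(0, 0), radius = 0.1,
                            zlim = c(0, 2), arc = c(0, 2 * pi), seed = 1,
                            radial_sd = 0) {
  set.seed(seed)
  th <- runif(n, arc[1], arc[2])
  r <- radius + rnorm(n, 0, radial_sd)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th),
        runif(n, zlim[1], zlim[2]))
}

flat_dtm <- function(extent = 20, z = 0, res = 0.5, center = c(0, 0)) {
  g <- expand.grid(x = seq(center[1] - extent, center[1] + extent, by = res),
                   y = seq(center[2] - extent, center[2] + extent, by = res))
  TerrainModel(cbind(g$x, g$y, z), resolution = res)
}

# small, quick synthetic scenes (coarse angular grid) cached per test run
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key, maker) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- maker()
  .scene_cache[[key]]
}

small_scene <- function(seed = 5, nTrees = 3, res = 0.25, areaSize = 20,
                        areaCenter = c(30, 0), ...) {
  key <- paste("s", seed, nTrees, res, areaSize, paste(areaCenter,
                                                       collapse = "_"))
  cached_scene(key, function()
    generateScene(sceneConfig(nTrees = nTrees, areaSize = areaSize,
                              areaCenter = areaCenter, seed = seed, ...),
                  scannerPose(angularResDeg = res)))
}

# the full-resolution default scene used by the acceptance checks
default_scene <- function(seed = 42) {
  cached_scene(paste("default", seed), function()
    generateScene(sceneConfig(seed = seed), scannerPose()))
}
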