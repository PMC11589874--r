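# Stem detection: local-PCA verticality classification, cylinder fitting,
# planimetric clustering into a stem map, and coarse cylinder-buffer
# segmentation.

#' Stem detection configuration
#'
#' The defaults are tuned for oblique mast-mounted scans of boreal stands;
#' every value is a first-class parameter.
#'
#' @param neighborhoodRadius metres; radius of the spherical neighbourhood
#'   used for the per-point PCA (default 0.5).
#' @param verticalityMaxAngle degrees; maximum angle between the dominant
#'   eigenvector and the local terrain normal (default 15).
#' @param linearityMin minimum linearity `(l1 - l2) / l1` of the neighbourhood
#'   eigenvalues, in `[0, 1]` (default 0.6).
#' @param minClusterPoints minimum stem-point count for a cluster to be
#'   fitted (default 50).
#' @param stemMergeXY metres; planimetric link distance for clustering stem
#'   points and for merging coincident stems (default 0.5).
#' @param maxRange metres; stems farther than this (3-D) from the scanner are
#'   discarded (default 200, the reliable detection limit of the
#'   acquisition).
#' @param maxBaseHeight metres; a stem is rooted, so clusters whose lowest
#'   point floats higher than this above the local ground are rejected
#'   (default 8: visible stem bases can start several metres up under
#'   partial occlusion, while detached crown-top fragments float near the
#'   tree top).
#' @param maxAxisTilt degrees; maximum tilt of the fitted cylinder axis from
#'   the vertical (default 5: stems in the emulated stands are near-plumb,
#'   whereas crown-edge silhouettes follow the crown slope of 10 degrees or
#'   more).
#' @param maxStemRadius metres; maximum plausible fitted stem radius
#'   (default 0.5); planar crown sheets fit with arbitrarily large radii.
#' @param bufferRadius metres; coarse segmentation cylinder radius
#'   (default 3.5).
#' @return a list of class `StemDetectionConfig`.
#' @export
stemDetectionConfig <- function(neighborhoodRadius = 0.5,
                                verticalityMaxAngle = 15,
                                linearityMin = 0.6,
                                minClusterPoints = 50,
                                stemMergeXY = 0.5,
                                maxRange = 200,
                                maxBaseHeight = 8,
                                maxAxisTilt = 5,
                                maxStemRadius = 0.5,
                                bufferRadius = 3.5) {
  stopifnot(neighborhoodRadius > 0, verticalityMaxAngle > 0,
            linearityMin >= 0, linearityMin <= 1, minClusterPoints > 0,
            stemMergeXY > 0, maxRange > 0, maxBaseHeight > 0,
            maxAxisTilt > 0, maxStemRadius > 0, bufferRadius > 0)
  structure(list(neighborhoodRadius = neighborhoodRadius,
                 verticalityMaxAngle = verticalityMaxAngle,
                 linearityMin = linearityMin,
                 minClusterPoints = minClusterPoints,
                 stemMergeXY = stemMergeXY, maxRange = maxRange,
                 maxBaseHeight = maxBaseHeight, maxAxisTilt = maxAxisTilt,
                 maxStemRadius = maxStemRadius, bufferRadius = bufferRadius),
            class = "StemDetectionConfig")
}

# terrain normal (unit, z >= 0) at each query footprint: local plane fit to
# the DTM support within 1 m, via the smallest covariance eigenvector
.terrain_normals <- function(dtm, xy) {
  sup <- dtm@points
  feats <- cpp_local_pca(sup, radius = max(1, 3 * dtm@resolution),
                         min_pts = 3L)
  nrm <- feats[, 6:8, drop = FALSE]
  bad <- !is.finite(nrm[, 1])
  nrm[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  flip <- nrm[, 3] < 0
  nrm[flip, ] <- -nrm[flip, ]
  nn <- cpp_knn(sup[, 1:2, drop = FALSE], xy, 1L)
  nrm[nn$index[, 1], , drop = FALSE]
}

#' Classify stem points by local-PCA verticality
#'
#' For each point, the principal directions of its spherical neighbourhood
#' are computed; the point is flagged as a stem candidate when the
#' neighbourhood has at least 5 points, the eigenvalue linearity
#' `(l1 - l2)/l1` reaches `linearityMin`, and the dominant eigenvector is
#' within `verticalityMaxAngle` of the local terrain normal (from a plane fit
#' to the DTM support around the point's footprint; a flat DTM gives +Z).
#'
#' @param cloud a [PointCloud-class], ground-normalized or georeferenced.
#' @param dtm a [TerrainModel-class] in the same frame (planimetrically
#'   overlapping; disjoint bounding boxes indicate a frame mismatch and are
#'   an error).
#' @param config a [stemDetectionConfig()].
#' @return logical mask, one entry per point.
#' @export
classifyStemPoints <- function(cloud, dtm, config = stemDetectionConfig()) {
  xyz <- coords(cloud)
  if (nrow(xyz) == 0) return(logical(0))
  sup <- dtm@points
  overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])
  if (!overlap(range(xyz[, 1]), range(sup[, 1])) ||
      !overlap(range(xyz[, 2]), range(sup[, 2])))
    stop("cloud and DTM bounding boxes are disjoint: frame mismatch?")

  feats <- cpp_local_pca(xyz, config$neighborhoodRadius, min_pts = 5L)
  nrm <- .terrain_normals(dtm, xyz[, 1:2, drop = FALSE])
  cosang <- abs(rowSums(feats[, 3:5, drop = FALSE] * nrm))
  ang <- .rad2deg(acos(pmin(1, cosang)))
  ok <- feats[, 1] >= 5 & !is.na(feats[, 2]) &
    feats[, 2] >= config$linearityMin & ang <= config$verticalityMaxAngle
  ok & !is.na(ok)
}

.cyl_axis_dist <- function(xyz, c0, d) {
  rel <- sweep(xyz, 2, c0)
  t <- rel %*% d
  sqrt(pmax(0, rowSums(rel^2) - t^2))
}

#' Least-squares cylinder fit
#'
#' Fits axis and radius minimizing the sum of squared radial residuals
#' `sum((dist_i - r)^2)` with Levenberg-Marquardt, initialized from the given
#' axis direction and a 2-D algebraic circle fit of the projected points.
#' Noise-free sampled cylinders are recovered to well below 1e-6.
#'
#' @param points a [PointCloud-class] or n x 3 matrix, n >= 6, not all
#'   collinear in the projection along `initDirection`.
#' @param initDirection initial unit axis direction (e.g. the neighbourhood
#'   PCA dominant direction); default vertical.
#' @return a [CylinderModel-class].
#' @export
fitCylinder <- function(points, initDirection = c(0, 0, 1)) {
  xyz <- if (is.matrix(points)) points else coords(points)
  n <- nrow(xyz)
  if (n < 6) stop("cylinder fit needs >= 6 points, got ", n)
  d0 <- initDirection / sqrt(sum(initDirection^2))
  if (d0[3] < 0) d0 <- -d0
  # orthonormal basis perpendicular to d0
  ref <- if (abs(d0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d0) * d0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d0[2] * e1[3] - d0[3] * e1[2],
          d0[3] * e1[1] - d0[1] * e1[3],
          d0[1] * e1[2] - d0[2] * e1[1])
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  u <- rel %*% e1
  v <- rel %*% e2
  if (stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12)
    stop("degenerate cylinder geometry: points collinear in projection")
  # algebraic (Kasa) circle fit in the projected plane
  A <- cbind(2 * u, 2 * v, 1)
  sol <- tryCatch(qr.solve(A, u^2 + v^2),
                  error = function(e) stop("degenerate cylinder geometry: ",
                                           conditionMessage(e)))
  r0 <- sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 1e-8))

  par0 <- c(a = 0, b = 0, p = sol[1], q = sol[2], r = r0)
  resid_fn <- function(par) {
    d <- d0 + par[1] * e1 + par[2] * e2
    d <- d / sqrt(sum(d^2))
    c0 <- ctr + par[3] * e1 + par[4] * e2
    .cyl_axis_dist(xyz, c0, d) - par[5]
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-15, ptol = 1e-15))
  par <- fit$par
  if (!is.finite(par[5]) || par[5] <= 0)
    stop("degenerate cylinder geometry: non-positive radius")
  d <- d0 + par[1] * e1 + par[2] * e2
  d <- d / sqrt(sum(d^2))
  if (d[3] < 0) d <- -d
  c0 <- ctr + par[3] * e1 + par[4] * e2
  res <- .cyl_axis_dist(xyz, c0, d) - par[5]
  new("CylinderModel", axisPoint = as.numeric(c0), axisDirection = d,
      radius = unname(par[5]), zExtent = range(xyz[, 3]),
      inlierRMSE = sqrt(mean(res^2)))
}

# ground position of a cylinder axis: intersect with the DTM surface by
# fixed-point iteration on the footprint
.axis_ground_position <- function(cyl, dtm) {
  c0 <- cyl@axisPoint
  d <- cyl@axisDirection
  if (abs(d[3]) < 0.2) return(NULL)  # near-horizontal axis: not a stem
  xy <- c0[1:2]
  zg <- groundElevation(dtm, xy)
  for (i in 1:8) {
    t <- (zg - c0[3]) / d[3]
    p <- c0 + t * d
    xy <- p[1:2]
    zg <- groundElevation(dtm, xy)
  }
  c(xy, zg)
}

#' Cluster stem points into a stem map with cylinder models
#'
#' Stem-classified points are grouped by planimetric connectivity (link
#' distance `stemMergeXY`); groups of at least `minClusterPoints` points are
#' fitted with [fitCylinder()] (initialized from the group's dominant PCA
#' direction). Groups whose fitted axes hit the ground within `stemMergeXY`
#' of each other are merged and refitted, restoring the coupling between
#' clustering and model fitting. Each stem's ground position is the
#' intersection of its axis with the DTM surface; stems farther than
#' `maxRange` (3-D) from the scanner are discarded.
#'
#' @param cloud a [PointCloud-class].
#' @param stemMask logical mask from [classifyStemPoints()].
#' @param dtm a [TerrainModel-class] in the same frame.
#' @param config a [stemDetectionConfig()].
#' @param scannerPosition scanner location in the cloud's frame
#'   (default origin).
#' @return a [StemMap-class] (empty when nothing qualifies).
#' @export
clusterStems <- function(cloud, stemMask, dtm,
                         config = stemDetectionConfig(),
                         scannerPosition = c(0, 0, 0)) {
  empty <- StemMap(data.frame(stem_id = integer(), x = numeric(),
                              y = numeric(), ground_z = numeric(),
                              n_points = integer()), list())
  idx <- which(stemMask)
  if (length(idx) == 0) return(empty)
  xyz <- coords(cloud)[idx, , drop = FALSE]
  lab <- cpp_dbscan(xyz[, 1:2, drop = FALSE], eps = config$stemMergeXY,
                    min_pts = 1L)
  groups <- split(seq_len(nrow(xyz)), lab)
  groups <- groups[vapply(groups, length, 1L) >= config$minClusterPoints]
  if (length(groups) == 0) return(empty)

  fit_group <- function(rows) {
    pts <- xyz[rows, , drop = FALSE]
    # the stem model describes the ground-rooted part of the cluster: fit on
    # the lowest vertically contiguous segment (0.5 m bins), which excludes
    # detached line-like crown pieces (e.g. conifer tops) merged into the
    # cluster by planimetric connectivity
    bins <- floor((pts[, 3] - min(pts[, 3])) / 0.5)
    occ <- sort(unique(bins))
    gap <- which(diff(occ) > 1)
    run_end <- if (length(gap)) occ[gap[1]] else occ[length(occ)]
    seg <- bins <= run_end
    fit_pts <- if (sum(seg) >= 6) pts[seg, , drop = FALSE] else pts
    dir0 <- tryCatch(stats::prcomp(fit_pts, center = TRUE)$rotation[, 1],
                     error = function(e) c(0, 0, 1))
    cyl <- tryCatch(fitCylinder(fit_pts, dir0), error = function(e) NULL)
    if (is.null(cyl)) return(NULL)
    tilt <- .rad2deg(acos(pmin(1, abs(cyl@axisDirection[3]))))
    if (tilt > config$maxAxisTilt) return(NULL)
    if (cyl@radius > config$maxStemRadius) return(NULL)
    gp <- .axis_ground_position(cyl, dtm)
    if (is.null(gp)) return(NULL)
    if (min(fit_pts[, 3]) - gp[3] > config$maxBaseHeight) return(NULL)
    list(rows = rows, cyl = cyl, ground = gp)
  }
  fits <- Filter(Negate(is.null), lapply(groups, fit_group))
  if (length(fits) == 0) return(empty)

  # merge stems whose ground positions planimetrically coincide, refit
  repeat {
    if (length(fits) < 2) break
    g <- t(vapply(fits, function(f) f$ground[1:2], numeric(2)))
    dd <- as.matrix(stats::dist(g))
    diag(dd) <- Inf
    hit <- which(dd < config$stemMergeXY, arr.ind = TRUE)
    if (nrow(hit) == 0) break
    i <- min(hit[1, ]); j <- max(hit[1, ])
    merged <- fit_group(c(fits[[i]]$rows, fits[[j]]$rows))
    fits[[j]] <- NULL
    if (is.null(merged)) fits[[i]] <- NULL else fits[[i]] <- merged
    if (length(fits) == 0) return(empty)
  }

  keep <- vapply(fits, function(f) {
    sqrt(sum((c(f$ground) - scannerPosition)^2)) <= config$maxRange
  }, logical(1))
  fits <- fits[keep]
  if (length(fits) == 0) return(empty)

  ord <- order(vapply(fits, function(f) f$ground[1], numeric(1)),
               vapply(fits, function(f) f$ground[2], numeric(1)))
  fits <- fits[ord]
  StemMap(
    data.frame(stem_id = seq_along(fits),
               x = vapply(fits, function(f) f$ground[1], numeric(1)),
               y = vapply(fits, function(f) f$ground[2], numeric(1)),
               ground_z = vapply(fits, function(f) f$ground[3], numeric(1)),
               n_points = vapply(fits, function(f) length(f$rows), 1L)),
    lapply(fits, function(f) f$cyl))
}

#' Coarse per-stem segmentation with cylindrical buffers
#'
#' For each stem, extracts all points whose planimetric distance to the stem
#' ground position is at most `bufferRadius` (boundary inclusive), over the
#' full z extent. Buffers of nearby stems overlap, so a point may appear in
#' several buffers.
#'
#' @param cloud a [PointCloud-class].
#' @param stemMap a [StemMap-class].
#' @param config a [stemDetectionConfig()].
#' @return named list of [PointCloud-class] buffers, one per stem
#'   (names = stem ids); empty list for an empty stem map.
#' @export
coarseSegment <- function(cloud, stemMap, config = stemDetectionConfig()) {
  st <- stems(stemMap)
  if (nrow(st) == 0) return(list())
  d <- pointData(cloud)
  out <- vector("list", nrow(st))
  names(out) <- as.character(st$stem_id)
  for (i in seq_len(nrow(st))) {
    dist2 <- (d$x - st$x[i])^2 + (d$y - st$y[i])^2
    out[[i]] <- cloud[dist2 <= config$bufferRadius^2]
  }
  out
}
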