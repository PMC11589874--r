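# Fine segmentation of a coarse buffer: horizontal layering, per-layer
# DBSCAN, tree detection by vertical-line fitting over stacked cluster
# centroids, and iterative fuzzy k-NN point labelling.

#' Layer segmentation configuration
#'
#' All numeric defaults are package choices, exposed as first-class
#' parameters (the appropriate values depend on point density and crown
#' geometry and are typically tuned per acquisition).
#'
#' @param layerThickness metres; horizontal slice thickness (default 0.5).
#' @param dbscanEps metres; DBSCAN reachability radius in the horizontal
#'   plane (default 0.4).
#' @param dbscanMinSamples DBSCAN core-point threshold, neighbourhood
#'   including the point itself (default 5).
#' @param lineXYTolerance metres; planimetric link distance when stacking
#'   cluster centroids across layers (default 0.5).
#' @param minLayersPerTree minimum number of distinct layers a centroid stack
#'   must span to become a tree seed (default 4).
#' @param fknnK neighbours used by the fuzzy k-NN classifier (default 10).
#' @param fuzzifierM fuzzifier exponent m > 1 (default 2).
#' @param maxAssignDist metres; a point whose nearest labelled neighbour is
#'   farther than this stays unassigned, label 0 (default 1.5).
#' @param sweepDirection `"bottom_up"` (default; stems anchor tree identity
#'   near the ground) or `"top_down"`.
#' @param seedSuppressRadius metres; a tree seed must be a local maximum of
#'   apex height - candidate centroid stacks whose apex lies within this
#'   planimetric radius of a taller candidate are partial crown fragments of
#'   that tree, not trees (default 1.75, below the minimum stem spacing of
#'   the emulated stands).
#' @param groundHeightMin metres; points below this normalized height are
#'   ground, excluded from tree detection and left unassigned (label 0) by
#'   the sweep (default 0.3). Without it the ground disc inside a buffer -
#'   whose planimetric centroid coincides with the stem - would be absorbed
#'   into the tree.
#' @return a list of class `LayerSegConfig`.
#' @export
layerSegConfig <- function(layerThickness = 0.5, dbscanEps = 0.4,
                           dbscanMinSamples = 5, lineXYTolerance = 0.5,
                           minLayersPerTree = 4, fknnK = 10,
                           fuzzifierM = 2, maxAssignDist = 1.5,
                           sweepDirection = c("bottom_up", "top_down"),
                           seedSuppressRadius = 1.75,
                           groundHeightMin = 0.3) {
  sweepDirection <- match.arg(sweepDirection)
  stopifnot(layerThickness > 0, dbscanEps > 0, dbscanMinSamples > 0,
            lineXYTolerance > 0, minLayersPerTree > 0, fknnK > 0,
            fuzzifierM > 1, maxAssignDist > 0, seedSuppressRadius >= 0,
            groundHeightMin >= 0)
  structure(list(layerThickness = layerThickness, dbscanEps = dbscanEps,
                 dbscanMinSamples = dbscanMinSamples,
                 lineXYTolerance = lineXYTolerance,
                 minLayersPerTree = minLayersPerTree, fknnK = fknnK,
                 fuzzifierM = fuzzifierM, maxAssignDist = maxAssignDist,
                 sweepDirection = sweepDirection,
                 seedSuppressRadius = seedSuppressRadius,
                 groundHeightMin = groundHeightMin),
            class = "LayerSegConfig")
}

#' Slice a height-normalized cloud into horizontal layers
#'
#' Layer `j` holds the points with `z` in the half-open interval
#' `[j*t, (j+1)*t)`; the layers partition the cloud.
#'
#' @param cloud a [PointCloud-class] with ground-normalized heights.
#' @param thickness layer thickness in metres.
#' @return named list of integer point-index vectors, ordered by layer index
#'   (names are the layer indices `j`).
#' @export
sliceLayers <- function(cloud, thickness = 0.5) {
  if (thickness <= 0) stop("layer thickness must be > 0")
  z <- pointData(cloud)$z
  j <- floor(z / thickness)
  idx <- split(seq_along(z), j)
  idx[order(as.numeric(names(idx)))]
}

#' DBSCAN clustering of one layer in the horizontal plane
#'
#' Standard DBSCAN semantics: a point is a core point when its
#' eps-neighbourhood (itself included) holds at least `minSamples` points;
#' clusters are the connected components of core points under
#' eps-reachability, with border points joining the first cluster that
#' reaches them (deterministic: expansion starts from the lowest-index
#' unvisited core point). Clustering is performed on x, y only.
#'
#' @param xy n x 2 matrix of planimetric coordinates (a n x 3 matrix may be
#'   passed; z is ignored).
#' @param eps reachability radius in metres.
#' @param minSamples core-point threshold.
#' @return integer labels: 0 for noise, clusters numbered from 1.
#' @export
clusterLayer <- function(xy, eps = 0.4, minSamples = 5) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  cpp_dbscan(xy, eps = eps, min_pts = as.integer(minSamples))
}

#' Detect tree seeds by stacking layer clusters along vertical lines
#'
#' Layers the cloud with [sliceLayers()], clusters each layer with
#' [clusterLayer()], then groups the per-layer cluster centroids by
#' planimetric proximity (link distance `lineXYTolerance`). A centroid group
#' spanning at least `minLayersPerTree` distinct layers becomes a tree: a 3-D
#' line is least-squares fitted through its centroids (groups more than 15
#' degrees off vertical are rejected), the apex is the centroid of the
#' group's topmost layer (the local z maximum), and the group's member
#' cluster points become the seed points. Tree ids are assigned in order of
#' decreasing apex height.
#'
#' @param cloud a height-normalized [PointCloud-class] buffer.
#' @param config a [layerSegConfig()].
#' @return list of tree seeds; each has `tree_id`, `apex_xy`, `line` (point,
#'   direction), `n_layers` and `seed_point_indices`.
#' @export
detectTrees <- function(cloud, config = layerSegConfig()) {
  xyz <- coords(cloud)
  above <- which(xyz[, 3] >= config$groundHeightMin)
  if (length(above) == 0) return(list())
  layers <- sliceLayers(cloud[above], config$layerThickness)
  if (length(layers) == 0) return(list())

  cent <- list()
  for (lname in names(layers)) {
    idx <- above[layers[[lname]]]
    lab <- clusterLayer(xyz[idx, , drop = FALSE], config$dbscanEps,
                        config$dbscanMinSamples)
    for (cl in setdiff(unique(lab), 0L)) {
      rows <- idx[lab == cl]
      cent[[length(cent) + 1L]] <- list(
        x = mean(xyz[rows, 1]), y = mean(xyz[rows, 2]),
        z = mean(xyz[rows, 3]), layer = as.numeric(lname), rows = rows)
    }
  }
  if (length(cent) == 0) return(list())
  cxy <- cbind(vapply(cent, `[[`, 1, "x"), vapply(cent, `[[`, 1, "y"))
  grp <- cpp_dbscan(cxy, eps = config$lineXYTolerance, min_pts = 1L)

  seeds <- list()
  for (g in sort(unique(grp))) {
    members <- cent[grp == g]
    lay <- vapply(members, `[[`, 1, "layer")
    if (length(unique(lay)) < config$minLayersPerTree) next
    pts <- cbind(vapply(members, `[[`, 1, "x"),
                 vapply(members, `[[`, 1, "y"),
                 vapply(members, `[[`, 1, "z"))
    ctr <- colMeans(pts)
    dir <- stats::prcomp(pts, center = TRUE)$rotation[, 1]
    if (dir[3] < 0) dir <- -dir
    if (.rad2deg(acos(pmin(1, abs(dir[3])))) > 15) next
    top <- members[lay == max(lay)]
    apex <- c(mean(vapply(top, `[[`, 1, "x")),
              mean(vapply(top, `[[`, 1, "y")))
    seeds[[length(seeds) + 1L]] <- list(
      apex_xy = apex, apex_z = max(vapply(members, `[[`, 1, "z")),
      line = list(point = ctr, direction = dir),
      n_layers = length(unique(lay)),
      seed_point_indices = sort(unlist(lapply(members, `[[`, "rows"))))
  }
  if (length(seeds) == 0) return(list())
  # local z-maxima rule: processing candidates from the tallest down, a
  # candidate whose apex lies within seedSuppressRadius of an accepted
  # taller seed is a partial crown fragment of that tree, not a tree
  ord <- order(-vapply(seeds, `[[`, 1, "apex_z"))
  seeds <- seeds[ord]
  kept <- list()
  for (s in seeds) {
    clash <- any(vapply(kept, function(k)
      sqrt(sum((k$apex_xy - s$apex_xy)^2)) < config$seedSuppressRadius,
      logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- s
  }
  for (i in seq_along(kept)) kept[[i]]$tree_id <- i
  kept
}

#' Fuzzy k-NN class memberships for a query point
#'
#' Over the `k` nearest labelled points, the membership of class `c` is
#' `u_c = sum_{j in c} w_j / sum_j w_j` with inverse-distance weights
#' `w_j = d_j^(-2/(m-1))`. A query coinciding with a labelled point
#' (distance 0) gets full membership in that point's class. Memberships sum
#' to one.
#'
#' @param query length-3 position.
#' @param labeledPos n x 3 matrix of labelled point positions.
#' @param labels integer class labels, one per row of `labeledPos`.
#' @param k number of neighbours (capped at n).
#' @param m fuzzifier exponent, > 1.
#' @return named numeric vector of memberships over the labels present in
#'   the neighbourhood (other labels implicitly 0).
#' @examples
#' fknnMembership(c(0, 0, 0), rbind(c(1, 0, 0), c(2, 0, 0)), c(1, 2),
#'                k = 2, m = 2)  # u = (0.8, 0.2)
#' @export
fknnMembership <- function(query, labeledPos, labels, k = 10, m = 2) {
  labeledPos <- as.matrix(labeledPos)
  n <- nrow(labeledPos)
  if (n == 0) stop("empty labelled set")
  stopifnot(m > 1, length(labels) == n)
  k <- min(k, n)
  dd <- sqrt(colSums((t(labeledPos) - query)^2))
  ord <- order(dd)[seq_len(k)]
  d <- dd[ord]
  lab <- labels[ord]
  if (d[1] == 0) {
    hit <- lab[d == 0]
    u <- stats::setNames(numeric(length(unique(hit))),
                         sort(unique(hit)))
    tabs <- table(hit)
    u[names(tabs)] <- as.numeric(tabs) / sum(tabs)
    return(u)
  }
  w <- d^(-2 / (m - 1))
  agg <- tapply(w, lab, sum)
  u <- as.numeric(agg) / sum(w)
  stats::setNames(u, names(agg))
}

#' Iterative fuzzy k-NN segmentation of a buffer
#'
#' Seed points are pre-labelled from [detectTrees()]; the remaining points
#' are then classified layer by layer in `sweepDirection`. Each unlabelled
#' point in the current layer (processed in ascending point index) receives
#' the argmax fuzzy membership over its `fknnK` nearest points among
#' everything labelled so far - seeds, previous layers, and already-labelled
#' points of the current layer - unless its nearest labelled neighbour is
#' farther than `maxAssignDist`, in which case it stays 0 (unassigned).
#' The result is deterministic for a fixed configuration.
#'
#' @param cloud a height-normalized [PointCloud-class] buffer.
#' @param seeds seed list from [detectTrees()].
#' @param config a [layerSegConfig()].
#' @return the cloud with an integer `label` column (0 = unassigned).
#' @export
segmentLayers <- function(cloud, seeds, config = layerSegConfig()) {
  if (length(seeds) == 0) stop("no tree seeds supplied")
  d <- pointData(cloud)
  n <- nrow(d)
  labels0 <- integer(n)
  for (s in seeds) labels0[s$seed_point_indices] <- s$tree_id
  above <- which(d$z >= config$groundHeightMin)
  lab <- integer(n)                      # ground stays unassigned
  if (length(above)) {
    layer <- as.integer(floor(d$z[above] / config$layerThickness))
    lab[above] <- cpp_fknn_sweep(coords(cloud)[above, , drop = FALSE],
                                 labels0[above], layer,
                                 bottom_up =
                                   config$sweepDirection == "bottom_up",
                                 k = as.integer(config$fknnK),
                                 m = config$fuzzifierM,
                                 max_dist = config$maxAssignDist)
  }
  d$label <- as.integer(lab)
  pointData(cloud) <- d
  cloud
}
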