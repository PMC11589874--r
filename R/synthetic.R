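# Seed-reproducible synthetic PLS forest scenes with per-point ground truth.
#
# The generator emulates the acquisition geometry of a mast-mounted scanner
# (default: 30 m above ground, boresight tilted 60 degrees down) by casting
# an angular ray grid against analytic surface primitives: a ground plane,
# stem cylinders, cone crowns for conifers and ellipsoid crowns for birch.
# First-hit occlusion, Gaussian range noise, class-dependent attribute
# synthesis and uniform frustum outliers give every pipeline stage a
# labelled, realistic-enough input at desk scale.

#' Scanner pose for scene simulation
#'
#' @param position scanner location in the world frame, metres
#'   (default `c(0, 0, 30)`: a 30 m mast over ground at z = 0).
#' @param tiltDeg boresight depression below the horizon, degrees
#'   (default 60).
#' @param headingDeg boresight azimuth from +X towards +Y, degrees
#'   (default 0).
#' @param fovVDeg,fovHDeg vertical/horizontal field of view, degrees
#'   (defaults 87 and 151).
#' @param angularResDeg angular grid step, degrees. The field instrument
#'   scans at 0.006 degrees; the default 0.05 keeps desk-scale scenes
#'   tractable (the 0.006 grid implies ~1e8 rays).
#' @param maxRange metres; no returns beyond this (default 200).
#' @return a list of class `ScannerPose`.
#' @export
scannerPose <- function(position = c(0, 0, 30), tiltDeg = 60,
                        headingDeg = 0, fovVDeg = 87, fovHDeg = 151,
                        angularResDeg = 0.05, maxRange = 200) {
  stopifnot(length(position) == 3, angularResDeg > 0, maxRange > 0,
            fovVDeg > 0, fovHDeg > 0)
  structure(list(position = as.numeric(position), tiltDeg = tiltDeg,
                 headingDeg = headingDeg, fovVDeg = fovVDeg,
                 fovHDeg = fovHDeg, angularResDeg = angularResDeg,
                 maxRange = maxRange),
            class = "ScannerPose")
}

#' Synthetic scene configuration
#'
#' Defaults describe the emulated stand: 10 trees with at least 2 m spacing
#' in a 40 m x 40 m plot centred 45 m in front of the scanner, a pine-heavy
#' 3/1/1 species mix, 5 mm range noise (the instrument's nominal accuracy)
#' and a 0.1 percent uniform outlier fraction.
#'
#' @param nTrees number of trees (default 10).
#' @param speciesMix named proportions over
#'   `pine`, `spruce`, `birch`, `unidentified`; must sum to 1.
#' @param areaSize square plot edge length, metres (default 40).
#' @param areaCenter plot centre (x, y), metres (default `c(45, 0)`).
#' @param terrain `"flat"` or `"sloped"`.
#' @param slope length-2 terrain gradient (dz/dx, dz/dy) used when
#'   `terrain = "sloped"` (default `c(0.1, 0)`).
#' @param minSpacing minimum tree spacing, metres (default 2).
#' @param stemRadiusRange stem radius range, metres (default 0.08-0.25).
#' @param heightRange named list of per-species height ranges, metres.
#' @param rangeNoiseSigma Gaussian range noise SD, metres (default 0.005).
#' @param outlierFraction uniform frustum outlier fraction (default 0.001).
#' @param occlusion keep only the first surface intersection per ray
#'   (default TRUE).
#' @param georefOffset translation from the world frame to the emulated
#'   geodetic frame recorded in the truth tables (default `c(500, 800, 0)`).
#' @param seed integer; the scene is fully determined by it.
#' @return a list of class `SceneConfig`.
#' @export
sceneConfig <- function(nTrees = 10,
                        speciesMix = c(pine = 0.6, spruce = 0.2,
                                       birch = 0.2, unidentified = 0),
                        areaSize = 40, areaCenter = c(45, 0),
                        terrain = c("flat", "sloped"), slope = c(0.1, 0),
                        minSpacing = 2,
                        stemRadiusRange = c(0.08, 0.25),
                        heightRange = list(pine = c(12, 22),
                                           spruce = c(10, 20),
                                           birch = c(8, 16),
                                           unidentified = c(5, 10)),
                        rangeNoiseSigma = 0.005, outlierFraction = 0.001,
                        occlusion = TRUE, georefOffset = c(500, 800, 0),
                        seed = 1L) {
  terrain <- match.arg(terrain)
  stopifnot(abs(sum(speciesMix) - 1) < 1e-9, all(speciesMix >= 0),
            areaSize > 0, minSpacing > 0, rangeNoiseSigma >= 0,
            outlierFraction >= 0)
  structure(list(nTrees = nTrees, speciesMix = speciesMix,
                 areaSize = areaSize, areaCenter = as.numeric(areaCenter),
                 terrain = terrain, slope = as.numeric(slope),
                 minSpacing = minSpacing, stemRadiusRange = stemRadiusRange,
                 heightRange = heightRange,
                 rangeNoiseSigma = rangeNoiseSigma,
                 outlierFraction = outlierFraction, occlusion = occlusion,
                 georefOffset = as.numeric(georefOffset),
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

# ---- analytic ray-primitive intersection -------------------------------

# smallest positive ray parameter t (or Inf) for each ray direction;
# S origin, D n x 3 unit directions
.isect <- function(prim, S, D) {
  t <- rep(Inf, nrow(D))
  if (prim$type == "plane") {
    # z = z0 + gx (x - cx) + gy (y - cy)
    gx <- prim$gx %||% 0; gy <- prim$gy %||% 0
    denom <- D[, 3] - gx * D[, 1] - gy * D[, 2]
    tt <- (prim$z0 + gx * (S[1] - prim$center[1]) +
             gy * (S[2] - prim$center[2]) - S[3]) / denom
    ok <- is.finite(tt) & tt > 0
    if (!is.null(prim$bounds)) {
      px <- S[1] + tt * D[, 1]; py <- S[2] + tt * D[, 2]
      ok <- ok & px >= prim$bounds[1] & px <= prim$bounds[2] &
        py >= prim$bounds[3] & py <= prim$bounds[4]
    }
    t[ok] <- tt[ok]
  } else if (prim$type == "cylinder") {
    u <- S[1] - prim$center[1]; v <- S[2] - prim$center[2]
    A <- D[, 1]^2 + D[, 2]^2
    B <- 2 * (u * D[, 1] + v * D[, 2])
    C <- u^2 + v^2 - prim$radius^2
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0 & A > 0
    tt <- rep(Inf, nrow(D))
    tt[ok] <- (-B[ok] - sqrt(disc[ok])) / (2 * A[ok])  # near side only
    z <- S[3] + tt * D[, 3]
    ok <- ok & tt > 0 & z >= prim$zlim[1] & z <= prim$zlim[2]
    t[ok] <- tt[ok]
  } else if (prim$type == "cone") {
    # vertical cone, apex (x, y, za), radius growing to baseRadius at baseZ
    k <- prim$baseRadius / (prim$apex[3] - prim$baseZ)
    u <- S[1] - prim$apex[1]; v <- S[2] - prim$apex[2]
    w <- prim$apex[3] - S[3]
    A <- D[, 1]^2 + D[, 2]^2 - k^2 * D[, 3]^2
    B <- 2 * (u * D[, 1] + v * D[, 2] + k^2 * w * D[, 3])
    C <- u^2 + v^2 - k^2 * w^2
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0 & abs(A) > 1e-12
    t1 <- rep(Inf, nrow(D)); t2 <- rep(Inf, nrow(D))
    t1[ok] <- (-B[ok] - sqrt(disc[ok])) / (2 * A[ok])
    t2[ok] <- (-B[ok] + sqrt(disc[ok])) / (2 * A[ok])
    for (cand in list(t1, t2)) {
      z <- S[3] + cand * D[, 3]
      good <- is.finite(cand) & cand > 0 & z >= prim$baseZ &
        z <= prim$apex[3] & cand < t
      t[good] <- cand[good]
    }
  } else if (prim$type == "ellipsoid") {
    a <- prim$semiXY; c2 <- prim$semiZ
    o <- c((S[1] - prim$center[1]) / a, (S[2] - prim$center[2]) / a,
           (S[3] - prim$center[3]) / c2)
    Dn <- cbind(D[, 1] / a, D[, 2] / a, D[, 3] / c2)
    A <- rowSums(Dn^2)
    B <- 2 * (Dn[, 1] * o[1] + Dn[, 2] * o[2] + Dn[, 3] * o[3])
    C <- sum(o^2) - 1
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0
    tt <- rep(Inf, nrow(D))
    tt[ok] <- (-B[ok] - sqrt(disc[ok])) / (2 * A[ok])
    ok <- ok & tt > 0
    t[ok] <- tt[ok]
  } else if (prim$type == "sphere") {
    o <- S - prim$center
    B <- 2 * as.vector(D %*% o)
    C <- sum(o^2) - prim$radius^2
    disc <- B^2 - 4 * C
    ok <- disc >= 0
    tt <- rep(Inf, nrow(D))
    tt[ok] <- (-B[ok] - sqrt(disc[ok])) / 2
    ok <- ok & tt > 0
    t[ok] <- tt[ok]
  } else stop("unknown primitive type: ", prim$type)
  t
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# angular ray grid in the level frame (origin at the scanner)
.ray_grid <- function(pose, azWindow = NULL, elWindow = NULL) {
  res <- pose$angularResDeg
  az <- seq(pose$headingDeg - pose$fovHDeg / 2,
            pose$headingDeg + pose$fovHDeg / 2, by = res)
  el <- seq(-pose$tiltDeg - pose$fovVDeg / 2,
            -pose$tiltDeg + pose$fovVDeg / 2, by = res)
  el <- el[el > -89.95 & el < 89.95]
  if (!is.null(azWindow)) az <- az[az >= azWindow[1] & az <= azWindow[2]]
  if (!is.null(elWindow)) el <- el[el >= elWindow[1] & el <= elWindow[2]]
  g <- expand.grid(az = az, el = el, KEEP.OUT.ATTRS = FALSE)
  a <- .deg2rad(g$az); e <- .deg2rad(g$el)
  list(az = g$az, el = g$el,
       dirs = cbind(cos(e) * cos(a), cos(e) * sin(a), sin(e)))
}

#' Cast an angular scan grid against analytic surfaces
#'
#' Rays leave the scanner over the pose's angular grid; each surface yields
#' its nearest (front-side) intersection. With `occlusion = TRUE` only the
#' globally first hit per ray survives, so e.g. the far side of a stem, or a
#' tree fully behind another, is never sampled. Hits beyond `maxRange` are
#' dropped. Gaussian range noise perturbs the hit distance along the ray.
#'
#' @param surfaces list of primitives; each a list with `type` one of
#'   `"plane"` (`z0`, `gx`, `gy`, `center`, optional `bounds`), `"cylinder"`
#'   (`center` (x, y), `radius`, `zlim`), `"cone"` (`apex` (x, y, z),
#'   `baseZ`, `baseRadius`), `"ellipsoid"` (`center`, `semiXY`, `semiZ`) or
#'   `"sphere"` (`center`, `radius`).
#' @param pose a [scannerPose()]. Positions are in the same world frame as
#'   the surfaces.
#' @param rangeNoiseSigma Gaussian range noise SD in metres (default 0).
#' @param occlusion keep only the first intersection per ray (default TRUE).
#' @param azWindow,elWindow optional angular windows (degrees) restricting
#'   the grid, e.g. to the scene's angular footprint.
#' @return a [PointCloud-class] in the world frame with a `label` column
#'   holding the 1-based surface index of each hit.
#' @export
simulateScan <- function(surfaces, pose = scannerPose(),
                         rangeNoiseSigma = 0, occlusion = TRUE,
                         azWindow = NULL, elWindow = NULL) {
  grid <- .ray_grid(pose, azWindow, elWindow)
  D <- grid$dirs
  S <- pose$position
  nray <- nrow(D)
  tbest <- rep(Inf, nray)
  sbest <- integer(nray)
  hits <- list()
  for (si in seq_along(surfaces)) {
    t <- .isect(surfaces[[si]], S, D)
    t[t > pose$maxRange] <- Inf
    if (occlusion) {
      better <- t < tbest
      tbest[better] <- t[better]
      sbest[better] <- si
    } else {
      ok <- is.finite(t)
      hits[[si]] <- list(ray = which(ok), t = t[ok], surface = si)
    }
  }
  if (occlusion) {
    ok <- is.finite(tbest)
    hits <- list(list(ray = which(ok), t = tbest[ok], surface = sbest[ok]))
  }
  ray <- unlist(lapply(hits, `[[`, "ray"))
  t <- unlist(lapply(hits, `[[`, "t"))
  surf <- unlist(lapply(hits, function(h) {
    if (length(h$surface) == 1) rep(h$surface, length(h$ray)) else h$surface
  }))
  if (length(ray) == 0)
    return(PointCloud(data.frame(x = numeric(), y = numeric(),
                                 z = numeric(), label = integer())))
  if (rangeNoiseSigma > 0) t <- t + stats::rnorm(length(t), 0,
                                                 rangeNoiseSigma)
  p <- cbind(S[1] + t * D[ray, 1], S[2] + t * D[ray, 2],
             S[3] + t * D[ray, 3])
  PointCloud(data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                        label = as.integer(surf)))
}

# uniform samples inside a crown volume (cone or ellipsoid)
.crown_volume_points <- function(tree, n) {
  if (n <= 0) return(NULL)
  if (tree$crown == "cone") {
    za <- tree$apex_z; zb <- tree$crown_base_z
    u <- stats::runif(n)
    z <- za - (za - zb) * u^(1 / 3)          # density grows towards base
    rmax <- tree$crown_radius * (za - z) / (za - zb)
    r <- rmax * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
  } else if (tree$crown == "ellipsoid") {
    z <- numeric(n); r <- numeric(n); th <- stats::runif(n, 0, 2 * pi)
    zc <- tree$crown_center_z
    u <- stats::runif(n, -1, 1)
    v <- sqrt(stats::runif(n))
    z <- zc + tree$crown_semi_z * u
    rmax <- tree$crown_radius * sqrt(pmax(0, 1 - u^2))
    r <- rmax * v
  } else return(NULL)
  cbind(tree$x + r * cos(th), tree$y + r * sin(th), z)
}

#' Generate a labelled synthetic PLS forest scene
#'
#' Places trees by rejection sampling (minimum spacing enforced), ray-casts
#' the surface primitives over the pose's angular grid, adds crown-interior
#' foliage points at reduced density (scaled by each tree's visible shell,
#' so a fully occluded crown receives none), synthesizes class-dependent
#' attributes (distinct reflectance/deviation distributions for ground,
#' stem, foliage and outliers) and returns the cloud in the scanner frame
#' together with full ground truth. Everything is determined by
#' `config$seed`.
#'
#' @param config a [sceneConfig()].
#' @param pose a [scannerPose()].
#' @return list with:
#'   \describe{
#'     \item{cloud}{[PointCloud-class] in the scanner frame, with
#'       `intensity`, `reflectance`, `deviation`, return fields, a truth
#'       `label` column (0 = ground/outlier) and a `ptclass` column
#'       (0 ground, 1 stem, 2 foliage, 3 outlier).}
#'     \item{truth}{list: `trees` (per-tree table with species, position,
#'       height, apex, in the georeferenced frame), `dtm`
#'       ([TerrainModel-class], georeferenced frame), `gcp` (8 control-point
#'       pairs rectified-frame to georeferenced frame), `helmert` (the exact
#'       [HelmertTransform-class] between those frames), `pose`, `seed`.}
#'   }
#' @export
generateScene <- function(config = sceneConfig(), pose = scannerPose()) {
  set.seed(config$seed)
  S <- pose$position
  cx <- config$areaCenter[1]; cy <- config$areaCenter[2]
  half <- config$areaSize / 2
  gx <- if (config$terrain == "sloped") config$slope[1] else 0
  gy <- if (config$terrain == "sloped") config$slope[2] else 0
  gz <- function(x, y) gx * (x - cx) + gy * (y - cy)

  # --- tree placement -------------------------------------------------
  margin <- 2
  pos <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pos) < config$nTrees) {
    cand <- c(stats::runif(1, cx - half + margin, cx + half - margin),
              stats::runif(1, cy - half + margin, cy + half - margin))
    if (nrow(pos) == 0 ||
        min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
          config$minSpacing)
      pos <- rbind(pos, cand)
    tries <- tries + 1
    if (tries > 20000)
      stop("cannot place ", config$nTrees, " trees at ", config$minSpacing,
           " m spacing in a ", config$areaSize, " m area")
  }

  # species assignment honouring the configured proportions
  sp_names <- c("pine", "spruce", "birch", "unidentified")
  mix <- config$speciesMix[sp_names]
  mix[is.na(mix)] <- 0
  counts <- floor(mix * config$nTrees)
  rem <- config$nTrees - sum(counts)
  if (rem > 0) {
    frac <- mix * config$nTrees - counts
    extra <- order(-frac)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  species_idx <- sample(rep(seq_along(sp_names), counts))

  trees <- vector("list", config$nTrees)
  for (i in seq_len(config$nTrees)) {
    sp <- sp_names[species_idx[i]]
    hr <- config$heightRange[[sp]]
    H <- stats::runif(1, hr[1], hr[2])
    zg <- gz(pos[i, 1], pos[i, 2])
    crown <- switch(sp, pine = "cone", spruce = "cone",
                    birch = "ellipsoid", unidentified = "none")
    tr <- list(tree_id = i, species_index = species_idx[i],
               x = pos[i, 1], y = pos[i, 2], ground_z = zg,
               height = H, apex_z = zg + H,
               stem_radius = stats::runif(1, config$stemRadiusRange[1],
                                          config$stemRadiusRange[2]),
               crown = crown)
    if (crown == "cone") {
      tr$crown_base_z <- zg + 0.35 * H
      tr$crown_radius <- stats::runif(1, 1.2, 2.2)
    } else if (crown == "ellipsoid") {
      tr$crown_center_z <- zg + 0.65 * H
      tr$crown_semi_z <- 0.35 * H
      tr$crown_radius <- stats::runif(1, 1.2, 2.5)
    }
    trees[[i]] <- tr
  }

  # --- surfaces -------------------------------------------------------
  surfaces <- list(list(type = "plane", z0 = 0, gx = gx, gy = gy,
                        center = c(cx, cy),
                        bounds = c(cx - half, cx + half, cy - half,
                                   cy + half)))
  surf_label <- 0L       # truth tree label per surface
  surf_class <- 0L       # 0 ground, 1 stem, 2 foliage
  for (tr in trees) {
    # the stem runs the full tree height (the top section is the leader);
    # inside the crown it is occluded except near the apex, where it pokes
    # through the narrowing crown shell - concentrating returns at the tree
    # top just as a real leader does
    surfaces <- c(surfaces, list(list(
      type = "cylinder", center = c(tr$x, tr$y), radius = tr$stem_radius,
      zlim = c(tr$ground_z, tr$apex_z))))
    surf_label <- c(surf_label, tr$tree_id)
    surf_class <- c(surf_class, 1L)
    if (tr$crown == "cone") {
      surfaces <- c(surfaces, list(list(
        type = "cone", apex = c(tr$x, tr$y, tr$apex_z),
        baseZ = tr$crown_base_z, baseRadius = tr$crown_radius)))
      surf_label <- c(surf_label, tr$tree_id)
      surf_class <- c(surf_class, 2L)
    } else if (tr$crown == "ellipsoid") {
      surfaces <- c(surfaces, list(list(
        type = "ellipsoid", center = c(tr$x, tr$y, tr$crown_center_z),
        semiXY = tr$crown_radius, semiZ = tr$crown_semi_z)))
      surf_label <- c(surf_label, tr$tree_id)
      surf_class <- c(surf_class, 2L)
    }
  }

  # angular window of the scene (corners at ground and max apex height)
  zmax <- max(vapply(trees, `[[`, 1, "apex_z"), 0)
  gcorn <- expand.grid(x = c(cx - half, cx + half),
                       y = c(cy - half, cy + half))
  zlo <- min(gz(gcorn$x, gcorn$y)) - 1
  corn <- expand.grid(x = c(cx - half, cx + half),
                      y = c(cy - half, cy + half),
                      z = c(zlo, zmax + 1))
  rel <- sweep(as.matrix(corn), 2, S)
  azs <- .rad2deg(atan2(rel[, 2], rel[, 1]))
  els <- .rad2deg(atan2(rel[, 3], sqrt(rel[, 1]^2 + rel[, 2]^2)))
  azW <- c(min(azs) - 1, max(azs) + 1)
  elW <- c(min(els) - 1, max(els) + 1)

  scan <- simulateScan(surfaces, pose, rangeNoiseSigma =
                         config$rangeNoiseSigma,
                       occlusion = config$occlusion,
                       azWindow = azW, elWindow = elW)
  d <- pointData(scan)
  surf_of <- d$label
  d$label <- surf_label[surf_of]
  d$ptclass <- as.numeric(surf_class[surf_of])

  # --- crown interior foliage points ----------------------------------
  shell_counts <- vapply(seq_along(trees), function(i)
    sum(d$label == i & d$ptclass == 2), numeric(1))
  vol <- list()
  for (i in seq_along(trees)) {
    n_int <- round(0.3 * shell_counts[i])
    p <- .crown_volume_points(trees[[i]], n_int)
    if (!is.null(p))
      vol[[length(vol) + 1L]] <- data.frame(
        x = p[, 1], y = p[, 2], z = p[, 3], label = i, ptclass = 2)
  }
  if (length(vol)) d <- rbind(d, do.call(rbind, vol))

  # --- outliers -------------------------------------------------------
  n_out <- round(config$outlierFraction * nrow(d))
  if (n_out > 0) {
    a <- .deg2rad(stats::runif(n_out, azW[1], azW[2]))
    e <- .deg2rad(stats::runif(n_out, elW[1], elW[2]))
    r <- stats::runif(n_out, 5, pose$maxRange * 0.9)
    d <- rbind(d, data.frame(
      x = S[1] + r * cos(e) * cos(a), y = S[2] + r * cos(e) * sin(a),
      z = S[3] + r * sin(e), label = 0, ptclass = 3))
  }

  # --- attributes by class --------------------------------------------
  n <- nrow(d)
  refl_mu <- c(`0` = -8, `1` = -5, `2` = -14, `3` = -25)
  dev_mu <- c(`0` = 15, `1` = 10, `2` = 40, `3` = 150)
  dev_sd <- c(`0` = 5, `1` = 4, `2` = 15, `3` = 20)
  key <- as.character(d$ptclass)
  d$reflectance <- stats::rnorm(n, refl_mu[key], 1.5)
  d$deviation <- pmax(0, stats::rnorm(n, dev_mu[key], dev_sd[key]))
  d$intensity <- round(pmax(0, 1200 + 60 * d$reflectance +
                              stats::rnorm(n, 0, 40)))
  d$return_number <- 1L
  d$number_of_returns <- 1L

  # --- to scanner frame ----------------------------------------------
  R <- rotationMatrix(0, pose$tiltDeg, 90)
  xyz <- sweep(as.matrix(d[, c("x", "y", "z")]), 2, S) %*% R
  world <- d[, c("x", "y", "z")]
  d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
  d$label <- as.integer(d$label)
  rownames(d) <- NULL
  cloud <- PointCloud(d)

  # --- truth in the georeferenced frame -------------------------------
  off <- config$georefOffset
  empty_truth <- data.frame(tree_id = integer(), species_index = integer(),
                            x = numeric(), y = numeric(),
                            ground_z = numeric(), height_m = numeric(),
                            apex_x = numeric(), apex_y = numeric(),
                            apex_z = numeric(), stem_radius = numeric())
  tru_trees <- do.call(rbind, lapply(trees, function(tr) data.frame(
    tree_id = tr$tree_id, species_index = tr$species_index,
    x = tr$x + off[1], y = tr$y + off[2], ground_z = tr$ground_z + off[3],
    height_m = tr$height, apex_x = tr$x + off[1], apex_y = tr$y + off[2],
    apex_z = tr$apex_z + off[3], stem_radius = tr$stem_radius)))
  if (is.null(tru_trees)) tru_trees <- empty_truth

  res_dtm <- 0.2
  gxs <- seq(cx - half, cx + half, by = res_dtm)
  gys <- seq(cy - half, cy + half, by = res_dtm)
  gg <- expand.grid(x = gxs, y = gys, KEEP.OUT.ATTRS = FALSE)
  dtm <- TerrainModel(cbind(gg$x + off[1], gg$y + off[2],
                            gz(gg$x, gg$y) + off[3]), resolution = res_dtm)

  # exact rectified-frame -> georeferenced-frame transform: translation by
  # scanner position plus the geodetic offset
  helm <- HelmertTransform(translation = S + off)
  gcp_local <- rbind(
    c(cx - half, cy - half, gz(cx - half, cy - half)),
    c(cx + half, cy - half, gz(cx + half, cy - half)),
    c(cx - half, cy + half, gz(cx - half, cy + half)),
    c(cx + half, cy + half, gz(cx + half, cy + half)),
    c(cx, cy, gz(cx, cy)),
    c(cx, cy - half, gz(cx, cy - half) + 5),
    c(cx - half, cy, gz(cx - half, cy) + 10),
    c(cx, cy + half, gz(cx, cy + half) + 15))
  gcp <- data.frame(sx = gcp_local[, 1] - S[1], sy = gcp_local[, 2] - S[2],
                    sz = gcp_local[, 3] - S[3],
                    tx = gcp_local[, 1] + off[1],
                    ty = gcp_local[, 2] + off[2],
                    tz = gcp_local[, 3] + off[3])

  list(cloud = cloud,
       truth = list(trees = tru_trees, dtm = dtm, gcp = gcp,
                    helmert = helm, pose = pose, seed = config$seed,
                    georef_offset = off, world = world))
}

#' Which planted trees are detectable in a synthetic scene?
#'
#' Under first-hit occlusion a tree can be partly or wholly hidden behind
#' nearer crowns. A tree is considered visible - i.e. detectable by the stem
#' detector - when the scene contains at least `minClusterPoints` of its
#' stem-class returns within `maxBaseHeight` of its local ground (rooted
#' stem returns; isolated leader returns at the tree top do not qualify).
#' Detection recall is measured over these trees, mirroring how per-tree
#' datasets exclude trees absent from the data.
#'
#' @param scene result of [generateScene()].
#' @param config a [stemDetectionConfig()] supplying the two thresholds.
#' @return logical vector along `scene$truth$trees`.
#' @export
visibleTrees <- function(scene, config = stemDetectionConfig()) {
  d <- pointData(scene$cloud)
  w <- scene$truth$world
  tt <- scene$truth$trees
  off <- scene$truth$georef_offset
  vapply(seq_len(nrow(tt)), function(i) {
    gz <- tt$ground_z[i] - off[3]
    sum(d$label == tt$tree_id[i] & d$ptclass == 1 &
          (w$z - gz) <= config$maxBaseHeight) >= config$minClusterPoints
  }, logical(1))
}
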