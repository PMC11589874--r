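# Attribute-threshold noise filtering and voxel-based thinning.

#' Resampling configuration
#'
#' @param voxelSize cubic voxel edge in metres (default 0.05; at most 5 cm is
#'   recommended for results comparable to full resolution).
#' @param reflectanceMin keep points with reflectance >= this (dB), inclusive;
#'   `NULL` disables the constraint. No numeric default is shipped: the
#'   thresholds are instrument- and site-specific.
#' @param deviationMax keep points with deviation <= this, inclusive; `NULL`
#'   disables.
#' @param gridOrigin length-3 voxel grid origin; `NULL` (default) uses the
#'   floor of the cloud's coordinate minima.
#' @return a list of class `ResampleConfig`.
#' @export
resampleConfig <- function(voxelSize = 0.05, reflectanceMin = NULL,
                           deviationMax = NULL, gridOrigin = NULL) {
  stopifnot(is.numeric(voxelSize), length(voxelSize) == 1, voxelSize > 0)
  if (voxelSize > 0.05)
    warning("voxel size ", voxelSize,
            " m exceeds the recommended 0.05 m maximum")
  structure(list(voxelSize = voxelSize, reflectanceMin = reflectanceMin,
                 deviationMax = deviationMax, gridOrigin = gridOrigin),
            class = "ResampleConfig")
}

#' Filter instrument and atmospheric noise by attribute thresholds
#'
#' Keeps points with `reflectance >= reflectanceMin` and
#' `deviation <= deviationMax` (both boundaries inclusive; an unset threshold
#' imposes no constraint). Point order is preserved. Setting a threshold whose
#' attribute column is absent is an error rather than a silent no-op.
#'
#' @param cloud a [PointCloud-class].
#' @param config a [resampleConfig()].
#' @return the filtered [PointCloud-class].
#' @export
filterNoise <- function(cloud, config = resampleConfig()) {
  d <- pointData(cloud)
  keep <- rep(TRUE, nrow(d))
  if (!is.null(config$reflectanceMin)) {
    if (!"reflectance" %in% names(d))
      stop("reflectance threshold set but cloud has no reflectance attribute")
    keep <- keep & d$reflectance >= config$reflectanceMin
  }
  if (!is.null(config$deviationMax)) {
    if (!"deviation" %in% names(d))
      stop("deviation threshold set but cloud has no deviation attribute")
    keep <- keep & d$deviation <= config$deviationMax
  }
  cloud[keep]
}

#' Voxel-based point cloud thinning
#'
#' Applies [filterNoise()] first, then partitions space into cubic voxels of
#' edge `voxelSize` (half-open cells, index `floor((coord - origin) / size)`)
#' and keeps, per non-empty voxel, the input point closest to the centroid of
#' the points in that voxel (ties broken by lowest input index). The retained
#' point keeps its own coordinates and return fields but carries the per-voxel
#' arithmetic means of `intensity`, `reflectance` and `deviation`. No
#' synthetic positions are ever created, so resampling an already-resampled
#' cloud at the same size and origin is the identity.
#'
#' @param cloud a [PointCloud-class].
#' @param config a [resampleConfig()].
#' @return the thinned [PointCloud-class], one point per non-empty voxel,
#'   ordered by retained input index.
#' @examples
#' pc <- PointCloud(data.frame(
#'   x = c(0.010, 0.020, 0.040), y = 0.010, z = 0.010,
#'   intensity = c(10, 20, 30)))
#' voxelResample(pc, resampleConfig(0.05, gridOrigin = c(0, 0, 0)))
#' @export
voxelResample <- function(cloud, config = resampleConfig()) {
  cloud <- filterNoise(cloud, config)
  d <- pointData(cloud)
  n <- nrow(d)
  if (n == 0) return(cloud)
  s <- config$voxelSize
  org <- config$gridOrigin
  if (is.null(org)) org <- floor(c(min(d$x), min(d$y), min(d$z)))

  averaged <- intersect(c("intensity", "reflectance", "deviation"), names(d))
  dt <- data.table::as.data.table(d[, c("x", "y", "z", averaged)])
  dt[, `.vx` := floor((x - org[1]) / s)]
  dt[, `.vy` := floor((y - org[2]) / s)]
  dt[, `.vz` := floor((z - org[3]) / s)]
  dt[, `.g` := .GRP, by = c(".vx", ".vy", ".vz")]

  # per-voxel means of coordinates (the centroid) and averaged attributes
  mg <- dt[, lapply(.SD, mean), by = ".g",
           .SDcols = c("x", "y", "z", averaged)]
  row_of <- match(dt$`.g`, mg$`.g`)
  dd <- (dt$x - mg$x[row_of])^2 + (dt$y - mg$y[row_of])^2 +
    (dt$z - mg$z[row_of])^2
  # first point per voxel in (distance, input index) order: the point
  # nearest the centroid, ties to the lowest input index
  ord <- order(dt$`.g`, dd, seq_len(n))
  sel <- ord[!duplicated(dt$`.g`[ord])]
  sel <- sort(sel)

  res <- d[sel, , drop = FALSE]
  row_of_sel <- match(dt$`.g`[sel], mg$`.g`)
  for (a in averaged) res[[a]] <- mg[[a]][row_of_sel]
  rownames(res) <- NULL
  pointData(cloud) <- res
  cloud
}
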