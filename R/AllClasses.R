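#' @import methods
NULL

# Optional per-point attribute columns with defined semantics. Extra numeric
# columns are allowed and carried through every stage untouched.
.known_attrs <- c("intensity", "reflectance", "deviation", "return_number",
                  "number_of_returns", "theta", "phi_az", "range", "label")

#' PointCloud: coordinates plus per-point attributes
#'
#' The currency of every pipeline stage. Holds x/y/z coordinates in metres and
#' any subset of the per-point attributes produced by the scanner or the
#' pipeline: `intensity` (unitless amplitude), `reflectance` (dB, range
#' corrected), `deviation` (unitless pulse-shape distortion), `return_number`
#' and `number_of_returns` (1--15), `theta` and `phi_az` (scan angles,
#' degrees), `range` (metres) and `label` (integer tree id, ground truth or
#' segmentation output). Absent attributes are genuinely absent -- they are
#' never zero-filled.
#'
#' @slot data data.frame with columns `x`, `y`, `z` and optional attribute
#'   columns, one row per point.
#' @slot crs character; coordinate reference system tag, e.g. `"EPSG:3067"`
#'   once georeferenced, `""` for local/scanner frames.
#'
#' @export
setClass("PointCloud",
  representation(data = "data.frame", crs = "character"),
  prototype(data = data.frame(x = numeric(), y = numeric(), z = numeric()),
            crs = ""))

setValidity("PointCloud", function(object) {
  d <- object@data
  msg <- character()
  if (!all(c("x", "y", "z") %in% names(d)))
    return("data must contain columns x, y, z")
  for (nm in names(d))
    if (!is.numeric(d[[nm]]))
      msg <- c(msg, sprintf("column '%s' must be numeric", nm))
  if (length(msg)) return(msg)
  if (nrow(d)) {
    for (nm in c("x", "y", "z"))
      if (!all(is.finite(d[[nm]])))
        msg <- c(msg, sprintf("non-finite values in '%s'", nm))
    if (all(c("return_number", "number_of_returns") %in% names(d))) {
      rn <- d$return_number; nr <- d$number_of_returns
      ok <- is.na(rn) | is.na(nr) | (rn >= 1 & rn <= nr & nr <= 15)
      if (!all(ok))
        msg <- c(msg, "need 1 <= return_number <= number_of_returns <= 15")
    }
    if ("range" %in% names(d) && any(d$range < 0, na.rm = TRUE))
      msg <- c(msg, "range must be >= 0")
  }
  if (length(object@crs) != 1L)
    msg <- c(msg, "crs must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a PointCloud
#'
#' @param data data.frame with columns `x`, `y`, `z` and optional attribute
#'   columns (see [PointCloud-class]).
#' @param crs coordinate reference system tag (default `""`, a local frame).
#' @return A [PointCloud-class] object.
#' @examples
#' pc <- PointCloud(data.frame(x = 1:3, y = 0, z = c(5, 6, 7)))
#' npoints(pc)
#' @export
PointCloud <- function(data, crs = "") {
  data <- as.data.frame(data)
  for (nm in c("return_number", "number_of_returns", "label"))
    if (nm %in% names(data)) data[[nm]] <- as.integer(data[[nm]])
  new("PointCloud", data = data, crs = crs)
}

#' TerrainModel: ground elevation support points
#'
#' A digital terrain model represented by its planimetric support points
#' (gridded or scattered) with ground elevations, plus the nominal resolution.
#'
#' @slot points numeric matrix, columns x, y, ground_z (metres).
#' @slot resolution nominal planimetric resolution in metres (0.20 default,
#'   matching a 20 cm DTM product).
#' @export
setClass("TerrainModel",
  representation(points = "matrix", resolution = "numeric"),
  prototype(points = matrix(numeric(), ncol = 3), resolution = 0.2))

setValidity("TerrainModel", function(object) {
  p <- object@points
  msg <- character()
  if (ncol(p) != 3) return("points must have 3 columns (x, y, ground_z)")
  if (nrow(p) == 0) msg <- c(msg, "terrain model has no support points")
  if (nrow(p) && !all(is.finite(p))) msg <- c(msg, "non-finite support point")
  if (nrow(p) && anyDuplicated(p[, 1:2, drop = FALSE]))
    msg <- c(msg, "duplicate planimetric support points")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "resolution must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a TerrainModel
#' @param points matrix or data.frame with columns x, y, ground_z (metres).
#' @param resolution nominal resolution in metres (default 0.2).
#' @return A [TerrainModel-class] object.
#' @export
TerrainModel <- function(points, resolution = 0.2) {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("x", "y", "ground_z"))
  new("TerrainModel", points = points, resolution = resolution)
}

#' HelmertTransform: 7-parameter similarity transform
#'
#' Three translations, a 3x3 orthonormal rotation and a scale factor mapping a
#' local frame into a reference frame, `p' = t + mu * R p`, plus the residual
#' statistics of the least-squares fit that produced it.
#'
#' @slot translation numeric length-3, metres.
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot scale positive scale factor mu.
#' @slot fitRMSE overall 3-D RMSE of the fit residuals, metres (NA when the
#'   transform was constructed rather than fitted).
#' @slot perAxisRMSE numeric length-3, per-axis RMSE, metres.
#' @export
setClass("HelmertTransform",
  representation(translation = "numeric", rotation = "matrix",
                 scale = "numeric", fitRMSE = "numeric",
                 perAxisRMSE = "numeric"),
  prototype(translation = c(0, 0, 0), rotation = diag(3), scale = 1,
            fitRMSE = NA_real_, perAxisRMSE = rep(NA_real_, 3)))

setValidity("HelmertTransform", function(object) {
  msg <- character()
  if (length(object@translation) != 3) msg <- c(msg, "translation not length 3")
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    msg <- c(msg, "rotation matrix not orthonormal")
  if (det(R) < 0) msg <- c(msg, "rotation must be proper (det +1)")
  if (length(object@scale) != 1 || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "scale must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a HelmertTransform
#' @param translation numeric length-3 translation (metres).
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param scale positive scale factor (default 1).
#' @param fitRMSE,perAxisRMSE residual statistics; NA for constructed
#'   transforms.
#' @return A [HelmertTransform-class] object.
#' @export
HelmertTransform <- function(translation = c(0, 0, 0), rotation = diag(3),
                             scale = 1, fitRMSE = NA_real_,
                             perAxisRMSE = rep(NA_real_, 3)) {
  new("HelmertTransform", translation = as.numeric(translation),
      rotation = rotation, scale = scale, fitRMSE = fitRMSE,
      perAxisRMSE = as.numeric(perAxisRMSE))
}

#' CylinderModel: fitted stem cylinder
#'
#' @slot axisPoint numeric length-3, a point on the axis (metres).
#' @slot axisDirection unit length-3 direction vector.
#' @slot radius cylinder radius, metres.
#' @slot zExtent numeric length-2, (low, high) z of the supporting points.
#' @slot inlierRMSE RMSE of radial residuals, metres.
#' @export
setClass("CylinderModel",
  representation(axisPoint = "numeric", axisDirection = "numeric",
                 radius = "numeric", zExtent = "numeric",
                 inlierRMSE = "numeric"))

setValidity("CylinderModel", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@axisDirection^2)) - 1) > 1e-6)
    msg <- c(msg, "axisDirection must be a unit vector")
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (length(object@zExtent) != 2 || object@zExtent[1] >= object@zExtent[2])
    msg <- c(msg, "zExtent must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

#' StemMap: detected stems with ground positions and cylinder models
#'
#' @slot stems data.frame with columns `stem_id`, `x`, `y`, `ground_z`
#'   (ground-level stem position, metres) and `n_points`.
#' @slot cylinders list of [CylinderModel-class], parallel to `stems` rows.
#' @export
setClass("StemMap",
  representation(stems = "data.frame", cylinders = "list"),
  prototype(stems = data.frame(stem_id = integer(), x = numeric(),
                               y = numeric(), ground_z = numeric(),
                               n_points = integer()),
            cylinders = list()))

setValidity("StemMap", function(object) {
  msg <- character()
  need <- c("stem_id", "x", "y", "ground_z", "n_points")
  if (!all(need %in% names(object@stems)))
    return(paste("stems must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@stems$stem_id)) msg <- c(msg, "duplicate stem ids")
  if (length(object@cylinders) != nrow(object@stems))
    msg <- c(msg, "one cylinder model per stem required")
  if (length(msg)) msg else TRUE
})

#' Construct a StemMap
#' @param stems data.frame with columns `stem_id`, `x`, `y`, `ground_z`,
#'   `n_points`.
#' @param cylinders list of [CylinderModel-class] objects, one per stem.
#' @return A [StemMap-class] object.
#' @export
StemMap <- function(stems, cylinders = vector("list", nrow(stems))) {
  stems <- as.data.frame(stems)
  stems$stem_id <- as.integer(stems$stem_id)
  new("StemMap", stems = stems, cylinders = cylinders)
}
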