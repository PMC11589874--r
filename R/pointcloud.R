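#' @describeIn PointCloud-class number of points.
#' @param x a PointCloud.
#' @export
setMethod("npoints", "PointCloud", function(x) nrow(x@data))

#' @describeIn PointCloud-class coordinate matrix (columns x, y, z).
#' @export
setMethod("coords", "PointCloud", function(x) {
  m <- as.matrix(x@data[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})

#' @describeIn PointCloud-class per-point data.frame.
#' @export
setMethod("pointData", "PointCloud", function(x) x@data)

#' @describeIn PointCloud-class replace per-point data (revalidates).
#' @param value replacement data.frame.
#' @export
setMethod("pointData<-", "PointCloud", function(x, value) {
  x@data <- as.data.frame(value)
  validObject(x)
  x
})

#' @describeIn PointCloud-class CRS tag.
#' @export
setMethod("crs", "PointCloud", function(x) x@crs)

#' @describeIn PointCloud-class set CRS tag.
#' @export
setMethod("crs<-", "PointCloud", function(x, value) {
  x@crs <- value
  validObject(x)
  x
})

#' @describeIn PointCloud-class test for an attribute column.
#' @param name column name.
#' @export
setMethod("hasAttribute", "PointCloud", function(x, name)
  name %in% names(x@data))

#' Subset a point cloud by point index
#' @param x a [PointCloud-class].
#' @param i integer or logical index of points to keep.
#' @param j,drop,... ignored.
#' @return a [PointCloud-class] with the selected points.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  x@data <- x@data[i, , drop = FALSE]
  rownames(x@data) <- NULL
  x
})

setMethod("show", "PointCloud", function(object) {
  extras <- setdiff(names(object@data), c("x", "y", "z"))
  cat(sprintf("PointCloud with %d points\n", nrow(object@data)))
  cat(sprintf("  attributes: %s\n",
              if (length(extras)) paste(extras, collapse = ", ") else "none"))
  cat(sprintf("  crs: %s\n",
              if (nzchar(object@crs)) object@crs else "<local>"))
  if (nrow(object@data)) {
    r <- apply(coords(object), 2, range)
    cat(sprintf("  extent: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
})

setMethod("show", "TerrainModel", function(object) {
  cat(sprintf("TerrainModel with %d support points, %.2f m resolution\n",
              nrow(object@points), object@resolution))
})

setMethod("show", "HelmertTransform", function(object) {
  cat("HelmertTransform\n")
  cat(sprintf("  translation: (%.4f, %.4f, %.4f) m\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
  ang <- helmertAngles(object)
  cat(sprintf("  rotation (pitch/roll/yaw): (%.6f, %.6f, %.6f) deg\n",
              ang["phi"], ang["omega"], ang["kappa"]))
  cat(sprintf("  scale: %.9f\n", object@scale))
  if (is.finite(object@fitRMSE))
    cat(sprintf("  fit RMSE: %.6f m (per axis %.6f / %.6f / %.6f)\n",
                object@fitRMSE, object@perAxisRMSE[1], object@perAxisRMSE[2],
                object@perAxisRMSE[3]))
})

setMethod("show", "StemMap", function(object) {
  cat(sprintf("StemMap with %d stems\n", nrow(object@stems)))
  if (nrow(object@stems)) print(utils::head(object@stems, 10))
})

setMethod("show", "CylinderModel", function(object) {
  cat(sprintf(
    "CylinderModel r=%.3f m, axis (%.3f, %.3f, %.3f), z [%.2f, %.2f], rmse %.4f m\n",
    object@radius, object@axisDirection[1], object@axisDirection[2],
    object@axisDirection[3], object@zExtent[1], object@zExtent[2],
    object@inlierRMSE))
})

#' @describeIn StemMap-class stem table.
#' @param x a StemMap.
#' @export
setMethod("stems", "StemMap", function(x) x@stems)

#' @describeIn StemMap-class cylinder model list.
#' @export
setMethod("cylinders", "StemMap", function(x) x@cylinders)

#' @describeIn StemMap-class number of stems.
#' @export
setMethod("length", "StemMap", function(x) nrow(x@stems))
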