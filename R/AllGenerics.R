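#' Number of points in a cloud
#' @param x a [PointCloud-class].
#' @return integer point count.
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' Coordinate matrix of a point cloud
#' @param x a [PointCloud-class].
#' @return numeric matrix with columns x, y, z.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-point data of a cloud
#' @param x a [PointCloud-class].
#' @return data.frame, one row per point.
#' @export
setGeneric("pointData", function(x) standardGeneric("pointData"))

#' Replace the per-point data of a cloud
#' @param x a [PointCloud-class].
#' @param value replacement data.frame.
#' @return the modified object.
#' @export
setGeneric("pointData<-", function(x, value) standardGeneric("pointData<-"))

#' Coordinate reference system tag
#' @param x an object carrying a CRS tag.
#' @return character scalar (e.g. `"EPSG:3067"`, or `""` for local frames).
#' @export
setGeneric("crs", function(x) standardGeneric("crs"))

#' @rdname crs
#' @param value replacement CRS tag.
#' @export
setGeneric("crs<-", function(x, value) standardGeneric("crs<-"))

#' Test for a per-point attribute column
#' @param x a [PointCloud-class].
#' @param name attribute column name.
#' @return logical scalar.
#' @export
setGeneric("hasAttribute", function(x, name) standardGeneric("hasAttribute"))

#' Stem table of a stem map
#' @param x a [StemMap-class].
#' @return data.frame of detected stems.
#' @export
setGeneric("stems", function(x) standardGeneric("stems"))

#' Cylinder models of a stem map
#' @param x a [StemMap-class].
#' @return list of [CylinderModel-class] objects.
#' @export
setGeneric("cylinders", function(x) standardGeneric("cylinders"))
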