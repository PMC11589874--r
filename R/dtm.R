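# Terrain-model and control-point input, plus DTM height normalization.

#' Read a digital terrain model
#'
#' Accepts a LAS point file (each point a ground support) or a delimited text
#' file with columns x, y, z (header optional). The nominal resolution is
#' taken from `resolution` when given, otherwise estimated as the median
#' planimetric nearest-neighbour spacing of the support points.
#'
#' @param path DTM file (.las/.laz point file, or .csv/.txt/.xyz table).
#' @param resolution optional nominal resolution in metres.
#' @return a [TerrainModel-class].
#' @export
readDTM <- function(path, resolution = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("las", "laz")) {
    pc <- readPointCloud(path)
    pts <- coords(pc)
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (!is.numeric(tab[[1]])) {  # header line present
      tab <- utils::read.table(path, header = TRUE, sep = "",
                               comment.char = "#")
    }
    if (ncol(tab) < 3) stop("DTM table needs columns x, y, z")
    pts <- as.matrix(tab[, 1:3])
  }
  if (nrow(pts) == 0) stop("empty DTM: ", path)
  if (is.null(resolution)) {
    if (nrow(pts) >= 2) {
      nn <- cpp_knn(pts[, 1:2, drop = FALSE], pts[, 1:2, drop = FALSE], 2L)
      resolution <- stats::median(nn$distance[, 2])
    } else resolution <- 0.2
  }
  TerrainModel(pts, resolution = resolution)
}

#' Read ground-control-point pairs
#'
#' CSV with header `sx,sy,sz,tx,ty,tz`: source coordinates in the local
#' (rectified) frame, targets in the reference frame (e.g. ETRS89/TM35FIN).
#' Fitting a seven-parameter transform needs at least three pairs, so fewer
#' is rejected at read time.
#'
#' @param path CSV file path.
#' @return data.frame with columns sx, sy, sz, tx, ty, tz, one row per pair.
#' @export
readControlPoints <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("sx", "sy", "sz", "tx", "ty", "tz")
  if (!all(need %in% names(tab)))
    stop("control point file must have header ", paste(need, collapse = ","))
  tab <- tab[, need]
  if (!all(vapply(tab, function(col) all(is.finite(col)), logical(1))))
    stop("non-finite control point coordinate")
  if (nrow(tab) < 3)
    stop("need >= 3 control point pairs, got ", nrow(tab))
  tab
}

#' Ground elevation under given planimetric locations
#'
#' Nearest-support-point lookup: each query takes the `ground_z` of the
#' closest DTM support in the horizontal plane.
#'
#' @param dtm a [TerrainModel-class].
#' @param xy numeric matrix (or length-2 vector) of planimetric locations.
#' @param maxDist optional gate: queries farther than this from any support
#'   are an error (used by [normalizeHeights()]).
#' @return numeric vector of ground elevations.
#' @export
groundElevation <- function(dtm, xy, maxDist = Inf) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  nn <- cpp_knn(dtm@points[, 1:2, drop = FALSE], xy, 1L)
  if (is.finite(maxDist)) {
    bad <- sum(nn$distance[, 1] > maxDist)
    if (bad > 0)
      stop(bad, " point(s) farther than ", maxDist,
           " m from any DTM support point")
  }
  unname(dtm@points[nn$index[, 1], 3])
}

#' Normalize point heights against a terrain model
#'
#' Subtracts, from each point's z, the ground elevation at its planimetric
#' location (nearest DTM support point). x and y are unchanged, so the
#' operation is exactly invertible with the same DTM via
#' [denormalizeHeights()]. Points farther than five DTM resolutions from any
#' support point indicate non-overlapping footprints and raise an error
#' listing their count.
#'
#' @param cloud a [PointCloud-class].
#' @param dtm a [TerrainModel-class] in the same frame.
#' @return the cloud with ground-normalized z.
#' @export
normalizeHeights <- function(cloud, dtm) {
  d <- pointData(cloud)
  if (nrow(d) == 0) return(cloud)
  gz <- groundElevation(dtm, cbind(d$x, d$y), maxDist = 5 * dtm@resolution)
  d$z <- d$z - gz
  pointData(cloud) <- d
  cloud
}

#' @rdname normalizeHeights
#' @export
denormalizeHeights <- function(cloud, dtm) {
  d <- pointData(cloud)
  if (nrow(d) == 0) return(cloud)
  gz <- groundElevation(dtm, cbind(d$x, d$y), maxDist = 5 * dtm@resolution)
  d$z <- d$z + gz
  pointData(cloud) <- d
  cloud
}
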