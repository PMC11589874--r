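# Per-tree attributes, quality flagging, scan selection, file naming and the
# JSON catalogue.

.species_names <- c(`1` = "Scots pine", `2` = "Norway spruce",
                    `3` = "silver birch", `4` = "unidentified")

#' Completeness quality level from commission/omission flags
#'
#' Encodes the five-level completeness scheme: failed segmentation is level
#' 0; otherwise no commission and no omission is level 4, commission only
#' level 3, omission only level 2, and both level 1. Commission means foreign
#' points were included in the tree segment; omission means part of the tree
#' structure is missing (occluded or unresolved).
#'
#' @param commission logical; extra points not belonging to the tree.
#' @param omission logical; part of the tree structure missing.
#' @param segFailed logical; fine segmentation failed outright.
#' @return integer quality level in 0..4.
#' @examples
#' assignQuality(FALSE, FALSE)       # 4
#' assignQuality(TRUE, TRUE)         # 1
#' assignQuality(TRUE, FALSE, TRUE)  # 0
#' @export
assignQuality <- function(commission, omission, segFailed = FALSE) {
  stopifnot(is.logical(commission), is.logical(omission),
            is.logical(segFailed))
  if (segFailed) return(0L)
  if (!commission && !omission) return(4L)
  if (commission && !omission) return(3L)
  if (!commission && omission) return(2L)
  1L
}

#' Tree height from the 99.95th height percentile
#'
#' Height is the difference between the 99.95th percentile of the point z
#' coordinates (linear interpolation between order statistics) and the
#' ground elevation at the nearest DTM support point to the tree location.
#' The estimate is clamped at zero (with a warning) should the cloud sit
#' below the local ground.
#'
#' @param cloud the tree's [PointCloud-class] (georeferenced, unnormalized).
#' @param dtm a [TerrainModel-class].
#' @param location length-2 (E, N) tree location, typically the stem ground
#'   position.
#' @return height in metres.
#' @export
estimateTreeHeight <- function(cloud, dtm, location) {
  if (npoints(cloud) == 0) stop("empty tree point cloud")
  top <- unname(stats::quantile(pointData(cloud)$z, 0.9995, type = 7))
  ground <- groundElevation(dtm, location[1:2])
  h <- top - ground
  if (h < 0) {
    warning("negative height estimate clamped to 0")
    h <- 0
  }
  h
}

#' Scanner-to-tree distances
#'
#' 3-D distances from the scanner position to the crown top (the highest
#' retained point of the tree cloud) and to the stem base
#' `(E, N, ground_z)`.
#'
#' @param cloud the tree's [PointCloud-class].
#' @param scannerPosition length-3 scanner location, same frame.
#' @param location length-2 (E, N) tree location.
#' @param dtm a [TerrainModel-class].
#' @return named numeric vector `c(crown_top_m, stem_base_m)`.
#' @export
scannerDistances <- function(cloud, scannerPosition, location, dtm) {
  if (npoints(cloud) == 0) stop("empty tree point cloud")
  xyz <- coords(cloud)
  top <- xyz[which.max(xyz[, 3]), ]
  base <- c(location[1], location[2], groundElevation(dtm, location[1:2]))
  c(crown_top_m = sqrt(sum((top - scannerPosition)^2)),
    stem_base_m = sqrt(sum((base - scannerPosition)^2)))
}

#' Planimetric point density of a tree cloud
#'
#' Point count divided by the area of the planimetric convex hull of the
#' tree's points. With fewer than 3 planimetrically non-collinear points the
#' footprint is degenerate and the density is reported as missing (`NA`).
#'
#' @param cloud the tree's [PointCloud-class].
#' @return points per square metre, or `NA` for a degenerate footprint.
#' @export
pointDensity <- function(cloud) {
  d <- pointData(cloud)
  if (nrow(d) < 3) return(NA_real_)
  hull <- grDevices::chull(d$x, d$y)
  if (length(hull) < 3) return(NA_real_)
  hx <- d$x[hull]; hy <- d$y[hull]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area <= 0) return(NA_real_)
  nrow(d) / area
}

#' Scan selection criteria
#'
#' Favourable-weather gates for accepting a scan: wind speed strictly below
#' `windMax`, relative humidity strictly below `rhMax`, and no precipitation
#' or snow at all.
#'
#' @param windMax m/s, exclusive bound (default 3).
#' @param rhMax percent, exclusive bound (default 90).
#' @return a list of class `ScanSelectionCriteria`.
#' @export
scanSelectionCriteria <- function(windMax = 3, rhMax = 90) {
  structure(list(windMax = windMax, precipitationAllowed = FALSE,
                 snowAllowed = FALSE, rhMax = rhMax),
            class = "ScanSelectionCriteria")
}

#' Select scans by weather conditions
#'
#' @param weather data.frame with columns `timestamp`, `wind` (m/s),
#'   `precipitation` (amount or 0/1 flag), `snow` (flag), `rh` (percent).
#' @param criteria a [scanSelectionCriteria()].
#' @return the accepted timestamps, in input order.
#' @examples
#' w <- data.frame(timestamp = c("a", "b", "c"),
#'                 wind = c(2, 3, 2), precipitation = 0, snow = 0,
#'                 rh = c(85, 85, 90))
#' selectScans(w)  # only "a": wind and RH bounds are strict
#' @export
selectScans <- function(weather, criteria = scanSelectionCriteria()) {
  need <- c("timestamp", "wind", "precipitation", "snow", "rh")
  miss <- setdiff(need, names(weather))
  if (length(miss))
    stop("weather table lacks column(s): ", paste(miss, collapse = ", "))
  ok <- weather$wind < criteria$windMax &
    weather$precipitation == 0 &
    weather$snow == 0 &
    weather$rh < criteria$rhMax
  weather$timestamp[ok]
}

#' Single-tree file name (YYMMDD_HHMMSS_treeID_Quality.laz)
#'
#' @param timestamp a POSIXct/POSIXlt scan time (treated as local clock time;
#'   no timezone conversion is applied).
#' @param treeId integer tree id (unpadded).
#' @param quality integer quality level 0..4.
#' @return the file name string.
#' @examples
#' makeTreeFilename(as.POSIXct("2020-04-06 01:23:45", tz = "UTC"), 17, 4)
#' @export
makeTreeFilename <- function(timestamp, treeId, quality) {
  stopifnot(quality %in% 0:4)
  sprintf("%s_%d_%d.laz", format(timestamp, "%y%m%d_%H%M%S"),
          as.integer(treeId), as.integer(quality))
}

#' @rdname makeTreeFilename
#' @param name a file name produced by `makeTreeFilename()`.
#' @return `parseTreeFilename()`: list with `timestamp` (POSIXct, UTC),
#'   `tree_id` and `quality`.
#' @export
parseTreeFilename <- function(name) {
  m <- regmatches(name,
                  regexec("^(\\d{6})_(\\d{6})_(\\d+)_(\\d)\\.laz$",
                          basename(name)))[[1]]
  if (length(m) != 5) stop("not a tree file name: ", name)
  list(timestamp = as.POSIXct(paste(m[2], m[3]), format = "%y%m%d %H%M%S",
                              tz = "UTC"),
       tree_id = as.integer(m[4]),
       quality = as.integer(m[5]))
}

#' Build the JSON tree catalogue
#'
#' One GeoJSON-style point feature per tree with the per-tree metadata in
#' `properties`. Key order is fixed, so serialization is deterministic:
#' identical records give byte-identical JSON.
#'
#' @param records data.frame with columns `tree_id`, `species_index`, `e`,
#'   `n`, `h`, `height_m`, `quality`, `dist_crown_top_m`, `dist_stem_base_m`,
#'   `point_density_per_m2`, and optionally `files` (list column of file
#'   names).
#' @param crs CRS tag recorded on the collection (default `"EPSG:3067"`).
#' @return a list ready for [writeCatalog()]; class `TreeCatalog`.
#' @export
buildCatalog <- function(records, crs = "EPSG:3067") {
  records <- as.data.frame(records)
  if (anyDuplicated(records$tree_id))
    stop("duplicate tree_id in catalogue records")
  feats <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    si <- as.integer(r$species_index)
    list(
      type = "Feature",
      id = as.integer(r$tree_id),
      geometry = list(type = "Point",
                      coordinates = c(r$e, r$n, r$h)),
      properties = list(
        tree_id = as.integer(r$tree_id),
        species_index = si,
        species_name = unname(.species_names[as.character(si)]),
        height_m = r$height_m,
        quality = as.integer(r$quality),
        dist_crown_top_m = r$dist_crown_top_m,
        dist_stem_base_m = r$dist_stem_base_m,
        point_density_per_m2 = r$point_density_per_m2,
        files = if ("files" %in% names(records))
          as.character(unlist(r$files)) else character()))
  })
  structure(list(type = "FeatureCollection", crs = crs, features = feats),
            class = "TreeCatalog")
}

#' @rdname buildCatalog
#' @param catalog a `TreeCatalog` from `buildCatalog()`.
#' @param path output JSON path.
#' @return `writeCatalog()` returns `path` invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  json <- jsonlite::toJSON(unclass(catalog), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname buildCatalog
#' @details `readCatalog()` reads a catalogue back into the same list shape.
#' @export
readCatalog <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
            class = "TreeCatalog")
}
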