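# End-to-end orchestration: scene (or simulation) -> scan attributes ->
# rectification -> georeferencing -> optional resampling -> stem detection ->
# coarse segmentation -> height normalization -> fine segmentation ->
# per-tree attributes and quality -> catalogue, with a machine-readable
# manifest.

#' Pipeline configuration
#'
#' Builds and validates the nested configuration driving [runPipeline()].
#' Either `input` (paths to an existing scene, DTM and control points) or
#' `simulate` (a [sceneConfig()]) must be provided.
#'
#' @param input list with paths `scene` (LAS), `dtm` (LAS or XYZ table) and
#'   `gcp` (control-point CSV); or `NULL` when simulating.
#' @param simulate a [sceneConfig()] (or argument list for one), or `NULL`.
#' @param pose a [scannerPose()] used when simulating.
#' @param angles rectification Euler angles, degrees (default
#'   `c(0, 60, 90)`).
#' @param resample `NULL` (default: resampling off, full resolution is kept
#'   for the dataset) or a [resampleConfig()].
#' @param stem a [stemDetectionConfig()].
#' @param layer a [layerSegConfig()].
#' @param commissionTol,omissionTol automatic completeness tolerances used
#'   when ground-truth labels are available.
#' @param timestamp scan acquisition time used in output file names.
#' @param crs CRS tag stamped on georeferenced outputs.
#' @param seed integer seed governing all stochastic stages.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, simulate = NULL,
                           pose = scannerPose(), angles = c(0, 60, 90),
                           resample = NULL,
                           stem = stemDetectionConfig(),
                           layer = layerSegConfig(),
                           commissionTol = 0.05, omissionTol = 0.10,
                           timestamp = as.POSIXct("2020-04-06 01:23:45",
                                                  tz = "UTC"),
                           crs = "EPSG:3067", seed = 1L) {
  if (is.null(input) && is.null(simulate))
    stop("pipeline config needs either 'input' paths or a 'simulate' block")
  if (!is.null(input)) {
    for (k in c("scene", "dtm", "gcp"))
      if (is.null(input[[k]]))
        stop("pipeline input lacks required path '", k, "'")
    for (k in c("scene", "dtm", "gcp"))
      if (!file.exists(input[[k]]))
        stop("pipeline input '", k, "' not found: ", input[[k]])
  }
  if (!is.null(simulate) && !inherits(simulate, "SceneConfig"))
    simulate <- do.call(sceneConfig, simulate)
  if (!is.null(resample) && !inherits(resample, "ResampleConfig"))
    resample <- do.call(resampleConfig, resample)
  if (!inherits(stem, "StemDetectionConfig"))
    stem <- do.call(stemDetectionConfig, stem)
  if (!inherits(layer, "LayerSegConfig"))
    layer <- do.call(layerSegConfig, layer)
  structure(list(input = input, simulate = simulate, pose = pose,
                 angles = angles, resample = resample, stem = stem,
                 layer = layer, commissionTol = commissionTol,
                 omissionTol = omissionTol, timestamp = timestamp,
                 crs = crs, seed = as.integer(seed),
                 schema_version = "1"),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the [pipelineConfig()] arguments; nested blocks
#' (`simulate`, `pose`, `stem`, `layer`, `resample`) hold the corresponding
#' constructor arguments. Validation happens before any work.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "simulate", "resample", "commissionTol",
              "omissionTol", "crs"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$pose)) args$pose <- do.call(scannerPose, y$pose)
  if (!is.null(y$stem)) args$stem <- do.call(stemDetectionConfig, y$stem)
  if (!is.null(y$layer)) args$layer <- do.call(layerSegConfig, y$layer)
  if (!is.null(y$angles)) args$angles <- as.numeric(y$angles)
  if (!is.null(y$timestamp))
    args$timestamp <- as.POSIXct(y$timestamp, tz = "UTC")
  if (!is.null(seed)) args$seed <- seed
  else if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipelineConfig, args)
}

.stage_msg <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  c(log, msg)
}

#' Run the full processing chain
#'
#' Executes: simulate (optional) -> scan-attribute derivation ->
#' rectification -> Helmert georeferencing -> optional voxel resampling ->
#' stem detection -> coarse cylinder-buffer segmentation -> DTM height
#' normalization -> layer-by-layer fine segmentation -> per-tree attributes
#' and quality -> JSON catalogue. Per-stage outputs land in `outDir`
#' together with a manifest carrying the configuration hash and exact
#' per-stage point counts. A re-run with unchanged inputs reproduces the
#' catalogue byte-for-byte.
#'
#' When ground-truth labels are present (simulated scenes) the per-tree
#' quality level is scored automatically against them; otherwise trees with
#' a successful segmentation are flagged level 4 and failures level 0.
#'
#' @param config a [pipelineConfig()] (or YAML path).
#' @param outDir output/run directory, created if needed.
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with `catalog_path`, `manifest_path`,
#'   `records`, `stem_map` and `manifest`.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config, seed = seed)
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  counts <- list()
  stage <- "setup"

  run <- function() {
    # ---- inputs ------------------------------------------------------
    stage <<- "input"
    truth <- NULL
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      scene <- generateScene(sim, config$pose)
      cloud <- scene$cloud
      truth <- scene$truth
      dtm <- truth$dtm
      gcp <- truth$gcp
      writePointCloud(cloud, file.path(outDir, "scene.las"))
      utils::write.csv(gcp, file.path(outDir, "gcp.csv"),
                       row.names = FALSE)
      log <<- .stage_msg(log, stage, "simulated scene with ",
                         npoints(cloud), " points")
    } else {
      cloud <- readPointCloud(config$input$scene)
      dtm <- readDTM(config$input$dtm)
      gcp <- readControlPoints(config$input$gcp)
      log <<- .stage_msg(log, stage, "read scene with ", npoints(cloud),
                         " points")
    }
    truth_label <- if (hasAttribute(cloud, "label"))
      pointData(cloud)$label else NULL
    counts$input <<- npoints(cloud)

    # ---- scan attributes + rectification + georeferencing -----------
    stage <<- "scan_attributes"
    cloud <- computeScanAttributes(cloud)
    stage <<- "rectify"
    cloud <- rectify(cloud, config$angles)
    stage <<- "georeference"
    helm <- fitHelmert(gcp)
    cloud <- applyHelmert(cloud, helm, crs = config$crs)
    scanner_pos <- as.vector(helm@translation +
                               helm@scale * helm@rotation %*% c(0, 0, 0))
    log <<- .stage_msg(log, stage, sprintf("helmert fit rmse %.6f m",
                                           helm@fitRMSE))
    counts$georeferenced <<- npoints(cloud)

    # ---- optional resampling ----------------------------------------
    if (!is.null(config$resample)) {
      stage <<- "resample"
      n0 <- npoints(cloud)
      cloud <- voxelResample(cloud, config$resample)
      truth_label <- if (hasAttribute(cloud, "label"))
        pointData(cloud)$label else NULL
      log <<- .stage_msg(log, stage, n0 - npoints(cloud),
                         " points removed")
    }
    counts$working <<- npoints(cloud)

    # ---- stem detection ---------------------------------------------
    stage <<- "stem_detection"
    mask <- classifyStemPoints(cloud, dtm, config$stem)
    stem_map <- clusterStems(cloud, mask, dtm, config$stem,
                             scannerPosition = scanner_pos)
    utils::write.csv(stems(stem_map), file.path(outDir, "stem_map.csv"),
                     row.names = FALSE)
    log <<- .stage_msg(log, stage, length(stem_map), " stems detected")
    counts$stems <<- length(stem_map)

    # ---- coarse segmentation ----------------------------------------
    stage <<- "coarse_segmentation"
    buffers <- coarseSegment(cloud, stem_map, config$stem)
    counts$buffers <<- lapply(buffers, npoints)

    # ---- fine segmentation + per-tree records -----------------------
    stage <<- "fine_segmentation"
    tree_dir <- file.path(outDir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    st <- stems(stem_map)
    records <- list()
    seg_counts <- list()
    unassigned <- list()
    for (b in seq_along(buffers)) {
      stem_id <- st$stem_id[b]
      buf <- buffers[[b]]
      rows_in_cloud <- which((pointData(cloud)$x - st$x[b])^2 +
                               (pointData(cloud)$y - st$y[b])^2 <=
                               config$stem$bufferRadius^2)
      norm <- normalizeHeights(buf, dtm)
      seeds <- detectTrees(norm, config$layer)
      rec <- list(tree_id = stem_id, e = st$x[b], n = st$y[b],
                  h = st$ground_z[b])
      if (length(seeds) == 0) {
        rec$quality <- 0L
        rec$species_index <- 4L
        rec$height_m <- NA_real_
        rec$dist_crown_top_m <- NA_real_
        rec$dist_stem_base_m <- sqrt(sum((c(st$x[b], st$y[b],
                                            st$ground_z[b]) -
                                            scanner_pos)^2))
        rec$point_density_per_m2 <- NA_real_
        rec$files <- character()
        seg_counts[[as.character(stem_id)]] <-
          list(n_points = npoints(buf), n_assigned = 0L,
               n_unassigned = npoints(buf))
        records[[length(records) + 1L]] <- rec
        next
      }
      # the buffer is centred on this stem: its tree is the seed whose
      # apex is planimetrically closest to the stem position
      apex_d <- vapply(seeds, function(s)
        sqrt(sum((s$apex_xy - c(st$x[b], st$y[b]))^2)), numeric(1))
      own <- seeds[[which.min(apex_d)]]$tree_id
      seg <- segmentLayers(norm, seeds, config$layer)
      seg_lab <- pointData(seg)$label
      tree_rows <- seg_lab == own
      tree_cloud <- buf[tree_rows]   # georeferenced z
      seg_counts[[as.character(stem_id)]] <-
        list(n_points = npoints(buf), n_assigned = sum(seg_lab > 0),
             n_unassigned = sum(seg_lab == 0))
      unassigned[[length(unassigned) + 1L]] <- buf[seg_lab == 0]

      # quality: against truth labels when available
      if (!is.null(truth_label) && !is.null(truth)) {
        tl <- truth_label[rows_in_cloud]
        td <- truth$trees
        tdist <- sqrt((td$x - st$x[b])^2 + (td$y - st$y[b])^2)
        ti <- which.min(tdist)
        if (tdist[ti] <= 1.5 && any(tl == td$tree_id[ti])) {
          truth_id <- td$tree_id[ti]
          segvec <- ifelse(tree_rows, truth_id, 0L)
          sc <- scoreCompleteness(segvec, tl, truth_id,
                                  config$commissionTol, config$omissionTol)
          rec$quality <- sc$quality
          rec$species_index <- td$species_index[ti]
        } else {
          rec$quality <- 1L          # no matching truth tree: commission
          rec$species_index <- 4L
        }
      } else {
        rec$quality <- if (npoints(tree_cloud) > 0) 4L else 0L
        rec$species_index <- 4L
      }

      if (npoints(tree_cloud) == 0) {
        rec$quality <- 0L
        rec$height_m <- NA_real_
        rec$dist_crown_top_m <- NA_real_
        rec$dist_stem_base_m <- sqrt(sum((c(st$x[b], st$y[b],
                                            st$ground_z[b]) -
                                            scanner_pos)^2))
        rec$point_density_per_m2 <- NA_real_
        rec$files <- character()
        records[[length(records) + 1L]] <- rec
        next
      }
      rec$height_m <- estimateTreeHeight(tree_cloud, dtm,
                                         c(st$x[b], st$y[b]))
      dists <- scannerDistances(tree_cloud, scanner_pos,
                                c(st$x[b], st$y[b]), dtm)
      rec$dist_crown_top_m <- unname(dists["crown_top_m"])
      rec$dist_stem_base_m <- unname(dists["stem_base_m"])
      rec$point_density_per_m2 <- pointDensity(tree_cloud)
      fname <- makeTreeFilename(config$timestamp, stem_id, rec$quality)
      writePointCloud(tree_cloud, file.path(tree_dir, fname))
      rec$files <- fname
      records[[length(records) + 1L]] <- rec
    }
    counts$segmentation <<- seg_counts
    if (length(unassigned)) {
      ua <- do.call(rbind, lapply(unassigned, pointData))
      if (nrow(ua))
        writePointCloud(PointCloud(ua, crs = config$crs),
                        file.path(tree_dir, "unassigned.laz"))
    }
    log <<- .stage_msg(log, stage, length(records), " tree records")

    # ---- catalogue + manifest ---------------------------------------
    stage <<- "catalogue"
    rec_df <- do.call(rbind, lapply(records, function(r)
      data.frame(tree_id = r$tree_id, species_index = r$species_index,
                 e = unname(r$e), n = unname(r$n), h = unname(r$h),
                 height_m = unname(r$height_m),
                 quality = r$quality,
                 dist_crown_top_m = r$dist_crown_top_m,
                 dist_stem_base_m = r$dist_stem_base_m,
                 point_density_per_m2 = r$point_density_per_m2,
                 files = I(list(r$files)), row.names = NULL)))
    if (is.null(rec_df))
      rec_df <- data.frame(tree_id = integer(), species_index = integer(),
                           e = numeric(), n = numeric(), h = numeric(),
                           height_m = numeric(), quality = integer(),
                           dist_crown_top_m = numeric(),
                           dist_stem_base_m = numeric(),
                           point_density_per_m2 = numeric())
    utils::write.csv(rec_df[, setdiff(names(rec_df), "files")],
                     file.path(outDir, "records.csv"), row.names = FALSE)
    catalog <- buildCatalog(rec_df, crs = config$crs)
    catalog_path <- file.path(outDir, "catalog.json")
    writeCatalog(catalog, catalog_path)

    cfg_json <- jsonlite::toJSON(.config_as_list(config),
                                 auto_unbox = TRUE, digits = NA,
                                 null = "null", pretty = TRUE)
    cfg_path <- file.path(outDir, "config.json")
    writeLines(cfg_json, cfg_path)
    manifest <- list(
      schema_version = config$schema_version,
      package_version = as.character(utils::packageVersion("plstree")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      counts = counts,
      helmert = list(translation = helm@translation,
                     scale = helm@scale, fit_rmse_m = helm@fitRMSE),
      log = log)
    manifest_path <- file.path(outDir, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               manifest_path)
    list(catalog_path = catalog_path, manifest_path = manifest_path,
         records = rec_df, stem_map = stem_map, manifest = manifest)
  }

  res <- tryCatch(run(), error = function(e) {
    writeLines(c(paste("FAILED at stage:", stage),
                 conditionMessage(e), log),
               file.path(outDir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# flatten a PipelineConfig into plain lists for hashing/serialization
.config_as_list <- function(config) {
  strip <- function(x) {
    if (inherits(x, "POSIXt")) return(format(x, "%Y-%m-%d %H:%M:%S"))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(unclass(config))
}
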