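# Reusable quality metrics: stem positional accuracy, cloud-to-cloud
# consistency, and automatic completeness scoring against ground truth.

#' Match detected stems against a reference stem map
#'
#' Greedy pairing by ascending planimetric distance within a gate: the
#' closest remaining (detected, reference) pair is matched first, each stem
#' at most once, so every accepted pair is mutually nearest among the stems
#' still available. The procedure is symmetric in the two maps.
#'
#' @param detected,reference [StemMap-class] objects (or data.frames with
#'   columns `x`, `y`) in a common frame.
#' @param gate metres; pairs farther apart than this are never matched
#'   (default 2).
#' @return list with `pairs` (data.frame: detected_id, reference_id, de, dn,
#'   distance; `de`/`dn` are signed detected-minus-reference disparities),
#'   `unmatched_detected` and `unmatched_reference` (counts).
#' @export
matchStems <- function(detected, reference, gate = 2.0) {
  as_tab <- function(x) {
    if (is(x, "StemMap")) stems(x)
    else cbind(stem_id = seq_len(nrow(x)), as.data.frame(x))
  }
  dts <- as_tab(detected)
  ref <- as_tab(reference)
  pairs <- data.frame(detected_id = integer(), reference_id = integer(),
                      de = numeric(), dn = numeric(), distance = numeric())
  if (nrow(dts) && nrow(ref)) {
    dd <- outer(seq_len(nrow(dts)), seq_len(nrow(ref)),
                function(i, j) sqrt((dts$x[i] - ref$x[j])^2 +
                                    (dts$y[i] - ref$y[j])^2))
    repeat {
      m <- which.min(dd)
      if (length(m) == 0 || dd[m] > gate || !is.finite(dd[m])) break
      i <- (m - 1) %% nrow(dts) + 1
      j <- (m - 1) %/% nrow(dts) + 1
      pairs <- rbind(pairs, data.frame(
        detected_id = dts$stem_id[i], reference_id = ref$stem_id[j],
        de = dts$x[i] - ref$x[j], dn = dts$y[i] - ref$y[j],
        distance = dd[m]))
      dd[i, ] <- Inf
      dd[, j] <- Inf
      if (all(!is.finite(dd))) break
    }
  }
  list(pairs = pairs,
       unmatched_detected = nrow(dts) - nrow(pairs),
       unmatched_reference = nrow(ref) - nrow(pairs))
}

#' Planimetric positional accuracy of matched stems
#'
#' Mean planimetric distance over the matched pairs, plus per-axis RMSEs of
#' the signed easting/northing disparities.
#'
#' @param match result of [matchStems()] (or its `pairs` data.frame).
#' @return list with `n_matched`, `mean_planimetric_m`, `rmse_e_m`,
#'   `rmse_n_m`, `unmatched_detected`, `unmatched_reference`.
#' @export
planimetricAccuracy <- function(match) {
  pairs <- if (is.data.frame(match)) match else match$pairs
  if (nrow(pairs) == 0) stop("no matched stem pairs")
  list(n_matched = nrow(pairs),
       mean_planimetric_m = mean(pairs$distance),
       rmse_e_m = sqrt(mean(pairs$de^2)),
       rmse_n_m = sqrt(mean(pairs$dn^2)),
       unmatched_detected = if (is.data.frame(match)) NA_integer_
                            else match$unmatched_detected,
       unmatched_reference = if (is.data.frame(match)) NA_integer_
                             else match$unmatched_reference)
}

#' Cloud-to-cloud distance report
#'
#' For each point of `a`, the distance to its nearest neighbour in `b`;
#' reports the mean and the fraction of distances within the threshold.
#' Directional (a to b) by design; `symmetric = TRUE` runs both directions
#' and reports the worse (larger mean, smaller fraction).
#'
#' @param a,b non-empty [PointCloud-class] objects in a common frame.
#' @param threshold metres (default 0.15).
#' @param symmetric run both directions and report the worse (default FALSE).
#' @return list with `mean_distance_m`, `fraction_within_threshold`,
#'   `threshold_m`.
#' @export
cloudToCloud <- function(a, b, threshold = 0.15, symmetric = FALSE) {
  if (npoints(a) == 0 || npoints(b) == 0) stop("empty point cloud")
  one <- function(p, q) {
    nn <- cpp_knn(coords(q), coords(p), 1L)
    d <- nn$distance[, 1]
    list(mean_distance_m = mean(d),
         fraction_within_threshold = mean(d <= threshold),
         threshold_m = threshold)
  }
  ab <- one(a, b)
  if (!symmetric) return(ab)
  ba <- one(b, a)
  list(mean_distance_m = max(ab$mean_distance_m, ba$mean_distance_m),
       fraction_within_threshold = min(ab$fraction_within_threshold,
                                       ba$fraction_within_threshold),
       threshold_m = threshold)
}

#' Automatic completeness scoring against ground-truth labels
#'
#' Compares one tree's segmentation against per-point truth labels:
#' commission is flagged when the fraction of foreign points among those
#' assigned to the tree exceeds `commissionTol`; omission when the fraction
#' of true tree points left unassigned to it exceeds `omissionTol`. Zero
#' assigned points mean the segmentation failed (level 0). The booleans feed
#' [assignQuality()]. Tolerances of 0 reproduce strict set-equality
#' classification.
#'
#' @param segmented integer vector of segmentation labels, or a
#'   [PointCloud-class] with a `label` column.
#' @param truth integer vector of ground-truth labels, same length/order.
#' @param treeId the tree to score.
#' @param commissionTol foreign-point fraction tolerance (default 0.05).
#' @param omissionTol missing-point fraction tolerance (default 0.10).
#' @return list with `quality` (0..4), `commission`, `omission`,
#'   `commission_fraction`, `omission_fraction`.
#' @export
scoreCompleteness <- function(segmented, truth, treeId,
                              commissionTol = 0.05, omissionTol = 0.10) {
  if (is(segmented, "PointCloud")) {
    stopifnot(hasAttribute(segmented, "label"))
    segmented <- pointData(segmented)$label
  }
  stopifnot(length(segmented) == length(truth))
  if (!treeId %in% truth)
    stop("tree id ", treeId, " absent from the truth labels")
  assigned <- segmented == treeId
  true_pts <- truth == treeId
  n_assigned <- sum(assigned)
  if (n_assigned == 0)
    return(list(quality = 0L, commission = FALSE, omission = TRUE,
                commission_fraction = NA_real_, omission_fraction = 1))
  cf <- sum(assigned & !true_pts) / n_assigned
  of <- sum(true_pts & !assigned) / sum(true_pts)
  commission <- cf > commissionTol
  omission <- of > omissionTol
  list(quality = assignQuality(commission, omission, FALSE),
       commission = commission, omission = omission,
       commission_fraction = cf, omission_fraction = of)
}
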