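# Morphology and clustering statistics.
#
# Per-punctum nearest-neighbour clustering ("mean distance of the k
# nearest neighbouring endosomes", k = 3 in the reference workflow),
# per-image summaries (volume distribution, density within the ROI, mean
# kNN distance) and per-case aggregation where every neuron image
# contributes one equally weighted value per metric.

#' Mean distance to the k nearest neighbours
#'
#' For each point, the arithmetic mean of the Euclidean distances (in
#' physical micrometres) to its k nearest other points; exact all-pairs
#' computation, no approximation. Defined only when at least k+1 points
#' are present; otherwise every value is NA with `defined = FALSE`.
#' Invariant under permutation, rigid translation and rotation of the
#' coordinates.
#'
#' @param centroids n x 3 matrix of (x, y, z) positions in um, or a
#'   puncta table with cx_um/cy_um/cz_um columns.
#' @param k neighbour count (>= 1; default 3 as in the reference
#'   clustering statistic).
#' @return data.frame: id, k, mean_knn_distance_um, defined.
#' @export
knn_mean_distance <- function(centroids, k = 3L) {
  if (k < 1) stopf("k must be >= 1")
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("cx_um", "cy_um", "cz_um")])
  n <- nrow(centroids)
  out <- data.frame(id = seq_len(n), k = as.integer(k),
                    mean_knn_distance_um = rep(NA_real_, n),
                    defined = rep(FALSE, n))
  if (n < k + 1) return(out)
  dm <- as.matrix(stats::dist(centroids))
  for (i in seq_len(n)) {
    d <- sort(dm[i, -i], partial = k)[seq_len(k)]
    out$mean_knn_distance_um[i] <- mean(d)
  }
  out$defined <- TRUE
  out
}

#' Attach neighbour statistics to a puncta table
#'
#' @param table puncta table with centroid columns.
#' @param k neighbour count.
#' @return the table with `mean_knn_distance_um` added (NA when fewer
#'   than k+1 puncta share the ROI).
#' @export
add_neighbor_stats <- function(table, k = 3L) {
  nn <- knn_mean_distance(table, k)
  table$mean_knn_distance_um <- nn$mean_knn_distance_um
  table
}

#' Puncta density within an ROI
#'
#' @param n_puncta puncta count.
#' @param roi_volume_um3 ROI volume in um^3 (> 0).
#' @return count per um^3; `density * volume` reproduces the count.
#' @export
puncta_density <- function(n_puncta, roi_volume_um3) {
  if (roi_volume_um3 <= 0) stopf("ROI volume must be > 0")
  n_puncta / roi_volume_um3
}

#' Per-image summary of one ROI's puncta
#'
#' Volume statistics (mean, sd, median, quartiles by linear interpolation
#' between order statistics, min, max), count, density within the ROI and
#' mean kNN distance. Degenerate inputs are flagged, not dropped: an empty
#' table yields count 0 and density 0 with NA distribution statistics; a
#' single punctum has NA sd.
#'
#' @param table (filtered) puncta table for one image and one ROI role.
#' @param roi the `roi_mask` the table was measured in (or its volume via
#'   a list with `volume_um3` and `role`).
#' @param k neighbour count for the clustering statistic.
#' @param case_id,image_id identifiers (defaults: taken from the table
#'   attributes when present).
#' @return one-row data.frame of class `image_summary`.
#' @export
summarize_image <- function(table, roi, k = 3L, case_id = "case",
                            image_id = "image") {
  n <- nrow(table)
  v <- table$volume_um3
  q <- if (n > 0) quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
       else rep(NA_real_, 3)
  knn <- if (n >= k + 1) mean(knn_mean_distance(table, k)$mean_knn_distance_um)
         else NA_real_
  out <- data.frame(
    case_id = case_id, image_id = image_id, roi_role = roi$role,
    n_puncta = n,
    mean_volume_um3 = if (n) mean(v) else NA_real_,
    sd_volume_um3 = if (n > 1) sd(v) else NA_real_,
    median_volume_um3 = q[2], q1_volume_um3 = q[1], q3_volume_um3 = q[3],
    min_volume_um3 = if (n) min(v) else NA_real_,
    max_volume_um3 = if (n) max(v) else NA_real_,
    density_per_um3 = if (isTRUE(roi$volume_um3 > 0)) n / roi$volume_um3
                      else NA_real_,
    mean_knn_um = knn,
    roi_volume_um3 = roi$volume_um3,
    stringsAsFactors = FALSE)
  class(out) <- c("image_summary", class(out))
  out
}

#' Per-case aggregation of image summaries
#'
#' Unweighted arithmetic mean and sd across the case's images for every
#' numeric metric: each neuron image contributes equally, regardless of
#' how many puncta it holds, matching the "mean value from all neurons
#' imaged per case" convention. A single image yields the image's values
#' with NA sd.
#'
#' @param images data.frame of stacked [summarize_image()] rows for one
#'   case and one ROI role.
#' @return one-row data.frame of class `case_summary` with `<metric>_mean`
#'   and `<metric>_sd` columns plus `n_images`.
#' @export
summarize_case <- function(images) {
  if (nrow(images) < 1) stopf("at least one image summary required")
  if (length(unique(images$case_id)) != 1) stopf("mixed case ids")
  if (length(unique(images$roi_role)) != 1) stopf("mixed ROI roles")
  metrics <- c("n_puncta", "mean_volume_um3", "median_volume_um3",
               "density_per_um3", "mean_knn_um", "roi_volume_um3")
  out <- data.frame(case_id = images$case_id[1],
                    roi_role = images$roi_role[1],
                    n_images = nrow(images), stringsAsFactors = FALSE)
  for (m in metrics) {
    x <- images[[m]]
    out[[paste0(m, "_mean")]] <- mean(x, na.rm = TRUE)
    out[[paste0(m, "_sd")]] <- if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE)
                               else NA_real_
  }
  class(out) <- c("case_summary", class(out))
  out
}

#' Export puncta positions for 3-D scatter visualisation
#'
#' Long-format table (x, y, z, metric value), one row per punctum, e.g.
#' to colour an xyz scatter by volume or by the mean-kNN clustering
#' statistic. Undefined metric values (e.g. kNN with too few puncta)
#' propagate as NA.
#'
#' @param table puncta table.
#' @param color_by metric column name ("volume_um3",
#'   "mean_knn_distance_um", ...).
#' @param path optional CSV output path.
#' @return data.frame x_um, y_um, z_um, value (named after the metric).
#' @export
export_spatial <- function(table, color_by = "volume_um3", path = NULL) {
  if (!color_by %in% names(table))
    stopf("unknown metric '%s'", color_by)
  out <- data.frame(x_um = table$cx_um, y_um = table$cy_um,
                    z_um = table$cz_um, value = table[[color_by]])
  names(out)[4] <- color_by
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
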