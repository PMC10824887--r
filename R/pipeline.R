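# Config-driven batch orchestration.
#
# The reference workflow is a two-batch structure: Batch 1 builds and
# refines the neuronal ROIs and masks are written to disk; an optional
# pause lets a user hand-edit the mask TIFFs; Batch 2 re-reads the masks,
# masks the punctate channel twice over and runs both detection workflows
# in both ROIs, then aggregates. Failures are isolated per image and the
# roster is accounted for exactly once each in the run manifest.

#' Pipeline configuration
#'
#' One flat, serialisable object collecting every stage's parameters; the
#' config is echoed verbatim into the run manifest for provenance. All
#' defaults mirror the package's documented stage defaults, including the
#' published protocol constants (minimum puncta volume 0.004 um^3 with
#' strict-< exclusion, admissible diameters 100-500 nm, k = 3 neighbours).
#'
#' @param roster data.frame with columns path, case_id, image_id.
#' @param roles a [channel_roles()].
#' @param out_dir output directory.
#' @param spacing_override optional [voxel_spacing()] for plain TIFFs.
#' @param deconvolve list: `enabled`, `iterations`, `psf_sigma_um`
#'   (Richardson-Lucy stand-in for the acquisition-side deconvolution;
#'   applied to the puncta channel before masking).
#' @param seg_somatodendritic,seg_nuclei [segmentation_params()] for the
#'   two ROI channels.
#' @param perinuclear_dilation_um physical dilation of the selected
#'   nucleus into the perinuclear ROI.
#' @param filter a [puncta_filter()].
#' @param surface a [surface_params()].
#' @param spots a [spots_params()].
#' @param d_range_um spots-mode diameter range.
#' @param k neighbour count for clustering statistics.
#' @param qc a [qc_config()].
#' @param match_tolerance_um tolerance for the surface/spots cross-check.
#' @param pause_for_edit stop after Batch 1 so masks can be hand-edited.
#' @param seed recorded in the manifest; no pipeline stage consumes
#'   randomness on fixed input, so results on real data are seed-free.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(roster, roles = channel_roles(), out_dir,
                            spacing_override = NULL,
                            deconvolve = list(enabled = TRUE,
                                              iterations = 10L,
                                              psf_sigma_um = c(0.08, 0.08, 0.2)),
                            seg_somatodendritic = segmentation_params(),
                            seg_nuclei = segmentation_params(
                              min_component_volume_um3 = 1),
                            perinuclear_dilation_um = 0.3,
                            filter = puncta_filter(),
                            surface = surface_params(),
                            spots = spots_params(),
                            d_range_um = c(0.1, 0.5),
                            k = 3L,
                            qc = qc_config(),
                            match_tolerance_um = 0.3,
                            pause_for_edit = FALSE,
                            seed = 1L) {
  if (nrow(roster) < 1) stopf("roster must be non-empty")
  if (anyDuplicated(roster$image_id)) stopf("image ids must be unique")
  structure(list(roster = roster, roles = roles, out_dir = out_dir,
                 spacing_override = spacing_override,
                 deconvolve = deconvolve,
                 seg_somatodendritic = seg_somatodendritic,
                 seg_nuclei = seg_nuclei,
                 perinuclear_dilation_um = perinuclear_dilation_um,
                 filter = filter, surface = surface, spots = spots,
                 d_range_um = d_range_um, k = as.integer(k), qc = qc,
                 match_tolerance_um = match_tolerance_um,
                 pause_for_edit = pause_for_edit, seed = as.integer(seed)),
            class = "pipeline_config")
}

mask_path <- function(out_dir, image_id, role)
  file.path(out_dir, "masks", sprintf("%s_%s.tif", image_id, role))

write_manifest <- function(out_dir, name, config, statuses) {
  manifest <- list(
    software = paste0("endopipe ",
                      as.character(utils::packageVersion("endopipe"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config_to_list(config),
    images = statuses)
  path <- file.path(out_dir, name)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null", force = TRUE),
             path)
  invisible(path)
}

# plain-list view of a config (JSON-ready); class attributes dropped
config_to_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "list",
         classes = c("numeric", "integer", "character", "logical"))
}

#' Write / read a pipeline config as JSON
#'
#' The flat JSON document round-trips every scalar field; the roster
#' travels inside it.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) / a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  pipeline_config(
    roster = as.data.frame(x$roster, stringsAsFactors = FALSE),
    roles = do.call(channel_roles, x$roles),
    out_dir = x$out_dir,
    spacing_override = if (length(x$spacing_override))
      do.call(voxel_spacing, x$spacing_override),
    deconvolve = x$deconvolve,
    seg_somatodendritic = do.call(segmentation_params, x$seg_somatodendritic),
    seg_nuclei = do.call(segmentation_params, x$seg_nuclei),
    perinuclear_dilation_um = x$perinuclear_dilation_um,
    filter = do.call(puncta_filter, x$filter),
    surface = do.call(surface_params, x$surface),
    spots = do.call(spots_params, x$spots),
    d_range_um = x$d_range_um,
    k = x$k,
    qc = do.call(qc_config, x$qc),
    match_tolerance_um = x$match_tolerance_um,
    pause_for_edit = x$pause_for_edit,
    seed = x$seed)
}

#' Batch 1: build, refine and write the neuronal ROIs
#'
#' Per roster image: read the stack, segment nuclei and the
#' somatodendritic channel, select the neuron (the raw component / nucleus
#' pair with maximal overlap), refine both ROIs, write them as 8-bit mask
#' TIFFs under `out_dir/masks/`, and append a QC row. A failing image is
#' recorded as errored and never aborts the batch.
#'
#' @param config a [pipeline_config()].
#' @return list: `qc` (data.frame, one row per completed image),
#'   `statuses` (per-image terminal status), `manifest_path`.
#' @export
run_batch1 <- function(config) {
  dir.create(file.path(config$out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  qc_rows <- NULL
  statuses <- list()
  for (i in seq_len(nrow(config$roster))) {
    entry <- config$roster[i, ]
    status <- tryCatch({
      stack <- read_stack(entry$path, roles = config$roles,
                          spacing_override = config$spacing_override,
                          case_id = entry$case_id, image_id = entry$image_id)
      nuclei <- segment_nuclei(stack, config$seg_nuclei)
      raw <- segment_somatodendritic(stack, config$seg_somatodendritic)
      seed_mask <- select_neuron_nucleus(raw, nuclei)
      somato <- refine_somatodendritic(raw, seed_mask)
      peri <- refine_perinuclear(nuclei, somato, config$perinuclear_dilation_um)
      qc <- qc_neuron(somato, peri, config$qc)
      write_mask(somato, mask_path(config$out_dir, entry$image_id,
                                   "somatodendritic"))
      write_mask(peri, mask_path(config$out_dir, entry$image_id, "perinuclear"))
      row <- cbind(data.frame(case_id = entry$case_id,
                              image_id = entry$image_id,
                              stringsAsFactors = FALSE), qc$metrics)
      qc_rows <- rbind(qc_rows, row)
      if (qc$pass) "completed" else "qc-excluded"
    }, error = function(e) {
      message(sprintf("batch1: image '%s' errored: %s", entry$image_id,
                      conditionMessage(e)))
      paste0("errored: ", conditionMessage(e))
    })
    statuses[[entry$image_id]] <- status
  }
  qc_path <- file.path(config$out_dir, "qc.csv")
  if (!is.null(qc_rows)) write.csv(qc_rows, qc_path, row.names = FALSE)
  manifest <- write_manifest(config$out_dir, "manifest_batch1.json", config,
                             statuses)
  if (any(grepl("^errored", unlist(statuses))))
    warning("batch 1 finished with errored images; see manifest", call. = FALSE)
  list(qc = qc_rows, statuses = statuses, manifest_path = manifest)
}

#' Pick the neuronal nucleus for ROI refinement
#'
#' The imaged neuron is identified as the (raw somatodendritic component,
#' nucleus) pair with maximal voxel overlap; the chosen nucleus is
#' returned as the seed mask for [refine_somatodendritic()]. Falls back to
#' the largest nucleus when nothing overlaps (refinement will then record
#' the QC failure).
#'
#' @param raw the unrefined `roi_mask` from [segment_somatodendritic()].
#' @param nuclei a `nucleus_labels` from [segment_nuclei()].
#' @return Logical 3-D mask of the selected nucleus.
#' @export
select_neuron_nucleus <- function(raw, nuclei) {
  nl <- nuclei$labels
  best <- c(overlap = -1, comp = 0, nuc = 0)
  counts <- tabulate(raw$labels[raw$labels > 0], nbins = max(raw$labels))
  for (nuc in seq_len(nuclei$n)) {
    sel <- nl == nuc
    inside <- raw$labels[sel]
    ov <- tabulate(inside[inside > 0], nbins = max(raw$labels))
    if (!length(ov) || all(ov == 0)) next
    comp <- which(ov == max(ov))
    if (length(comp) > 1) comp <- comp[counts[comp] == max(counts[comp])][1]
    if (max(ov) > best["overlap"]) best <- c(overlap = max(ov), comp = comp,
                                             nuc = nuc)
  }
  if (best["nuc"] == 0) {
    # no nucleus touches any MAP2 component; fall back to the largest nucleus
    best["nuc"] <- which.max(nuclei$voxel_counts)
  }
  m <- nl == best[["nuc"]]
  dim(m) <- dim(nl)
  m
}

#' Batch 2: detect, measure and aggregate puncta in both ROIs
#'
#' Per completed image: re-read the stack, optionally deconvolve the
#' puncta channel, load the (possibly hand-edited) Batch-1 masks, mask the
#' channel with each ROI, run surface-mode detection (volume filter
#' applied) and spots-mode detection, cross-match the two modes, attach
#' kNN statistics, and summarise per image; per case and ROI role a case
#' summary is added. Images that failed Batch 1 QC or lack masks are
#' skipped with a recorded reason.
#'
#' @param config a [pipeline_config()].
#' @param masks_dir directory holding the Batch-1 masks (default
#'   `out_dir/masks`).
#' @return list of data.frames: `puncta`, `spots`, `matches`,
#'   `image_summaries`, `case_summaries`, plus `statuses` and
#'   `manifest_path`. All are also written as CSV under `out_dir`.
#' @export
run_batch2 <- function(config, masks_dir = file.path(config$out_dir, "masks")) {
  qc_path <- file.path(config$out_dir, "qc.csv")
  qc <- if (file.exists(qc_path)) read.csv(qc_path, stringsAsFactors = FALSE)
        else NULL
  puncta_all <- NULL; spots_all <- NULL; match_all <- NULL; img_sum <- NULL
  statuses <- list()

  for (i in seq_len(nrow(config$roster))) {
    entry <- config$roster[i, ]
    if (!is.null(qc) && entry$image_id %in% qc$image_id &&
        !isTRUE(qc$pass[qc$image_id == entry$image_id])) {
      statuses[[entry$image_id]] <- "qc-excluded"
      next
    }
    status <- tryCatch({
      stack <- read_stack(entry$path, roles = config$roles,
                          spacing_override = config$spacing_override,
                          case_id = entry$case_id, image_id = entry$image_id)
      channel <- get_channel(stack, "puncta")
      if (isTRUE(config$deconvolve$enabled)) {
        channel <- richardson_lucy(channel, stack$spacing,
          deconvolution_params(config$deconvolve$psf_sigma_um,
                               config$deconvolve$iterations))
      }
      for (role in c("somatodendritic", "perinuclear")) {
        mp <- file.path(masks_dir, sprintf("%s_%s.tif", entry$image_id, role))
        if (!file.exists(mp)) stopf("missing %s mask for image %s", role,
                                    entry$image_id)
        roi <- read_mask(mp, role = role,
                         spacing_override = stack$spacing)
        masked <- mask_channel(channel, roi)
        tab <- detect_surface_mode(masked, stack$spacing, config$surface,
                                   roi = roi, roi_role = role)
        tab <- apply_filter(tab, config$filter)
        tab <- add_neighbor_stats(tab, config$k)
        sp <- detect_spots_mode(masked, stack$spacing, config$d_range_um,
                                config$spots, roi = roi)
        mm <- match_modes(tab, sp, config$match_tolerance_um)
        ids <- data.frame(case_id = entry$case_id, image_id = entry$image_id,
                          stringsAsFactors = FALSE)
        puncta_all <- rbind(puncta_all, cbind(ids, tab))
        if (nrow(sp))
          spots_all <- rbind(spots_all,
                             cbind(ids, roi_role = role, sp))
        match_all <- rbind(match_all, cbind(ids, data.frame(
          roi_role = role,
          n_surface = nrow(tab), n_spots = nrow(sp),
          matched_fraction_surface = mm$matched_fraction_surface,
          matched_fraction_spots = mm$matched_fraction_spots)))
        img_sum <- rbind(img_sum,
                         summarize_image(tab, roi, config$k,
                                         case_id = entry$case_id,
                                         image_id = entry$image_id))
      }
      "completed"
    }, error = function(e) {
      message(sprintf("batch2: image '%s' skipped: %s", entry$image_id,
                      conditionMessage(e)))
      paste0("errored: ", conditionMessage(e))
    })
    statuses[[entry$image_id]] <- status
  }

  case_sum <- NULL
  if (!is.null(img_sum)) {
    for (cid in unique(img_sum$case_id)) {
      for (role in unique(img_sum$roi_role)) {
        sub <- img_sum[img_sum$case_id == cid & img_sum$roi_role == role, ,
                       drop = FALSE]
        if (nrow(sub)) case_sum <- rbind(case_sum, summarize_case(sub))
      }
    }
  }

  out <- config$out_dir
  if (!is.null(puncta_all))
    write.csv(puncta_all, file.path(out, "puncta.csv"), row.names = FALSE)
  if (!is.null(spots_all))
    write.csv(spots_all, file.path(out, "spots.csv"), row.names = FALSE)
  if (!is.null(match_all))
    write.csv(match_all, file.path(out, "mode_match.csv"), row.names = FALSE)
  if (!is.null(img_sum))
    write.csv(img_sum, file.path(out, "image_summary.csv"), row.names = FALSE)
  if (!is.null(case_sum))
    write.csv(case_sum, file.path(out, "case_summary.csv"), row.names = FALSE)
  manifest <- write_manifest(out, "manifest_batch2.json", config, statuses)

  list(puncta = puncta_all, spots = spots_all, matches = match_all,
       image_summaries = img_sum, case_summaries = case_sum,
       statuses = statuses, manifest_path = manifest)
}

#' Run the full two-batch pipeline
#'
#' Batch 1 then Batch 2. With `pause_for_edit = TRUE` in the config, the
#' run stops after Batch 1 with instructions to edit the mask TIFFs and
#' resume via [run_batch2()]; otherwise the composition is identical to
#' running the batches separately with untouched masks.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `batch1` and (unless paused) `batch2`.
#' @export
run_all <- function(config) {
  b1 <- run_batch1(config)
  if (isTRUE(config$pause_for_edit)) {
    message(sprintf(paste0(
      "Batch 1 complete. Edit the mask TIFFs under %s if needed, then ",
      "resume with run_batch2(config)."), file.path(config$out_dir, "masks")))
    return(list(batch1 = b1, batch2 = NULL, paused = TRUE))
  }
  b2 <- run_batch2(config)
  list(batch1 = b1, batch2 = b2, paused = FALSE)
}
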