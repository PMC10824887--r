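# Shared fixtures: a reduced phantom for fast unit tests (144 px plane,
# scaled-down neuron) and small utilities. Acceptance tests use the full
# default spec instead.

small_phantom_spec <- function(seed = 1L, noise = FALSE, ...) {
  sp <- phantom_spec(
    profile = acquisition_profile(plane_shape = c(144L, 144L), n_z = 14L),
    soma = list(semi_axes_um = c(1.5, 1.5, 0.85), center_um = NULL),
    dendrite = list(radius_um = 0.3, length_um = 1.0, taper = 0.4),
    nucleus = list(semi_axes_um = c(0.7, 0.7, 0.5),
                   invagination_amplitude = 0.1),
    n_distractor_nuclei = 0L,
    n_disconnected_neurites = 0L,
    puncta_count_somatodendritic = 8L,
    puncta_count_perinuclear = 3L,
    autofluorescence = list(n_granules = 0L, radius_um = 0.3,
                            bleed = c(nuclear = 0.05, somatodendritic = 0.05,
                                      puncta = 0.15)),
    min_separation_um = 0.5,
    seed = seed,
    ...)
  sp$noise$enabled <- noise
  sp
}

# truth puncta whose centre voxel lies inside a given ROI mask
truth_in_roi <- function(truth, roi, spacing) {
  p <- truth$puncta
  if (nrow(p) == 0) return(p[0, ])
  vz <- cbind(floor(p$cz_um / spacing$dz), floor(p$cy_um / spacing$dy),
              floor(p$cx_um / spacing$dx)) + 1
  keep <- vapply(seq_len(nrow(vz)), function(i)
    roi$voxels[vz[i, 1], vz[i, 2], vz[i, 3]], logical(1))
  p[keep, , drop = FALSE]
}

# greedy 1-to-1 matching count between truth centres and detection centres
matched_count <- function(truth_xyz, det_xyz, tol_um) {
  if (nrow(truth_xyz) == 0 || nrow(det_xyz) == 0) return(0L)
  dm <- sqrt(outer(truth_xyz[, 1], det_xyz[, 1], "-")^2 +
             outer(truth_xyz[, 2], det_xyz[, 2], "-")^2 +
             outer(truth_xyz[, 3], det_xyz[, 3], "-")^2)
  used_t <- logical(nrow(truth_xyz)); used_d <- logical(nrow(det_xyz))
  n <- 0L
  for (o in order(dm)) {
    if (dm[o] > tol_um) break
    i <- (o - 1) %% nrow(truth_xyz) + 1
    j <- (o - 1) %/% nrow(truth_xyz) + 1
    if (used_t[i] || used_d[j]) next
    used_t[i] <- TRUE; used_d[j] <- TRUE; n <- n + 1L
  }
  n
}

# independent O(n^2) brute-force oracle for the k-nearest-neighbour mean
knn_oracle <- function(xyz, k) {
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j)
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)), numeric(1))
    mean(sort(d[-i])[seq_len(k)])
  }, numeric(1))
}

# end-to-end ROI construction on a phantom (the batch-1 core)
build_rois <- function(ph) {
  stack <- ph$stack
  nuclei <- segment_nuclei(stack, segmentation_params(min_component_volume_um3 = 1))
  raw <- segment_somatodendritic(stack)
  somato <- refine_somatodendritic(raw, endopipe:::select_neuron_nucleus(raw, nuclei))
  peri <- refine_perinuclear(nuclei, somato, 0.3)
  list(nuclei = nuclei, raw = raw, somatodendritic = somato, perinuclear = peri)
}
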