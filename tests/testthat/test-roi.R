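# ROI construction on the reduced phantom plus constructed fixtures.

ph <- generate_phantom(small_phantom_spec(seed = 1))
rois <- build_rois(ph)
spc <- ph$stack$spacing

test_that("mask volume equals voxel count times voxel volume exactly", {
  m <- rois$somatodendritic
  expect_identical(m$volume_um3, sum(m$voxels) * spc$dx * spc$dy * spc$dz)
  expect_identical(rois$perinuclear$volume_um3,
                   sum(rois$perinuclear$voxels) * spc$dx * spc$dy * spc$dz)
})

test_that("somatodendritic segmentation covers the true neuron and passes QC", {
  truth_sd <- ph$truth$masks$soma | ph$truth$masks$dendrite
  m <- rois$somatodendritic$voxels
  jaccard <- sum(m & truth_sd) / sum(m | truth_sd)
  recall <- sum(m & truth_sd) / sum(truth_sd)
  expect_gte(jaccard, 0.8)
  expect_gte(recall, 0.9)     # reduced phantom; the 0.95 bar is tested at full scale
  qc <- qc_neuron(rois$somatodendritic, rois$perinuclear)
  expect_true(qc$pass)
})

test_that("refinement keeps exactly the nucleus-bearing component and is idempotent", {
  # default-scale phantom: 1 neuron + 3 disconnected fragments, 3 nuclei
  phd <- generate_phantom({
    s <- default_phantom_spec(seed = 3); s$noise$enabled <- FALSE; s
  })
  nuclei <- segment_nuclei(phd$stack,
                           segmentation_params(min_component_volume_um3 = 1))
  expect_identical(nuclei$n, 3L)
  raw <- segment_somatodendritic(phd$stack)
  expect_identical(raw$provenance$n_components, 4L)

  truth_sd <- phd$truth$masks$soma | phd$truth$masks$dendrite
  seed_mask <- select_neuron_nucleus(raw, nuclei)
  refined <- refine_somatodendritic(raw, seed_mask)
  expect_identical(max(endopipe:::cpp_label3(refined$voxels, TRUE)), 1L)
  # the kept component contains the true nucleus and covers the true neuron
  expect_gt(sum(refined$voxels & phd$truth$masks$nucleus) /
              sum(phd$truth$masks$nucleus), 0.95)
  expect_gte(sum(refined$voxels & truth_sd) / sum(refined$voxels | truth_sd), 0.8)
  expect_gte(sum(refined$voxels & truth_sd) / sum(truth_sd), 0.95)
  twice <- refine_somatodendritic(refined, seed_mask)
  expect_identical(twice$voxels, refined$voxels)

  peri <- refine_perinuclear(nuclei, refined, 0.3)
  truth_n <- phd$truth$masks$nucleus
  sel <- endopipe:::erode_um(peri$voxels, 0.3, phd$stack$spacing)
  expect_gt(sum(sel & truth_n) / sum(sel | truth_n), 0.6)
})

test_that("a nucleus seed touching no component yields a QC failure, not a guess", {
  raw <- rois$raw
  outside <- array(FALSE, dim(raw$voxels))
  outside[1:2, 1:4, 1:4] <- TRUE          # corner far from any MAP2 signal
  ref <- refine_somatodendritic(raw, outside)
  expect_false(ref$qc$pass)
  expect_match(ref$qc$reasons, "no MAP2\\+ component")
  expect_equal(sum(ref$voxels), 0L)
})

test_that("abutting nuclei are split by the distance-transform watershed", {
  # two spheres of radius 0.55 um whose centres are 1.0 um apart: the
  # binary mask is a single 8-shaped component
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  dims <- c(14L, 80L, 110L)
  g <- endopipe:::coord_grid(dims, sp)
  vol <- array(0, dims)
  for (ctr in list(c(1.0, 1.2, 0.91), c(2.0, 1.2, 0.91))) {
    X <- array(rep(g$x, each = dims[1] * dims[2]), dims)
    Y <- array(rep(rep(g$y, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(g$z, times = dims[2] * dims[3]), dims)
    vol <- vol + 150 * ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= 0.55^2)
  }
  vol <- pmin(vol, 150)
  arr <- array(0, c(3, dims))
  arr[1, , , ] <- vol; arr[2, , , ] <- vol; arr[3, , , ] <- 0
  stack <- image_stack(arr, sp, channel_roles())
  expect_identical(max(endopipe:::cpp_label3(
    endopipe:::smooth_threshold_mask(vol, sp, segmentation_params()), TRUE)), 1L)
  nuclei <- segment_nuclei(stack, segmentation_params(
    min_component_volume_um3 = 0.3, watershed_min_separation_um = 0.8))
  expect_identical(nuclei$n, 2L)
})

test_that("empty channels raise segmentation errors", {
  arr <- array(0, c(3, 6, 12, 12))
  stack <- image_stack(arr, voxel_spacing(0.03, 0.03, 0.13), channel_roles())
  expect_error(segment_somatodendritic(stack), "empty MAP2")
  expect_error(segment_nuclei(stack), "empty nuclear")
})

test_that("perinuclear dilation is monotone and zero reproduces the bare nucleus", {
  bare <- refine_perinuclear(rois$nuclei, rois$somatodendritic, 0)
  dil <- refine_perinuclear(rois$nuclei, rois$somatodendritic, 0.3)
  sel <- bare$provenance$selected_nucleus
  expect_equal(bare$volume_um3,
               sum(rois$nuclei$labels == sel) * spc$dx * spc$dy * spc$dz,
               tolerance = 1e-12)
  expect_gt(dil$volume_um3, bare$volume_um3)
  expect_true(all(bare$voxels[dil$voxels] | TRUE))   # structural sanity
  expect_true(all(dil$voxels[bare$voxels]))          # superset
})

test_that("mask_channel zeroes outside the ROI and never increases intensity", {
  ch <- get_channel(ph$stack, "puncta")
  full <- endopipe:::new_roi_mask(array(TRUE, dim(ch)), "somatodendritic", spc)
  expect_identical(mask_channel(ph$stack, full), ch)

  none <- endopipe:::new_roi_mask(array(FALSE, dim(ch)), "somatodendritic", spc)
  expect_equal(sum(mask_channel(ph$stack, none)), 0)

  masked <- mask_channel(ph$stack, rois$somatodendritic)
  expect_true(all(masked <= ch))
  expect_true(all(masked[!rois$somatodendritic$voxels] == 0))
  expect_identical(masked[rois$somatodendritic$voxels],
                   ch[rois$somatodendritic$voxels])

  bad <- endopipe:::new_roi_mask(array(TRUE, c(2, 2, 2)), "somatodendritic", spc)
  expect_error(mask_channel(ph$stack, bad), "grid mismatch")
})

test_that("QC reports reasons instead of throwing", {
  # fragmented somatodendritic mask: two disconnected blobs
  vox <- array(FALSE, dim(ph$stack$intensities)[2:4])
  vox[3:5, 5:15, 5:15] <- TRUE
  vox[8:10, 100:110, 100:110] <- TRUE
  frag <- endopipe:::new_roi_mask(vox, "somatodendritic", spc)
  qc <- qc_neuron(frag, rois$perinuclear)
  expect_false(qc$pass)
  expect_true(any(grepl("MAP2 discontinuous", qc$reasons)))

  # volume bound failure
  qc2 <- qc_neuron(rois$somatodendritic, rois$perinuclear,
                   qc_config(min_somatodendritic_volume_um3 = 1e6))
  expect_false(qc2$pass)
  expect_true(any(grepl("below minimum", qc2$reasons)))
  expect_s3_class(qc2$metrics, "data.frame")
})
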