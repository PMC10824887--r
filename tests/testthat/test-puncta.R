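test_that("spherical volume closed form and diameter round trip", {
  expect_equal(sphere_volume_from_diameter(0.2), pi * 0.008 / 6, tolerance = 1e-12)
  expect_equal(sphere_volume_from_diameter(0.2), 0.00419, tolerance = 1e-3)
  expect_identical(sphere_volume_from_diameter(0), 0)
  expect_equal(sphere_volume_from_diameter(0.5), 0.0654, tolerance = 1e-3)
  expect_error(sphere_volume_from_diameter(-0.1), ">= 0")

  v <- c(1e-4, 0.004, 0.01, 0.0654)
  expect_equal(sphere_volume_from_diameter(equivalent_diameter(v)), v,
               tolerance = 1e-9)
})

test_that("the volume filter excludes strictly below the bound and keeps the bound", {
  tab <- data.frame(id = 1:3, volume_um3 = c(0.003, 0.004, 0.005))
  kept <- apply_filter(tab, puncta_filter(min_volume_um3 = 0.004,
                                          max_volume_um3 = Inf))
  expect_identical(kept$volume_um3, c(0.004, 0.005))
  expect_identical(kept$id, 2:3)                      # order preserved

  expect_identical(nrow(apply_filter(tab[0, ], puncta_filter())), 0L)
  expect_identical(apply_filter(tab, puncta_filter(0, Inf)), tab)

  # monotone in the lower bound, idempotent
  set.seed(5)
  tab2 <- data.frame(id = 1:50, volume_um3 = rlnorm(50, log(0.008), 0.6))
  counts <- vapply(seq(0, 0.02, by = 0.002), function(m)
    nrow(apply_filter(tab2, puncta_filter(m, Inf))), integer(1))
  expect_true(all(diff(counts) <= 0))
  f <- puncta_filter(0.004, 0.03)
  once <- apply_filter(tab2, f)
  expect_identical(apply_filter(once, f), once)

  expect_error(puncta_filter(0.01, 0.005), "min")
})

test_that("two puncta 0.5 um apart are split into two objects by the watershed", {
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  dims <- c(14L, 60L, 60L)
  centers <- rbind(c(0.91, 0.7, 0.65), c(0.91, 0.7, 1.15))  # (z, y, x) um
  occ <- endopipe:::cpp_raster_spheres(dims, c(sp$dz, sp$dy, sp$dx), centers,
                                       rep(0.15, 2), rep(300, 2), 3L)
  vol <- endopipe:::blur_um(occ, c(0.08, 0.08, 0.2), sp)
  tab <- detect_surface_mode(vol, sp)
  expect_identical(nrow(tab), 2L)
  expect_equal(sort(tab$cx_um), c(0.65, 1.15), tolerance = 0.08)
})

test_that("an all-zero channel yields an empty table and no spots", {
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  zero <- array(0, c(8, 20, 20))
  expect_identical(nrow(detect_surface_mode(zero, sp)), 0L)
  expect_identical(nrow(detect_spots_mode(zero, sp)), 0L)
  # uniform background: zero spots (no scale-space maxima above threshold)
  unif <- array(10, c(8, 20, 20))
  roi <- endopipe:::new_roi_mask(array(TRUE, dim(unif)), "somatodendritic", sp)
  expect_identical(nrow(detect_spots_mode(unif, sp, roi = roi)), 0L)
})

test_that("LoG scale response estimates a 300 nm punctum's diameter", {
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  dims <- c(14L, 50L, 50L)
  occ <- endopipe:::cpp_raster_spheres(dims, c(sp$dz, sp$dy, sp$dx),
                                       rbind(c(0.91, 0.75, 0.75)),
                                       0.15, 300, 3L)
  vol <- endopipe:::blur_um(occ, c(0.05, 0.05, 0.1), sp)
  spots <- detect_spots_mode(vol, sp)
  expect_identical(nrow(spots), 1L)
  expect_gte(spots$scale_um, 0.2)
  expect_lte(spots$scale_um, 0.45)
  expect_equal(c(spots$cx_um, spots$cy_um, spots$cz_um), c(0.75, 0.75, 0.91),
               tolerance = 0.08)
})

test_that("surface and spots workflows agree on a clean phantom", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  rois <- build_rois(ph)
  sp <- ph$stack$spacing
  dec <- richardson_lucy(get_channel(ph$stack, "puncta"), sp,
                         deconvolution_params(n_iterations = 10L))
  masked <- mask_channel(dec, rois$somatodendritic)
  tab <- detect_surface_mode(masked, sp, roi = rois$somatodendritic)
  spots <- detect_spots_mode(masked, sp, roi = rois$somatodendritic)
  mm <- match_modes(tab, spots, tolerance_um = 0.3)
  expect_gte(mm$matched_fraction_surface, 0.9)

  expect_identical(match_modes(tab, spots[0, ], 0.3)$matched_fraction_surface, 0)
  # zero tolerance: only exactly coincident centres can match
  mm0 <- match_modes(tab, tab[, c("cx_um", "cy_um", "cz_um")], 0)
  expect_identical(nrow(mm0$pairs), nrow(tab))

  # measured volume can never exceed the ROI volume
  expect_lte(sum(tab$volume_um3), rois$somatodendritic$volume_um3)
})

test_that("degenerate spot diameter ranges are rejected", {
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  expect_error(detect_spots_mode(array(1, c(4, 4, 4)), sp,
                                 d_range_um = c(0.5, 0.5)), "degenerate")
})
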