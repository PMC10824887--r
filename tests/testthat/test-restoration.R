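sp_iso <- voxel_spacing(0.03, 0.03, 0.13)

test_that("a blurred point source sharpens in place under Richardson-Lucy", {
  vol <- array(0, c(14, 31, 31))
  vol[7, 16, 16] <- 100
  psf <- c(0.08, 0.08, 0.2)
  blurred <- endopipe:::blur_um(vol, psf, sp_iso)
  dec <- richardson_lucy(blurred, sp_iso,
                         deconvolution_params(psf_sigma_um = psf,
                                              n_iterations = 25L))
  expect_gt(max(dec), max(blurred))                   # strictly sharper
  expect_identical(which.max(dec), which.max(blurred))  # peak stays put
  expect_true(all(dec >= 0))
})

test_that("a uniform volume is a fixed point", {
  vol <- array(5, c(10, 20, 20))
  dec <- richardson_lucy(vol, sp_iso, deconvolution_params(n_iterations = 5L))
  expect_equal(dec, vol, tolerance = 1e-6)
})

test_that("the blurred-estimate residual is non-increasing on noise-free input", {
  set.seed(3)
  obj <- array(0, c(14, 24, 24))
  obj[5:9, 8:14, 10:16] <- 50
  psf <- c(0.06, 0.06, 0.18)
  obs <- endopipe:::blur_um(obj, psf, sp_iso)
  sig_vox <- endopipe:::sigma_vox_zyx(psf, sp_iso)
  resid <- vapply(1:6, function(k) {
    est <- richardson_lucy(obs, sp_iso,
                           deconvolution_params(psf_sigma_um = psf,
                                                n_iterations = k))
    sqrt(sum((endopipe:::cpp_blur3(est, sig_vox) - obs)^2))
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-8))
})

test_that("total intensity is conserved for interior signal", {
  set.seed(11)
  vol <- array(0, c(14, 40, 40))
  vol[6:9, 15:25, 15:25] <- runif(4 * 11 * 11, 10, 60)
  dec <- richardson_lucy(vol, sp_iso, deconvolution_params(n_iterations = 10L))
  expect_equal(sum(dec), sum(vol), tolerance = 0.01)
})

test_that("deconvolution with the matched PSF shrinks an isolated punctum's FWHM by >= 20%", {
  sp <- small_phantom_spec(seed = 9)
  sp$puncta_count_somatodendritic <- 1L
  sp$puncta_count_perinuclear <- 0L
  sp$psf_sigma_um <- c(0.1, 0.1, 0.3)
  # a 200 nm punctum: small against the PSF, so restoration can shrink its
  # apparent width well below the 20% bar (a 400 nm one could not: its true
  # FWHM is already 86% of the blurred one)
  sp$puncta_volume_law$meanlog <- log(sphere_volume_from_diameter(0.2))
  sp$puncta_volume_law$sdlog <- 1e-4
  ph <- generate_phantom(sp)
  ch <- get_channel(ph$stack, "puncta")
  dec <- richardson_lucy(ch, ph$stack$spacing,
                         deconvolution_params(psf_sigma_um = c(0.1, 0.1, 0.3),
                                              n_iterations = 30L))
  fwhm_x <- function(vol) {
    pk <- arrayInd(which.max(vol), dim(vol))
    prof <- vol[pk[1], pk[2], ]
    sum(prof >= max(prof) / 2) * ph$stack$spacing$dx
  }
  expect_lte(fwhm_x(dec), 0.8 * fwhm_x(ch))
})

test_that("invalid inputs are rejected", {
  vol <- array(1, c(6, 6, 6))
  vol[1] <- -1
  expect_error(richardson_lucy(vol, sp_iso), "negative")
  expect_error(deconvolution_params(n_iterations = 0), "n_iterations")
  expect_error(richardson_lucy(array(1, c(4, 4, 4)), sp_iso,
                               deconvolution_params(psf_sigma_um = c(1, 1, 1))),
               "wider")
})
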