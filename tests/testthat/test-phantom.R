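test_that("identical spec and seed reproduce the stack bit for bit", {
  a <- generate_phantom(default_phantom_spec(seed = 7))
  b <- generate_phantom(default_phantom_spec(seed = 7))
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_identical(a$truth$puncta, b$truth$puncta)

  c <- generate_phantom(default_phantom_spec(seed = 8))
  expect_false(identical(a$stack$intensities, c$stack$intensities))
})

test_that("default spec states the published acquisition geometry", {
  sp <- default_phantom_spec()
  expect_identical(sp$profile$n_z, 14L)
  expect_equal(sp$profile$spacing$dz, 0.13)
  expect_equal(sp$profile$spacing$dx, 0.03)
  expect_equal(sp$profile$spacing$dy, 0.03)
  expect_equal(sp$puncta_volume_law$d_range_nm, c(100, 500))
})

test_that("zero puncta leaves an empty truth table and a puncta channel of background only", {
  sp <- small_phantom_spec(seed = 2)
  sp$puncta_count_somatodendritic <- 0L
  sp$puncta_count_perinuclear <- 0L
  ph <- generate_phantom(sp)
  expect_identical(nrow(ph$truth$puncta), 0L)
  # no granules, no noise in this spec: channel must be exactly zero
  expect_equal(max(get_channel(ph$stack, "puncta")), 0)
})

test_that("every true punctum centre lies inside its compartment mask", {
  for (s in 1:3) {
    ph <- generate_phantom(small_phantom_spec(seed = s))
    tr <- ph$truth
    sp <- ph$stack$spacing
    vz <- cbind(floor(tr$puncta$cz_um / sp$dz), floor(tr$puncta$cy_um / sp$dy),
                floor(tr$puncta$cx_um / sp$dx)) + 1
    inside <- vapply(seq_len(nrow(vz)), function(i) {
      m <- if (tr$puncta$compartment[i] == "somatodendritic")
        tr$masks$somatodendritic_compartment else tr$masks$perinuclear_compartment
      m[vz[i, 1], vz[i, 2], vz[i, 3]]
    }, logical(1))
    expect_true(all(inside))
    expect_identical(nrow(tr$puncta),
                     ph$truth$spec$puncta_count_somatodendritic +
                       ph$truth$spec$puncta_count_perinuclear)
  }
})

test_that("sampled volumes follow the truncated log-normal law", {
  law <- default_phantom_spec()$puncta_volume_law
  set.seed(99)
  v <- endopipe:::draw_volumes(10000L, law)
  lv <- log(v)
  # truncation at ~+/-4 sigma barely moves the first two moments
  expect_lt(abs(mean(lv) - law$meanlog), 3 * law$sdlog / sqrt(length(v)))
  expect_lt(abs(sd(lv) - law$sdlog), 3 * law$sdlog / sqrt(2 * length(v)))
  d <- (6 * v / pi)^(1 / 3)
  expect_true(all(d >= 0.1 - 1e-12 & d <= 0.5 + 1e-12))
})

test_that("the puncta channel conserves flux: integrated intensity tracks total true volume", {
  sp <- small_phantom_spec(seed = 4)
  sp$autofluorescence$n_granules <- 0L     # isolate the puncta signal
  ph <- generate_phantom(sp)
  flux <- sum(get_channel(ph$stack, "puncta"))
  vox_vol <- with(ph$stack$spacing, dx * dy * dz)
  expected <- sum(ph$truth$puncta$volume_um3) / vox_vol * sp$amplitudes$puncta
  expect_equal(flux, expected, tolerance = 0.05)
})

test_that("Thomas-process clustering stays inside the compartment", {
  sp <- small_phantom_spec(seed = 6)
  sp$clustering <- list(n_parents = 3L, sigma_um = 0.3)
  sp$min_separation_um <- 0
  ph <- generate_phantom(sp)
  tr <- ph$truth
  spx <- ph$stack$spacing
  p <- tr$puncta[tr$puncta$compartment == "somatodendritic", ]
  vz <- cbind(floor(p$cz_um / spx$dz), floor(p$cy_um / spx$dy),
              floor(p$cx_um / spx$dx)) + 1
  inside <- vapply(seq_len(nrow(vz)), function(i)
    tr$masks$somatodendritic_compartment[vz[i, 1], vz[i, 2], vz[i, 3]],
    logical(1))
  expect_true(all(inside))
})

test_that("impossible placement requests fail loudly, not silently", {
  sp <- small_phantom_spec(seed = 1)
  sp$puncta_count_somatodendritic <- 500L   # cannot fit at 0.5 um separation
  expect_error(generate_phantom(sp), "unable to place")
})
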