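test_that("Nyquist QC passes the reference acquisition and is monotone in pixel size", {
  prof <- acquisition_profile()          # 0.03 um lateral, resolution 0.2 um
  qc <- check_nyquist(prof)
  expect_true(qc$pass)
  expect_equal(unname(qc$factors["x"]), 0.2 / 0.03, tolerance = 1e-12)

  coarse <- acquisition_profile(spacing = voxel_spacing(0.15, 0.15, 0.13))
  expect_false(check_nyquist(coarse)$pass)

  boundary <- acquisition_profile(spacing = voxel_spacing(0.2, 0.2, 0.13),
                                  min_oversampling_factor = 1)
  expect_true(check_nyquist(boundary)$pass)

  # increasing dx can never turn a fail into a pass
  dxs <- seq(0.02, 0.3, by = 0.02)
  passes <- vapply(dxs, function(dx)
    check_nyquist(acquisition_profile(spacing = voxel_spacing(dx, dx, 0.13)))$pass,
    logical(1))
  expect_true(all(diff(passes) <= 0))

  expect_error(check_nyquist(acquisition_profile(lateral_resolution_um = -1)),
               "resolution")
})

test_that("spacing and stack constructors enforce their invariants", {
  expect_error(voxel_spacing(0, 0.03, 0.13), "positive")
  expect_error(voxel_spacing(0.03, 0.03, -1), "positive")
  expect_error(channel_roles(1, 1, 2), "distinct")

  arr <- array(1, dim = c(3, 1, 4, 4))
  expect_error(image_stack(arr, voxel_spacing(0.03, 0.03, 0.13)), "z-stack")
  arr <- array(1, dim = c(2, 3, 4, 4))
  expect_error(image_stack(arr, voxel_spacing(0.03, 0.03, 0.13),
                           roles = channel_roles()), "3 channels")
  arr <- array(-1, dim = c(3, 3, 4, 4))
  expect_error(image_stack(arr, voxel_spacing(0.03, 0.03, 0.13)),
               "non-negative")
})

test_that("stacks round-trip through OME-TIFF with spacing metadata intact", {
  set.seed(42)
  arr <- array(sample.int(4096L, 3 * 4 * 8 * 6, replace = TRUE) - 1L,
               dim = c(3, 4, 8, 6))
  st <- image_stack(arr, voxel_spacing(0.03, 0.03, 0.13), channel_roles(),
                    case_id = "c1", image_id = "i1")
  path <- tempfile(fileext = ".ome.tif")
  write_stack(st, path)
  rt <- read_stack(path, roles = channel_roles())
  expect_identical(dim(rt$intensities), dim(st$intensities))
  expect_equal(rt$intensities, st$intensities)   # integer data: bit-exact
  expect_equal(rt$spacing$dx, 0.03, tolerance = 1e-6)
  expect_equal(rt$spacing$dz, 0.13, tolerance = 1e-6)

  # metadata beats a user override, with a warning
  expect_warning(read_stack(path, roles = channel_roles(),
                            spacing_override = voxel_spacing(1, 1, 1)),
                 "OME")
})

test_that("read_stack rejects degenerate inputs with clear errors", {
  expect_error(read_stack(tempfile(fileext = ".tif")), "not found")

  # plain TIFF without metadata and without an override
  path <- tempfile(fileext = ".tif")
  endopipe:::tiff_write(path, list(matrix(1L, 4, 4), matrix(2L, 4, 4)), bits = 16L)
  expect_error(read_stack(path), "no voxel spacing")
  st <- read_stack(path, spacing_override = voxel_spacing(0.03, 0.03, 0.13))
  expect_equal(dim(st$intensities)[2], 2L)

  # single plane is not a z-stack
  path1 <- tempfile(fileext = ".tif")
  endopipe:::tiff_write(path1, list(matrix(1L, 4, 4)), bits = 16L)
  expect_error(read_stack(path1, spacing_override = voxel_spacing(0.03, 0.03, 0.13)),
               "z-stack required")
})

test_that("masks round-trip bit-exactly and empty masks stay empty", {
  sp <- voxel_spacing(0.03, 0.03, 0.13)
  set.seed(7)
  vox <- array(runif(14 * 16 * 16) > 0.7, dim = c(14, 16, 16))
  path <- tempfile(fileext = ".tif")
  write_mask(vox, path, spacing = sp)
  rt <- read_mask(path, role = "somatodendritic")
  expect_identical(rt$voxels, vox)
  expect_equal(rt$volume_um3, sum(vox) * 0.03 * 0.03 * 0.13, tolerance = 1e-12)

  write_mask(array(FALSE, c(3, 4, 4)), path, spacing = sp)
  expect_equal(sum(read_mask(path, "perinuclear")$voxels), 0L)
})

test_that("written TIFFs are readable by an independent reader (tifffile)", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  path <- tempfile(fileext = ".ome.tif")
  write_stack(ph$stack, path)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- paste(
    "import tifffile, numpy, sys",
    sprintf("a = tifffile.imread(%s)", deparse(path)),
    "print(a.dtype, a.shape, int(a.sum()))",
    sep = "\n")
  out <- system2(py, "-", input = script, stdout = TRUE)
  expect_match(out[1], "^uint16")
  d <- dim(ph$stack$intensities)
  expect_match(out[1], sprintf("(%d, %d, %d)", d[1] * d[2], d[3], d[4]),
               fixed = TRUE)
  expect_equal(as.numeric(sub(".*\\) ", "", out[1])),
               sum(round(ph$stack$intensities)))
})
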