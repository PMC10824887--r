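#' Physical voxel spacing
#'
#' Micrometres per voxel along x, y and z. Anisotropy is permitted and
#' typical for confocal stacks (the reference acquisition uses
#' 0.03 x 0.03 x 0.13 um).
#'
#' @param dx,dy,dz micrometres per voxel; all strictly positive.
#' @return An object of class `voxel_spacing`.
#' @export
voxel_spacing <- function(dx, dy, dz) {
  if (any(!is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stopf("voxel spacing must be strictly positive and finite")
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: %.4g x %.4g x %.4g um (x, y, z)\n",
              x$dx, x$dy, x$dz))
  invisible(x)
}

#' Channel role map
#'
#' Maps the three analysis roles to channel indices (1-based) so the
#' pipeline stays marker-agnostic: any nuclear stain / somatodendritic
#' marker / punctate vesicle marker combination works (DAPI + MAP2 + EEA1,
#' DAPI + MAP2 + SORLA, ...).
#'
#' @param nuclear,somatodendritic,puncta 1-based channel indices; distinct.
#' @return An object of class `channel_roles`.
#' @export
channel_roles <- function(nuclear = 1L, somatodendritic = 2L, puncta = 3L) {
  idx <- c(nuclear, somatodendritic, puncta)
  if (any(idx < 1) || anyDuplicated(idx))
    stopf("channel role indices must be distinct and >= 1")
  structure(list(nuclear = as.integer(nuclear),
                 somatodendritic = as.integer(somatodendritic),
                 puncta = as.integer(puncta)),
            class = "channel_roles")
}

#' Acquisition profile
#'
#' Describes the stack geometry plus the optical scale used by the
#' Nyquist-sampling check. Defaults reproduce the reference confocal
#' acquisition (14 z-planes of 0.13 um at 0.03 um lateral pixels); the
#' lateral resolution default (0.2 um, diffraction scale for a 1.4 NA lens
#' at green emission) is this package's own choice and only feeds the QC.
#'
#' @param plane_shape integer (ny, nx) pixels per plane.
#' @param n_z number of z planes (>= 2).
#' @param spacing a [voxel_spacing()].
#' @param lateral_resolution_um optics-limited smallest resolvable object.
#' @param min_oversampling_factor required samples per resolvable distance
#'   in x and y (>= 1); the protocol guideline is 2.
#' @return An object of class `acquisition_profile`.
#' @export
acquisition_profile <- function(plane_shape = c(256L, 256L), n_z = 14L,
                                spacing = voxel_spacing(0.03, 0.03, 0.13),
                                lateral_resolution_um = 0.2,
                                min_oversampling_factor = 2) {
  if (n_z < 2) stopf("n_z must be >= 2 (z-stack required)")
  if (min_oversampling_factor < 1) stopf("min_oversampling_factor must be >= 1")
  structure(list(plane_shape = as.integer(plane_shape), n_z = as.integer(n_z),
                 spacing = spacing,
                 lateral_resolution_um = lateral_resolution_um,
                 min_oversampling_factor = min_oversampling_factor),
            class = "acquisition_profile")
}

#' Nyquist oversampling QC
#'
#' Passes when the lateral pixel size oversamples the smallest resolvable
#' object by at least `min_oversampling_factor` in both x and y
#' (resolution / pixel size >= factor). Increasing the pixel size can only
#' move a pass towards fail.
#'
#' @param profile an [acquisition_profile()].
#' @return A list with `pass`, per-axis `factors`, and the inputs used.
#' @export
check_nyquist <- function(profile) {
  res <- profile$lateral_resolution_um
  if (!is.finite(res) || res <= 0) stopf("lateral resolution must be > 0")
  fx <- res / profile$spacing$dx
  fy <- res / profile$spacing$dy
  need <- profile$min_oversampling_factor
  structure(list(pass = (fx >= need) && (fy >= need),
                 factors = c(x = fx, y = fy),
                 required = need, lateral_resolution_um = res),
            class = "nyquist_qc")
}

#' @export
print.nyquist_qc <- function(x, ...) {
  cat(sprintf("Nyquist QC: %s (x %.2fx, y %.2fx; required %.2gx)\n",
              if (x$pass) "PASS" else "FAIL",
              x$factors[["x"]], x$factors[["y"]], x$required))
  invisible(x)
}

#' Multichannel 3-D image stack
#'
#' The in-memory container for a z-stack: a 4-D intensity array in fixed
#' (channel, z, y, x) axis order, the physical voxel spacing, the channel
#' role map and case/image identifiers.
#'
#' @param intensities 4-D non-negative finite array (channel, z, y, x).
#' @param spacing a [voxel_spacing()].
#' @param roles a [channel_roles()] or NULL.
#' @param case_id,image_id identifiers carried into all tabular output.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, spacing, roles = NULL,
                        case_id = "case", image_id = "image") {
  d <- dim(intensities)
  if (length(d) != 4) stopf("intensities must be a 4-D (channel, z, y, x) array")
  if (d[2] < 2) stopf("z-stack required (>= 2 z planes)")
  if (any(!is.finite(intensities))) stopf("intensities must be finite")
  if (any(intensities < 0)) stopf("intensities must be non-negative")
  if (!is.null(roles)) {
    if (d[1] < 3) stopf("at least 3 channels required when roles are assigned")
    if (max(roles$nuclear, roles$somatodendritic, roles$puncta) > d[1])
      stopf("channel role index out of range (stack has %d channels)", d[1])
  }
  structure(list(intensities = intensities, spacing = spacing, roles = roles,
                 case_id = case_id, image_id = image_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack '%s/%s': %d channel(s), %d x %d x %d (z,y,x) voxels\n",
              x$case_id, x$image_id, d[1], d[2], d[3], d[4]))
  print(x$spacing)
  invisible(x)
}

#' Extract one channel as a 3-D (z, y, x) volume
#'
#' @param stack an [image_stack()].
#' @param channel integer index or one of "nuclear", "somatodendritic",
#'   "puncta" (resolved through the stack's role map).
#' @return 3-D numeric array.
#' @export
get_channel <- function(stack, channel) {
  if (is.character(channel)) {
    if (is.null(stack$roles)) stopf("stack has no channel role map")
    channel <- stack$roles[[match.arg(channel,
      c("nuclear", "somatodendritic", "puncta"))]]
  }
  d <- dim(stack$intensities)
  if (channel < 1 || channel > d[1]) stopf("channel index out of range")
  v <- stack$intensities[channel, , , , drop = TRUE]
  dim(v) <- d[2:4]
  v
}

#' Read a multichannel z-stack from TIFF / OME-TIFF
#'
#' Planes are reassembled into the package's fixed (channel, z, y, x) axis
#' order. Voxel spacing is taken from OME metadata in the ImageDescription
#' when present; otherwise `spacing_override` is used. When both are
#' available the file metadata wins, with a warning. Channel/z layout
#' comes from OME SizeC/SizeZ (plane order C fastest, as in DimensionOrder
#' XYCZT); without metadata, `n_channels` decides.
#'
#' @param path TIFF file path.
#' @param roles a [channel_roles()] or NULL.
#' @param spacing_override optional [voxel_spacing()] used when the file
#'   carries no spacing metadata.
#' @param n_channels channel count fallback for plain TIFFs (default 1).
#' @param case_id,image_id identifiers attached to the stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, roles = NULL, spacing_override = NULL,
                       n_channels = 1L, case_id = "case",
                       image_id = sub("\\.[^.]*$", "", basename(path))) {
  tf <- tiff_read(path)
  meta <- parse_ome_description(tf$description)
  if (!is.null(meta) && all(is.finite(c(meta$dx, meta$dy, meta$dz)))) {
    if (!is.null(spacing_override))
      warning("file carries OME voxel spacing; ignoring spacing_override",
              call. = FALSE)
    spacing <- voxel_spacing(meta$dx, meta$dy, meta$dz)
  } else if (!is.null(spacing_override)) {
    spacing <- spacing_override
  } else {
    stopf("no voxel spacing: file has no OME metadata and no spacing_override given")
  }
  nc <- if (!is.null(meta) && !is.na(meta$size_c %||% NA)) meta$size_c else as.integer(n_channels)
  n_planes <- length(tf$planes)
  if (n_planes %% nc != 0)
    stopf("plane count %d not divisible by channel count %d", n_planes, nc)
  nz <- n_planes %/% nc
  if (nz < 2) stopf("z-stack required (>= 2 z planes), got %d", nz)
  ny <- nrow(tf$planes[[1]]); nx <- ncol(tf$planes[[1]])
  arr <- array(0, dim = c(nc, nz, ny, nx))
  for (p in seq_len(n_planes)) {
    ch <- (p - 1L) %% nc + 1L       # C fastest (XYCZT)
    z <- (p - 1L) %/% nc + 1L
    arr[ch, z, , ] <- tf$planes[[p]]
  }
  image_stack(arr, spacing, roles = roles, case_id = case_id,
              image_id = image_id)
}

#' Write a stack as 16-bit OME-TIFF
#'
#' Intensities are rounded and clipped to the unsigned 16-bit range; voxel
#' spacing and channel/z layout are recorded in an OME-style
#' ImageDescription so [read_stack()] round-trips without an override.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$intensities)
  planes <- vector("list", d[1] * d[2])
  for (z in seq_len(d[2])) for (ch in seq_len(d[1])) {
    m <- stack$intensities[ch, z, , ]
    dim(m) <- d[3:4]
    planes[[(z - 1L) * d[1] + ch]] <- m
  }
  desc <- ome_description(d[1], d[2], d[3], d[4], stack$spacing, bits = 16L)
  tiff_write(path, planes, bits = 16L, description = desc)
  invisible(path)
}

#' Write a binary ROI mask as 8-bit TIFF
#'
#' 0 = outside, 255 = inside; one page per z plane. The mask's voxel
#' spacing is embedded so the file can be re-read (possibly after hand
#' editing in an external tool) without extra metadata. Round-trips
#' bit-exactly through [read_mask()].
#'
#' @param mask a [roi_mask] (see [segment_somatodendritic()]) or a logical
#'   3-D (z, y, x) array (then `spacing` is required).
#' @param path output file path.
#' @param spacing required when `mask` is a bare array.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = NULL) {
  if (inherits(mask, "roi_mask")) {
    vox <- mask$voxels
    spacing <- mask$spacing
  } else {
    vox <- mask
    if (is.null(spacing)) stopf("spacing required for a bare mask array")
  }
  d <- dim(vox)
  planes <- lapply(seq_len(d[1]), function(z) {
    m <- ifelse(vox[z, , ], 255L, 0L)
    dim(m) <- d[2:3]
    m
  })
  desc <- ome_description(1L, d[1], d[2], d[3], spacing, bits = 8L)
  tiff_write(path, planes, bits = 8L, description = desc)
  invisible(path)
}

#' Read a binary ROI mask written by [write_mask()] (or hand-edited)
#'
#' Any strictly positive voxel counts as inside, so masks edited in image
#' tools that paint with other values still load.
#'
#' @param path TIFF file path.
#' @param role "somatodendritic" or "perinuclear".
#' @param spacing_override spacing fallback for files without metadata.
#' @return A [roi_mask] object.
#' @export
read_mask <- function(path, role = c("somatodendritic", "perinuclear"),
                      spacing_override = NULL) {
  role <- match.arg(role)
  tf <- tiff_read(path)
  meta <- parse_ome_description(tf$description)
  if (!is.null(meta) && all(is.finite(c(meta$dx, meta$dy, meta$dz)))) {
    spacing <- voxel_spacing(meta$dx, meta$dy, meta$dz)
  } else if (!is.null(spacing_override)) {
    spacing <- spacing_override
  } else {
    stopf("no voxel spacing available for mask %s", path)
  }
  nz <- length(tf$planes)
  ny <- nrow(tf$planes[[1]]); nx <- ncol(tf$planes[[1]])
  vox <- array(FALSE, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) vox[z, , ] <- tf$planes[[z]] > 0
  new_roi_mask(vox, role, spacing,
               provenance = list(source = "file", path = path))
}
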