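# Internal helpers shared across modules.

# volumes are 3-D arrays dim (nz, ny, nx); voxel (i,j,k) 0-based has its
# physical centre at ((i+.5)*dz, (j+.5)*dy, (k+.5)*dx) micrometres.

vox_volume <- function(spacing) spacing$dx * spacing$dy * spacing$dz

# spacing along array axes (z, y, x)
spacing_zyx <- function(spacing) c(spacing$dz, spacing$dy, spacing$dx)

# per-axis sigma in voxels from physical sigma given in (x, y, z) order
sigma_vox_zyx <- function(sigma_um_xyz, spacing) {
  c(sigma_um_xyz[3] / spacing$dz,
    sigma_um_xyz[2] / spacing$dy,
    sigma_um_xyz[1] / spacing$dx)
}

blur_um <- function(vol, sigma_um_xyz, spacing) {
  cpp_blur3(vol, sigma_vox_zyx(sigma_um_xyz, spacing))
}

# isotropic-in-micrometres binary morphology via the exact EDT
dilate_um <- function(mask, r_um, spacing) {
  if (r_um <= 0) return(mask)
  d <- cpp_edt3(mask, spacing_zyx(spacing))
  out <- d <= r_um
  dim(out) <- dim(mask)
  out
}

erode_um <- function(mask, r_um, spacing) {
  if (r_um <= 0) return(mask)
  d <- cpp_edt3(!mask, spacing_zyx(spacing))
  out <- mask & (d > r_um)
  dim(out) <- dim(mask)
  out
}

close_um <- function(mask, r_um, spacing) {
  if (r_um <= 0) return(mask)
  erode_um(dilate_um(mask, r_um, spacing), r_um, spacing)
}

# Otsu's threshold on a numeric vector (256-bin histogram, deterministic).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(n_bins, floor((x - lo) / (hi - lo) * n_bins) + 1L),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  centers[which.max(between)]
}

# voxel-centre coordinate grids (micrometres) for a (nz, ny, nx) volume
coord_grid <- function(dim_zyx, spacing) {
  list(z = (seq_len(dim_zyx[1]) - 0.5) * spacing$dz,
       y = (seq_len(dim_zyx[2]) - 0.5) * spacing$dy,
       x = (seq_len(dim_zyx[3]) - 0.5) * spacing$dx)
}

# convert 0-based (z, y, x) voxel coordinates to physical micrometres
vox_to_um <- function(zyx, spacing) {
  cbind(z = (zyx[, 1] + 0.5) * spacing$dz,
        y = (zyx[, 2] + 0.5) * spacing$dy,
        x = (zyx[, 3] + 0.5) * spacing$dx)
}

# linear (1-based) index -> 0-based (z, y, x) voxel coordinates
lin_to_zyx <- function(idx, dim_zyx) {
  idx0 <- idx - 1
  z <- idx0 %% dim_zyx[1]
  y <- (idx0 %/% dim_zyx[1]) %% dim_zyx[2]
  x <- idx0 %/% (dim_zyx[1] * dim_zyx[2])
  cbind(z = z, y = y, x = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
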