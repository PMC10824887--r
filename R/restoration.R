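# Richardson-Lucy deconvolution.
#
# The reference images were restored by a proprietary adaptive confocal
# deconvolution on the acquisition side; its internals are not published, so
# this module provides a classical Richardson-Lucy stage with a Gaussian
# PSF as a documented stand-in. It is optional and bypassable: every
# downstream module behaves identically whether the stage ran or not.

#' Deconvolution parameters
#'
#' @param psf_sigma_um Gaussian PSF sigma (x, y, z) in micrometres.
#' @param n_iterations Richardson-Lucy iterations (>= 1; default 20 --
#'   there is no published iteration count to copy).
#' @param clip_negative clamp tiny negative excursions to 0 after the last
#'   iteration (RL itself preserves non-negativity; this guards rounding).
#' @return An object of class `deconvolution_params`.
#' @export
deconvolution_params <- function(psf_sigma_um = c(0.08, 0.08, 0.2),
                                 n_iterations = 20L,
                                 clip_negative = TRUE) {
  if (any(psf_sigma_um <= 0)) stopf("PSF sigmas must be > 0")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  structure(list(psf_sigma_um = psf_sigma_um,
                 n_iterations = as.integer(n_iterations),
                 clip_negative = clip_negative),
            class = "deconvolution_params")
}

#' Richardson-Lucy deconvolution of one channel volume
#'
#' Multiplicative RL updates with a separable Gaussian PSF (reflective
#' edge handling, flux-conserving): `estimate <- estimate * blur(observed /
#' blur(estimate))`. Starting point is the observed volume. With
#' noise-free input the blurred-estimate residual is non-increasing over
#' iterations, non-negativity is preserved throughout, and a uniform
#' volume is a fixed point.
#'
#' @param vol non-negative 3-D (z, y, x) intensity array.
#' @param spacing a [voxel_spacing()] (PSF sigmas are physical um).
#' @param params a [deconvolution_params()].
#' @return Deconvolved array, same shape, non-negative.
#' @export
richardson_lucy <- function(vol, spacing, params = deconvolution_params()) {
  if (any(vol < 0)) stopf("negative input values")
  sig_vox <- sigma_vox_zyx(params$psf_sigma_um, spacing)
  if (any(4 * sig_vox >= dim(vol)))
    stopf("PSF wider than the volume (sigma %s voxels vs dims %s)",
          paste(signif(sig_vox, 3), collapse = "x"),
          paste(dim(vol), collapse = "x"))
  eps <- 1e-12
  est <- vol
  for (it in seq_len(params$n_iterations)) {
    blurred <- cpp_blur3(est, sig_vox)
    ratio <- vol / pmax(blurred, eps)
    dim(ratio) <- dim(vol)
    est <- est * cpp_blur3(ratio, sig_vox)   # Gaussian PSF is symmetric
  }
  if (isTRUE(params$clip_negative)) est <- pmax(est, 0)
  dim(est) <- dim(vol)
  est
}
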