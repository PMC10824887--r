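# Synthetic confocal phantom generator.
#
# Emulates the reference acquisition: a 14-plane anisotropic z-stack
# (0.03 x 0.03 x 0.13 um voxels) through one MAP2+ pyramidal soma with a
# proximal dendrite, a neuronal nucleus with low-order surface
# invaginations plus distractor nuclei, disconnected neurite fragments in
# the surrounding neuropil, sub-resolution puncta (100-500 nm) with a
# right-skewed (log-normal) volume law split between a somatodendritic and
# a perinuclear compartment, lipofuscin-like autofluorescent granules that
# bleed into all channels, Gaussian PSF blur, Poisson shot noise and
# Gaussian read noise. Every run is fully determined by (spec, seed).

#' Phantom specification
#'
#' All geometry is in physical micrometres. Defaults state a desk-scale
#' version of the reference acquisition: the 1256 x 1256 plane is shrunk
#' to 256 x 256 at identical voxel spacing and z geometry (14 planes of
#' 0.13 um), and the puncta volume law is a log-normal over um^3 truncated
#' to the 100-500 nm electron-microscopy diameter range.
#'
#' @param profile an [acquisition_profile()].
#' @param soma list: ellipsoid `semi_axes_um` (x, y, z) and `center_um`
#'   (x, y, z; NULL = placed automatically left-of-centre).
#' @param dendrite list: `radius_um`, `length_um` beyond the soma surface,
#'   `taper` (fractional radius loss at the tip), orientation fixed +x.
#' @param nucleus list: `semi_axes_um` and `invagination_amplitude`
#'   (fractional low-order spherical-harmonic perturbation of the surface).
#' @param n_distractor_nuclei,n_disconnected_neurites distractor counts.
#' @param puncta_count_somatodendritic,puncta_count_perinuclear true
#'   puncta per compartment.
#' @param puncta_volume_law list `meanlog`, `sdlog` (log um^3) and
#'   `d_range_nm` truncation (admissible sphere diameters).
#' @param clustering NULL for uniform placement, or a Thomas-process
#'   list `n_parents`, `sigma_um`.
#' @param min_separation_um minimum centre-to-centre distance enforced
#'   between all placed puncta (0 = unconstrained clustering allowed).
#' @param placement_margin_um minimum distance of puncta centres from the
#'   boundary of their compartment.
#' @param perinuclear_shell_um thickness of the shell outside the nucleus
#'   surface in which perinuclear puncta live.
#' @param compartment_gap_um buffer between the perinuclear shell and the
#'   somatodendritic compartment so ground-truth ROI membership stays
#'   unambiguous at segmented-ROI boundaries.
#' @param autofluorescence list `n_granules`, `radius_um` and per-channel
#'   `bleed` fractions of the puncta amplitude.
#' @param amplitudes expected photon counts: per-channel structure
#'   amplitudes and the puncta amplitude per fully occupied voxel.
#' @param psf_sigma_um Gaussian PSF sigma (x, y, z).
#' @param noise list `enabled`, `photon_scale` (Poisson at
#'   lambda = photon_scale * signal, rescaled back) and `read_sd`.
#' @param seed integer seed; identical (spec, seed) gives bit-identical
#'   stacks and truth.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(
    profile = acquisition_profile(),
    soma = list(semi_axes_um = c(2.7, 2.7, 0.85), center_um = NULL),
    dendrite = list(radius_um = 0.35, length_um = 2.2, taper = 0.4),
    nucleus = list(semi_axes_um = c(1.1, 1.1, 0.55),
                   invagination_amplitude = 0.12),
    n_distractor_nuclei = 2L,
    n_disconnected_neurites = 3L,
    puncta_count_somatodendritic = 25L,
    puncta_count_perinuclear = 8L,
    puncta_volume_law = list(meanlog = log(0.008), sdlog = 0.5,
                             d_range_nm = c(100, 500)),
    clustering = NULL,
    min_separation_um = 0,
    placement_margin_um = 0.2,
    perinuclear_shell_um = 0.3,
    compartment_gap_um = 0.25,
    autofluorescence = list(n_granules = 4L, radius_um = 0.3,
                            bleed = c(nuclear = 0.05, somatodendritic = 0.05,
                                      puncta = 0.15)),
    amplitudes = list(nuclear = 150, somatodendritic = 120, puncta = 300,
                      granule = 300),
    psf_sigma_um = c(0.08, 0.08, 0.2),
    noise = list(enabled = TRUE, photon_scale = 1, read_sd = 2),
    seed = 1L) {
  if (puncta_volume_law$sdlog <= 0) stopf("sdlog must be > 0")
  dr <- puncta_volume_law$d_range_nm
  if (dr[1] >= dr[2]) stopf("diameter range must satisfy d_min < d_max")
  if (any(psf_sigma_um <= 0)) stopf("PSF sigmas must be > 0")
  counts <- c(n_distractor_nuclei, n_disconnected_neurites,
              puncta_count_somatodendritic, puncta_count_perinuclear,
              autofluorescence$n_granules)
  if (any(counts < 0)) stopf("counts must be >= 0")
  structure(list(profile = profile, soma = soma, dendrite = dendrite,
                 nucleus = nucleus,
                 n_distractor_nuclei = as.integer(n_distractor_nuclei),
                 n_disconnected_neurites = as.integer(n_disconnected_neurites),
                 puncta_count_somatodendritic = as.integer(puncta_count_somatodendritic),
                 puncta_count_perinuclear = as.integer(puncta_count_perinuclear),
                 puncta_volume_law = puncta_volume_law,
                 clustering = clustering,
                 min_separation_um = min_separation_um,
                 placement_margin_um = placement_margin_um,
                 perinuclear_shell_um = perinuclear_shell_um,
                 compartment_gap_um = compartment_gap_um,
                 autofluorescence = autofluorescence,
                 amplitudes = amplitudes,
                 psf_sigma_um = psf_sigma_um,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom specification
#'
#' @param seed integer seed.
#' @return A [phantom_spec()] with all defaults.
#' @export
default_phantom_spec <- function(seed = 1L) phantom_spec(seed = seed)

# truncated log-normal volume draw (rejection; vectorised rounds)
draw_volumes <- function(n, law) {
  if (n == 0) return(numeric(0))
  v_lo <- sphere_volume_from_diameter(law$d_range_nm[1] / 1000)
  v_hi <- sphere_volume_from_diameter(law$d_range_nm[2] / 1000)
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    draw <- rlnorm(2 * n + 16, law$meanlog, law$sdlog)
    out <- c(out, draw[draw >= v_lo & draw <= v_hi])
    guard <- guard + 1
    if (guard > 1000) stopf("volume law rejection sampling failed; check truncation range")
  }
  out[seq_len(n)]
}

# sample `n` points uniformly over TRUE voxels of `mask` (+ in-voxel jitter),
# keeping >= min_sep from each other and from `existing` (matrix z,y,x um)
sample_in_mask <- function(n, mask, spacing, min_sep, existing = NULL,
                           cluster = NULL, what = "punctum") {
  if (n == 0) return(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("z", "y", "x"))))
  cand <- which(mask)
  if (length(cand) == 0) stopf("empty placement compartment for %s", what)
  d <- dim(mask)
  centers <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("z", "y", "x")))
  acc <- if (is.null(existing)) matrix(numeric(0), 0, 3) else existing

  parents <- NULL
  if (!is.null(cluster)) {
    pidx <- cand[sample.int(length(cand), cluster$n_parents, replace = TRUE)]
    parents <- vox_to_um(lin_to_zyx(pidx, d), spacing)
  }
  sp <- spacing_zyx(spacing)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      if (is.null(parents)) {
        idx <- cand[sample.int(length(cand), 1L)]
        p <- vox_to_um(lin_to_zyx(idx, d), spacing)[1, ] +
          runif(3, -0.5, 0.5) * sp
      } else {
        par <- parents[sample.int(nrow(parents), 1L), ]
        p <- par + rnorm(3, 0, cluster$sigma_um)
        vz <- floor(p / sp)
        if (any(vz < 0) || any(vz >= d)) next
        if (!mask[vz[1] + 1, vz[2] + 1, vz[3] + 1]) next
      }
      if (min_sep > 0 && nrow(acc) > 0) {
        if (min(sqrt(colSums((t(acc) - p)^2))) < min_sep) next
      }
      centers[i, ] <- p
      acc <- rbind(acc, p)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("unable to place %s %d within its compartment after max retries",
            what, i)
  }
  centers
}

# ellipsoid voxel mask with optional low-order angular surface perturbation
ellipsoid_mask <- function(dim_zyx, spacing, center_xyz, semi_xyz,
                           invagination = 0) {
  g <- coord_grid(dim_zyx, spacing)
  uz <- (g$z - center_xyz[3]) / semi_xyz[3]
  uy <- (g$y - center_xyz[2]) / semi_xyz[2]
  ux <- (g$x - center_xyz[1]) / semi_xyz[1]
  UZ <- array(rep(uz, times = dim_zyx[2] * dim_zyx[3]), dim = dim_zyx)
  UY <- array(rep(rep(uy, each = dim_zyx[1]), times = dim_zyx[3]), dim = dim_zyx)
  UX <- array(rep(ux, each = dim_zyx[1] * dim_zyx[2]), dim = dim_zyx)
  rho <- sqrt(UZ^2 + UY^2 + UX^2)
  if (invagination == 0) return(rho <= 1)
  # l = 3 sectoral harmonic-like ripple; makes the surface non-convex
  phi <- atan2(UY, UX)
  sin_theta_sq <- ifelse(rho > 0, (UX^2 + UY^2) / pmax(rho^2, 1e-12), 0)
  pert <- 1 + invagination * sin(3 * phi) * sin_theta_sq^1.5
  rho <= pert
}

# finite tapered cylinder along +x
cylinder_x_mask <- function(dim_zyx, spacing, y0, z0, x_range, r0, r1) {
  g <- coord_grid(dim_zyx, spacing)
  X <- array(rep(g$x, each = dim_zyx[1] * dim_zyx[2]), dim = dim_zyx)
  t <- pmin(pmax((X - x_range[1]) / max(x_range[2] - x_range[1], 1e-9), 0), 1)
  R <- r0 + (r1 - r0) * t
  DY <- array(rep(rep(g$y - y0, each = dim_zyx[1]), times = dim_zyx[3]),
              dim = dim_zyx)
  DZ <- array(rep(g$z - z0, times = dim_zyx[2] * dim_zyx[3]), dim = dim_zyx)
  (X >= x_range[1]) & (X <= x_range[2]) & (DY^2 + DZ^2 <= R^2)
}

# minimum distance between two 3-D segments (capsule collision test)
segment_distance <- function(p1, p2, q1, q2) {
  best <- Inf
  for (t in seq(0, 1, length.out = 9)) {
    a <- p1 + t * (p2 - p1)
    for (s in seq(0, 1, length.out = 9)) {
      b <- q1 + s * (q2 - q1)
      best <- min(best, sqrt(sum((a - b)^2)))
    }
  }
  best
}

# arbitrary-orientation capsule (used for neurite fragments)
capsule_mask <- function(dim_zyx, spacing, p0_xyz, p1_xyz, radius) {
  g <- coord_grid(dim_zyx, spacing)
  X <- array(rep(g$x, each = dim_zyx[1] * dim_zyx[2]), dim = dim_zyx)
  Y <- array(rep(rep(g$y, each = dim_zyx[1]), times = dim_zyx[3]), dim = dim_zyx)
  Z <- array(rep(g$z, times = dim_zyx[2] * dim_zyx[3]), dim = dim_zyx)
  v <- p1_xyz - p0_xyz
  L2 <- sum(v^2)
  t <- ((X - p0_xyz[1]) * v[1] + (Y - p0_xyz[2]) * v[2] + (Z - p0_xyz[3]) * v[3]) /
    max(L2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  dx <- X - (p0_xyz[1] + t * v[1])
  dy <- Y - (p0_xyz[2] + t * v[2])
  dz <- Z - (p0_xyz[3] + t * v[3])
  dx^2 + dy^2 + dz^2 <= radius^2
}

#' Generate a synthetic 3-channel confocal phantom with ground truth
#'
#' Renders the nuclear, somatodendritic and puncta channels of the
#' specified phantom, applies the Gaussian PSF and the configured noise,
#' and returns both the [image_stack()] and the ground truth (true puncta
#' table plus all structure and compartment voxel masks). Puncta are
#' rasterised by analytic sphere-voxel overlap on a supersampled grid so
#' sub-resolution volumes are represented faithfully rather than being
#' quantised to whole voxels.
#'
#' @param spec a [phantom_spec()].
#' @param case_id,image_id identifiers for the generated stack.
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `phantom_truth`: `$puncta` data frame with one row per true
#'   punctum -- id, cx_um, cy_um, cz_um, volume_um3, diameter_um,
#'   compartment -- plus `$masks`, `$granules` and the echoed `$spec`).
#' @export
generate_phantom <- function(spec = default_phantom_spec(),
                             case_id = "phantom",
                             image_id = sprintf("seed%03d", spec$seed)) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  prof <- spec$profile
  spacing <- prof$spacing
  dzyx <- c(prof$n_z, prof$plane_shape[1], prof$plane_shape[2])
  extent <- c(x = dzyx[3] * spacing$dx, y = dzyx[2] * spacing$dy,
              z = dzyx[1] * spacing$dz)

  soma_center <- spec$soma$center_um %||%
    c(extent[["x"]] * 0.34, extent[["y"]] * 0.5, extent[["z"]] * 0.5)
  soma_m <- ellipsoid_mask(dzyx, spacing, soma_center, spec$soma$semi_axes_um)
  dend_x0 <- soma_center[1]
  dend_x1 <- soma_center[1] + spec$soma$semi_axes_um[1] + spec$dendrite$length_um
  dend_m <- cylinder_x_mask(dzyx, spacing, soma_center[2], soma_center[3],
                            c(dend_x0, min(dend_x1, extent[["x"]] - 2 * spacing$dx)),
                            spec$dendrite$radius_um,
                            spec$dendrite$radius_um * (1 - spec$dendrite$taper))
  nucleus_m <- ellipsoid_mask(dzyx, spacing, soma_center,
                              spec$nucleus$semi_axes_um,
                              spec$nucleus$invagination_amplitude)
  structure_m <- soma_m | dend_m
  structure_edt <- cpp_edt3(structure_m, spacing_zyx(spacing))

  # --- distractor nuclei: ellipsoids clear of the neuron --------------------
  distractor_m <- array(FALSE, dzyx)
  distr_centers <- NULL
  if (spec$n_distractor_nuclei > 0) {
    semi <- spec$nucleus$semi_axes_um * 0.75
    for (i in seq_len(spec$n_distractor_nuclei)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        c_xy <- runif(2, max(semi[1:2]) + 0.2,
                      c(extent[["x"]], extent[["y"]]) - max(semi[1:2]) - 0.2)
        cand <- c(c_xy, extent[["z"]] * 0.5)
        vz <- pmin(pmax(floor(c(cand[3] / spacing$dz, cand[2] / spacing$dy,
                                cand[1] / spacing$dx)), 0), dzyx - 1)
        if (structure_edt[vz[1] + 1, vz[2] + 1, vz[3] + 1] <
            max(semi) + 0.4) next
        if (!is.null(distr_centers) &&
            min(sqrt(colSums((t(distr_centers) - cand)^2))) <
            2.2 * max(semi[1:2])) next
        distractor_m <- distractor_m | ellipsoid_mask(dzyx, spacing, cand, semi)
        distr_centers <- rbind(distr_centers, cand)
        ok <- TRUE
        break
      }
      if (!ok) stopf("unable to place distractor nucleus %d", i)
    }
  }

  # --- disconnected neurite fragments ---------------------------------------
  fragment_m <- array(FALSE, dzyx)
  if (spec$n_disconnected_neurites > 0) {
    frag_r <- 0.25
    frag_len <- 1.0
    frag_centers <- NULL
    clearance <- frag_r + 0.4
    edt_at <- function(p_xyz) {
      vz <- pmin(pmax(floor(c(p_xyz[3] / spacing$dz, p_xyz[2] / spacing$dy,
                              p_xyz[1] / spacing$dx)), 0), dzyx - 1)
      structure_edt[vz[1] + 1, vz[2] + 1, vz[3] + 1]
    }
    for (i in seq_len(spec$n_disconnected_neurites)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- c(runif(1, 0.9, extent[["x"]] - 0.9),
                  runif(1, 0.9, extent[["y"]] - 0.9),
                  runif(1, 0.5, extent[["z"]] - 0.5))
        if (edt_at(cand) < clearance) next
        ang <- runif(1, 0, pi)
        half <- c(cos(ang), sin(ang), 0) * frag_len / 2
        e1 <- cand - half; e2 <- cand + half
        if (any(c(e1[1:2], e2[1:2]) < 0.4) ||
            any(c(e1[1], e2[1]) > extent[["x"]] - 0.4) ||
            any(c(e1[2], e2[2]) > extent[["y"]] - 0.4)) next
        if (edt_at(e1) < clearance || edt_at(e2) < clearance) next
        if (!is.null(frag_centers)) {
          too_close <- FALSE
          for (j in seq_len(nrow(frag_centers) / 2)) {
            if (segment_distance(e1, e2, frag_centers[2 * j - 1, ],
                                 frag_centers[2 * j, ]) <
                2 * frag_r + 0.4) { too_close <- TRUE; break }
          }
          if (too_close) next
        }
        fragment_m <- fragment_m |
          capsule_mask(dzyx, spacing, e1, e2, frag_r)
        frag_centers <- rbind(frag_centers, e1, e2)
        ok <- TRUE
        break
      }
      if (!ok) stopf("unable to place neurite fragment %d", i)
    }
  }

  # --- placement compartments ------------------------------------------------
  shell_outer <- dilate_um(nucleus_m, spec$perinuclear_shell_um, spacing)
  margin <- spec$placement_margin_um
  somadend_core <- erode_um(structure_m, margin, spacing)
  somato_comp <- somadend_core &
    !dilate_um(nucleus_m, spec$perinuclear_shell_um +
                 (spec$compartment_gap_um %||% 0), spacing)
  peri_comp <- shell_outer & !nucleus_m & erode_um(soma_m, margin, spacing)
  if (spec$puncta_count_somatodendritic > 0 && !any(somato_comp))
    stopf("somatodendritic compartment empty; geometry too small for the margin")
  if (spec$puncta_count_perinuclear > 0 && !any(peri_comp))
    stopf("perinuclear compartment empty; geometry too small for the margin")

  # --- autofluorescent granules (placed first; puncta then keep their
  # distance from them) --------------------------------------------------------
  af <- spec$autofluorescence
  gran_centers <- matrix(numeric(0), 0, 3)
  if (af$n_granules > 0) {
    # granules are cytoplasmic organelles: fully interior (never clipped by
    # the structure surface) and clear of the thin perinuclear band so that
    # ground-truth membership of that band stays unambiguous
    gran_comp <- erode_um(structure_m, margin + af$radius_um, spacing) &
      !dilate_um(nucleus_m, spec$perinuclear_shell_um +
                   (spec$compartment_gap_um %||% 0) + af$radius_um, spacing)
    gran_sep <- max(spec$min_separation_um, 2 * af$radius_um)
    gran_centers <- sample_in_mask(af$n_granules, gran_comp, spacing,
                                   gran_sep,
                                   what = "autofluorescent granule")
  }

  # --- puncta ----------------------------------------------------------------
  vols_s <- draw_volumes(spec$puncta_count_somatodendritic, spec$puncta_volume_law)
  vols_p <- draw_volumes(spec$puncta_count_perinuclear, spec$puncta_volume_law)
  cen_s <- sample_in_mask(spec$puncta_count_somatodendritic, somato_comp,
                          spacing, spec$min_separation_um,
                          existing = gran_centers,
                          cluster = spec$clustering, what = "somatodendritic punctum")
  cen_p <- sample_in_mask(spec$puncta_count_perinuclear, peri_comp, spacing,
                          spec$min_separation_um,
                          existing = rbind(gran_centers, cen_s),
                          what = "perinuclear punctum")
  centers <- rbind(cen_s, cen_p)
  volumes <- c(vols_s, vols_p)
  radii <- (volumes * 3 / (4 * pi))^(1 / 3)
  compartment <- c(rep("somatodendritic", nrow(cen_s)),
                   rep("perinuclear", nrow(cen_p)))

  # --- render channels --------------------------------------------------------
  amp <- spec$amplitudes
  nuclear_ch <- (nucleus_m | distractor_m) * amp$nuclear
  somadend_ch <- (structure_m | fragment_m) * amp$somatodendritic
  puncta_ch <- array(0, dzyx)
  if (nrow(centers) > 0)
    puncta_ch <- cpp_raster_spheres(dzyx, spacing_zyx(spacing), centers,
                                    radii, rep(amp$puncta, nrow(centers)), 3L)
  if (nrow(gran_centers) > 0) {
    g_r <- rep(af$radius_um, nrow(gran_centers))
    bl <- af$bleed
    nuclear_ch <- nuclear_ch +
      cpp_raster_spheres(dzyx, spacing_zyx(spacing), gran_centers, g_r,
                         rep(amp$granule * bl[["nuclear"]], nrow(gran_centers)), 3L)
    somadend_ch <- somadend_ch +
      cpp_raster_spheres(dzyx, spacing_zyx(spacing), gran_centers, g_r,
                         rep(amp$granule * bl[["somatodendritic"]], nrow(gran_centers)), 3L)
    puncta_ch <- puncta_ch +
      cpp_raster_spheres(dzyx, spacing_zyx(spacing), gran_centers, g_r,
                         rep(amp$granule * bl[["puncta"]], nrow(gran_centers)), 3L)
  }
  psf <- spec$psf_sigma_um
  nuclear_ch <- blur_um(nuclear_ch, psf, spacing)
  somadend_ch <- blur_um(somadend_ch, psf, spacing)
  puncta_ch <- blur_um(puncta_ch, psf, spacing)

  if (isTRUE(spec$noise$enabled)) {
    sc <- spec$noise$photon_scale
    shot <- function(v) {
      n <- length(v)
      out <- rpois(n, as.vector(v) * sc) / sc + rnorm(n, 0, spec$noise$read_sd)
      out <- pmax(out, 0)
      dim(out) <- dim(v)
      out
    }
    nuclear_ch <- shot(nuclear_ch)
    somadend_ch <- shot(somadend_ch)
    puncta_ch <- shot(puncta_ch)
  }

  arr <- array(0, dim = c(3, dzyx))
  arr[1, , , ] <- nuclear_ch
  arr[2, , , ] <- somadend_ch
  arr[3, , , ] <- puncta_ch
  stack <- image_stack(arr, spacing, channel_roles(1L, 2L, 3L),
                       case_id = case_id, image_id = image_id)

  puncta_df <- data.frame(
    id = seq_along(volumes),
    cx_um = if (nrow(centers)) centers[, "x"] else numeric(0),
    cy_um = if (nrow(centers)) centers[, "y"] else numeric(0),
    cz_um = if (nrow(centers)) centers[, "z"] else numeric(0),
    volume_um3 = volumes,
    diameter_um = 2 * radii,
    compartment = compartment,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    puncta = puncta_df,
    masks = list(soma = soma_m, dendrite = dend_m, nucleus = nucleus_m,
                 distractor_nuclei = distractor_m,
                 neurite_fragments = fragment_m,
                 somatodendritic_compartment = somato_comp,
                 perinuclear_compartment = peri_comp),
    granules = if (nrow(gran_centers))
      data.frame(cx_um = gran_centers[, "x"], cy_um = gran_centers[, "y"],
                 cz_um = gran_centers[, "z"], radius_um = af$radius_um)
    else data.frame(cx_um = numeric(0), cy_um = numeric(0),
                    cz_um = numeric(0), radius_um = numeric(0)),
    spec = spec), class = "phantom_truth")

  list(stack = stack, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d puncta (%d somatodendritic, %d perinuclear), %d granules\n",
              nrow(x$puncta), sum(x$puncta$compartment == "somatodendritic"),
              sum(x$puncta$compartment == "perinuclear"), nrow(x$granules)))
  invisible(x)
}

#' Simulate a phantom cohort on disk
#'
#' Writes one OME-TIFF stack and one truth CSV per image under `out_dir`
#' and returns a roster data frame suitable for [pipeline_config()]. Image
#' seeds are derived deterministically from `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_cases,images_per_case cohort shape.
#' @param spec base [phantom_spec()]; its seed field is overridden per image.
#' @param seed cohort-level seed.
#' @return Roster data frame: path, case_id, image_id, truth_path, seed.
#' @export
simulate_cohort <- function(out_dir, n_cases = 3L, images_per_case = 8L,
                            spec = default_phantom_spec(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  roster <- NULL
  k <- 0L
  for (ci in seq_len(n_cases)) {
    case_id <- sprintf("case%02d", ci)
    for (ii in seq_len(images_per_case)) {
      k <- k + 1L
      im_seed <- as.integer((seed %% 100000L) * 10000L + k)  # stays < 2^31
      sp <- spec
      sp$seed <- im_seed
      image_id <- sprintf("%s_img%02d", case_id, ii)
      ph <- generate_phantom(sp, case_id = case_id, image_id = image_id)
      path <- file.path(out_dir, paste0(image_id, ".ome.tif"))
      truth_path <- file.path(out_dir, paste0(image_id, "_truth.csv"))
      write_stack(ph$stack, path)
      write.csv(ph$truth$puncta, truth_path, row.names = FALSE)
      roster <- rbind(roster, data.frame(
        path = path, case_id = case_id, image_id = image_id,
        truth_path = truth_path, seed = im_seed, stringsAsFactors = FALSE))
    }
  }
  roster
}
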