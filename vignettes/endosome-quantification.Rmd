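---
title: "Quantifying neuronal early-endosome morphology in 3D confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal early-endosome morphology in 3D confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopipe)
```

## The problem

Early endosomes are sub-micron vesicles (roughly 100-500 nm in diameter by
electron microscopy) whose enlargement and clustering are early
cytopathological signs in Alzheimer's disease neurons. Quantifying them in
postmortem brain tissue means detecting hundreds of diffraction-scale
fluorescent puncta per neuron inside specific cellular compartments of a
high-resolution confocal z-stack, under heavy anisotropy (here 0.03 um
lateral pixels versus 0.13 um z-steps, 14 planes) and with lipofuscin
autofluorescence as a confound.

`endopipe` reproduces, as scriptable batch code, an interactive two-batch
workflow built around commercial 3D analysis software:

1. **Batch 1 (ROIs).** Two regions of interest are segmented per neuron
   image: the *somatodendritic* ROI from a somatodendritic marker channel
   (MAP2) and the *perinuclear* ROI from the nuclear stain (DAPI). The
   original workflow pauses here for manual cleanup; `endopipe` replaces
   the manual steps with deterministic rules and still supports the pause
   (`pause_for_edit`) so masks can be hand-edited as TIFFs and reloaded.
2. **Batch 2 (puncta).** The punctate vesicle channel (EEA1, SORLA, ...)
   is masked by each ROI and analysed by two detection modes: voxel-level
   segmentation per object ("surface" mode, with full 3D morphology) and
   point detection with an estimated diameter ("spots" mode). Statistics
   are aggregated per image and per case.

## The measurement model

### Geometry and units

All computation is voxel-based internally (axis order channel, z, y, x;
0-based indices) but every exported quantity is physical: centroids and
distances in micrometres, volumes in cubic micrometres. A voxel with index
`i` along an axis of spacing `d` is centred at `(i + 0.5) * d`. ROI
volumes are exactly `voxel count x dx dy dz`.

### The spherical minimum-volume filter

The protocol standardises "what counts as an endosome" through size: with
endosomes assumed spherical and the published EM diameter range 100-500 nm,
puncta with measured volume strictly below `pi * 0.2^3 / 6 = 0.004` um^3
are excluded. The filter is strict-less-than, so a volume of exactly
0.004 um^3 is retained; this boundary semantics is tested. `endopipe` adds
a configurable upper bound, defaulting to the 500 nm sphere volume
(~0.0654 um^3); it is an extension of the same EM range (the published
protocol states only the lower cut, so `max_volume_um3 = Inf` reproduces
it exactly) and doubles as the rejection rule for fused autofluorescent
blobs, which are far larger than any single endosome.

### ROI construction

Each ROI channel is smoothed with a small anisotropic Gaussian (default
sigma 0.06, 0.06, 0.13 um - about one voxel per axis), thresholded, closed
morphologically (0.1 um), and labelled with 26-connectivity. Thresholding
is Otsu's method computed over the non-empty support of the smoothed
channel (voxels above 1% of the channel maximum). The support restriction
matters: these volumes are mostly empty background, and classical global
Otsu with such unbalanced classes drifts far below the object boundary (on
phantoms it inflated nucleus volumes by a factor of two). The concrete
parameters of the original interactive workflow are not published, so
these defaults are this package's own and are recorded in every mask's
provenance.

The manual cleanup steps become deterministic rules:

* *Somatodendritic refinement*: of all raw components, keep exactly the
  one with maximal voxel overlap with the neuronal nucleus (ties broken by
  larger volume, then lower label). No overlapping component means the
  neuron fails QC - mirroring the exclusion of neurons without continuous
  somatodendritic staining - rather than silently guessing.
* *Perinuclear refinement*: nuclei are split by a distance-transform
  watershed (seeds at least 1.2 um apart), the nucleus with maximal
  overlap with the somatodendritic ROI is kept and dilated isotropically
  by 0.3 um (configurable; 0 gives the bare nuclear surface). The dilation
  operationalises the observation that perinuclear endosomes surround the
  nuclear stain without colocalising with it; how far the original
  software's nuclear surface extends beyond the raw signal is not
  published, hence the parameter.

### Restoration stand-in

The reference images were restored by a proprietary adaptive deconvolution
before analysis. Its internals are unavailable, so `endopipe` ships a
classical Richardson-Lucy stage with a Gaussian PSF as a documented
stand-in - optional and bypassable, with every downstream module behaving
identically either way. The module default is 20 iterations with
reflective edges. The *pipeline* default is 10 iterations: on phantoms,
15+ noise-free iterations produce enough ringing around compact objects
that spurious watershed seeds appear and large blobs split, while 10
iterations give exact count recovery. Whether the published quantitative
results depend on the proprietary algorithm's specifics cannot be assessed
without it; treat absolute volumes from different restoration settings as
different instruments.

### Surface mode

Background is removed by grayscale opening with a physical radius
(separable box structuring element, 0.3 um default - a rolling-ball
analogue), the residue is smoothed by a small matched filter (0.05, 0.05,
0.1 um), and seeds are local maxima at least 0.2 um apart (the smallest
admissible punctum diameter). Seeding and region support use a slightly
heavier smoothing (0.08, 0.08, 0.16 um) so restoration ringing on large
blobs cannot seed spurious splits; measurement stays on the finer scale.
Touching puncta are split by a marker-based watershed. The detection
threshold is `max(5 * MAD of the smoothed ROI voxels, 2e-3 * channel
peak)`: the MAD term adapts to shot noise, the floor keeps a noise-free
zero background from seeding.

Per object, the volume is the supersampled (3x per axis, trilinear)
occupancy above `0.4 x` that object's smoothed peak. Whole-voxel counting
would quantise a 200 nm punctum (about two z-voxels) hopelessly; the
supersampled boundary recovers sub-voxel extent. The 0.4 level rather
than the textbook 0.5 (FWHM) compensates the centre overshoot that
Richardson-Lucy puts on compact objects; it was calibrated on noise-free
phantoms against known true volumes (mean recovered volume within about
+-30% across the 100-500 nm log-normal population; individual
sub-resolution volumes remain the least reliable measurement in the
pipeline, bounded below by the residual resolution volume). Sphericity is
estimated from the intensity-weighted second moments via an
equivalent-ellipsoid surface area (Thomsen's approximation), clamped to
(0, 1].

### Spots mode

Multiscale scale-normalised Laplacian-of-Gaussian detection with six
logarithmic scales spanning the admissible diameter range, each sigma
anisotropy-corrected to voxels through the physical spacing. For a solid
sphere of radius `r` the response peaks near `sigma = r / sqrt(3)`, so the
estimated diameter is `2 sqrt(3) sigma`. Local maxima are collected across
scales, overlap-suppressed (centres closer than 0.7x the sum of the two
radii collapse to the stronger response), and refined to sub-voxel
precision by separable quadratic fits. On noise-free phantoms every true
punctum is matched by a spot within 0.15 um.

### Clustering and aggregation

The per-punctum clustering statistic is the mean Euclidean distance to the
k nearest neighbouring puncta within the same ROI of the same image
(k = 3 by default, matching the reference statistic; centroid-to-centroid,
since whether the original used surface-to-surface distance is not
stated). It is computed exactly (all pairs), is undefined below k+1 puncta
and is flagged rather than silently dropped. Image summaries use linear
interpolation between order statistics for quartiles (R type 7; stated
because conventions differ across tools). Case summaries weight every
neuron image equally regardless of its puncta count, matching the
"mean value from all neurons imaged per case" convention. A punctum
belongs to an ROI iff its intensity-weighted centroid lies inside the
mask; when ROIs overlap a punctum may legitimately appear in both
analyses, as the two masked channels are analysed independently.

## The phantom: what it emulates, what it does not

Cohort-level results from the original tissue images are not reproducible
(no images are deposited), so validation rests on a seeded synthetic
phantom with known ground truth:

```{r phantom, eval = FALSE}
ph <- generate_phantom(default_phantom_spec(seed = 7))
ph$stack          # 3 channels, 14 x 256 x 256, 0.03 x 0.03 x 0.13 um
head(ph$truth$puncta)
```

The default spec states a desk-scale version of the reference
acquisition: identical voxel geometry (14 z-planes of 0.13 um, 0.03 um
pixels) with the 1256 x 1256 plane shrunk to 256 x 256, one MAP2+ soma
(ellipsoid, 2.7 x 2.7 x 0.85 um semi-axes) with a tapering proximal
dendrite, a neuronal nucleus with a low-order non-convex surface ripple
(so the perinuclear geometry is not trivially ellipsoidal), two distractor
nuclei, three disconnected neurite fragments, and lipofuscin-like granules
(0.3 um, placed in the somatic cytoplasm) that bleed into all three
channels at low fractions - the published observation is only "overall low
levels" after quenching, so the bleed fractions are free parameters.

True puncta volumes follow a log-normal law over um^3 (meanlog
`log(0.008)`, i.e. a 250 nm median sphere; sdlog 0.5) truncated to the
100-500 nm EM diameter range - right-skewed, as reported for endosome
volume distributions. Counts default to 25 somatodendritic plus 8
perinuclear puncta, giving ROI densities of 2-3 per um^3. Sub-resolution
spheres are rendered by analytic sphere-voxel overlap on a 3x supersampled
grid (naive binary rasterisation would quantise 100-200 nm volumes to
zero), blurred by a Gaussian PSF (0.08, 0.08, 0.2 um), and degraded by
Poisson shot noise at a photon scale giving peak SNR near 10 plus Gaussian
read noise; no noise figures are published, so these are the package's
choices.

Three deliberate clean-world simplifications keep ground truth
unambiguous, and bound what a green test establishes. Puncta centres stay
at least 0.2 um inside their compartment boundary; the perinuclear shell
(0.3 um outside the nucleus) is separated from the somatodendritic
population by a 0.25 um buffer; granules stay out of that band and fully
interior. Real tissue has none of these guarantees - puncta touch
boundaries, populations mix, lipofuscin sits anywhere - so phantom
recovery demonstrates that the machinery is correct and calibrated, not
that tissue-level accuracy will match. The phantom also uses a Gaussian
PSF with no depth aberration, uniform staining within structures, and a
single neuron per field, all idealisations.

Identical spec and seed give bit-identical stacks and truth (a fixed,
versioned RNG is set and restored); nothing downstream of the generator
consumes randomness, so two pipeline runs on fixed input are
byte-identical.

## Numerical choices and degenerate inputs

* Distance transforms are exact anisotropic Euclidean (Felzenszwalb);
  binary erosion/dilation/closing in physical units derive from them, so
  morphology is voxel-size independent.
* Component selection ties break by overlap, then volume, then lowest
  label - documented and deterministic.
* Watershed flooding is highest-intensity-first with FIFO tie-breaks;
  plateau local-maxima ties resolve to the lowest linear index.
* Empty segmentations raise errors; empty puncta tables are legal
  everywhere downstream (summaries flag undefined statistics as NA).
* QC never throws: it returns pass/fail with reasons so batches record
  exclusions and continue; one failing image never affects another.

## Known limitations

* Absolute volumes of sub-resolution puncta carry the resolution floor of
  the instrument model; between-group comparisons at fixed settings are
  the intended use, as in the reference protocol.
* The Richardson-Lucy stand-in is not the proprietary restoration used on
  the original images; constants calibrated here need not transfer to
  images restored by other software.
* The phantom validates the pipeline's machinery, not tissue realism (see
  above); no pathology (tangles, plaques) or multi-neuron fields are
  simulated.
* `stats` re-aggregation from a bare puncta CSV cannot recompute densities
  (ROI volumes are not in that file); those fields are NA.
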