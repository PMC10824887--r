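# endopipe

Batch quantification of neuronal early-endosome morphology in
high-resolution 3D confocal z-stacks.

Abnormal early-endosome size and clustering are among the earliest
cytopathological changes in Alzheimer's disease neurons. Measuring them in
postmortem tissue means detecting hundreds of sub-resolution fluorescent
puncta (EEA1+, or any punctate endosomal marker such as SORLA) inside
specific neuronal compartments of anisotropic confocal stacks. `endopipe`
is an open, scriptable re-implementation of a two-batch interactive
workflow built on commercial 3D software, for image analysts and
neuropathology labs who need the same measurements reproducibly and at
cohort scale:

* **Stack I/O** — multichannel TIFF / OME-TIFF with physical voxel
  spacing (reference geometry: 0.03 × 0.03 × 0.13 µm, 14 z-planes), plus a
  Nyquist oversampling QC.
* **Batch 1 — neuronal ROIs.** A somatodendritic ROI from the MAP2
  channel and a perinuclear ROI from the DAPI channel (nucleus selected
  deterministically, dilated 0.3 µm). Manual-cleanup steps of the original
  workflow are replaced by seed-based rules; masks are written as 8-bit
  TIFFs and can be hand-edited and reloaded between batches.
* **Batch 2 — puncta.** The masked vesicle channel is analysed in two
  modes: voxel segmentation with watershed splitting and sub-voxel volume
  measurement ("surface"), and multiscale Laplacian-of-Gaussian point
  detection ("spots", diameters 100–500 nm). The protocol's spherical
  minimum-volume exclusion is applied as published: puncta with volume
  < 0.004 µm³ (a 200 nm sphere, V = πd³/6) are excluded, strictly below —
  exactly 0.004 µm³ is retained.
* **Statistics** — per-punctum volume, equivalent diameter, sphericity,
  intensity; mean distance to the k = 3 nearest neighbouring endosomes
  (exact, all pairs); per-image summaries (quartiles, density = count/ROI
  volume); per-case means with every neuron image weighted equally; 3D
  scatter exports.
* **Restoration (optional)** — a Richardson–Lucy stage with Gaussian PSF
  as a documented stand-in for the proprietary acquisition-side
  deconvolution; fully bypassable.
* **Phantom generator** — seeded synthetic 3-channel stacks with ground
  truth (soma + dendrite, invaginated nucleus, distractor nuclei,
  disconnected neurites, log-normal sub-resolution puncta, lipofuscin-like
  granules, PSF blur, shot noise), so the entire pipeline is testable
  without tissue data.

## Worked example

```r
library(endopipe)

# a synthetic neuron with known ground truth; a 0.6 um minimum separation
# keeps every simulated endosome individually resolvable (the default, 0,
# permits arbitrarily tight clusters, which merge into single surfaces
# exactly as they would in real images)
spec <- default_phantom_spec(seed = 7)
spec$min_separation_um <- 0.6
ph <- generate_phantom(spec)
ph$stack
#> image_stack 'phantom/seed007': 3 channel(s), 14 x 256 x 256 (z,y,x) voxels
#> voxel spacing: 0.03 x 0.03 x 0.13 um (x, y, z)
ph$truth
#> phantom_truth: 33 puncta (25 somatodendritic, 8 perinuclear), 4 granules

# batch 1: ROIs
nuclei <- segment_nuclei(ph$stack, segmentation_params(min_component_volume_um3 = 1))
raw    <- segment_somatodendritic(ph$stack)
somato <- refine_somatodendritic(raw, select_neuron_nucleus(raw, nuclei))
peri   <- refine_perinuclear(nuclei, somato, 0.3)
somato
#> roi_mask [somatodendritic]: 232964 voxels, 27.257 um^3

# batch 2: restore, mask, detect, filter, summarise
dec    <- richardson_lucy(get_channel(ph$stack, "puncta"), ph$stack$spacing,
                          deconvolution_params(n_iterations = 10))
masked <- mask_channel(dec, somato)
tab    <- apply_filter(detect_surface_mode(masked, ph$stack$spacing, roi = somato))
nrow(tab)
#> [1] 33
summarize_image(add_neighbor_stats(tab), somato, k = 3,
                case_id = "phantom", image_id = "seed007")[
  , c("n_puncta", "mean_volume_um3", "density_per_um3", "mean_knn_um")]
#>   n_puncta mean_volume_um3 density_per_um3 mean_knn_um
#> 1       33      0.01221304        1.210708    0.829907
```

All 33 simulated puncta inside the somatodendritic ROI (25 somatodendritic
plus 8 perinuclear ones, whose shell lies within the soma) are detected
and survive the volume filter, while the 4 brighter-than-life lipofuscin
granules are rejected by the upper volume bound. The mean measured volume
(0.0122 µm³) recovers the generating law's truncated mean (0.0091 µm³) to
within the calibrated ~+/-35% tolerance — sub-resolution volumes carry the
instrument's resolution floor — the density is count over ROI volume by
construction, and the clustering statistic is the mean distance to the
three nearest neighbouring endosomes in µm.

For whole cohorts, `simulate_cohort()` + `pipeline_config()` +
`run_all()` (or the `inst/cli/endopipe.R` script with subcommands
`simulate`, `batch1`, `batch2`, `run`, `stats`) produce a full output tree:
`masks/`, `qc.csv`, `puncta.csv`, `spots.csv`, `image_summary.csv`,
`case_summary.csv` and JSON run manifests.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch against the
installed package: it simulates a seeded phantom cohort at the default
acquisition profile, runs both batch stages (ROIs, restoration, both
detection modes, filtering, per-image and per-case aggregation) and writes
the acceptance JSON to `--out`.

## Documentation

The methods vignette (`vignettes/endosome-quantification.Rmd`) describes
the measurement model, every tunable parameter with units and defaults,
what the phantom does and does not emulate, numerical conventions, and
known limitations.
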