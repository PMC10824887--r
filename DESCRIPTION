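Package: endopipe
Title: Quantification of Neuronal Early-Endosome Morphology in 3D Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Batch pipeline for high-resolution 3D quantification of
    endo-lysosomal puncta (e.g. EEA1+ early endosomes) in multichannel
    confocal z-stacks of neurons. Builds somatodendritic (MAP2+) and
    perinuclear (DAPI+) regions of interest, masks the punctate channel
    with each, detects puncta in a voxel-segmentation ("surface") mode
    and a Laplacian-of-Gaussian ("spots") mode with a spherical
    minimum-volume exclusion, and reports per-punctum, per-image and
    per-case morphology and clustering statistics (volumes, densities,
    mean distance to the k nearest neighbours). Includes an optional
    Richardson-Lucy deconvolution stage and a seeded synthetic-phantom
    generator with ground truth so the whole pipeline can be validated
    without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
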