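Package: mp2seg
Title: Brain Tissue Segmentation from Multi-Contrast MP2RAGE Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Segments gray matter, white matter, and cerebrospinal fluid from
    the co-registered contrasts of a single MP2RAGE acquisition (UNI, T1 map,
    INV1) by min-max feature scaling of in-brain intensities followed by
    simple binary mask arithmetic on normalized-intensity differences.
    Includes brain-mask application with morphological erosion, segmentation
    similarity metrics (absolute volume difference, Dice coefficient, and the
    modified Hausdorff distance on axial slice boundaries), region-of-interest
    SNR estimation, and a digital phantom generator that emits synthetic
    MP2RAGE volumes with ground-truth tissue labels and controllable Gaussian
    noise for validation without scanner data. All volumes are read and
    written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
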