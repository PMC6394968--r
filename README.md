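# mp2seg

Fast brain tissue segmentation (gray matter, white matter, CSF) from the
co-registered contrasts of a single MP2RAGE acquisition, plus the
evaluation metrics and the synthetic phantom needed to validate it without
scanner data.

## The problem and the method

At ultra-high field (7T), whole-brain sub-millimeter volumes make
conventional atlas- or model-based segmentation slow, and the standard
MPRAGE T1-weighted image suffers severe intensity inhomogeneity. An
MP2RAGE sequence instead delivers, in one scan and on one voxel grid, two
inversion-time gradient-echo images (INV1, INV2), a bias-field-cancelling
"uniform" T1-weighted image (UNI), and a quantitative T1 map. Because the
contrasts are co-registered by construction, tissues can be separated with
plain intensity arithmetic.

Each brain-extracted contrast *S* is min-max feature-scaled over the
in-brain voxels,

    S_norm = (S_raw − min S_raw) / (max S_raw − min S_raw),

and the tissues are classified by binarized differences of the normalized
images (bin = strict threshold at 0, "−" = set difference, "+" = union):

    CSF = bin(nINV1 − nUNI)
    GM  = bin(nT1  − nUNI) − CSF
    WM  = bin(nUNI)        − (CSF + GM)

This is a handful of vectorized array operations — no template, atlas, or
iterative fit — so runtime is seconds even for large grids. The package
also provides:

* brain-mask application with configurable 3D morphological erosion
  (skull stripping itself is consumed, not performed);
* similarity metrics: absolute volume difference (AVD), Dice coefficient,
  and the modified Hausdorff distance (MHD, Dubuisson–Jain) on tissue
  boundaries of an axial slice, in mm; ROI-based SNR;
* a digital phantom (nested-ellipsoid geometry, empirical or
  inversion-recovery-based rendering, seeded Gaussian noise) with
  ground-truth labels;
* a command-line tool (`exec/mp2seg`) with subcommands `simulate`,
  `extract`, `segment`, `evaluate`, and `pipeline`, writing a JSON run
  manifest per run.

All volumes are NIfTI-1 (`.nii` / `.nii.gz`).

## Worked example

Simulate the default 64³ phantom (0.8 mm voxels), segment it, and score
the result against the ground-truth labels:

```r
library(mp2seg)

ph  <- simulate_phantom(phantom_spec(noise_percent = 0, seed = 42))
seg <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                       ph$mask, erosion_iterations = 1)

truth <- ph$labels$data
truth[seg$mask$data == 0L] <- 0L   # compare on the eroded domain
similarity_report(seg$labels, tissue_labels(truth, ph$labels$spacing))
#>   tissue avd_percent dice_percent mhd_mm slice_index n_test n_ref
#> 1    CSF           0          100      0          32  29136 29136
#> 2     GM           0          100      0          32  28320 28320
#> 3     WM           0          100      0          32  11848 11848
```

Perfect recovery at zero noise is a designed property: the phantom's
default intensity model encodes the normalized-intensity orderings the
rules rely on with wide margins. Adding 9% Gaussian noise (SD = 9% of the
in-brain intensity range, per contrast) degrades the overlap:

```r
ph  <- simulate_phantom(phantom_spec(noise_percent = 9, seed = 42))
seg <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                       ph$mask, erosion_iterations = 1)
truth <- ph$labels$data; truth[seg$mask$data == 0L] <- 0L
similarity_report(seg$labels, tissue_labels(truth, ph$labels$spacing))
#>   tissue avd_percent dice_percent mhd_mm slice_index n_test n_ref
#> 1    CSF        49.3         80.2   1.79          32  43502 29136
#> 2     GM        69.7         46.5   1.01          32   8580 28320
#> 3     WM        45.4         81.5   2.06          32  17222 11848
```

AVD is asymmetric (the second label map is the reference in the
denominator); Dice is a symmetric overlap percentage; MHD is the larger
directed mean nearest-boundary distance in mm on the reported axial
slice. Single-seed results at high noise vary noticeably because noise
shifts the min/max normalization anchors; mean Dice over seeds declines
smoothly with the noise level (see the vignette).

The same pipeline from the shell:

```sh
exec/mp2seg pipeline --out run/ --seed 42 --noise 9
cat run/report.csv
```

## Scope and limitations

The intensity rules misclassify structures whose contrast deviates from
the global tissue pattern (subcortical gray matter, large vessels) and do
not model partial-volume effects or residual B1 inhomogeneity; the
phantom validates the arithmetic and noise response on idealized
geometry, not anatomical accuracy on real brains. See the methods
vignette (`vignettes/mp2seg-methods.Rmd`) for the full account of the
model, parameter choices, and validation design.
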