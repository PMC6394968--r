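#' @name phantom
#' @title Digital MP2RAGE phantom
#'
#' @description
#' A nested-ellipsoid head phantom with known tissue labels, rendered into
#' synthetic INV1/INV2/UNI/T1 volumes in one of two modes:
#' \describe{
#'   \item{empirical}{each tissue's intensity in each contrast is drawn from
#'     a Gaussian whose default means encode the per-tissue normalized
#'     intensity orderings observed in real MP2RAGE data (CSF:
#'     nT1 > nINV1 > nUNI; GM: nT1 > nUNI > nINV1; WM: nUNI > nT1 > nINV1);}
#'   \item{physics}{tissue intensities follow a two-point inversion-recovery
#'     signal model evaluated at the two inversion times, combined into a
#'     UNI ratio image; the T1 volume holds the per-tissue T1 itself.}
#' }
#' Gaussian noise at a percentage of the in-brain intensity range can be
#' added to every contrast, reproducing the noise-robustness study design.
#' Every stochastic step is a pure function of the spec's seed.
NULL

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default empirical intensity model
#'
#' Per-tissue, per-contrast means and standard deviations (arbitrary units;
#' T1 in seconds, matching the default 7T tissue T1 values). The means are
#' chosen so that after in-brain min-max normalization of each contrast the
#' per-tissue orderings of normalized intensities match those seen in real
#' 7T MP2RAGE data, with margins of at least three voxelwise standard
#' deviations so the sign rules of the segmentation hold for essentially
#' every voxel at zero added noise.
#'
#' @return A data frame with columns `tissue`, `contrast`, `mean`, `sd`.
#' @export
default_intensity_model <- function() {
  data.frame(
    tissue   = rep(c("CSF", "GM", "WM"), each = 4),
    contrast = rep(c("UNI", "T1", "INV1", "INV2"), times = 3),
    mean = c(0.05, 4.4, 0.70, 0.30,    # CSF
             0.17, 2.0, 0.06, 0.45,    # GM
             0.95, 1.2, 0.02, 0.55),   # WM
    sd   = c(0.015, 0.05, 0.050, 0.02,
             0.015, 0.10, 0.010, 0.02,
             0.015, 0.10, 0.005, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic MP2RAGE phantom
#'
#' Geometry is a set of strictly nested ellipsoids (in voxel units) forming,
#' from outside in, a CSF shell, a GM shell, and a WM core, plus an optional
#' CSF "ventricle" ellipsoid inside the WM. Defaults give a 64^3 grid at
#' 0.8 mm isotropic spacing -- the voxel size of a typical 7T MP2RAGE
#' protocol -- with roughly 76k brain voxels.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing_mm Voxel size per axis in mm.
#' @param center Ellipsoid center in voxel coordinates; default grid center.
#' @param semi_csf,semi_gm,semi_wm Semi-axes (voxels) of the outer CSF, GM,
#'   and WM ellipsoids; must be strictly nested (`semi_wm < semi_gm <
#'   semi_csf` on every axis).
#' @param ventricle Semi-axes of a CSF ventricle centered at `center`,
#'   or `NULL` for none. Must fit inside the WM ellipsoid.
#' @param mode `"empirical"` (default) or `"physics"`.
#' @param intensity_model Empirical-mode model as from
#'   [default_intensity_model()].
#' @param t1_s Named per-tissue T1 (seconds) for physics mode; defaults are
#'   7T-plausible (WM 1.2, GM 2.0, CSF 4.4).
#' @param pd Named per-tissue relative proton density.
#' @param ti1_s,ti2_s Inversion times in seconds (defaults 0.8 / 2.6).
#' @param fa1_deg,fa2_deg Excitation flip angles in degrees (defaults 4 / 5).
#' @param efficiency Inversion efficiency in \[0, 1\].
#' @param t1_cap Upper clip for the rendered T1 map, seconds.
#' @param noise_percent Gaussian noise SD as a percentage of a reference
#'   intensity scale of each contrast (see `noise_reference`).
#' @param noise_reference What the noise percentage refers to: the in-brain
#'   intensity `"range"` (default), `"max"`, or `"mean"` (absolute value).
#' @param seed Integer seed controlling all randomness.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing_mm = c(0.8, 0.8, 0.8),
                         center = (grid_shape + 1) / 2,
                         semi_csf = c(27, 27, 25),
                         semi_gm = c(22, 22, 20),
                         semi_wm = c(15, 15, 13),
                         ventricle = c(6, 4, 4),
                         mode = c("empirical", "physics"),
                         intensity_model = default_intensity_model(),
                         t1_s = c(CSF = 4.4, GM = 2.0, WM = 1.2),
                         pd = c(CSF = 1.0, GM = 0.8, WM = 0.65),
                         ti1_s = 0.8, ti2_s = 2.6,
                         fa1_deg = 4, fa2_deg = 5,
                         efficiency = 0.96,
                         t1_cap = 5.0,
                         noise_percent = 0,
                         noise_reference = c("range", "max", "mean"),
                         seed = 42L) {
  mode <- match.arg(mode)
  noise_reference <- match.arg(noise_reference)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(center) == 3L,
            length(semi_csf) == 3L, length(semi_gm) == 3L,
            length(semi_wm) == 3L,
            is.numeric(ti1_s), ti1_s > 0, is.numeric(ti2_s), ti2_s > 0,
            efficiency >= 0, efficiency <= 1,
            t1_cap > 0, noise_percent >= 0)
  if (!all(semi_wm < semi_gm) || !all(semi_gm < semi_csf))
    stop("phantom_spec: shells not nested (need semi_wm < semi_gm < semi_csf ",
         "on every axis)", call. = FALSE)
  if (!is.null(ventricle)) {
    stopifnot(length(ventricle) == 3L)
    if (!all(ventricle < semi_wm))
      stop("phantom_spec: ventricle must fit strictly inside the WM core",
           call. = FALSE)
  }
  for (tt in c("CSF", "GM", "WM")) {
    if (is.na(t1_s[tt]) || is.na(pd[tt]))
      stop("phantom_spec: missing tissue parameter for ", tt, call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 center = as.numeric(center),
                 semi_csf = as.numeric(semi_csf),
                 semi_gm = as.numeric(semi_gm),
                 semi_wm = as.numeric(semi_wm),
                 ventricle = if (is.null(ventricle)) NULL else as.numeric(ventricle),
                 mode = mode, intensity_model = intensity_model,
                 t1_s = t1_s, pd = pd,
                 ti1_s = ti1_s, ti2_s = ti2_s,
                 fa1_deg = fa1_deg, fa2_deg = fa2_deg,
                 efficiency = efficiency, t1_cap = t1_cap,
                 noise_percent = noise_percent,
                 noise_reference = noise_reference,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

inside_ellipsoid <- function(shape, center, semi) {
  x <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  z <- (seq_len(shape[3]) - center[3]) / semi[3]
  d <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d <= 1
}

#' Generate the phantom's ground-truth label map
#'
#' Deterministic (no randomness): outermost shell CSF, then GM, then the WM
#' core, with the optional ventricle re-labeled CSF inside the WM.
#'
#' @param spec A [phantom_spec()].
#' @return A [tissue_labels()] volume.
#' @export
make_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  codes <- tissue_codes()
  lab <- array(codes[["background"]], dim = spec$grid_shape)
  lab[inside_ellipsoid(spec$grid_shape, spec$center, spec$semi_csf)] <- codes[["CSF"]]
  lab[inside_ellipsoid(spec$grid_shape, spec$center, spec$semi_gm)]  <- codes[["GM"]]
  lab[inside_ellipsoid(spec$grid_shape, spec$center, spec$semi_wm)]  <- codes[["WM"]]
  if (!is.null(spec$ventricle))
    lab[inside_ellipsoid(spec$grid_shape, spec$center, spec$ventricle)] <- codes[["CSF"]]
  for (tt in c("CSF", "GM", "WM"))
    if (!any(lab == codes[[tt]]))
      stop("make_labels: tissue ", tt, " is empty with this geometry",
           call. = FALSE)
  tissue_labels(lab, spacing = spec$spacing_mm)
}

#' Inversion-recovery signal
#'
#' Signed longitudinal signal after an inversion pulse of the given
#' efficiency, read out at inversion time `ti_s`:
#' `pd * sin(fa) * (1 - 2 * efficiency * exp(-ti / t1))`. Monotone
#' increasing in `ti_s` for fixed `t1_s`; zero at `ti = t1 * log(2)` for a
#' perfect inversion.
#'
#' @param t1_s Longitudinal relaxation time, seconds (> 0). Vectorized.
#' @param pd Relative proton density (> 0).
#' @param ti_s Inversion time, seconds (> 0).
#' @param fa_deg Excitation flip angle, degrees.
#' @param efficiency Inversion efficiency in \[0, 1\].
#' @return Signed signal in arbitrary units.
#' @export
#' @examples
#' ir_signal(1.2, 1, ti_s = 1.2 * log(2), fa_deg = 90, efficiency = 1) # ~0
ir_signal <- function(t1_s, pd = 1, ti_s = 0.8, fa_deg = 4, efficiency = 0.96) {
  if (any(t1_s <= 0)) stop("ir_signal: t1_s must be positive", call. = FALSE)
  if (any(ti_s <= 0)) stop("ir_signal: ti_s must be positive", call. = FALSE)
  stopifnot(efficiency >= 0, efficiency <= 1)
  pd * sin(fa_deg * pi / 180) * (1 - 2 * efficiency * exp(-ti_s / t1_s))
}

#' Combine two inversion-time signals into a UNI ratio
#'
#' `(s1 * s2) / (s1^2 + s2^2)`, the real-valued analogue of the MP2RAGE
#' uniform-image combination; bounded in \[-0.5, 0.5\], with 0/0 defined
#' as 0. The bounds are attained exactly at `s1 = s2` (+0.5) and
#' `s1 = -s2` (-0.5).
#'
#' @param s1,s2 Signed signals (vectorized).
#' @return Ratio in \[-0.5, 0.5\].
#' @export
combine_uni <- function(s1, s2) {
  den <- s1^2 + s2^2
  out <- ifelse(den == 0, 0, (s1 * s2) / ifelse(den == 0, 1, den))
  out
}

#' Add Gaussian noise to a volume
#'
#' Zero-mean Gaussian noise with standard deviation `level_percent / 100`
#' times a reference intensity scale of the volume -- by default the range
#' (max - min) of the in-mask intensities, the package's reading of
#' percentage noise levels. The reference region defaults to the whole
#' volume when no mask is given.
#'
#' @param volume A [contrast_volume()].
#' @param level_percent Noise level, >= 0. Zero returns the input unchanged.
#' @param seed Integer seed; same seed, same output.
#' @param mask Optional [brain_mask()] defining the in-brain region over
#'   which the reference scale is computed.
#' @param reference `"range"` (default), `"max"`, or `"mean"` of absolute
#'   in-mask intensities.
#' @return A [contrast_volume()] with noise added everywhere.
#' @export
add_noise <- function(volume, level_percent, seed, mask = NULL,
                      reference = c("range", "max", "mean")) {
  stopifnot(inherits(volume, "contrast_volume"))
  reference <- match.arg(reference)
  if (level_percent < 0)
    stop("add_noise: level_percent must be >= 0", call. = FALSE)
  if (level_percent == 0) return(volume)
  vals <- if (is.null(mask)) volume$data else {
    check_same_grid(volume = volume, mask = mask)
    volume$data[mask$data == 1L]
  }
  scale <- switch(reference,
                  range = diff(range(vals)),
                  max   = max(abs(vals)),
                  mean  = mean(abs(vals)))
  if (scale == 0)
    stop("add_noise: reference intensity scale is zero", call. = FALSE)
  sigma <- level_percent / 100 * scale
  noisy <- with_seed(seed, volume$data + array(rnorm(length(volume$data),
                                                     sd = sigma),
                                               dim = dim(volume$data)))
  contrast_volume(noisy, spacing = volume$spacing, kind = volume$kind,
                  meta = volume$meta)
}

model_lookup <- function(model, tissue, contrast) {
  row <- model[model$tissue == tissue & model$contrast == contrast, ]
  if (nrow(row) != 1L)
    stop("intensity model: missing entry for tissue ", tissue,
         ", contrast ", contrast, call. = FALSE)
  row
}

render_noise_seeds <- function(seed) {
  # fixed per-contrast offsets keep noise independent across contrasts
  c(INV1 = seed + 101L, INV2 = seed + 102L, UNI = seed + 103L, T1 = seed + 104L)
}

apply_spec_noise <- function(vols, labels, spec) {
  if (spec$noise_percent == 0) return(vols)
  mask <- brain_mask(array(as.integer(labels$data > 0L), dim = dim(labels$data)),
                     spacing = labels$spacing)
  seeds <- render_noise_seeds(spec$seed)
  for (k in names(vols))
    vols[[k]] <- add_noise(vols[[k]], spec$noise_percent, seed = seeds[[k]],
                           mask = mask, reference = spec$noise_reference)
  vols
}

#' Render phantom contrasts from the empirical intensity model
#'
#' Each voxel's intensity is drawn independently from its tissue's Gaussian
#' for that contrast; Gaussian noise at `spec$noise_percent` is then added
#' per [add_noise()]. Deterministic under the spec's seed.
#'
#' @param labels Ground-truth [tissue_labels()], e.g. from [make_labels()].
#' @param spec A [phantom_spec()].
#' @return Named list of [contrast_volume()]s: `INV1`, `INV2`, `UNI`, `T1`.
#' @export
render_empirical <- function(labels, spec) {
  stopifnot(inherits(labels, "tissue_labels"), inherits(spec, "phantom_spec"))
  codes <- tissue_codes()
  contrasts <- c("INV1", "INV2", "UNI", "T1")
  vols <- with_seed(spec$seed, {
    out <- list()
    for (ct in contrasts) {
      data <- array(0, dim = spec$grid_shape)
      for (tt in c("CSF", "GM", "WM")) {
        row <- model_lookup(spec$intensity_model, tt, ct)
        idx <- which(labels$data == codes[[tt]])
        data[idx] <- rnorm(length(idx), mean = row$mean, sd = row$sd)
      }
      out[[ct]] <- contrast_volume(data, spacing = spec$spacing_mm, kind = ct)
    }
    out
  })
  apply_spec_noise(vols, labels, spec)
}

#' Render phantom contrasts from the inversion-recovery signal model
#'
#' INV1 and INV2 are the magnitudes of [ir_signal()] at the two inversion
#' times, UNI is [combine_uni()] of the signed signals, and the T1 volume
#' holds each tissue's T1 in seconds clipped at `spec$t1_cap`. With zero
#' noise the result is piecewise constant (one value per tissue per
#' contrast); Gaussian noise is then added per [add_noise()].
#'
#' @inheritParams render_empirical
#' @return Named list of [contrast_volume()]s: `INV1`, `INV2`, `UNI`, `T1`.
#' @export
render_physics <- function(labels, spec) {
  stopifnot(inherits(labels, "tissue_labels"), inherits(spec, "phantom_spec"))
  codes <- tissue_codes()
  tissues <- c("CSF", "GM", "WM")
  s1 <- vapply(tissues, function(tt)
    ir_signal(spec$t1_s[[tt]], spec$pd[[tt]], spec$ti1_s, spec$fa1_deg,
              spec$efficiency), numeric(1))
  s2 <- vapply(tissues, function(tt)
    ir_signal(spec$t1_s[[tt]], spec$pd[[tt]], spec$ti2_s, spec$fa2_deg,
              spec$efficiency), numeric(1))
  per_tissue <- list(INV1 = abs(s1), INV2 = abs(s2),
                     UNI = combine_uni(s1, s2),
                     T1 = pmin(unlist(spec$t1_s[tissues]), spec$t1_cap))
  vols <- lapply(names(per_tissue), function(ct) {
    vals <- per_tissue[[ct]]
    data <- array(0, dim = spec$grid_shape)
    for (i in seq_along(tissues))
      data[labels$data == codes[[tissues[i]]]] <- vals[[i]]
    contrast_volume(data, spacing = spec$spacing_mm, kind = ct)
  })
  names(vols) <- names(per_tissue)
  apply_spec_noise(vols, labels, spec)
}

#' Generate a complete synthetic MP2RAGE dataset
#'
#' Convenience wrapper: labels, whole-brain mask (all labeled voxels), and
#' the four rendered contrasts, in the spec's mode.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `labels` ([tissue_labels()]), `mask`
#'   ([brain_mask()]), and `volumes` (named list `INV1`, `INV2`, `UNI`,
#'   `T1`).
#' @export
simulate_phantom <- function(spec) {
  labels <- make_labels(spec)
  vols <- switch(spec$mode,
                 empirical = render_empirical(labels, spec),
                 physics = render_physics(labels, spec))
  mask <- brain_mask(array(as.integer(labels$data > 0L), dim = dim(labels$data)),
                     spacing = spec$spacing_mm)
  list(labels = labels, mask = mask, volumes = vols)
}
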