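#' @name segmentation
#' @title Normalized-intensity tissue segmentation
#'
#' @description
#' The heart of the method. Each brain-extracted contrast is min-max
#' feature-scaled over the in-brain voxels,
#' \deqn{S_{norm} = (S_{raw} - \min S_{raw}) / (\max S_{raw} - \min S_{raw}),}
#' which removes arbitrary intensity scaling and makes the contrasts
#' directly comparable. Tissues are then classified by binarized
#' differences of the normalized images (threshold 0, strict inequality):
#' \deqn{CSF = bin(nINV1 - nUNI)}
#' \deqn{GM  = bin(nT1 - nUNI) - CSF}
#' \deqn{WM  = bin(nUNI) - (CSF + GM)}
#' where "-" is set difference and "+" is union. Thresholds are exposed as
#' adjustable compensation values `tau_csf`, `tau_gm`, `tau_wm`, all
#' defaulting to 0. With `tau_wm = 0` the WM rule assigns every remaining
#' in-brain voxel to WM (since nUNI is nonnegative everywhere by
#' construction, a strict zero threshold would exclude only the single
#' in-brain minimum voxel); with `tau_wm > 0` it is a genuine strict
#' threshold, and voxels passing no rule keep the dedicated "unassigned"
#' label so that CSF, GM, WM, and unassigned always partition the brain
#' exactly.
NULL

#' Segmentation thresholds
#'
#' Compensation values for the three binarization steps, defaulting to 0.
#'
#' @param tau_csf,tau_gm,tau_wm Finite reals.
#' @return A `segmentation_thresholds` object.
#' @export
segmentation_thresholds <- function(tau_csf = 0, tau_gm = 0, tau_wm = 0) {
  stopifnot(is.finite(tau_csf), is.finite(tau_gm), is.finite(tau_wm))
  structure(list(tau_csf = tau_csf, tau_gm = tau_gm, tau_wm = tau_wm),
            class = "segmentation_thresholds")
}

#' Min-max feature scaling over the brain domain
#'
#' Maps in-mask intensities to \[0, 1\] by `(s - min) / (max - min)`, with
#' min and max taken over in-mask voxels only; out-of-mask voxels are set
#' to 0. Invariant under any positive affine rescaling of the input
#' intensities, which is what makes the segmentation independent of scanner
#' intensity dialects.
#'
#' @param volume A [contrast_volume()].
#' @param domain A nonempty [brain_mask()] on the same grid.
#' @return A `normalized_volume`: a [contrast_volume()] subclass whose
#'   in-mask values span exactly \[0, 1\], carrying the domain mask.
#' @export
normalize_volume <- function(volume, domain) {
  stopifnot(inherits(volume, "contrast_volume"), inherits(domain, "brain_mask"))
  check_same_grid(volume = volume, domain = domain)
  idx <- domain$data == 1L
  if (!any(idx))
    stop("normalize_volume: empty domain mask", call. = FALSE)
  vals <- volume$data[idx]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo)
    stop("normalize_volume: degenerate intensity range (constant in-mask ",
         "intensities)", call. = FALSE)
  out <- array(0, dim = dim(volume$data))
  out[idx] <- (vals - lo) / (hi - lo)
  v <- contrast_volume(out, spacing = volume$spacing, kind = volume$kind,
                       meta = volume$meta)
  v$domain <- domain
  class(v) <- c("normalized_volume", class(v))
  v
}

#' Binarize a volume over a domain
#'
#' In-domain voxels strictly greater than `threshold` map to 1, all others
#' (including every out-of-domain voxel) to 0. Strict inequality is the
#' package's reading of "threshold of 0" on difference images, where exact
#' ties carry no evidence.
#'
#' @param volume A [contrast_volume()] (typically a normalized volume or a
#'   voxelwise difference of two).
#' @param threshold Real scalar.
#' @param domain A [brain_mask()] on the same grid.
#' @return A [brain_mask()].
#' @export
binarize <- function(volume, threshold, domain) {
  stopifnot(inherits(volume, "contrast_volume"), inherits(domain, "brain_mask"))
  check_same_grid(volume = volume, domain = domain)
  m <- (volume$data > threshold) & (domain$data == 1L)
  brain_mask(array(as.integer(m), dim = dim(m)), spacing = volume$spacing,
             meta = domain$meta)
}

diff_volume <- function(a, b) {
  contrast_volume(a$data - b$data, spacing = a$spacing)
}

#' Segment brain tissues from normalized MP2RAGE contrasts
#'
#' Applies the three mask-arithmetic rules (see the module description) to
#' normalized UNI, T1, and INV1 volumes sharing one brain domain. CSF is
#' claimed first, GM from the remainder, then WM; in-brain voxels passing
#' no rule (possible only with `tau_wm > 0`) are labeled unassigned, so the
#' four classes always partition the domain exactly.
#'
#' @param nuni,nt1,ninv1 [normalize_volume()] outputs for the UNI, T1, and
#'   INV1 contrasts, normalized over `domain`.
#' @param domain The shared [brain_mask()].
#' @param thresholds A [segmentation_thresholds()] object.
#' @return A [tissue_labels()] volume.
#' @export
segment_tissues <- function(nuni, nt1, ninv1, domain,
                            thresholds = segmentation_thresholds()) {
  for (v in list(nuni, nt1, ninv1))
    stopifnot(inherits(v, "normalized_volume"))
  stopifnot(inherits(domain, "brain_mask"),
            inherits(thresholds, "segmentation_thresholds"))
  check_same_grid(nuni = nuni, nt1 = nt1, ninv1 = ninv1, domain = domain)
  for (v in list(nuni, nt1, ninv1))
    if (!identical(v$domain$data, domain$data))
      stop("segment_tissues: inputs were not normalized over the supplied ",
           "domain", call. = FALSE)

  csf <- binarize(diff_volume(ninv1, nuni), thresholds$tau_csf, domain)$data == 1L
  gm <- (binarize(diff_volume(nt1, nuni), thresholds$tau_gm, domain)$data == 1L) & !csf
  wm_pool <- if (thresholds$tau_wm == 0) domain$data == 1L
             else binarize(nuni, thresholds$tau_wm, domain)$data == 1L
  wm <- wm_pool & !csf & !gm

  codes <- tissue_codes()
  lab <- array(codes[["background"]], dim = dim(domain$data))
  lab[domain$data == 1L] <- codes[["unassigned"]]
  lab[csf] <- codes[["CSF"]]
  lab[gm]  <- codes[["GM"]]
  lab[wm]  <- codes[["WM"]]
  tissue_labels(lab, spacing = domain$spacing, meta = domain$meta)
}

#' Run the full segmentation pipeline on raw contrasts
#'
#' Convenience wrapper: brain extraction (mask application + erosion),
#' normalization of UNI, T1, and INV1 over the eroded domain, and tissue
#' classification.
#'
#' @param uni,t1,inv1 Raw [contrast_volume()]s on one grid.
#' @param mask The brain [brain_mask()].
#' @param erosion_iterations Passed to [extract_brain()] (default 1).
#' @param connectivity Erosion neighborhood (default 6).
#' @param thresholds A [segmentation_thresholds()] object.
#' @return List with `labels` ([tissue_labels()]), `mask` (the eroded
#'   domain), and `normalized` (named list of the three normalized
#'   volumes).
#' @export
segment_mp2rage <- function(uni, t1, inv1, mask, erosion_iterations = 1L,
                            connectivity = 6,
                            thresholds = segmentation_thresholds()) {
  ex <- extract_brain(list(UNI = uni, T1 = t1, INV1 = inv1), mask,
                      erosion_iterations, connectivity)
  dom <- ex$mask
  nuni  <- normalize_volume(ex$volumes$UNI, dom)
  nt1   <- normalize_volume(ex$volumes$T1, dom)
  ninv1 <- normalize_volume(ex$volumes$INV1, dom)
  labels <- segment_tissues(nuni, nt1, ninv1, dom, thresholds)
  list(labels = labels, mask = dom,
       normalized = list(nUNI = nuni, nT1 = nt1, nINV1 = ninv1))
}
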