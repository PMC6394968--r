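#' @name metrics
#' @title Segmentation similarity metrics
#'
#' @description
#' Three complementary measures compare two segmentations of the same grid:
#' the absolute volume difference (AVD, a voxel-count agreement percentage,
#' asymmetric -- the second argument is the reference in the denominator),
#' the Dice coefficient (spatial overlap percentage, symmetric), and the
#' modified Hausdorff distance (MHD, Dubuisson-Jain: the larger of the two
#' directed mean nearest-neighbor distances between boundary point sets,
#' in mm), computed on the tissue mask edges of a single axial slice.
#' A region-of-interest SNR estimator supports the noise study.
NULL

mask_count <- function(mask) sum(mask$data == 1L)

#' Absolute volume difference (percent)
#'
#' `|count(a) - count(b)| / count(b) * 100`. Asymmetric: `mask_b` is the
#' reference whose count sits in the denominator.
#'
#' @param mask_a Candidate [brain_mask()].
#' @param mask_b Reference [brain_mask()], nonempty.
#' @return AVD in percent (>= 0).
#' @export
avd <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "brain_mask"), inherits(mask_b, "brain_mask"))
  check_same_grid(mask_a = mask_a, mask_b = mask_b)
  nb <- mask_count(mask_b)
  if (nb == 0L)
    stop("avd: reference mask is empty", call. = FALSE)
  abs(mask_count(mask_a) - nb) / nb * 100
}

#' Dice similarity coefficient (percent)
#'
#' `2 |a intersect b| / (|a| + |b|) * 100`; symmetric, 100 iff the masks are
#' identical as voxel sets.
#'
#' @param mask_a,mask_b [brain_mask()]s on one grid, not both empty.
#' @return Dice overlap in percent, in \[0, 100\].
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "brain_mask"), inherits(mask_b, "brain_mask"))
  check_same_grid(mask_a = mask_a, mask_b = mask_b)
  na <- mask_count(mask_a); nb <- mask_count(mask_b)
  if (na + nb == 0L)
    stop("dice: both masks are empty", call. = FALSE)
  ninter <- sum(mask_a$data == 1L & mask_b$data == 1L)
  2 * ninter / (na + nb) * 100
}

#' Boundary points of a mask in one axial slice
#'
#' A mask voxel of the chosen slice is an edge point when at least one of
#' its in-slice 4-neighbors lies outside the mask (grid borders count as
#' outside). Coordinates are returned in mm, scaled by the in-plane
#' spacing.
#'
#' @param mask A [brain_mask()].
#' @param slice_index Axial (third-axis) slice, 1-based.
#' @return An `edge_set`: data frame with columns `x_mm`, `y_mm` (unique
#'   points), with the slice index and spacing as attributes. May have
#'   zero rows.
#' @export
mask_edge <- function(mask, slice_index) {
  stopifnot(inherits(mask, "brain_mask"))
  d <- dim(mask$data)
  slice_index <- as.integer(slice_index)
  if (slice_index < 1L || slice_index > d[3])
    stop("mask_edge: slice index ", slice_index, " out of range [1, ",
         d[3], "]", call. = FALSE)
  sl <- mask$data[, , slice_index] == 1L
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sl
  core <- pad[2:(nx + 1L), 2:(ny + 1L)]
  nbr_all <- pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
             pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
  edge <- core & !nbr_all
  idx <- which(edge, arr.ind = TRUE)
  out <- data.frame(x_mm = idx[, 1] * mask$spacing[1],
                    y_mm = idx[, 2] * mask$spacing[2])
  attr(out, "slice_index") <- slice_index
  attr(out, "spacing") <- mask$spacing[1:2]
  class(out) <- c("edge_set", class(out))
  out
}

#' Modified Hausdorff distance between two edge sets
#'
#' Dubuisson-Jain definition: the maximum of the two directed mean
#' nearest-neighbor Euclidean distances, in mm. Symmetric; 0 iff the point
#' sets are equal. Undefined (`NA`) when either set is empty.
#'
#' @param edge_a,edge_b `edge_set`s from [mask_edge()] (any data frame with
#'   `x_mm`, `y_mm` columns works).
#' @return Distance in mm, or `NA_real_` with a warning if an edge set is
#'   empty.
#' @export
mhd <- function(edge_a, edge_b) {
  if (nrow(edge_a) == 0L || nrow(edge_b) == 0L) {
    warning("mhd: empty edge set; distance undefined", call. = FALSE)
    return(NA_real_)
  }
  dx <- outer(edge_a$x_mm, edge_b$x_mm, `-`)
  dy <- outer(edge_a$y_mm, edge_b$y_mm, `-`)
  dmat <- sqrt(dx^2 + dy^2)
  max(mean(apply(dmat, 1, min)), mean(apply(dmat, 2, min)))
}

#' Region-of-interest signal-to-noise ratio
#'
#' Mean intensity over the signal ROI divided by the noise standard
#' deviation, the latter either measured as the SD of intensities over a
#' reference ROI or supplied directly as a known injected noise SD.
#'
#' @param volume A [contrast_volume()].
#' @param signal_roi Nonempty [brain_mask()] selecting the signal region.
#' @param reference Either a [brain_mask()] (noise SD = SD of the volume
#'   over that region) or a single positive number (known noise SD).
#' @return The SNR ratio.
#' @export
snr_roi <- function(volume, signal_roi, reference) {
  stopifnot(inherits(volume, "contrast_volume"),
            inherits(signal_roi, "brain_mask"))
  check_same_grid(volume = volume, signal_roi = signal_roi)
  if (mask_count(signal_roi) == 0L)
    stop("snr_roi: empty signal ROI", call. = FALSE)
  if (inherits(reference, "brain_mask")) {
    check_same_grid(volume = volume, reference = reference)
    noise_sd <- sd(volume$data[reference$data == 1L])
  } else {
    stopifnot(is.numeric(reference), length(reference) == 1L)
    noise_sd <- reference
  }
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("snr_roi: zero noise SD", call. = FALSE)
  mean(volume$data[signal_roi$data == 1L]) / noise_sd
}

label_mask <- function(labels, code) {
  brain_mask(array(as.integer(labels$data == code), dim = dim(labels$data)),
             spacing = labels$spacing)
}

#' Per-tissue similarity report between two label maps
#'
#' For each tissue (CSF, GM, WM): AVD with `labels_b` as reference, Dice,
#' and MHD on one axial slice. The slice defaults to the axial slice
#' through the centroid of the reference's brain voxels. A tissue absent
#' from the reference yields `NA` metrics with a warning, never 0.
#'
#' @param labels_a Candidate [tissue_labels()].
#' @param labels_b Reference [tissue_labels()] (AVD denominator).
#' @param slice_index Axial slice for MHD, or `"auto"` (default).
#' @return Data frame with one row per tissue: `tissue`, `avd_percent`,
#'   `dice_percent`, `mhd_mm`, `slice_index`, `n_test`, `n_ref`.
#' @export
similarity_report <- function(labels_a, labels_b, slice_index = "auto") {
  stopifnot(inherits(labels_a, "tissue_labels"),
            inherits(labels_b, "tissue_labels"))
  check_same_grid(labels_a = labels_a, labels_b = labels_b)
  if (identical(slice_index, "auto")) {
    zidx <- which(labels_b$data > 0L & labels_b$data < 4L,
                  arr.ind = TRUE)[, 3]
    if (length(zidx) == 0L)
      stop("similarity_report: reference has no tissue voxels", call. = FALSE)
    slice_index <- as.integer(round(mean(zidx)))
  }
  codes <- tissue_codes()
  tissues <- c("CSF", "GM", "WM")
  rows <- lapply(tissues, function(tt) {
    ma <- label_mask(labels_a, codes[[tt]])
    mb <- label_mask(labels_b, codes[[tt]])
    na <- mask_count(ma); nb <- mask_count(mb)
    if (nb == 0L) {
      warning("similarity_report: tissue ", tt,
              " absent from reference; metrics undefined", call. = FALSE)
      return(data.frame(tissue = tt, avd_percent = NA_real_,
                        dice_percent = NA_real_, mhd_mm = NA_real_,
                        slice_index = slice_index, n_test = na, n_ref = nb))
    }
    ea <- mask_edge(ma, slice_index)
    eb <- mask_edge(mb, slice_index)
    mh <- if (nrow(ea) == 0L || nrow(eb) == 0L) {
      warning("similarity_report: tissue ", tt, " has an empty edge set in ",
              "slice ", slice_index, "; MHD undefined", call. = FALSE)
      NA_real_
    } else mhd(ea, eb)
    data.frame(tissue = tt, avd_percent = avd(ma, mb),
               dice_percent = dice(ma, mb), mhd_mm = mh,
               slice_index = slice_index, n_test = na, n_ref = nb)
  })
  do.call(rbind, rows)
}
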