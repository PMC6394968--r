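#' @name volumes
#' @title Spatial data types for MP2RAGE processing
#'
#' @description
#' Three light containers are used throughout the package, all carrying a 3D
#' array, a per-axis voxel spacing in millimetres, and (opaquely) any NIfTI
#' header read from disk:
#' \describe{
#'   \item{`contrast_volume`}{one MP2RAGE contrast image (UNI, T1, INV1,
#'     INV2, or UNIDEN), arbitrary intensity units;}
#'   \item{`brain_mask`}{a binary volume defining the extracted-brain
#'     domain;}
#'   \item{`tissue_labels`}{an integer label volume with codes
#'     0 = background, 1 = CSF, 2 = GM, 3 = WM, 4 = unassigned-in-brain.}
#' }
#' All processing happens in voxel space on a common grid; spatial metadata
#' is passed through untouched so outputs stay aligned with their inputs.
NULL

CONTRAST_KINDS <- c("UNI", "T1", "INV1", "INV2", "UNIDEN")

#' Tissue label codes
#'
#' @return Named integer vector mapping tissue names to label codes used in
#'   `tissue_labels` volumes.
#' @export
#' @examples
#' tissue_codes()
tissue_codes <- function() {
  c(background = 0L, CSF = 1L, GM = 2L, WM = 3L, unassigned = 4L)
}

check_array3d <- function(data, what) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop(what, ": data must be a 3D array, got dimensions (",
         paste(dim(data), collapse = ", "), ")", call. = FALSE)
  if (any(dim(data) < 1L))
    stop(what, ": all three dimensions must be >= 1", call. = FALSE)
  invisible(data)
}

check_spacing <- function(spacing, what) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(what, ": spacing must be 3 strictly positive values (mm)",
         call. = FALSE)
  spacing
}

#' Construct a contrast volume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Per-axis voxel size in mm (length 3, positive).
#' @param kind Contrast kind, one of `"UNI"`, `"T1"`, `"INV1"`, `"INV2"`,
#'   `"UNIDEN"`, or `NA` when unknown.
#' @param meta Optional NIfTI header carried through to [write_volume()].
#' @return An object of class `contrast_volume`.
#' @export
contrast_volume <- function(data, spacing = c(1, 1, 1), kind = NA_character_,
                            meta = NULL) {
  check_array3d(data, "contrast_volume")
  if (!is.na(kind))
    kind <- match.arg(kind, CONTRAST_KINDS)
  if (any(!is.finite(data)))
    stop("contrast_volume: data contains non-finite values", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = check_spacing(spacing, "contrast_volume"),
                 kind = kind, meta = meta),
            class = c("contrast_volume", "mp2_volume"))
}

#' Construct a binary brain mask
#'
#' Values must be exactly 0 or 1.
#'
#' @inheritParams contrast_volume
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, spacing = c(1, 1, 1), meta = NULL) {
  check_array3d(data, "brain_mask")
  if (any(!is.finite(data)) || !all(data %in% c(0, 1)))
    stop("brain_mask: values must be exactly 0 or 1", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = check_spacing(spacing, "brain_mask"),
                 meta = meta),
            class = c("brain_mask", "mp2_volume"))
}

#' Construct a tissue label map
#'
#' @inheritParams contrast_volume
#' @return An object of class `tissue_labels`; codes as in [tissue_codes()].
#' @export
tissue_labels <- function(data, spacing = c(1, 1, 1), meta = NULL) {
  check_array3d(data, "tissue_labels")
  if (any(!is.finite(data)) || !all(data %in% 0:4))
    stop("tissue_labels: label codes must be in {0,1,2,3,4}", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = check_spacing(spacing, "tissue_labels"),
                 meta = meta),
            class = c("tissue_labels", "mp2_volume"))
}

#' @export
print.mp2_volume <- function(x, ...) {
  kind <- if (!is.null(x$kind)) paste0(" [", x$kind, "]") else ""
  cat(sprintf("<%s>%s %s voxels, spacing %s mm\n",
              class(x)[1], kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  if (inherits(x, "brain_mask"))
    cat(sprintf("  %d voxels in mask\n", sum(x$data)))
  if (inherits(x, "tissue_labels")) {
    cnt <- tabulate(x$data + 1L, nbins = 5L)
    names(cnt) <- names(tissue_codes())
    cat("  voxels per label: ",
        paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3D NIfTI-1 image (`.nii` or `.nii.gz`) into a [contrast_volume()],
#' taking voxel spacing from the header and keeping the header itself so it
#' can be written back unchanged. Integer-scaled UNI dialects (e.g. 0--4095)
#' are accepted as-is; downstream min-max normalization removes any positive
#' affine intensity scaling.
#'
#' @param path Path to an existing NIfTI-1 file.
#' @param expected_kind Optional contrast kind recorded on the result.
#' @param nonfinite Policy for non-finite voxels: `"error"` (default)
#'   rejects the file; `"zero"` maps them to 0 and emits a message with the
#'   count. Silent NaN propagation would corrupt min/max normalization, so
#'   there is no pass-through option.
#' @return A [contrast_volume()].
#' @seealso [read_mask()], [read_labels()], [write_volume()]
#' @export
read_volume <- function(path, expected_kind = NA_character_,
                        nonfinite = c("error", "zero")) {
  nonfinite <- match.arg(nonfinite)
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim = dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("read_volume: non-3D image (", length(dim(data)),
         " dimensions): ", path, call. = FALSE)
  nbad <- sum(!is.finite(data))
  if (nbad > 0) {
    if (nonfinite == "error")
      stop("read_volume: ", nbad, " non-finite voxels in ", path,
           " (use nonfinite = \"zero\" to map them to 0)", call. = FALSE)
    message("read_volume: mapped ", nbad, " non-finite voxels to 0 in ", path)
    data[!is.finite(data)] <- 0
  }
  contrast_volume(data, spacing = RNifti::pixdim(img)[1:3],
                  kind = expected_kind, meta = RNifti::niftiHeader(img))
}

#' Read a NIfTI-1 file as a brain mask
#'
#' Voxels strictly greater than 0.5 become 1; this tolerates masks stored as
#' float 0/1.
#'
#' @inheritParams read_volume
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  brain_mask(array(as.integer(v$data > 0.5), dim = dim(v$data)),
             spacing = v$spacing, meta = v$meta)
}

#' Read a NIfTI-1 file as a tissue label map
#'
#' @inheritParams read_volume
#' @return A [tissue_labels()] volume; values are rounded to the nearest
#'   integer before validation so float-encoded label files are accepted.
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  tissue_labels(array(as.integer(round(v$data)), dim = dim(v$data)),
                spacing = v$spacing, meta = v$meta)
}

#' Write a volume, mask, or label map as NIfTI-1
#'
#' Contrast volumes are stored as float64 so that write-then-read is exact;
#' masks and label maps are stored with an integer datatype.
#'
#' @param x A `contrast_volume`, `brain_mask`, or `tissue_labels` object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "mp2_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("write_volume: directory does not exist: ", dir, call. = FALSE)
  img <- if (!is.null(x$meta)) RNifti::asNifti(x$data, reference = x$meta)
         else RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  dtype <- if (inherits(x, "contrast_volume")) "double" else "uint8"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

grid_signature <- function(x) {
  list(shape = dim(x$data), spacing = x$spacing)
}

#' Check that volumes share one voxel grid
#'
#' The segmentation assumes contrasts acquired in a single MP2RAGE sequence,
#' i.e. co-registered by construction; this guard refuses mixed grids rather
#' than resampling.
#'
#' @param ... `mp2_volume` objects, or a single list of them. Named
#'   arguments improve the error message.
#' @return Invisibly `TRUE`; otherwise an error naming the offending pair.
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && !inherits(vols[[1]], "mp2_volume"))
    vols <- vols[[1]]
  if (length(vols) == 0L)
    stop("check_same_grid: no volumes supplied", call. = FALSE)
  nms <- names(vols)
  if (is.null(nms)) nms <- rep("", length(vols))
  nms <- ifelse(nms == "", paste0("volume ", seq_along(vols)), nms)
  ref <- grid_signature(vols[[1]])
  for (i in seq_along(vols)[-1]) {
    sig <- grid_signature(vols[[i]])
    if (!identical(as.integer(sig$shape), as.integer(ref$shape)))
      stop(sprintf("check_same_grid: shape mismatch between %s (%s) and %s (%s)",
                   nms[1], paste(ref$shape, collapse = "x"),
                   nms[i], paste(sig$shape, collapse = "x")), call. = FALSE)
    if (!isTRUE(all.equal(sig$spacing, ref$spacing, tolerance = 1e-6)))
      stop(sprintf("check_same_grid: spacing mismatch between %s (%s mm) and %s (%s mm)",
                   nms[1], paste(format(ref$spacing), collapse = "x"),
                   nms[i], paste(format(sig$spacing), collapse = "x")),
           call. = FALSE)
  }
  invisible(TRUE)
}
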