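#' @name extraction
#' @title Brain extraction by mask application
#'
#' @description
#' Skull stripping itself is out of scope: the package consumes a binary
#' brain mask produced externally (typically from the INV2 image, whose
#' contrast suits automated extraction) or taken from phantom ground truth.
#' The mask is applied to the remaining contrasts, optionally after binary
#' morphological erosion to peel off residual non-brain voxels at the mask
#' border.
NULL

connectivity_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dist <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6"  = dist == 1,
                 "18" = dist >= 1 & pmax(abs(off$dx), abs(off$dy), abs(off$dz)) == 1 & dist <= 2,
                 "26" = dist >= 1,
                 stop("connectivity must be 6, 18, or 26", call. = FALSE))
  off[keep, , drop = FALSE]
}

shift_and <- function(acc, m, dx, dy, dz) {
  d <- dim(m)
  shifted <- array(FALSE, dim = d)
  xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
  ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
  zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
  shifted[xs, ys, zs] <- m[xs + dx, ys + dy, zs + dz]
  acc & shifted
}

erode_once <- function(m, offsets) {
  acc <- m
  for (i in seq_len(nrow(offsets)))
    acc <- shift_and(acc, m, offsets$dx[i], offsets$dy[i], offsets$dz[i])
  acc
}

#' Binary morphological erosion of a brain mask
#'
#' A voxel survives one iteration iff it and all neighbors in the chosen 3D
#' neighborhood are inside the mask; voxels beyond the grid edge count as
#' outside. Repeated `iterations` times. The result is always a subset of
#' the input.
#'
#' @param mask A [brain_mask()], nonempty.
#' @param iterations Number of erosion passes; 0 returns the mask unchanged.
#' @param connectivity Neighborhood: 6 (faces, default), 18 (faces + edges),
#'   or 26 (full cube).
#' @return The eroded [brain_mask()].
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = 6) {
  stopifnot(inherits(mask, "brain_mask"))
  iterations <- as.integer(iterations)
  if (iterations < 0)
    stop("erode_mask: iterations must be >= 0", call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("erode_mask: mask is empty", call. = FALSE)
  if (iterations == 0L) return(mask)
  offsets <- connectivity_offsets(connectivity)
  m <- mask$data == 1L
  for (i in seq_len(iterations)) {
    m <- erode_once(m, offsets)
    if (!any(m))
      stop("erode_mask: mask emptied after ", i,
           " iteration(s); use fewer iterations", call. = FALSE)
  }
  brain_mask(array(as.integer(m), dim = dim(m)), spacing = mask$spacing,
             meta = mask$meta)
}

#' Apply a brain mask to a set of contrast volumes
#'
#' Erodes the (INV2-derived) mask `erosion_iterations` times, then zeroes
#' every out-of-mask voxel of each volume. In-mask intensities pass through
#' bit-exact.
#'
#' @param volumes A named list of [contrast_volume()]s on one grid.
#' @param inv2_mask The [brain_mask()] (e.g. from brain-extracted INV2).
#' @param erosion_iterations Erosion passes applied to the mask first
#'   (default 1).
#' @param connectivity Erosion neighborhood, see [erode_mask()].
#' @return List with `volumes` (masked copies, same names) and `mask` (the
#'   eroded [brain_mask()]).
#' @export
extract_brain <- function(volumes, inv2_mask, erosion_iterations = 1L,
                          connectivity = 6) {
  stopifnot(is.list(volumes), length(volumes) >= 1L,
            inherits(inv2_mask, "brain_mask"))
  check_same_grid(c(volumes, list(mask = inv2_mask)))
  mask <- erode_mask(inv2_mask, erosion_iterations, connectivity)
  keep <- mask$data == 1L
  masked <- lapply(volumes, function(v) {
    d <- v$data
    d[!keep] <- 0
    contrast_volume(d, spacing = v$spacing, kind = v$kind, meta = v$meta)
  })
  list(volumes = masked, mask = mask)
}
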