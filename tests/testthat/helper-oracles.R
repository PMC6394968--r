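# Brute-force reference implementations and tiny fixtures, independent of
# the package's vectorized code paths.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 32),
               semi_csf = c(13, 13, 12), semi_gm = c(10, 10, 9),
               semi_wm = c(7, 7, 6), ventricle = c(3, 2, 2), ...)
}

random_mask <- function(shape, p = 0.4) {
  brain_mask(array(as.integer(runif(prod(shape)) < p), dim = shape),
             spacing = c(1, 1, 1))
}

# AVD / DICE by explicit voxel loops
avd_oracle <- function(a, b) {
  na <- 0L; nb <- 0L
  for (i in seq_along(a$data)) {
    na <- na + (a$data[i] == 1L)
    nb <- nb + (b$data[i] == 1L)
  }
  abs(na - nb) / nb * 100
}

dice_oracle <- function(a, b) {
  na <- 0L; nb <- 0L; ni <- 0L
  for (i in seq_along(a$data)) {
    na <- na + (a$data[i] == 1L)
    nb <- nb + (b$data[i] == 1L)
    ni <- ni + (a$data[i] == 1L && b$data[i] == 1L)
  }
  2 * ni / (na + nb) * 100
}

# in-slice 4-neighborhood edge detection by per-pixel scan
edge_oracle <- function(mask, k) {
  sl <- mask$data[, , k]
  pts <- NULL
  for (i in seq_len(nrow(sl))) for (j in seq_len(ncol(sl))) {
    if (sl[i, j] != 1L) next
    nb <- c(if (i > 1) sl[i - 1, j] else 0L,
            if (i < nrow(sl)) sl[i + 1, j] else 0L,
            if (j > 1) sl[i, j - 1] else 0L,
            if (j < ncol(sl)) sl[i, j + 1] else 0L)
    if (any(nb == 0L))
      pts <- rbind(pts, c(i * mask$spacing[1], j * mask$spacing[2]))
  }
  if (is.null(pts)) data.frame(x_mm = numeric(0), y_mm = numeric(0))
  else data.frame(x_mm = pts[, 1], y_mm = pts[, 2])
}

# Dubuisson-Jain MHD via the full pairwise distance table
mhd_oracle <- function(ea, eb) {
  dmin_ab <- numeric(nrow(ea))
  for (i in seq_len(nrow(ea))) {
    best <- Inf
    for (j in seq_len(nrow(eb)))
      best <- min(best, sqrt((ea$x_mm[i] - eb$x_mm[j])^2 +
                             (ea$y_mm[i] - eb$y_mm[j])^2))
    dmin_ab[i] <- best
  }
  dmin_ba <- numeric(nrow(eb))
  for (j in seq_len(nrow(eb))) {
    best <- Inf
    for (i in seq_len(nrow(ea)))
      best <- min(best, sqrt((ea$x_mm[i] - eb$x_mm[j])^2 +
                             (ea$y_mm[i] - eb$y_mm[j])^2))
    dmin_ba[j] <- best
  }
  max(mean(dmin_ab), mean(dmin_ba))
}

# binary erosion by explicit neighborhood scan (6-connectivity)
erode_oracle6 <- function(m) {
  d <- dim(m)
  out <- array(0L, dim = d)
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) 0L
    else m[i, j, k]
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] == 1L &&
        at(i - 1, j, k) && at(i + 1, j, k) &&
        at(i, j - 1, k) && at(i, j + 1, k) &&
        at(i, j, k - 1) && at(i, j, k + 1))
      out[i, j, k] <- 1L
  }
  out
}

# per-voxel three-rule classification loop (threshold 0, strict)
segment_oracle <- function(nuni, nt1, ninv1, domain) {
  d <- dim(domain$data)
  lab <- array(0L, dim = d)
  for (i in seq_along(lab)) {
    if (domain$data[i] != 1L) next
    if (ninv1$data[i] - nuni$data[i] > 0) lab[i] <- 1L
    else if (nt1$data[i] - nuni$data[i] > 0) lab[i] <- 2L
    else lab[i] <- 3L
  }
  lab
}

dice_vs_truth <- function(labels_a, labels_b, tissue) {
  code <- tissue_codes()[[tissue]]
  ma <- brain_mask(array(as.integer(labels_a$data == code),
                         dim = dim(labels_a$data)), labels_a$spacing)
  mb <- brain_mask(array(as.integer(labels_b$data == code),
                         dim = dim(labels_b$data)), labels_b$spacing)
  dice(ma, mb)
}
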