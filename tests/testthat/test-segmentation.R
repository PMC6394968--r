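domain_of <- function(shape) brain_mask(array(1L, dim = shape))

test_that("normalize_volume implements feature scaling with its invariants", {
  v <- contrast_volume(array(c(3, 5, 7, 5, 3, 7, 7, 3), dim = c(2, 2, 2)))
  dom <- domain_of(c(2, 2, 2))
  n <- normalize_volume(v, dom)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.5, 1))
  expect_equal(min(n$data[dom$data == 1L]), 0)
  expect_equal(max(n$data[dom$data == 1L]), 1)

  # min/max over in-mask voxels only; out-of-mask forced to 0
  dom2 <- brain_mask(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), dim = c(2, 2, 2)))
  n2 <- normalize_volume(v, dom2)
  expect_equal(max(n2$data[dom2$data == 1L]), 1)
  expect_true(all(n2$data[dom2$data == 0L] == 0))

  # affine invariance: normalize(a*v + b) == normalize(v) for a > 0
  set.seed(8)
  w <- contrast_volume(array(rnorm(27), dim = c(3, 3, 3)))
  dom3 <- domain_of(c(3, 3, 3))
  base <- normalize_volume(w, dom3)$data
  for (i in 1:5) {
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    scaled <- contrast_volume(a * w$data + b)
    expect_equal(normalize_volume(scaled, dom3)$data, base, tolerance = 1e-12)
  }

  const <- contrast_volume(array(4, dim = c(3, 3, 3)))
  expect_error(normalize_volume(const, dom3), "degenerate intensity range")
})

test_that("binarize uses strict inequality and respects the domain", {
  v <- contrast_volume(array(c(-0.2, 0, 0.3, 1, -1, 0.5, 0, 2), dim = c(2, 2, 2)))
  dom <- domain_of(c(2, 2, 2))
  b <- binarize(v, 0, dom)
  expect_identical(as.vector(b$data), c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L))

  expect_identical(sum(binarize(v, -Inf, dom)$data), 8L)

  # out-of-domain always 0
  dom2 <- brain_mask(array(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L), dim = c(2, 2, 2)))
  b2 <- binarize(v, -Inf, dom2)
  expect_identical(b2$data, dom2$data)

  # voxel-by-voxel loop oracle on random volumes
  set.seed(21)
  for (i in 1:10) {
    r <- contrast_volume(array(rnorm(64), dim = c(4, 4, 4)))
    dm <- random_mask(c(4, 4, 4), 0.7)
    thr <- rnorm(1, sd = 0.5)
    got <- binarize(r, thr, dm)$data
    want <- array(0L, dim = c(4, 4, 4))
    for (j in seq_along(want))
      want[j] <- as.integer(dm$data[j] == 1L && r$data[j] > thr)
    expect_identical(got, want)
  }
})

test_that("segment_tissues reproduces the hand-evaluated single-voxel rules", {
  # (ninv1, nt1, nuni) triplets and their expected labels:
  cases <- list(list(c(0.7, 0.9, 0.1), "CSF"),   # nINV1 - nUNI > 0
                list(c(0.2, 0.5, 0.4), "GM"),    # nINV1 <= nUNI, nT1 > nUNI
                list(c(0.0, 0.2, 0.9), "WM"))    # both differences <= 0
  # embed each triplet in a 3-voxel domain alongside anchor voxels that pin
  # the in-mask min to 0 and max to 1 so normalization is the identity
  for (cs in cases) {
    tri <- cs[[1]]
    dom <- brain_mask(array(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), dim = c(2, 2, 2)))
    mk <- function(x) {
      v <- contrast_volume(array(c(x, 0, 1, 0, 0, 0, 0, 0), dim = c(2, 2, 2)))
      normalize_volume(v, dom)
    }
    seg <- segment_tissues(mk(tri[3]), mk(tri[2]), mk(tri[1]), dom)
    expect_identical(seg$data[1], tissue_codes()[[cs[[2]]]],
                     label = paste("triplet", paste(tri, collapse = "/")))
  }
})

test_that("segment_tissues matches the per-voxel rule oracle on random inputs", {
  set.seed(99)
  for (i in 1:5) {
    dom <- random_mask(c(8, 8, 8), 0.8)
    mkrand <- function() {
      v <- contrast_volume(array(rnorm(512), dim = c(8, 8, 8)))
      normalize_volume(v, dom)
    }
    nuni <- mkrand(); nt1 <- mkrand(); ninv1 <- mkrand()
    seg <- segment_tissues(nuni, nt1, ninv1, dom)
    expect_identical(seg$data, segment_oracle(nuni, nt1, ninv1, dom))
  }
})

test_that("CSF/GM/WM/unassigned partition the domain exactly", {
  set.seed(13)
  for (i in 1:5) {
    spec <- small_spec(seed = 500L + i, noise_percent = runif(1, 0, 12))
    ph <- simulate_phantom(spec)
    thr <- segmentation_thresholds(tau_csf = rnorm(1, 0, 0.1),
                                   tau_gm = rnorm(1, 0, 0.1),
                                   tau_wm = runif(1, 0, 0.2))
    seg <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                           ph$mask, erosion_iterations = 0, thresholds = thr)
    lab <- seg$labels$data
    dom <- seg$mask$data
    expect_true(all(lab[dom == 1L] %in% 1:4))       # every in-brain voxel labeled
    expect_true(all(lab[dom == 0L] == 0L))          # nothing outside
  }
})

test_that("tau_wm > 0 excludes sub-threshold voxels as unassigned; tau_wm = 0 labels the whole remainder", {
  spec <- small_spec(seed = 4L)
  ph <- simulate_phantom(spec)
  seg0 <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                          ph$mask, erosion_iterations = 0)
  expect_identical(sum(seg0$labels$data == tissue_codes()[["unassigned"]]), 0L)

  thr <- segmentation_thresholds(tau_wm = 0.97)
  seg1 <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                          ph$mask, erosion_iterations = 0, thresholds = thr)
  un <- seg1$labels$data == tissue_codes()[["unassigned"]]
  expect_gt(sum(un), 0L)
  # unassigned voxels are exactly those failing all three rules
  n <- seg1$normalized
  expect_true(all(n$nUNI$data[un] <= 0.97))
  expect_true(all(n$nINV1$data[un] - n$nUNI$data[un] <= 0))
  expect_true(all(n$nT1$data[un] - n$nUNI$data[un] <= 0))
})

test_that("segmentation is invariant under positive affine rescaling of raw inputs", {
  spec <- small_spec(seed = 60L, noise_percent = 5)
  ph <- simulate_phantom(spec)
  base <- segment_mp2rage(ph$volumes$UNI, ph$volumes$T1, ph$volumes$INV1,
                          ph$mask)$labels$data
  set.seed(61)
  for (i in 1:3) {
    scale_one <- function(v) {
      contrast_volume(runif(1, 0.2, 30) * v$data + runif(1, -50, 50),
                      spacing = v$spacing, kind = v$kind)
    }
    vs <- lapply(ph$volumes, scale_one)
    got <- segment_mp2rage(vs$UNI, vs$T1, vs$INV1, ph$mask)$labels$data
    expect_identical(got, base)
  }
})

test_that("segment_tissues refuses mismatched domains", {
  dom <- domain_of(c(3, 3, 3))
  other <- brain_mask(array(c(rep(1L, 13), rep(0L, 14)), dim = c(3, 3, 3)))
  mk <- function(d) normalize_volume(contrast_volume(array(rnorm(27), dim = c(3, 3, 3))), d)
  set.seed(1)
  expect_error(segment_tissues(mk(dom), mk(dom), mk(other), dom),
               "not normalized over")
})
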