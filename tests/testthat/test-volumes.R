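test_that("ultrasound_volume validates its invariants", {
  arr <- array(runif(8), c(2, 2, 2))
  v <- ultrasound_volume(arr, c(0.1, 0.2, 0.3))
  expect_s3_class(v, "us_volume")
  expect_equal(unname(volume_extent_mm(v)), c(0.2, 0.4, 0.6))
  expect_error(ultrasound_volume(arr, c(0, 0.2, 0.3)), "spacing")
  expect_error(ultrasound_volume(array(1, c(1, 2, 2)), c(1, 1, 1)),
               "at least 2")
  arr[1] <- NA
  expect_error(ultrasound_volume(arr, c(1, 1, 1)), "finite")
})

test_that("extract_roi reproduces the canonical ABUS ROI geometry", {
  set.seed(1)
  v <- ultrasound_volume(array(runif(200 * 200 * 40), c(200, 200, 40)),
                         c(0.07, 0.07, 0.53))
  roi <- extract_roi(v, center_mm = c(7, 7, 10.6), size_mm = c(10, 10, 10))
  expect_equal(roi$size, c(143L, 143L, 19L))
  # physical size recomputed from voxel counts within half a voxel per axis
  expect_true(all(abs(roi$physical_size - c(10, 10, 10)) <=
                    v$spacing / 2 + 1e-12))
  # a different spacing: plain rounding arithmetic
  v2 <- ultrasound_volume(array(runif(120 * 120 * 30), c(120, 120, 30)),
                          c(0.1, 0.1, 0.5))
  roi2 <- extract_roi(v2, c(6, 6, 7.5), c(10, 10, 10))
  expect_equal(roi2$size, c(100L, 100L, 20L))
  # full-volume ROI centered => origin 0
  ext <- volume_extent_mm(v2)
  expect_equal(extract_roi(v2, ext / 2, ext)$origin, c(0L, 0L, 0L))
  # out-of-bounds is an error, not a clip
  expect_error(extract_roi(v, c(1, 1, 1), c(10, 10, 10)), "bounds")
})

test_that("slice_plane does the axis bookkeeping", {
  # hand-labeled toy volume: value = 100*z + 10*x + y (0-based indices)
  d <- c(4, 3, 5)
  arr <- array(0, d)
  for (z in 1:d[1]) for (x in 1:d[2]) for (y in 1:d[3])
    arr[z, x, y] <- 100 * (z - 1) + 10 * (x - 1) + (y - 1)
  roi <- as_roi3d(arr, c(1, 1, 1))
  cor <- slice_plane(roi, "coronal", 2)       # fixed z = 2
  expect_equal(dim(cor$data), c(3, 5))        # width x sweep
  expect_equal(cor$data[2, 4], 100 * 2 + 10 * 1 + 3)
  ax <- slice_plane(roi, "axial", 1)          # fixed y = 1
  expect_equal(dim(ax$data), c(4, 3))         # depth x width
  expect_equal(ax$data[3, 2], 100 * 2 + 10 * 1 + 1)
  sag <- slice_plane(roi, "sagittal", 0)      # fixed x = 0
  expect_equal(dim(sag$data), c(4, 5))        # depth x sweep
  # central slice defaults and bounds
  expect_equal(slice_plane(roi, "coronal")$index, 1L)   # floor((4-1)/2)
  expect_error(slice_plane(roi, "coronal", -1), "out of range")
  expect_error(slice_plane(roi, "coronal", 4), "out of range")
})

test_that("canonical 143x143x19 ROI slices to 143x19 coronal, 143x143 axial", {
  roi <- structure(list(origin = c(0L, 0L, 0L), size = c(143L, 143L, 19L),
                        spacing = c(z = 0.07, x = 0.07, y = 0.53),
                        physical_size = c(10.01, 10.01, 10.07),
                        data = array(0, c(143, 143, 19))),
                   class = "roi3d")
  expect_equal(dim(slice_plane(roi, "coronal")$data), c(143, 19))
  expect_equal(dim(slice_plane(roi, "axial")$data), c(143, 143))
})

test_that("slices of a sweep-constant volume are identical across sweep", {
  set.seed(2)
  sl <- matrix(runif(6 * 5), 6, 5)
  arr <- array(rep(sl, 4), c(6, 5, 4))       # constant along sweep
  roi <- as_roi3d(arr)
  ax <- lapply(0:3, function(i) slice_plane(roi, "axial", i)$data)
  for (i in 2:4) expect_identical(ax[[i]], ax[[1]])
})

test_that("quantize bins uniformly, handles degenerate input, is monotone", {
  expect_true(all(quantize(matrix(5, 4, 4), 32) == 0L))
  # full 0..255 ramp at G = 2: lower half 0, upper half 1 (brute force)
  r <- matrix(0:255, 16, 16)
  q <- quantize(r, 2)
  expect_true(all(q[r <= 127] == 0L))
  expect_true(all(q[r >= 128] == 1L))
  expect_error(quantize(r, 1), "G")
  set.seed(3)
  for (G in c(2, 5, 32)) {
    x <- matrix(rnorm(400), 20, 20)
    q <- quantize(x, G)
    expect_lte(max(q), G - 1L)
    expect_gte(min(q), 0L)
    ord <- order(x)
    expect_true(all(diff(q[ord]) >= 0L))     # monotone in intensity
  }
})

test_that("NIfTI round trip preserves data, spacing and axes", {
  set.seed(4)
  v <- ultrasound_volume(array(runif(10 * 12 * 9), c(10, 12, 9)),
                         c(0.07, 0.07, 0.53))
  for (ext in c(".nii", ".nii.gz")) {
    tf <- tempfile(fileext = ext)
    write_nifti(v, tf)
    v2 <- load_volume(tf)
    expect_equal(v2$data, v$data, tolerance = 1e-6)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    unlink(tf)
  }
})

test_that("sidecar metadata overrides and validates spacing", {
  set.seed(5)
  v <- ultrasound_volume(array(runif(8^3), c(8, 8, 8)), c(0.1, 0.1, 0.1))
  tf <- tempfile(fileext = ".nii")
  write_nifti(v, tf)
  sc <- tempfile(fileext = ".json")
  writeLines('{"spacing_mm": [0.07, 0.07, 0.53], "axes": "zxy"}', sc)
  v2 <- load_volume(tf, sidecar = sc)
  expect_equal(unname(v2$spacing), c(0.07, 0.07, 0.53))
  writeLines('{"spacing_mm": [0, 0.07, 0.53]}', sc)
  expect_error(load_volume(tf, sidecar = sc), "spacing")
  unlink(c(tf, sc))
})
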