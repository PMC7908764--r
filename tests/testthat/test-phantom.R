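# Small phantoms (coarse grids) keep these tests fast; the full-scale
# benchmark world is exercised in test-acceptance.R.

small_spec <- function(...) {
  phantom_spec(shape_mm = c(20, 10, 10), spacing_mm = c(0.2, 0.2, 0.5),
               depth_mm = 10, ...)
}

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(pore_size_mm = 0.4, filament_width_mm = 0.5),
               "pore_size")
  expect_error(phantom_spec(depth_mm = 99, shape_mm = c(40, 14, 14)),
               "depth")
  expect_error(phantom_spec(shrink_factor = 0), "shrink")
  expect_error(phantom_spec(speckle_scale = -1), "scale")
})

test_that("speckle generation is seeded and has the Rayleigh mean", {
  sp <- small_spec(seed = 99, blur_sigma_mm = c(0, 0, 0))
  v1 <- make_speckle_volume(sp)
  v2 <- make_speckle_volume(sp)
  expect_identical(v1$data, v2$data)
  sp2 <- small_spec(seed = 100, blur_sigma_mm = c(0, 0, 0))
  expect_false(identical(make_speckle_volume(sp2)$data, v1$data))
  # Rayleigh(s) mean = s*sqrt(pi/2), within 3 standard errors
  s <- 2.5
  spb <- phantom_spec(shape_mm = c(20, 20, 20), spacing_mm = c(0.2, 0.2, 0.2),
                      speckle_scale = s, blur_sigma_mm = c(0, 0, 0),
                      seed = 5)
  x <- make_speckle_volume(spb)$data
  se <- s * sqrt((4 - pi) / 2) / sqrt(length(x))
  expect_lt(abs(mean(x) - s * sqrt(pi / 2)), 3 * se)
  # blur preserves the mean (circular convolution, unit DC gain)
  spc <- small_spec(seed = 5)
  raw <- small_spec(seed = 5, blur_sigma_mm = c(0, 0, 0))
  expect_equal(mean(make_speckle_volume(spc)$data),
               mean(make_speckle_volume(raw)$data), tolerance = 1e-6)
})

test_that("mesh mask is a periodic lattice with the right period", {
  # 0.07 mm in-plane, pore 3 mm: autocorrelation peak at lag 43 pixels
  sp <- phantom_spec(shape_mm = c(4, 10, 10),
                     spacing_mm = c(0.07, 0.07, 0.5),
                     depth_mm = 2, echogenicity = 4, seed = 2)
  bg <- make_speckle_volume(sp)
  res <- add_mesh_sheet(bg, sp)
  zc <- round(2 / 0.07)
  m <- res$mesh_mask[zc, , ]               # coronal mask plane
  expect_gt(sum(m), 0)
  prof <- m[, 3]                           # along width at one sweep line
  ac <- vapply(1:100, function(l) {
    a <- prof[1:(length(prof) - l)]; b <- prof[(l + 1):length(prof)]
    mean(a == b)
  }, numeric(1))
  expect_lte(abs(which.max(ac[30:60]) + 29 - 43), 1)
  # shrink halves the period
  sp2 <- sp; sp2$shrink_factor <- 0.5
  res2 <- add_mesh_sheet(bg, sp2)
  m2 <- res2$mesh_mask[zc, , 3]
  runs <- rle(as.vector(m2))
  gap <- max(runs$lengths[!runs$values])
  runs1 <- rle(as.vector(prof))
  gap1 <- max(runs1$lengths[!runs1$values])
  expect_lt(gap, gap1 * 0.7)
  # masks disjoint and same shape
  expect_equal(dim(res$mesh_mask), dim(bg$data))
  expect_false(any(res$mesh_mask & res$fascia_mask))
})

test_that("tilted sheets respect the volume bounds", {
  sp <- phantom_spec(shape_mm = c(10, 10, 10), spacing_mm = c(0.2, 0.2, 0.5),
                     depth_mm = 5, tilt_deg = 90, sheet_size_mm = 10,
                     seed = 3)
  bg <- make_speckle_volume(sp)
  expect_s3_class(add_mesh_sheet(bg, sp), "phantom_result")
  sp$depth_mm <- 1
  expect_error(add_mesh_sheet(bg, sp), "exits")
})

test_that("filament volume fraction scales ~linearly with filament width", {
  base <- phantom_spec(shape_mm = c(4, 12, 12),
                       spacing_mm = c(0.05, 0.05, 0.5),
                       depth_mm = 2, seed = 4, fascia_patchiness = 0)
  bg <- make_speckle_volume(base)
  # areal fraction in the sheet's central coronal plane: the sheet
  # thickness also scales with filament width, so the volume fraction is
  # quadratic while the in-plane lattice coverage is ~linear
  zc <- round(2 / 0.05)
  frac <- vapply(c(0.2, 0.4), function(w) {
    sp <- base; sp$filament_width_mm <- w
    mean(add_mesh_sheet(bg, sp)$mesh_mask[zc, , ])
  }, numeric(1))
  expect_lt(abs(frac[2] / frac[1] - 2), 0.1 * 2)   # within 10% of linear
})

test_that("fascia band is smooth, bright and non-periodic", {
  # patchiness off: the core contract is a smooth hyperechoic band; the
  # fibrous modulation is a dataset-level realism knob tested elsewhere
  sp <- small_spec(seed = 6, echogenicity = 4, fascia_patchiness = 0)
  bg <- make_speckle_volume(sp)
  res <- add_fascia_sheet(bg, sp)
  v <- res$volume$data
  expect_gt(mean(v[res$fascia_mask]), mean(v[!res$fascia_mask]))
  # axial slice shows a bright band at depth_mm +- thickness/2
  ax <- v[, , dim(v)[3] %/% 2]
  depth_prof <- rowMeans(ax)
  zc <- round(sp$depth_mm / sp$spacing_mm[1])
  expect_equal(which.max(depth_prof), zc, tolerance = 3)
  band <- round(sp$fascia_thickness_mm / sp$spacing_mm[1] / 2)
  expect_gt(min(depth_prof[(zc - band):(zc + band)]),
            2 * median(depth_prof))
  # no periodic autocorrelation peak in the coronal slice through the band
  sl <- v[zc, , ] - mean(v[zc, , ])
  prof <- rowMeans(sl)
  n <- length(prof)
  ac <- vapply(2:(n - 5), function(l)
    cor(prof[1:(n - l)], prof[(l + 1):n]), numeric(1))
  # background comparison: same statistic on a pure speckle plane
  bgp <- bg$data[2, , ] - mean(bg$data[2, , ])
  pb <- rowMeans(bgp)
  acb <- vapply(2:(n - 5), function(l)
    cor(pb[1:(n - l)], pb[(l + 1):n]), numeric(1))
  expect_lt(max(ac), max(abs(acb)) + 3 * sd(acb) + 0.1)
})

test_that("labeled dataset generation is deterministic bookkeeping", {
  base <- small_spec()
  ds <- generate_labeled_dataset(5, 5, seed = 8, base_spec = base,
                                 render = FALSE)
  expect_equal(nrow(ds$samples), 10L)
  expect_equal(sum(ds$samples$label == "mesh"), 5L)
  expect_true(all(ds$samples$cz_mm >= 9 & ds$samples$cz_mm <= 16))
  ds2 <- generate_labeled_dataset(5, 5, seed = 8, base_spec = base,
                                  render = FALSE)
  expect_identical(ds$samples, ds2$samples)
  # rendered volumes are deterministic under the seed too
  d1 <- generate_labeled_dataset(1, 1, seed = 9, base_spec = base)
  d2 <- generate_labeled_dataset(1, 1, seed = 9, base_spec = base)
  expect_identical(d1$volumes[[1]]$volume$data, d2$volumes[[1]]$volume$data)
  expect_false(identical(
    d1$volumes[[1]]$volume$data,
    generate_labeled_dataset(1, 1, seed = 10,
                             base_spec = base)$volumes[[1]]$volume$data))
})

test_that("dataset depths span the 1-3 cm placement range", {
  ds <- generate_labeled_dataset(40, 5, seed = 11,
                                 base_spec = phantom_spec(
                                   shape_mm = c(40, 14, 14),
                                   spacing_mm = c(0.5, 0.5, 0.5)),
                                 render = FALSE)
  d <- ds$samples$cz_mm
  expect_true(all(d >= 9 & d <= 31))
  expect_gt(max(d) - min(d), 10)
})

test_that("written dataset round-trips through rois.csv byte-identically", {
  base <- small_spec()
  out1 <- file.path(tempdir(), "ds1"); out2 <- file.path(tempdir(), "ds2")
  generate_labeled_dataset(2, 2, seed = 12, base_spec = base,
                           out_dir = out1, render = FALSE)
  generate_labeled_dataset(2, 2, seed = 12, base_spec = base,
                           out_dir = out2, render = FALSE)
  csv1 <- readBin(file.path(out1, "rois.csv"), "raw",
                  file.size(file.path(out1, "rois.csv")))
  csv2 <- readBin(file.path(out2, "rois.csv"), "raw",
                  file.size(file.path(out2, "rois.csv")))
  # identical content modulo the differing volume_path prefix
  t1 <- gsub(out1, "", rawToChar(csv1), fixed = TRUE)
  t2 <- gsub(out2, "", rawToChar(csv2), fixed = TRUE)
  expect_identical(t1, t2)
  unlink(c(out1, out2), recursive = TRUE)
})
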