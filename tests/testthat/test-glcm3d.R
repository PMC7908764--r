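test_that("the 13 canonical directions close to the 26-neighborhood", {
  d <- enumerate_directions_3d()
  expect_equal(nrow(d), 13L)
  expect_equal(ncol(d), 3L)
  closure <- unique(rbind(d, -d))
  expect_equal(nrow(closure), 26L)
  # no pair of canonical directions are negatives of each other
  for (i in 1:12) for (j in (i + 1):13)
    expect_false(all(d[i, ] == -d[j, ]))
})

test_that("triplet tables of simple volumes match hand derivation", {
  g <- compute_glcm3d(quantize(array(2, c(3, 3, 3)), 2), c(1, 0, 0))
  expect_equal(g$P[1, 1, 1], 1)
  # alternating stripes along the first axis: only (0,1,0) and (1,0,1)
  v <- quantize(array(rep(c(0, 1), length.out = 4 * 3 * 3), c(4, 3, 3)), 2)
  g <- compute_glcm3d(v, c(1, 0, 0))
  expect_equal(g$P[1, 2, 1], 0.5)
  expect_equal(g$P[2, 1, 2], 0.5)
  expect_equal(sum(g$P), 1)
  f <- haralick12_3d(g)
  expect_equal(unname(f["f2"]), 2)       # hand evaluation on the two entries
  expect_equal(unname(f["f1"]), 0.5)
  # constant region features
  fc <- haralick12_3d(compute_glcm3d(quantize(array(1, c(3, 3, 3)), 2),
                                     c(0, 1, 0)))
  expect_equal(unname(fc[c("f1", "f2", "f7", "f12", "f3")]),
               c(1, 0, 0, 1, 0))
  # too-small region errors
  expect_error(compute_glcm3d(quantize(array(1, c(2, 2, 2)), 2), c(1, 0, 0)),
               "too small")
})

test_that("3D table and all 12 features match the brute-force oracle", {
  set.seed(20)
  dirs <- enumerate_directions_3d()
  for (rep in 1:6) {
    G <- sample(2:3, 1)
    dm <- sample(3:5, 3, replace = TRUE)
    q <- random_quantized_3d(dm[1], dm[2], dm[3], G)
    for (di in seq_len(nrow(dirs))) {
      g <- compute_glcm3d(q, dirs[di, ])
      expect_equal(g$P, glcm3d_oracle(unclass(q), G, dirs[di, ]),
                   tolerance = 1e-12)
      expect_equal(haralick12_3d(g), haralick3d_oracle(g$P),
                   tolerance = 1e-12)
    }
  }
})

test_that("triplet tables are normalized with reversal symmetry", {
  set.seed(21)
  q <- random_quantized_3d(4, 4, 4, 3)
  dirs <- enumerate_directions_3d()
  for (di in seq_len(nrow(dirs))) {
    P <- compute_glcm3d(q, dirs[di, ])$P
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, aperm(P, c(3, 2, 1)))   # P(i,j,k) = P(k,j,i)
  }
})

test_that("triplet pair-marginal agrees with restricted pair enumeration", {
  # volume built by replicating one slice along depth; in-slice direction
  # triplets marginalized over the third level must equal the pair counts
  # over triplet-extendable pairs (independent enumeration)
  set.seed(22)
  sl <- matrix(sample(0:2, 30, replace = TRUE), 5, 6)
  arr <- array(rep(sl, 4), c(5, 6, 4))
  arr <- aperm(arr, c(3, 1, 2))             # depth-replicated (4,5,6)
  q <- structure(array(as.integer(arr), dim(arr)), G = 3L,
                 class = "quantized_region")
  g <- compute_glcm3d(q, c(0, 1, 0))        # direction along dim 2
  pair_from_triplet <- apply(g$P, c(1, 2), sum)
  # oracle: pairs (p, p+e2) whose extension p+2*e2 stays in bounds
  cnt <- matrix(0, 3, 3)
  for (z in 1:4) for (r in 1:5) for (c in 1:6) {
    if (r + 2 <= 5) {
      i <- arr[z, r, c] + 1; j <- arr[z, r + 1, c] + 1
      cnt[i, j] <- cnt[i, j] + 1
      # reversed triplet contributes its own leading pair (k, j)
      k <- arr[z, r + 2, c] + 1
      cnt[k, j] <- cnt[k, j] + 1
    }
  }
  expect_equal(pair_from_triplet, cnt / sum(cnt), tolerance = 1e-12)
})

test_that("direction averaging sees anisotropy and ignores order", {
  arr <- array(0, c(5, 5, 5))
  arr[c(2, 4), , ] <- 1                     # stripes along depth only
  v <- quantize(arr, 2)
  f_x <- haralick12_3d(compute_glcm3d(v, c(1, 0, 0)))["f2"]
  f_y <- haralick12_3d(compute_glcm3d(v, c(0, 1, 0)))["f2"]
  expect_gt(abs(f_x - f_y), 0.1)
  avg <- directional_average_3d(v)["f2"]
  dirs <- enumerate_directions_3d()
  all_f2 <- vapply(seq_len(nrow(dirs)), function(i)
    haralick12_3d(compute_glcm3d(v, dirs[i, ]))["f2"], numeric(1))
  expect_gte(avg, min(all_f2)); expect_lte(avg, max(all_f2))
  expect_equal(unname(avg), mean(all_f2), tolerance = 1e-12)
})
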