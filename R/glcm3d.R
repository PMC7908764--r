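# Volumetric co-occurrence statistics over collinear voxel triplets.
#
# The G x G x G table P(i, j, k) counts gray-level triplets along the 13
# symmetry-independent unit offsets of the 26-neighborhood: for each
# in-bounds voxel v the collinear triplet (v, v + D, v + 2D) contributes
# (i, j, k) and its reversal (k, j, i) -- the 3D analogue of 2D symmetric
# pair accumulation, giving P(i,j,k) = P(k,j,i). Offsets are in voxel
# units on the native anisotropic grid (no spacing correction).

#' The 13 canonical 3D co-occurrence directions
#'
#' All offsets with components in \{-1, 0, 1\}, not all zero, keeping one
#' canonical representative per +/- pair (first nonzero component
#' positive). Their closure under negation has the full 26 members of the
#' 3D Moore neighborhood.
#'
#' @return integer matrix, 13 rows x 3 columns (dz, dx, dy).
#' @export
enumerate_directions_3d <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nonzero <- apply(g, 1, function(r) r[which(r != 0)[1]])
  out <- g[first_nonzero > 0, , drop = FALSE]
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Compute a 3D triplet co-occurrence table
#'
#' @param region a 3D `quantized_region`.
#' @param direction integer length-3 offset (dz, dx, dy), components in
#'   \{-1, 0, 1\}, not all zero (a row of [enumerate_directions_3d()]).
#' @param d voxel distance (default 1).
#' @return A `glcm3d` object: list with `P` (G x G x G probability array,
#'   axes indexed by gray level 0..G-1), `G`, `direction`, `d`,
#'   `n_triplets`.
#' @export
compute_glcm3d <- function(region, direction, d = 1L) {
  region <- .as_quantized(region, 3L)
  G <- attr(region, "G")
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  direction <- as.integer(direction)
  if (length(direction) != 3L || all(direction == 0L) ||
      any(abs(direction) > 1L))
    stop("`direction` must be a nonzero offset with components in {-1,0,1}",
         call. = FALSE)
  off <- direction * d
  dm <- dim(region)
  lo <- pmax(1L, 1L - 2L * off)
  hi <- pmin(dm, dm - 2L * off)
  if (any(lo > hi))
    stop(sprintf("region (%s) too small for collinear triplets along (%s)",
                 paste(dm, collapse = ","), paste(off, collapse = ",")),
         call. = FALSE)
  i1 <- seq.int(lo[1], hi[1]); i2 <- seq.int(lo[2], hi[2])
  i3 <- seq.int(lo[3], hi[3])
  a <- region[i1, i2, i3, drop = FALSE]
  b <- region[i1 + off[1], i2 + off[2], i3 + off[3], drop = FALSE]
  cc <- region[i1 + 2L * off[1], i2 + 2L * off[2], i3 + 2L * off[3],
               drop = FALSE]
  # linear index with i (first voxel) fastest so array(|counts|) has
  # [i+1, j+1, k+1] = count of triplet (i, j, k)
  counts <- tabulate(a + b * G + cc * G * G + 1L, nbins = G^3) +
            tabulate(cc + b * G + a * G * G + 1L, nbins = G^3)
  n_triplets <- sum(counts)
  structure(list(P = array(counts / n_triplets, dim = c(G, G, G)),
                 G = G, direction = direction, d = d,
                 n_triplets = n_triplets),
            class = "glcm3d")
}

# level-index arrays and marginal statistics for a normalized triplet table
glcm3d_marginals <- function(P) {
  G <- dim(P)[1]
  lev <- 0:(G - 1)
  px <- apply(P, 1, sum); py <- apply(P, 2, sum); pz <- apply(P, 3, sum)
  mu <- c(x = sum(lev * px), y = sum(lev * py), z = sum(lev * pz))
  v  <- c(x = sum((lev - mu["x"])^2 * px),
          y = sum((lev - mu["y"])^2 * py),
          z = sum((lev - mu["z"])^2 * pz))
  names(v) <- c("x", "y", "z")
  list(mu = mu, var = v)
}

#' Twelve Haralick-style features of a 3D triplet table
#'
#' The 3D analogues of the 2D feature set, computed on the normalized
#' triplet table: energy, contrast (sum of the three pairwise squared
#' level differences), correlation (third cross central moment over the
#' product of marginal standard deviations; 0 for a zero-variance table),
#' variance (sum of squared deviations of table entries from the mean
#' entry 1/G^3), homogeneity, sum average over the triplet sum marginal
#' s = i+j+k, entropy (natural log), triple autocorrelation i*j*k,
#' dissimilarity |i-j||i-k||j-k|, cluster shade/prominence of
#' i+j+k - mu_x - mu_y - mu_z, and maximum probability.
#'
#' @param glcm a `glcm3d`.
#' @return named numeric vector `f1` .. `f12`.
#' @export
haralick12_3d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm3d"))
  P <- glcm$P
  G <- glcm$G
  lev <- 0:(G - 1)
  I <- array(lev, dim = c(G, G, G))
  J <- aperm(I, c(2, 1, 3))
  K <- aperm(I, c(3, 2, 1))
  m <- glcm3d_marginals(P)
  sds <- sqrt(m$var)
  q <- (I - J)^2 + (I - K)^2 + (J - K)^2
  s_arr <- I + J + K
  csum <- s_arr - sum(m$mu)
  pos <- P > 0
  f3 <- if (all(sds > 0))
    sum(P * (I - m$mu["x"]) * (J - m$mu["y"]) * (K - m$mu["z"])) /
      prod(sds) else 0
  # sum marginal P_{x+y+z}(s), s = 0 .. 3(G-1)
  s_lev <- 0:(3 * (G - 1))
  p_sum <- vapply(s_lev, function(k) sum(P[s_arr == k]), numeric(1))
  c(f1  = sum(P^2),
    f2  = sum(P * q),
    f3  = unname(f3),
    f4  = sum((P - 1 / G^3)^2),
    f5  = sum(P / (1 + q)),
    f6  = sum(s_lev * p_sum),
    f7  = -sum(P[pos] * log(P[pos])),
    f8  = sum(I * J * K * P),
    f9  = sum(abs(I - J) * abs(I - K) * abs(J - K) * P),
    f10 = sum(csum^3 * P),
    f11 = sum(csum^4 * P),
    f12 = max(P))
}

#' Direction-averaged 3D Haralick features
#'
#' Computes the twelve triplet-table features for each of the 13 canonical
#' directions and returns their arithmetic mean.
#'
#' @param region a 3D `quantized_region`.
#' @param d voxel distance (default 1).
#' @return named numeric vector `f1` .. `f12`.
#' @export
directional_average_3d <- function(region, d = 1L) {
  dirs <- enumerate_directions_3d()
  feats <- vapply(seq_len(nrow(dirs)),
                  function(i)
                    haralick12_3d(compute_glcm3d(region, dirs[i, ], d)),
                  numeric(12))
  rowMeans(feats)
}
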