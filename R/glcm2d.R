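# 2D gray-level co-occurrence matrices and the twelve Haralick-style
# features, direction-averaged over the four canonical directions.
#
# Gray levels are 0-based (0 .. G-1), matching quantize(). Pair accumulation
# is symmetric: every ordered in-bounds pixel pair (p, p + D) is counted
# together with its reverse, so the four independent directions exhaust the
# 8-neighborhood and P = t(P).

#' Canonical 2D co-occurrence directions
#'
#' The four independent directions of the 8-neighborhood at unit distance:
#' 0, 45, 90 and 135 degrees. Together with their negatives they cover all
#' 8 neighboring pixel pairs.
#'
#' @return named list of integer (row, col) offsets.
#' @export
glcm_directions_2d <- function() {
  list(`0`   = c(0L, 1L),
       `45`  = c(1L, 1L),
       `90`  = c(1L, 0L),
       `135` = c(1L, -1L))
}

.as_quantized <- function(region, ndim) {
  if (!inherits(region, "quantized_region"))
    stop("expected a quantized_region (see quantize())", call. = FALSE)
  if (length(dim(region)) != ndim)
    stop(sprintf("expected a %dD quantized region", ndim), call. = FALSE)
  region
}

#' Compute a 2D gray-level co-occurrence matrix
#'
#' Counts every in-bounds ordered pixel pair separated by the displacement
#' `d` steps along direction `phi`, accumulates symmetrically, and
#' normalizes by the total count.
#'
#' @param region a 2D `quantized_region`.
#' @param phi direction angle in degrees, one of 0, 45, 90, 135.
#' @param d pixel distance (default 1).
#' @return A `glcm2d` object: list with `P` (G x G probability matrix, rows
#'   and columns indexed by gray level 0..G-1), `G`, `phi`, `d`, `n_pairs`.
#' @export
compute_glcm2d <- function(region, phi = 0, d = 1L) {
  region <- .as_quantized(region, 2L)
  G <- attr(region, "G")
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  dirs <- glcm_directions_2d()
  key <- as.character(phi)
  if (!key %in% names(dirs))
    stop("`phi` must be one of 0, 45, 90, 135", call. = FALSE)
  off <- dirs[[key]] * d
  nr <- nrow(region); nc <- ncol(region)
  rlo <- max(1L, 1L - off[1]); rhi <- min(nr, nr - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(nc, nc - off[2])
  if (rlo > rhi || clo > chi)
    stop(sprintf("region %d x %d too small for displacement (%d, %d)",
                 nr, nc, off[1], off[2]), call. = FALSE)
  rows <- seq.int(rlo, rhi)
  cols <- seq.int(clo, chi)
  a <- region[rows, cols, drop = FALSE]
  b <- region[rows + off[1], cols + off[2], drop = FALSE]
  counts <- tabulate(a * G + b + 1L, nbins = G * G)
  Pc <- matrix(counts, G, G, byrow = TRUE)   # row = level of a, col = of b
  Pc <- Pc + t(Pc)                           # symmetric accumulation
  n_pairs <- sum(Pc)
  structure(list(P = Pc / n_pairs, G = G, phi = phi, d = d,
                 n_pairs = n_pairs),
            class = "glcm2d")
}

# Marginal statistics of a symmetric normalized GLCM: means and second
# central moments of the row/column level distributions, plus the sum
# marginal P_{x+y}(s), s = 0 .. 2(G-1).
glcm2d_marginals <- function(P) {
  G <- nrow(P)
  lev <- 0:(G - 1)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  var_x <- sum((lev - mu_x)^2 * px)
  var_y <- sum((lev - mu_y)^2 * py)
  s <- outer(lev, lev, `+`)
  pxy <- vapply(0:(2 * (G - 1)), function(k) sum(P[s == k]), numeric(1))
  list(mu_x = mu_x, mu_y = mu_y, var_x = var_x, var_y = var_y,
       p_sum = pxy)
}

#' Twelve Haralick-style features of a 2D GLCM
#'
#' Energy, contrast, correlation, variance, homogeneity, sum average,
#' entropy (natural log), autocorrelation, dissimilarity, cluster shade,
#' cluster prominence and maximum probability, in that order. The
#' correlation denominator uses the square roots of the second central
#' moments of the marginals; a zero-variance (constant-region) GLCM yields
#' correlation 0 by convention so degenerate inputs still produce finite
#' feature vectors.
#'
#' @param glcm a `glcm2d`.
#' @return named numeric vector `f1` .. `f12`.
#' @export
haralick12_2d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm2d"))
  P <- glcm$P
  G <- glcm$G
  lev <- 0:(G - 1)
  I <- matrix(lev, G, G)          # row level i
  J <- t(I)                       # col level j
  m <- glcm2d_marginals(P)
  sd_x <- sqrt(m$var_x); sd_y <- sqrt(m$var_y)
  diff2 <- (I - J)^2
  csum <- I + J - m$mu_x - m$mu_y
  pos <- P > 0
  f3 <- if (sd_x > 0 && sd_y > 0)
    (sum(I * J * P) - m$mu_x * m$mu_y) / (sd_x * sd_y) else 0
  s <- 0:(2 * (G - 1))
  c(f1  = sum(P^2),
    f2  = sum(P * diff2),
    f3  = f3,
    f4  = sum((I - m$mu_x)^2 * P),
    f5  = sum(P / (1 + diff2)),
    f6  = sum(s * m$p_sum),
    f7  = -sum(P[pos] * log(P[pos])),
    f8  = sum(I * J * P),
    f9  = sum(abs(I - J) * P),
    f10 = sum(csum^3 * P),
    f11 = sum(csum^4 * P),
    f12 = max(P))
}

#' Direction-averaged 2D Haralick features
#'
#' Computes the twelve features for each of the four canonical directions
#' and returns their arithmetic mean, the single measure used downstream.
#'
#' @param region a 2D `quantized_region`.
#' @param d pixel distance (default 1).
#' @return named numeric vector `f1` .. `f12`.
#' @export
directional_average_2d <- function(region, d = 1L) {
  feats <- vapply(names(glcm_directions_2d()),
                  function(phi)
                    haralick12_2d(compute_glcm2d(region, as.numeric(phi), d)),
                  numeric(12))
  rowMeans(feats)
}
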