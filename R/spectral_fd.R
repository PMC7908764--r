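# Spectral fractal dimension: radially averaged FFT power spectra and the
# log-log power-law fit FD = (3*D_T + 2 - beta)/2.
#
# The input is mean-subtracted before the transform (a nonzero DC term
# would dominate and destroy the log-log fit) and the DC bin is excluded
# from the radial sampling. Frequencies are computed per axis in cycles/mm
# from the voxel spacing, so the radial frequency is physically meaningful
# on the anisotropic ultrasound grid; pass spacing = 1 per axis for
# voxel-unit frequencies.

.fftshift_idx <- function(n) c(seq.int(n - floor(n / 2) + 1L, n),
                               seq.int(1L, n - floor(n / 2)))

.shifted_freq <- function(n, spacing) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * spacing)
}

#' FFT power spectrum of a 2D or 3D region
#'
#' Mean-subtracts the region, optionally applies a separable Hann window,
#' computes the discrete Fourier transform and returns the squared modulus
#' on a zero-centered frequency grid in cycles/mm.
#'
#' @param region numeric matrix or 3D array, or a `roi2d`/`roi3d` (whose
#'   own spacing is then used).
#' @param spacing voxel size in mm per axis (recycled); ignored when
#'   `region` carries its own.
#' @param window `"none"` (default; the estimator is defined without one)
#'   or `"hann"` for users who need leakage control.
#' @return A `power_spectrum`: list with `P` (nonnegative array, DC at the
#'   center), `freq` (list of per-axis frequency vectors, cycles/mm),
#'   `spacing`, `ndim`.
#' @export
power_spectrum <- function(region, spacing = 1, window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(region, c("roi2d", "roi3d"))) {
    spacing <- region$spacing
    region <- region$data
  }
  x <- as.array(region)
  d <- dim(x)
  if (length(d) < 2L || length(d) > 3L)
    stop("region must be 2D or 3D", call. = FALSE)
  if (any(d < 8L))
    stop("each axis needs at least 8 samples for a spectrum", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), length(d))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive", call. = FALSE)
  x <- x - mean(x)
  if (window == "hann") {
    for (ax in seq_along(d)) {
      w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[ax]) - 1) / (d[ax] - 1))
      x <- sweep(x, ax, w, `*`)
    }
  }
  P <- Mod(stats::fft(x))^2
  # shift DC to the center on every axis
  P <- do.call(`[`, c(list(P), lapply(d, .fftshift_idx), list(drop = FALSE)))
  freq <- Map(.shifted_freq, d, spacing)
  structure(list(P = P, freq = freq, spacing = spacing, ndim = length(d)),
            class = "power_spectrum")
}

# multilinear interpolation of a uniform-grid array at arbitrary points;
# pts: matrix n x ndim of coordinates in the units of `freq`
.interp_multilinear <- function(P, freq, pts) {
  d <- dim(P)
  nd <- length(d)
  # fractional 1-based indices
  fi <- lapply(seq_len(nd), function(ax) {
    (pts[, ax] - freq[[ax]][1]) / (freq[[ax]][2] - freq[[ax]][1]) + 1
  })
  lo <- lapply(seq_len(nd), function(ax) pmin(pmax(floor(fi[[ax]]), 1), d[ax] - 1))
  wt <- lapply(seq_len(nd), function(ax) pmin(pmax(fi[[ax]] - lo[[ax]], 0), 1))
  out <- numeric(nrow(pts))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  stride <- cumprod(c(1, d[-nd]))
  for (ci in seq_len(nrow(corners))) {
    idx <- 0
    w <- rep(1, nrow(pts))
    for (ax in seq_len(nd)) {
      b <- corners[ci, ax]
      idx <- idx + (lo[[ax]] + b - 1) * stride[ax]
      w <- w * if (b == 1) wt[[ax]] else 1 - wt[[ax]]
    }
    out <- out + w * P[idx + 1]
  }
  out
}

#' Radially averaged power spectrum profile
#'
#' Samples the spectrum at `n_radii` uniformly spaced radial frequencies
#' (from the lowest nonzero radial bin to the common Nyquist radius) along
#' a fixed fan of directions -- 24 in 2D, 24 azimuth x 12 zenith in 3D --
#' by multilinear interpolation, then averages over directions at each
#' radius.
#'
#' @param spectrum a `power_spectrum`.
#' @param n_dirs azimuth directions (default 24).
#' @param n_zenith zenith angles for 3D (default 12).
#' @param n_radii radial sample points per direction (default 30).
#' @return A `radial_profile`: list with `f` (radial frequency, cycles/mm),
#'   `Pf` (direction-averaged power), `ndim`.
#' @export
radial_average <- function(spectrum, n_dirs = 24L, n_zenith = 12L,
                           n_radii = 30L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (max(spectrum$P) <= 0)
    stop("degenerate spectrum: input was constant", call. = FALSE)
  nd <- spectrum$ndim
  d <- dim(spectrum$P)
  # fundamental (first nonzero bin) per axis and usable positive maximum
  df <- vapply(spectrum$freq, function(f) f[2] - f[1], numeric(1))
  fpos_max <- vapply(spectrum$freq, max, numeric(1))
  f_min <- max(df)
  f_max <- min(fpos_max)
  radii <- seq(f_min, f_max, length.out = n_radii)
  if (nd == 2L) {
    ang <- 2 * pi * (seq_len(n_dirs) - 1) / n_dirs
    dirs <- cbind(cos(ang), sin(ang))
  } else {
    ang <- 2 * pi * (seq_len(n_dirs) - 1) / n_dirs
    zen <- pi * (seq_len(n_zenith) - 0.5) / n_zenith
    grid <- expand.grid(phi = ang, theta = zen)
    dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                  sin(grid$theta) * sin(grid$phi),
                  cos(grid$theta))
  }
  pts <- dirs[rep(seq_len(nrow(dirs)), each = n_radii), , drop = FALSE] *
    rep(radii, nrow(dirs))
  vals <- .interp_multilinear(spectrum$P, spectrum$freq, pts)
  Pf <- rowMeans(matrix(vals, nrow = n_radii))
  structure(list(f = radii, Pf = Pf, ndim = nd,
                 n_dirs = if (nd == 2L) n_dirs else n_dirs * n_zenith),
            class = "radial_profile")
}

#' Fit the spectral fractal dimension
#'
#' Ordinary least squares of log(P_f) against log(f). With the convention
#' P_f proportional to f^(-beta), beta is the negative of the fitted
#' slope, and FD = (3*D_T + 2 - beta)/2: (8 - beta)/2 for a 2D region,
#' (11 - beta)/2 in 3D.
#'
#' @param profile a `radial_profile`.
#' @param dim topological dimension, 2 or 3; defaults to the profile's.
#' @return An `fd_result`: list with `beta`, `fd`, `r2`, `dim`.
#' @export
fit_fd <- function(profile, dim = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  if (is.null(dim)) dim <- profile$ndim
  if (!dim %in% c(2, 3)) stop("`dim` must be 2 or 3", call. = FALSE)
  keep <- profile$Pf > 0 & profile$f > 0
  if (sum(keep) < 3L)
    stop("need at least 3 positive profile points for the log-log fit",
         call. = FALSE)
  lx <- log(profile$f[keep]); ly <- log(profile$Pf[keep])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  beta <- -slope
  # a constant profile is fit exactly by slope 0
  r2 <- if (stats::var(ly) == 0) 1 else stats::cor(lx, ly)^2
  structure(list(beta = beta, fd = (3 * dim + 2 - beta) / 2,
                 r2 = r2, dim = dim),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> %dD: beta = %.4f, FD = %.4f (r2 = %.3f)\n",
              x$dim, x$beta, x$fd, x$r2))
  invisible(x)
}

#' One-call spectral fractal dimension
#'
#' Convenience wrapper: [power_spectrum()] then [radial_average()] then
#' [fit_fd()].
#'
#' @inheritParams power_spectrum
#' @inheritParams radial_average
#' @return an `fd_result`.
#' @export
spectral_fd <- function(region, spacing = 1, window = "none",
                        n_dirs = 24L, n_zenith = 12L, n_radii = 30L) {
  ps <- power_spectrum(region, spacing, window)
  fit_fd(radial_average(ps, n_dirs, n_zenith, n_radii))
}
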