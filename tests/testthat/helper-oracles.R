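# Independent brute-force oracles for the co-occurrence statistics and
# constructed-spectrum fields for the fractal-dimension estimator. These
# deliberately use plain loops and direct formula transcriptions, sharing
# no code with the package implementation.

# all in-bounds ordered pairs (p, p + off) and reverses, double loop
glcm2d_oracle <- function(region, G, off) {
  P <- matrix(0, G, G)
  nr <- nrow(region); nc <- ncol(region)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- region[r, c] + 1; j <- region[r2, c2] + 1
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P / sum(P)
}

haralick2d_oracle <- function(P) {
  G <- nrow(P)
  f <- numeric(12)
  mu_x <- mu_y <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    mu_x <- mu_x + i * P[i + 1, j + 1]
    mu_y <- mu_y + j * P[i + 1, j + 1]
  }
  v_x <- v_y <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    v_x <- v_x + (i - mu_x)^2 * P[i + 1, j + 1]
    v_y <- v_y + (j - mu_y)^2 * P[i + 1, j + 1]
  }
  cross <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    f[1] <- f[1] + p^2
    f[2] <- f[2] + p * (i - j)^2
    cross <- cross + i * j * p
    f[4] <- f[4] + (i - mu_x)^2 * p
    f[5] <- f[5] + p / (1 + (i - j)^2)
    f[6] <- f[6] + (i + j) * p          # sum average via direct identity
    if (p > 0) f[7] <- f[7] - p * log(p)
    f[8] <- f[8] + i * j * p
    f[9] <- f[9] + abs(i - j) * p
    f[10] <- f[10] + (i + j - mu_x - mu_y)^3 * p
    f[11] <- f[11] + (i + j - mu_x - mu_y)^4 * p
  }
  f[3] <- if (v_x > 0 && v_y > 0)
    (cross - mu_x * mu_y) / (sqrt(v_x) * sqrt(v_y)) else 0
  f[12] <- max(P)
  names(f) <- paste0("f", 1:12)
  f
}

# all in-bounds collinear triplets (v, v+off, v+2*off) and reverses
glcm3d_oracle <- function(region, G, off) {
  P <- array(0, dim = c(G, G, G))
  d <- dim(region)
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (c in seq_len(d[3])) {
    a2 <- a + off[1]; b2 <- b + off[2]; c2 <- c + off[3]
    a3 <- a + 2 * off[1]; b3 <- b + 2 * off[2]; c3 <- c + 2 * off[3]
    if (a2 >= 1 && a2 <= d[1] && b2 >= 1 && b2 <= d[2] &&
        c2 >= 1 && c2 <= d[3] &&
        a3 >= 1 && a3 <= d[1] && b3 >= 1 && b3 <= d[2] &&
        c3 >= 1 && c3 <= d[3]) {
      i <- region[a, b, c] + 1
      j <- region[a2, b2, c2] + 1
      k <- region[a3, b3, c3] + 1
      P[i, j, k] <- P[i, j, k] + 1
      P[k, j, i] <- P[k, j, i] + 1
    }
  }
  P / sum(P)
}

haralick3d_oracle <- function(P) {
  G <- dim(P)[1]
  f <- numeric(12)
  mu <- c(0, 0, 0)
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) for (k in 0:(G - 1)) {
    p <- P[i + 1, j + 1, k + 1]
    mu <- mu + c(i, j, k) * p
  }
  v <- c(0, 0, 0)
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) for (k in 0:(G - 1)) {
    p <- P[i + 1, j + 1, k + 1]
    v <- v + (c(i, j, k) - mu)^2 * p
  }
  num3 <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) for (k in 0:(G - 1)) {
    p <- P[i + 1, j + 1, k + 1]
    q <- (i - j)^2 + (i - k)^2 + (j - k)^2
    f[1] <- f[1] + p^2
    f[2] <- f[2] + p * q
    num3 <- num3 + p * (i - mu[1]) * (j - mu[2]) * (k - mu[3])
    f[4] <- f[4] + (p - 1 / G^3)^2
    f[5] <- f[5] + p / (1 + q)
    f[6] <- f[6] + (i + j + k) * p      # sum marginal via direct identity
    if (p > 0) f[7] <- f[7] - p * log(p)
    f[8] <- f[8] + i * j * k * p
    f[9] <- f[9] + abs(i - j) * abs(i - k) * abs(j - k) * p
    f[10] <- f[10] + (i + j + k - sum(mu))^3 * p
    f[11] <- f[11] + (i + j + k - sum(mu))^4 * p
  }
  f[3] <- if (all(v > 0)) num3 / prod(sqrt(v)) else 0
  f[12] <- max(P)
  names(f) <- paste0("f", 1:12)
  f
}

# random quantized regions for property tests
random_quantized_2d <- function(nr, nc, G) {
  quantize(matrix(runif(nr * nc), nr, nc), G)
}
random_quantized_3d <- function(d1, d2, d3, G) {
  quantize(array(runif(d1 * d2 * d3), c(d1, d2, d3)), G)
}

# isotropic power-law random-phase field: |F| = f^(-beta/2), built directly
# in the frequency domain and inverse-transformed
make_powerlaw_field_2d <- function(n, beta, seed) {
  set.seed(seed)
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  r <- sqrt(outer(fx^2, fx^2, `+`))
  amp <- ifelse(r > 0, r^(-beta / 2), 0)
  ph <- array(runif(n * n, 0, 2 * pi), c(n, n))
  Re(fft(amp * exp(1i * ph), inverse = TRUE))
}

make_powerlaw_field_3d <- function(n, beta, seed) {
  set.seed(seed)
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  r <- sqrt(outer(outer(fx^2, fx^2, `+`), fx^2, `+`))
  amp <- ifelse(r > 0, r^(-beta / 2), 0)
  ph <- array(runif(n^3, 0, 2 * pi), c(n, n, n))
  Re(fft(amp * exp(1i * ph), inverse = TRUE))
}

# wrap a bare array as a full-volume ROI
as_roi3d <- function(arr, spacing = c(1, 1, 1)) {
  v <- ultrasound_volume(arr, spacing)
  ext <- volume_extent_mm(v)
  extract_roi(v, ext / 2, ext)
}
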