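# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear (zero-padded, non-circular) autocorrelation sums of each column of
# `x`: ac[k+1, j] = sum_t x[t, j] * x[t + k, j], k = 0..n-1. FFT-based; equal
# to direct lag sums up to float roundoff.
fft_autocorr_sums <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- stats::nextn(2L * n, c(2, 3, 5))
  xp <- rbind(x, matrix(0, m - n, ncol(x)))
  sp <- stats::mvfft(xp)
  ac <- Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / m
  ac[seq_len(n), , drop = FALSE]
}

# Multi-tau style log-spaced integer lag grid, `per_octave` lags per octave,
# first lag = 1 bin.
multitau_lags <- function(n_max, per_octave = 16) {
  if (n_max < 1) stop("`n_max` must be >= 1", call. = FALSE)
  k <- unique(round(2^(seq(0, log2(n_max), by = 1 / per_octave))))
  k[k >= 1 & k <= n_max]
}

# Gaussian kernel with peak value 1 (unnormalized), radius 4 sigma.
gaussian_kernel_peak1 <- function(sigma, radius = ceiling(4 * sigma)) {
  offs <- seq(-radius, radius)
  exp(-offs^2 / (2 * sigma^2))
}

# Reflective-edge 1-D convolution of the rows of `x` (pixel axis) with a
# symmetric kernel given as (center value, one-sided tail values).
convolve_rows_reflect <- function(x, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  centre <- kernel[radius + 1L]
  p <- nrow(x)
  out <- centre * x
  if (radius == 0L || p == 1L) return(out)
  # whole-line reflection (period 2p - 2), valid for any offset
  reflect <- function(i) {
    if (p == 1L) return(rep(1L, length(i)))
    m <- (i - 1L) %% (2L * p - 2L)
    ifelse(m >= p, 2L * p - 2L - m, m) + 1L
  }
  for (j in seq_len(radius)) {
    w <- kernel[radius + 1L + j]
    out <- out + w * (x[reflect(seq_len(p) - j), , drop = FALSE] +
                        x[reflect(seq_len(p) + j), , drop = FALSE])
  }
  out
}

# Centered rolling mean of each row of `x` with an odd window of `w` bins;
# edges use a shrinking window. Returns the rolling-mean matrix.
rolling_mean_rows <- function(x, w) {
  n <- ncol(x)
  h <- (w - 1L) %/% 2L
  cs <- t(apply(x, 1L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[, hi, drop = FALSE]
  lower <- cbind(0, cs)[, lo, drop = FALSE]
  sweep(upper - lower, 2L, hi - lo + 1L, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
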