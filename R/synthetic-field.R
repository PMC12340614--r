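# Seeded generator of correlated complex speckle fields. The temporal field
# statistics are imposed by spectral synthesis: the symmetrized target
# autocovariance is embedded in a circulant, its (real) eigenvalue spectrum is
# clipped at zero, and white circular complex Gaussian noise is filtered
# through the square-root spectrum. Each speckle is an independent
# realization of the same stationary process.

# Resolve a g1 target into a plain function of tau.
.g1_target_fun <- function(target_g1) {
  if (is.function(target_g1)) return(target_g1)
  if (inherits(target_g1, "correlation_curve")) {
    if (curve_kind(target_g1) != "g1") {
      stop("`target_g1` curve must be of kind \"g1\"", call. = FALSE)
    }
    tau <- target_g1$tau
    val <- target_g1$value
    return(function(t) {
      stats::approx(tau, val, xout = t, rule = 2)$y
    })
  }
  stop("`target_g1` must be a function of tau or a g1 correlation_curve",
       call. = FALSE)
}

# Clipped circulant spectrum for covariance sequence r (length n) embedded in
# a circulant of (composite) size >= 2n - 2.
.circulant_spectrum <- function(r, clip_warn = 0.05, clip_error = 0.20) {
  n <- length(r)
  m <- stats::nextn(2L * (n - 1L), c(2, 3, 5))
  c_ext <- numeric(m)
  c_ext[seq_len(n)] <- r
  c_ext[m - seq_len(n - 1L) + 1L] <- r[seq_len(n - 1L) + 1L]
  lam <- Re(stats::fft(c_ext))
  clipped <- sum(pmax(-lam, 0))
  frac <- clipped / sum(abs(lam))
  if (frac > clip_error) {
    stop(sprintf(
      "target correlation not realizable on this grid: %.1f%% of spectral mass clipped",
      100 * frac), call. = FALSE)
  }
  if (frac > clip_warn) {
    warning(sprintf("clipped %.1f%% of spectral mass in field synthesis",
                    100 * frac), call. = FALSE)
  }
  pmax(lam, 0)
}

#' Simulate a stationary correlated complex speckle field
#'
#' Generates `n_speckles` independent realizations of a zero-mean circular
#' complex Gaussian process whose autocovariance follows the target field
#' autocorrelation `g1`. Intensity samples `|E|^2` then carry the
#' fully-developed speckle statistics (`<I^2>/<I>^2 = 2`) with intensity
#' autocorrelation `1 + |g1|^2`.
#'
#' @param target_g1 Either a function of delay time returning `g1`, or a
#'   [correlation_curve()] of kind `"g1"` covering `(0, n_time * dt)`.
#' @param n_time Number of time samples.
#' @param dt Sample interval (s).
#' @param n_speckles Number of independent speckles (rows of the output).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `speckle_field`: a list with `field`
#'   (complex `n_speckles x n_time` matrix), `dt`, `target_g1` and `seed`.
#' @export
sample_correlated_field <- function(target_g1, n_time, dt, n_speckles = 1,
                                    seed = 1) {
  g1f <- .g1_target_fun(target_g1)
  n_time <- as.integer(n_time)
  if (n_time < 2) stop("`n_time` must be >= 2", call. = FALSE)
  r <- g1f((seq_len(n_time) - 1) * dt)
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-9)) {
    stop("`target_g1` must be finite and within [-1, 1] on the grid",
         call. = FALSE)
  }
  lam <- .circulant_spectrum(r)
  m <- length(lam)
  amp <- sqrt(lam / m)
  # speckles are synthesized in blocks to bound peak memory (the circulant
  # workspace is ~2x the output length per speckle)
  block <- 16L
  field <- with_seed(seed, {
    out <- matrix(0i, nrow = n_speckles, ncol = n_time)
    for (b0 in seq.int(1L, n_speckles, by = block)) {
      cols <- b0:min(b0 + block - 1L, n_speckles)
      nb <- length(cols)
      z <- complex(real = stats::rnorm(m * nb),
                   imaginary = stats::rnorm(m * nb)) / sqrt(2)
      dim(z) <- c(m, nb)
      x <- stats::mvfft(amp * z)
      out[cols, ] <- t(x[seq_len(n_time), , drop = FALSE])
    }
    out
  })
  structure(
    list(field = field, dt = dt, target_g1 = g1f, seed = seed),
    class = "speckle_field"
  )
}

#' Intensity samples of a speckle field
#'
#' @param field A `speckle_field`.
#' @return Numeric matrix `n_speckles x n_time` of `|E|^2`.
#' @export
field_intensity <- function(field) {
  stopifnot(inherits(field, "speckle_field"))
  Re(field$field * Conj(field$field))
}

#' Empirical field autocorrelation of a speckle field
#'
#' Averages the normalized lagged products `E(t) E*(t+tau)` over time and
#' speckles; used to verify that the synthesized process follows its target.
#'
#' @param field A `speckle_field`.
#' @param lags Integer lags (in samples) at which to evaluate.
#' @return A tibble with columns `tau` and `g1` (real part shown; the
#'   process is constructed with a real target so the imaginary part is
#'   noise).
#' @export
empirical_field_g1 <- function(field, lags) {
  stopifnot(inherits(field, "speckle_field"))
  e <- field$field
  n <- ncol(e)
  var0 <- mean(Re(e * Conj(e)))
  g1 <- vapply(lags, function(k) {
    if (k == 0) return(1)
    a <- e[, seq_len(n - k), drop = FALSE]
    b <- e[, seq_len(n - k) + k, drop = FALSE]
    Re(mean(a * Conj(b))) / var0
  }, numeric(1))
  tibble::tibble(tau = lags * field$dt, g1 = g1)
}
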