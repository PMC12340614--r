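# iDWS processing chain: rolling-mean subtraction isolating the heterodyne
# interference term, spatial Gaussian filtering across the line-scan pixels,
# Wiener-Khinchin autocorrelation per 0.05 s segment, pixel summation with
# reference-arm correction, and the squared-G2 cost-function fit.

#' Rolling-mean subtraction of a line-scan record
#'
#' Removes a centered per-pixel rolling mean (0.1 s default) from the raw
#' interferogram, isolating the zero-mean heterodyne fluctuation
#' `deltaI(x, t)`. Edge samples computed with a shrinking window (the first
#' and last half window) are flagged and excluded from downstream segments.
#'
#' @param record A `linescan_record` (see [simulate_idws_record()]).
#' @param window Rolling-mean window in seconds (default 0.1 s).
#' @return An object of class `idws_fluct`: list with `delta`
#'   (`n_pixels x n_time`), `dt` and `valid_time` (logical).
#' @export
rolling_mean_subtract <- function(record, window = 0.1) {
  stopifnot(inherits(record, "linescan_record"))
  n <- ncol(record$counts)
  w <- as.integer(round(window / record$dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (n < w) stop("record shorter than the rolling-mean window", call. = FALSE)
  x <- record$counts
  storage.mode(x) <- "double"
  delta <- x - rolling_mean_rows(x, w)
  h <- (w - 1L) %/% 2L
  valid <- rep(TRUE, n)
  valid[seq_len(h)] <- FALSE
  valid[seq.int(n - h + 1L, n)] <- FALSE
  structure(list(delta = delta, dt = record$dt, valid_time = valid),
            class = "idws_fluct")
}

#' Spatial Gaussian filtering across line-scan pixels
#'
#' Convolves the fluctuation at every time point across the pixel axis with
#' an unnormalized Gaussian window (peak value 1, standard deviation 0.9669
#' pixels by default), with reflective edge handling. This accounts for
#' neighbouring pixels sampling the same speckle.
#'
#' @param fluct An `idws_fluct`.
#' @param sigma Kernel standard deviation in pixels.
#' @return The `idws_fluct` with filtered `delta`.
#' @export
spatial_filter <- function(fluct, sigma = 0.9669) {
  stopifnot(inherits(fluct, "idws_fluct"))
  kern <- gaussian_kernel_peak1(sigma)
  fluct$delta <- convolve_rows_reflect(fluct$delta, kern)
  fluct
}

#' Wiener-Khinchin autocorrelation per pixel and segment
#'
#' Splits the valid part of the fluctuation into non-overlapping segments
#' (0.05 s default, the 20 Hz output rate) and computes the unnormalized
#' per-pixel autocorrelation sums
#' `G2(x, tau) = sum_t deltaI(x, t) deltaI(x, t + tau)` via zero-padded FFT
#' (exactly the linear, non-circular estimator), truncated to `n_lags`
#' uniform lags at the native sample spacing.
#'
#' @param fluct An `idws_fluct` (after [spatial_filter()]).
#' @param segment Segment length in seconds (default 0.05 s).
#' @param n_lags Number of uniformly spaced lags to keep (default 4000; a
#'   shorter segment reduces this with a flag).
#' @return A tibble with one row per segment: `segment`, `time` (segment
#'   centre), `reduced_lags` and `g2` (list-column of
#'   `n_pixels x n_lags` matrices); the lag grid is in
#'   `attr(, "tau")`.
#' @export
wk_autocorrelation <- function(fluct, segment = 0.05, n_lags = 4000) {
  stopifnot(inherits(fluct, "idws_fluct"))
  dt <- fluct$dt
  n_seg <- as.integer(round(segment / dt))
  ok <- which(fluct$valid_time)
  if (length(ok) < n_seg) {
    stop("not enough valid samples for one segment", call. = FALSE)
  }
  start <- ok[1]
  n_avail <- ok[length(ok)] - start + 1L
  n_win <- n_avail %/% n_seg
  reduced <- n_lags > n_seg - 1L
  l_keep <- min(n_lags, n_seg - 1L)
  rows <- vector("list", n_win)
  for (iw in seq_len(n_win)) {
    cols <- start + (iw - 1L) * n_seg + seq_len(n_seg) - 1L
    seg <- fluct$delta[, cols, drop = FALSE]
    ac <- fft_autocorr_sums(t(seg))  # n_seg x n_pixels
    rows[[iw]] <- tibble::tibble(
      segment = iw,
      time = (cols[1] + cols[n_seg]) / 2 * dt,
      reduced_lags = reduced,
      g2 = list(t(ac[seq_len(l_keep + 1L), , drop = FALSE]))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "tau") <- (0:l_keep) * dt
  if (reduced) {
    warning("segment shorter than requested lag count; lags reduced to ",
            l_keep, call. = FALSE)
  }
  out
}

#' Pixel summation and reference-arm correction
#'
#' Sums the per-pixel autocorrelation functions of each segment and
#' subtracts the pixel-summed autocorrelation of a sample-blocked reference
#' run processed identically (same segment length and lag grid).
#'
#' @param g2_tbl Output of [wk_autocorrelation()] for the measurement.
#' @param reference Either the output of [wk_autocorrelation()] for the
#'   reference run (averaged over its segments) or a numeric vector of
#'   pixel-summed reference G2 values on the same lag grid.
#' @return A tibble with `segment`, `time` and `curve` (list-column of
#'   [correlation_curve()] objects of kind `"G2_idws"`).
#' @export
sum_and_reference_correct <- function(g2_tbl, reference) {
  tau <- attr(g2_tbl, "tau")
  if (is.data.frame(reference)) {
    tau_ref <- attr(reference, "tau")
    if (length(tau_ref) != length(tau) ||
        any(abs(tau_ref - tau) > 1e-12)) {
      stop("reference lag grid does not match the measurement", call. = FALSE)
    }
    ref_sum <- rowMeans(vapply(reference$g2, colSums,
                               numeric(length(tau))))
  } else {
    ref_sum <- reference
    if (length(ref_sum) != length(tau)) {
      stop("reference lag grid does not match the measurement", call. = FALSE)
    }
  }
  curves <- purrr::map(g2_tbl$g2, function(m) {
    correlation_curve(tau, colSums(m) - ref_sum, kind = "G2_idws")
  })
  tibble::tibble(segment = g2_tbl$segment, time = g2_tbl$time,
                 curve = curves)
}

#' Fit BFi to a reference-corrected interferometric autocorrelation
#'
#' Default mode (`"g1sq_all"`) minimizes the squared-correlation cost
#' `sum_tau (G2^2 - (A * g1(tau; BFi))^2)^2`, summed from the first nonzero
#' lag up to (not including) the first lag at which the measured correlation,
#' normalized by its first-lag value, goes negative. `A` absorbs the unknown
#' coupling coefficient (including the `2*beta*<I_R>` prefactor), so fits
#' are invariant to overall detector gain. Modes `"g1_all"` (linear cost over
#' the same range) and `"g1_over_1e"` (linear cost restricted to lags with
#' normalized correlation above 1/e) reproduce the alternative fitting
#' strategies.
#'
#' @param curve A [correlation_curve()] of kind `"G2_idws"` (lag 0 first).
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param fit_mode One of `"g1sq_all"`, `"g1_all"`, `"g1_over_1e"`.
#' @param bfi_bounds Search bounds for BFi (cm^2/s).
#' @return A one-row tibble of class `idws_fit`: `bfi`, `amplitude`,
#'   `fit_range_end`, `residual`, `valid`.
#' @export
fit_g2sq_bfi <- function(curve, medium, geometry,
                         fit_mode = c("g1sq_all", "g1_all", "g1_over_1e"),
                         bfi_bounds = c(1e-12, 1e-4)) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(inherits(curve, "correlation_curve"))
  tau <- curve$tau
  val <- curve$value
  if (length(val) < 3 || !(val[1] > 0 || val[2] > 0)) {
    stop("G2 must be positive near zero lag", call. = FALSE)
  }
  # measured correlation normalized by its tau->0 value (first nonzero lag:
  # the zero-lag point carries the noise variance and is excluded)
  norm <- val / val[2]
  neg <- which(norm[-1] < 0)
  fit_range_end <- if (length(neg) == 0) length(val) else neg[1] + 1L
  idx <- seq.int(2L, fit_range_end - 1L)
  if (length(idx) < 2) {
    return(structure(
      tibble::tibble(bfi = NA_real_, amplitude = NA_real_,
                     fit_range_end = fit_range_end, residual = NA_real_,
                     valid = FALSE),
      class = c("idws_fit", "tbl_df", "tbl", "data.frame")))
  }
  tau_f <- tau[idx]
  y <- val[idx]
  if (fit_mode == "g1_over_1e") {
    keep <- norm[idx] > exp(-1)
    if (sum(keep) >= 2) {
      tau_f <- tau_f[keep]
      y <- y[keep]
    }
  }
  cost <- switch(
    fit_mode,
    g1sq_all = function(lb) {
      h <- .g1_values(medium, geometry, 10^lb, tau_f)^2
      a2 <- sum(y^2 * h) / sum(h^2)          # profile of A^2
      if (!is.finite(a2) || a2 <= 0) return(list(cost = Inf, a = NA))
      list(cost = sum((y^2 - a2 * h)^2), a = sqrt(a2))
    },
    function(lb) {
      g <- .g1_values(medium, geometry, 10^lb, tau_f)
      a <- sum(y * g) / sum(g^2)
      if (!is.finite(a) || a <= 0) return(list(cost = Inf, a = NA))
      list(cost = sum((y - a * g)^2), a = a)
    }
  )
  grid <- seq(log10(bfi_bounds[1]), log10(bfi_bounds[2]), by = 0.25)
  cg <- vapply(grid, function(lb) cost(lb)$cost, numeric(1))
  if (all(!is.finite(cg))) {
    return(structure(
      tibble::tibble(bfi = NA_real_, amplitude = NA_real_,
                     fit_range_end = fit_range_end, residual = NA_real_,
                     valid = FALSE),
      class = c("idws_fit", "tbl_df", "tbl", "data.frame")))
  }
  lb0 <- grid[which.min(cg)]
  opt <- stats::optimize(function(lb) cost(lb)$cost,
                         c(lb0 - 0.3, lb0 + 0.3), tol = 1e-10)
  res <- cost(opt$minimum)
  bfi <- 10^opt$minimum
  at_bound <- bfi <= bfi_bounds[1] * 1.01 || bfi >= bfi_bounds[2] / 1.01
  out <- tibble::tibble(
    bfi = bfi, amplitude = res$a, fit_range_end = fit_range_end,
    residual = res$cost, valid = !at_bound
  )
  class(out) <- c("idws_fit", class(out))
  out
}

#' Pixel-summed reference autocorrelation from a sample-blocked run
#'
#' Processes a reference record through the identical chain (rolling-mean
#' subtraction, spatial filter, Wiener-Khinchin autocorrelation) and returns
#' the pixel-summed G2 averaged over its segments.
#'
#' @inheritParams rolling_mean_subtract
#' @inheritParams wk_autocorrelation
#' @param sigma Spatial filter standard deviation (pixels).
#' @return Numeric vector of reference G2 sums with the lag grid as
#'   `attr(, "tau")`.
#' @export
idws_reference_curve <- function(record, window = 0.1, sigma = 0.9669,
                                 segment = 0.05, n_lags = 4000) {
  tbl <- record |>
    rolling_mean_subtract(window = window) |>
    spatial_filter(sigma = sigma) |>
    wk_autocorrelation(segment = segment, n_lags = n_lags)
  out <- rowMeans(vapply(tbl$g2, colSums, numeric(length(attr(tbl, "tau")))))
  attr(out, "tau") <- attr(tbl, "tau")
  out
}

#' Process an iDWS line-scan record into a BFi time series
#'
#' Full chain: rolling-mean subtraction, spatial filtering, per-segment
#' Wiener-Khinchin autocorrelation, pixel summation with reference
#' correction, and the squared-G2 fit per 0.05 s segment.
#'
#' @inheritParams rolling_mean_subtract
#' @inheritParams fit_g2sq_bfi
#' @inheritParams wk_autocorrelation
#' @param reference A reference `linescan_record` or a precomputed
#'   pixel-summed reference vector from [idws_reference_curve()].
#' @param sigma Spatial filter standard deviation (pixels).
#' @return A [flow_series()] tibble (modality `"iDWS"`) with per-segment
#'   `bfi`, `amplitude`, `fit_range_end`, `residual`, `valid`.
#' @export
process_idws <- function(record, reference, medium, geometry,
                         window = 0.1, sigma = 0.9669, segment = 0.05,
                         n_lags = 4000, fit_mode = "g1sq_all") {
  if (inherits(reference, "linescan_record")) {
    reference <- idws_reference_curve(reference, window = window,
                                      sigma = sigma, segment = segment,
                                      n_lags = n_lags)
  }
  corrected <- record |>
    rolling_mean_subtract(window = window) |>
    spatial_filter(sigma = sigma) |>
    wk_autocorrelation(segment = segment, n_lags = n_lags) |>
    sum_and_reference_correct(reference)
  fits <- dplyr::bind_rows(purrr::map(
    corrected$curve, fit_g2sq_bfi, medium = medium, geometry = geometry,
    fit_mode = fit_mode))
  flow_series(
    time = corrected$time, bfi = fits$bfi, modality = "iDWS",
    rate = 1 / segment, valid = fits$valid,
    extra = tibble::tibble(amplitude = fits$amplitude,
                           fit_range_end = fits$fit_range_end,
                           residual = fits$residual)
  )
}
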