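# DCS processing: software intensity autocorrelator on photon-count streams,
# channel averaging, coherence-parameter calibration, and the single-parameter
# semi-infinite CDE fit recovering BFi.

#' Software intensity autocorrelator
#'
#' Splits each channel's photon-count stream into consecutive integration
#' windows (0.05 s default, giving the instrument's 20 Hz output rate) and
#' computes the normalized intensity autocorrelation
#' `g2(tau) = <I(t) I(t+tau)> / <I>^2` on a multi-tau style log-spaced lag
#' grid. Lag sums are evaluated with a zero-padded FFT and divided by the
#' number of contributing pairs, which is exactly equivalent to direct lag
#' summation. Windows with zero total counts are flagged invalid and not
#' fitted downstream.
#'
#' @param counts A `photon_counts` object (see [simulate_dcs_counts()]).
#' @param integration Window length in seconds (default 0.05 s).
#' @param lags_per_octave Lag-grid density (default 16).
#' @param max_lag_fraction Largest lag as a fraction of the window (default
#'   1/4; late lags of a finite window estimator are noisy).
#' @return A tibble with one row per window and channel: columns `window`,
#'   `time` (window centre, s), `channel`, `valid` and `curve` (a
#'   list-column of [correlation_curve()] objects of kind `"g2"`).
#' @export
software_autocorrelator <- function(counts, integration = 0.05,
                                    lags_per_octave = 16,
                                    max_lag_fraction = 0.25) {
  stopifnot(inherits(counts, "photon_counts"))
  dt <- counts$dt
  n_bins <- ncol(counts$counts)
  w <- as.integer(round(integration / dt))
  if (w < 100) {
    stop("integration window must span at least 100 bins", call. = FALSE)
  }
  n_win <- n_bins %/% w
  if (n_win < 1) stop("record shorter than one window", call. = FALSE)
  lags <- multitau_lags(max(2L, floor(w * max_lag_fraction)), lags_per_octave)
  tau <- lags * dt
  rows <- vector("list", n_win * counts$n_channels)
  r <- 0
  for (iw in seq_len(n_win)) {
    seg <- counts$counts[, ((iw - 1L) * w + 1L):(iw * w), drop = FALSE]
    ac <- fft_autocorr_sums(t(seg))
    for (ch in seq_len(counts$n_channels)) {
      r <- r + 1
      tot <- sum(seg[ch, ])
      if (tot == 0) {
        rows[[r]] <- tibble::tibble(
          window = iw, time = (iw - 0.5) * w * dt, channel = ch,
          valid = FALSE, curve = list(NULL))
        next
      }
      mu <- tot / w
      g2 <- (ac[lags + 1L, ch] / (w - lags)) / mu^2
      rows[[r]] <- tibble::tibble(
        window = iw, time = (iw - 0.5) * w * dt, channel = ch, valid = TRUE,
        curve = list(correlation_curve(tau, g2, kind = "g2")))
    }
  }
  dplyr::bind_rows(rows)
}

#' Average per-channel g2 curves within each window
#'
#' Unweighted pointwise mean over the valid channels of each window; invalid
#' channels are excluded and their count recorded. A window with no valid
#' channel is itself invalid.
#'
#' @param g2_tbl Output of [software_autocorrelator()].
#' @return A tibble with one row per window: `window`, `time`, `n_valid`,
#'   `valid`, `curve`.
#' @export
average_channels <- function(g2_tbl) {
  g2_tbl |>
    dplyr::group_by(.data$window, .data$time) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      curve = {
        ok <- .data$valid
        if (!any(ok)) {
          list(NULL)
        } else {
          cs <- .data$curve[ok]
          vals <- rowMeans(vapply(cs, function(cc) cc$value,
                                  numeric(nrow(cs[[1]]))))
          list(correlation_curve(cs[[1]]$tau, vals, kind = "g2"))
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$n_valid > 0)
}

#' Pointwise mean of correlation curves sharing a tau grid
#'
#' @param curves List of [correlation_curve()] objects (NULL entries are
#'   dropped).
#' @param kind Kind of the averaged curve (defaults to the first curve's).
#' @return A [correlation_curve()].
#' @export
mean_curve <- function(curves, kind = NULL) {
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (length(curves) == 0) stop("no valid curves to average", call. = FALSE)
  tau <- curves[[1]]$tau
  vals <- rowMeans(vapply(curves, function(cc) cc$value, numeric(length(tau))))
  correlation_curve(tau, vals, kind = kind %||% curve_kind(curves[[1]]))
}

# Profile fit of 1 + beta * g1(tau; bfi)^2 to a measured g2 curve: beta is
# linear given bfi, bfi is optimized on a log grid then refined.
.profile_beta_fit <- function(tau, g2, medium, geometry,
                              bfi_bounds = c(1e-12, 1e-4)) {
  y <- g2 - 1
  cost <- function(lb) {
    h <- .g1_values(medium, geometry, 10^lb, tau)^2
    beta <- sum(y * h) / sum(h * h)
    if (!is.finite(beta) || beta <= 0) return(list(cost = Inf, beta = NA))
    list(cost = sum((y - beta * h)^2), beta = beta)
  }
  grid <- seq(log10(bfi_bounds[1]), log10(bfi_bounds[2]), by = 0.25)
  cg <- vapply(grid, function(lb) cost(lb)$cost, numeric(1))
  if (all(!is.finite(cg))) {
    stop("beta calibration failed: no decay consistent with the model",
         call. = FALSE)
  }
  lb0 <- grid[which.min(cg)]
  opt <- stats::optimize(function(lb) cost(lb)$cost,
                         c(lb0 - 0.3, lb0 + 0.3), tol = 1e-10)
  res <- cost(opt$minimum)
  list(bfi = 10^opt$minimum, beta = res$beta, residual = res$cost)
}

#' Calibrate the DCS coherence parameter
#'
#' Jointly fits `(beta, BFi)` to the time-averaged g2 curve (typically the
#' first minute of a session); `beta` is then frozen for per-window
#' single-parameter fits, mirroring standard DCS practice.
#'
#' @param g2 A [correlation_curve()] of kind `"g2"`, a list of curves, or
#'   the output tibble of [average_channels()] (all valid curves are
#'   averaged pointwise before fitting).
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param bfi_bounds Search bounds for BFi (cm^2/s).
#' @return An object of class `dcs_calibration`: list with `beta`, `bfi`,
#'   `residual`, `n_curves`, and the averaged `curve`.
#' @export
calibrate_beta <- function(g2, medium, geometry, bfi_bounds = c(1e-12, 1e-4)) {
  if (inherits(g2, "correlation_curve")) {
    avg <- g2
    n_curves <- 1L
  } else if (is.data.frame(g2)) {
    curves <- g2$curve[g2$valid]
    avg <- mean_curve(curves)
    n_curves <- length(curves)
  } else {
    avg <- mean_curve(g2)
    n_curves <- length(g2)
  }
  if (max(avg$value) - 1 < 1e-6) {
    stop("beta calibration failed: g2 shows no measurable decay amplitude",
         call. = FALSE)
  }
  fit <- .profile_beta_fit(avg$tau, avg$value, medium, geometry, bfi_bounds)
  structure(
    list(beta = fit$beta, bfi = fit$bfi, residual = fit$residual,
         n_curves = n_curves, curve = avg),
    class = "dcs_calibration"
  )
}

# Select fit lags: all lags whose g2 - 1 exceeds 3x the late-lag noise floor
# (standard deviation over the last quarter of lags); falls back to all lags
# when too few qualify.
.dcs_fit_lags <- function(g2) {
  n <- length(g2)
  tail_idx <- seq.int(max(1L, floor(0.75 * n)), n)
  floor_sd <- stats::sd(g2[tail_idx] - 1)
  if (!is.finite(floor_sd) || floor_sd == 0) {
    keep <- which(g2 - 1 > 0)
  } else {
    keep <- which(g2 - 1 > 3 * floor_sd)
  }
  if (length(keep) < 5) keep <- seq_len(n)
  seq_len(max(keep))
}

#' Fit BFi to a measured g2 curve
#'
#' Single-parameter nonlinear least squares over BFi minimizing
#' `sum((g2 - 1 - beta * g1(tau; BFi)^2)^2)` against the semi-infinite CDE
#' solution, with `beta` frozen from calibration. `joint = TRUE` refits
#' `(beta, BFi)` per curve instead (the robustness-check mode).
#'
#' @param g2 A [correlation_curve()] of kind `"g2"`.
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param beta Calibrated coherence parameter (or a `dcs_calibration`).
#' @param fit_range `"auto"` restricts to lags above 3x the late-lag noise
#'   floor; `"all"` uses every lag.
#' @param joint If `TRUE`, fit `beta` jointly with BFi for this curve.
#' @param bfi_bounds Search bounds for BFi (cm^2/s).
#' @return A one-row tibble of class `dcs_fit`: `bfi`, `beta`, `residual`,
#'   `n_lags_used`, `at_bound`, `valid`.
#' @export
fit_g2_bfi <- function(g2, medium, geometry, beta,
                       fit_range = c("auto", "all"), joint = FALSE,
                       bfi_bounds = c(1e-12, 1e-4)) {
  fit_range <- match.arg(fit_range)
  if (inherits(beta, "dcs_calibration")) beta <- beta$beta
  stopifnot(inherits(g2, "correlation_curve"))
  tau <- g2$tau
  y <- g2$value
  idx <- if (fit_range == "auto") .dcs_fit_lags(y) else seq_along(y)
  tau_f <- tau[idx]
  y_f <- y[idx]
  if (joint) {
    fit <- .profile_beta_fit(tau_f, y_f, medium, geometry, bfi_bounds)
    bfi <- fit$bfi
    beta_out <- fit$beta
    resid <- fit$residual
  } else {
    if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
    sse <- function(lb) {
      h <- .g1_values(medium, geometry, 10^lb, tau_f)^2
      sum((y_f - 1 - beta * h)^2)
    }
    grid <- seq(log10(bfi_bounds[1]), log10(bfi_bounds[2]), by = 0.25)
    lb0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
    opt <- stats::optimize(sse, c(lb0 - 0.3, lb0 + 0.3), tol = 1e-10)
    bfi <- 10^opt$minimum
    beta_out <- beta
    resid <- opt$objective
  }
  at_bound <- bfi <= bfi_bounds[1] * 1.01 || bfi >= bfi_bounds[2] / 1.01
  out <- tibble::tibble(
    bfi = bfi, beta = beta_out, residual = resid,
    n_lags_used = length(idx), at_bound = at_bound, valid = !at_bound
  )
  class(out) <- c("dcs_fit", class(out))
  out
}

#' Process a DCS photon-count record into a BFi time series
#'
#' Runs the software autocorrelator, averages channels per window,
#' calibrates `beta` on the first `calibration_window` seconds (or uses a
#' supplied value), and fits BFi per window.
#'
#' @inheritParams software_autocorrelator
#' @inheritParams fit_g2_bfi
#' @param calibration_window Seconds of data averaged for the beta
#'   calibration (default: the whole record, capped at 60 s).
#' @param beta Optional fixed coherence parameter; calibrated when `NULL`.
#' @return A [flow_series()] tibble (modality `"DCS"`) with per-window
#'   `bfi`, `beta`, `residual` and `valid`.
#' @export
process_dcs <- function(counts, medium, geometry, integration = 0.05,
                        beta = NULL, calibration_window = 60,
                        fit_range = "auto", joint = FALSE) {
  g2_tbl <- software_autocorrelator(counts, integration = integration)
  avg <- average_channels(g2_tbl)
  if (is.null(beta)) {
    cal_rows <- avg$valid & avg$time <= calibration_window
    cal <- calibrate_beta(avg[cal_rows, ], medium, geometry)
    beta <- cal$beta
  }
  fits <- purrr::map(seq_len(nrow(avg)), function(i) {
    if (!avg$valid[i]) {
      return(tibble::tibble(bfi = NA_real_, beta = beta, residual = NA_real_,
                            n_lags_used = 0L, at_bound = FALSE, valid = FALSE))
    }
    fit_g2_bfi(avg$curve[[i]], medium, geometry, beta,
               fit_range = fit_range, joint = joint)
  })
  fits <- dplyr::bind_rows(fits)
  flow_series(
    time = avg$time, bfi = fits$bfi, modality = "DCS",
    rate = 1 / integration, valid = fits$valid & avg$valid,
    extra = tibble::tibble(beta = fits$beta, residual = fits$residual)
  )
}
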