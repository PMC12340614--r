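# SCOS processing: dark calibration, windowed speckle contrast, the noise
# correction chain (read, shot, quantization, spatial), and the inversion of
# the exposure-integrated contrast model for BFi.

# Per-window sums over non-overlapping `window x window` tiles of a matrix.
# Returns a list with per-window mean, unbiased variance, and tile indices.
.window_stats <- function(mat, window) {
  h <- nrow(mat); w <- ncol(mat)
  nh <- h %/% window; nw <- w %/% window
  if (nh < 1 || nw < 1) stop("frame smaller than the contrast window",
                             call. = FALSE)
  mat <- mat[seq_len(nh * window), seq_len(nw * window), drop = FALSE]
  row_grp <- rep(seq_len(nh), each = window)
  col_grp <- rep(seq_len(nw), each = window)
  grp <- outer(row_grp, (col_grp - 1L) * nh, "+")
  n <- window^2
  s1 <- rowsum(as.vector(mat), as.vector(grp))[, 1]
  s2 <- rowsum(as.vector(mat)^2, as.vector(grp))[, 1]
  mu <- s1 / n
  v <- (s2 - n * mu^2) / (n - 1)
  list(
    win_row = rep(seq_len(nh), times = nw),
    win_col = rep(seq_len(nw), each = nh),
    mu = unname(mu),
    var = pmax(unname(v), 0)
  )
}

#' Dark calibration of the SCOS camera
#'
#' Computes the per-pixel dark offset and dark variance maps from a stack of
#' frames collected with no source light. The read-noise contrast
#' `kappa_read^2 = sigma_dark^2 / mu^2` is evaluated later against each lit
#' window's mean.
#'
#' @param dark A `frame_stack` of dark frames (at least 10).
#' @param gain Camera gain (counts per photoelectron) to carry in the
#'   calibration.
#' @param n_avg Number of lit frames to average for the spatial correction.
#' @param lit_threshold Warn if any pixel's dark mean exceeds the stack
#'   median by more than this many counts (stray light in the dark stack).
#' @return An object of class `camera_calibration`: list with `offset_map`,
#'   `dark_var_map`, `gain`, `n_avg`.
#' @export
dark_calibration <- function(dark, gain = 9.64, n_avg = 100,
                             lit_threshold = 50) {
  stopifnot(inherits(dark, "frame_stack"))
  nf <- dim(dark$frames)[3]
  if (is.na(nf) || nf == 0) stop("empty dark stack", call. = FALSE)
  if (nf < 10) stop("need at least 10 dark frames", call. = FALSE)
  if (n_avg < 2) stop("`n_avg` must be >= 2", call. = FALSE)
  x <- dark$frames
  storage.mode(x) <- "double"
  offset <- apply(x, c(1, 2), mean)
  m2 <- apply(x^2, c(1, 2), mean)
  dark_var <- (m2 - offset^2) * nf / (nf - 1)
  if (any(offset > stats::median(offset) + lit_threshold)) {
    warning("dark stack contains pixels well above the median offset; ",
            "possible stray light", call. = FALSE)
  }
  structure(list(offset_map = offset, dark_var_map = dark_var, gain = gain,
                 n_avg = n_avg),
            class = "camera_calibration")
}

#' Windowed speckle contrast of one frame
#'
#' Computes the measured squared contrast `kappa_meas^2 = sigma^2 / mu^2`
#' (unbiased sample variance over mean squared) of the dark-corrected counts
#' in each non-overlapping `window x window` tile; tiles truncated at the
#' image edge are discarded. Windows with nonpositive mean are invalid.
#'
#' @param frame A numeric matrix of camera counts (one frame).
#' @param calibration A `camera_calibration`.
#' @param window Window side length in pixels (default 7).
#' @return A tibble with per-window `win_row`, `win_col`, `mu`,
#'   `kappa_meas_sq`, `dark_var` (window-mean dark variance) and `valid`.
#' @export
windowed_contrast <- function(frame, calibration, window = 7) {
  stopifnot(inherits(calibration, "camera_calibration"))
  frame <- as.matrix(frame)
  if (nrow(frame) < window || ncol(frame) < window) {
    stop("frame smaller than the contrast window", call. = FALSE)
  }
  corr <- frame - calibration$offset_map
  st <- .window_stats(corr, window)
  dk <- .window_stats(calibration$dark_var_map, window)
  valid <- st$mu > 0
  tibble::tibble(
    win_row = st$win_row, win_col = st$win_col, mu = st$mu,
    kappa_meas_sq = ifelse(valid, st$var / st$mu^2, NA_real_),
    dark_var = dk$mu,
    valid = valid
  )
}

#' Spatial (static-pattern) variance correction
#'
#' Temporally averages `n_avg` consecutive dark-corrected lit frames and
#' computes, per window, the shot-corrected spatial variance of the average,
#' `sigma_spatial^2 = sigma_avg^2 - gain * mu_avg / n_avg`. This captures
#' static spatial structure (vignetting, fixed-pattern nonuniformity) not
#' attributable to the sample; negative estimates (residual shot noise) are
#' clamped to zero with a warning.
#'
#' @param stack A `frame_stack` of lit frames (uses the first `n_avg`).
#' @param calibration A `camera_calibration`.
#' @param window Window side length in pixels.
#' @param n_avg Frames to average (default from the calibration; at least 2).
#' @return A tibble with per-window `win_row`, `win_col`, `mu_avg`,
#'   `sigma_spatial_sq`.
#' @export
spatial_variance <- function(stack, calibration, window = 7, n_avg = NULL) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(calibration, "camera_calibration"))
  n_avg <- n_avg %||% calibration$n_avg
  nf <- dim(stack$frames)[3]
  if (n_avg < 2) stop("`n_avg` must be >= 2", call. = FALSE)
  n_avg <- min(n_avg, nf)
  if (n_avg < 2) stop("need at least 2 frames for the spatial correction",
                      call. = FALSE)
  x <- stack$frames[, , seq_len(n_avg), drop = FALSE]
  storage.mode(x) <- "double"
  avg <- apply(x, c(1, 2), mean) - calibration$offset_map
  st <- .window_stats(avg, window)
  ssq <- st$var - calibration$gain * st$mu / n_avg
  if (any(ssq < 0)) {
    warning("negative spatial variance estimate clamped to zero ",
            "(residual shot noise)", call. = FALSE)
    ssq <- pmax(ssq, 0)
  }
  tibble::tibble(win_row = st$win_row, win_col = st$win_col,
                 mu_avg = st$mu, sigma_spatial_sq = ssq)
}

#' Noise corrections of the measured speckle contrast
#'
#' Populates the full contrast decomposition per window:
#' `kappa_f^2 = kappa_meas^2 - kappa_read^2 - kappa_shot^2 -
#'  kappa_quant^2 - kappa_spatial^2`, with
#' `kappa_read^2 = sigma_dark^2/mu^2`, `kappa_shot^2 = gain/mu`,
#' `kappa_quant^2 = 1/(12 mu^2)` and
#' `kappa_spatial^2 = sigma_spatial^2/mu^2`. The identity holds exactly for
#' every window; windows with negative fundamental contrast are marked
#' invalid, never clipped.
#'
#' @param contrast Output of [windowed_contrast()].
#' @param calibration A `camera_calibration`.
#' @param spatial Output of [spatial_variance()] on matching windows, or
#'   `NULL` for no spatial correction (`kappa_spatial^2 = 0`).
#' @return A tibble of class `contrast_record` with all squared-contrast
#'   terms, `mu` and `valid`.
#' @export
noise_corrections <- function(contrast, calibration, spatial = NULL) {
  stopifnot(inherits(calibration, "camera_calibration"))
  g <- calibration$gain
  if (is.null(g) || g <= 0) stop("calibration gain missing", call. = FALSE)
  mu <- contrast$mu
  k_read <- contrast$dark_var / mu^2
  k_shot <- g / mu
  k_quant <- 1 / (12 * mu^2)
  if (is.null(spatial)) {
    k_spatial <- rep(0, length(mu))
  } else {
    key <- paste(contrast$win_row, contrast$win_col)
    skey <- paste(spatial$win_row, spatial$win_col)
    k_spatial <- spatial$sigma_spatial_sq[match(key, skey)] / mu^2
  }
  k_f <- contrast$kappa_meas_sq - k_read - k_shot - k_quant - k_spatial
  out <- tibble::tibble(
    win_row = contrast$win_row, win_col = contrast$win_col, mu = mu,
    kappa_meas_sq = contrast$kappa_meas_sq,
    kappa_read_sq = k_read, kappa_shot_sq = k_shot,
    kappa_quant_sq = k_quant, kappa_spatial_sq = k_spatial,
    kappa_f_sq = k_f,
    valid = contrast$valid & is.finite(k_f) & k_f > 0
  )
  class(out) <- c("contrast_record", class(out))
  out
}

#' Invert the speckle-contrast model for BFi
#'
#' One-dimensional root finding of the exposure-integrated contrast model
#' (see [kappa_squared_theory()]) in BFi; the model is strictly monotone in
#' BFi so the root is unique. Values with `kappa_f^2 <= 0` or
#' `kappa_f^2 >= beta_assumed` are invalid. The output is flagged
#' `"relative"`: the absolute scale depends on the assumed coherence
#' parameter. In phantom mode, supply `reference_db` and `reference_idx` to
#' rescale the series so its mean over those indices matches the reference
#' (the Stokes-Einstein normalization).
#'
#' @param kappa_f_sq Numeric vector of fundamental squared contrasts (one
#'   per frame).
#' @param t_exp Exposure time (s).
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param beta_assumed Assumed coherence parameter (default 0.3).
#' @param bfi_bounds Search bounds (cm^2/s).
#' @param reference_db Optional reference diffusion coefficient (cm^2/s)
#'   for rescaling.
#' @param reference_idx Indices of `kappa_f_sq` over which the mean
#'   recovered BFi is matched to `reference_db`.
#' @param n_nodes Quadrature nodes for the contrast model.
#' @return A tibble with `kappa_f_sq`, `bfi` and `valid`; attribute
#'   `scale` is `"relative"` or `"rescaled"`.
#' @export
fit_kappa2_bfi <- function(kappa_f_sq, t_exp, medium, geometry,
                           beta_assumed = 0.3, bfi_bounds = c(1e-12, 1e-4),
                           reference_db = NULL, reference_idx = NULL,
                           n_nodes = 512) {
  if (t_exp <= 0) stop("`t_exp` must be positive", call. = FALSE)
  k2_model <- function(lb) {
    kappa_squared_from_g1(
      function(tau) .g1_values(medium, geometry, 10^lb, tau),
      beta = beta_assumed, t_exp = t_exp, n_nodes = n_nodes, check = FALSE)
  }
  lo <- log10(bfi_bounds[1]); hi <- log10(bfi_bounds[2])
  k_lo <- k2_model(hi)  # fastest flow -> smallest contrast
  k_hi <- k2_model(lo)
  bfi <- vapply(kappa_f_sq, function(k) {
    if (!is.finite(k) || k <= 0 || k >= beta_assumed) return(NA_real_)
    if (k >= k_hi || k <= k_lo) return(NA_real_)
    10^stats::uniroot(function(lb) k2_model(lb) - k, c(lo, hi),
                      tol = 1e-10)$root
  }, numeric(1))
  scale <- "relative"
  if (!is.null(reference_db)) {
    reference_idx <- reference_idx %||% seq_along(bfi)
    ref_mean <- mean(bfi[reference_idx], na.rm = TRUE)
    bfi <- bfi * reference_db / ref_mean
    scale <- "rescaled"
  }
  out <- tibble::tibble(kappa_f_sq = kappa_f_sq, bfi = bfi,
                        valid = is.finite(bfi))
  attr(out, "scale") <- scale
  out
}

#' Process an SCOS frame stack into a BFi time series
#'
#' Per frame: windowed contrast, noise corrections (with the spatial term
#' refreshed every `n_avg` frames and applied forward), frame-mean
#' fundamental contrast across windows, and the contrast-model inversion.
#' Frames whose mean fundamental contrast is nonpositive are flagged
#' invalid, never fitted.
#'
#' @param stack A lit `frame_stack`.
#' @param dark A dark `frame_stack` (or a `camera_calibration`).
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param beta_assumed Assumed coherence parameter.
#' @param window Contrast window side (pixels).
#' @param n_avg Frames per spatial-correction block.
#' @param gain Camera gain override; defaults to the calibration's.
#' @param spatial_correction Apply the spatial variance correction
#'   (default TRUE).
#' @param ... Passed to [fit_kappa2_bfi()].
#' @return A [flow_series()] tibble (modality `"SCOS"`) with per-frame
#'   `bfi`, `kappa_meas_sq`, `kappa_f_sq`, `valid`; attribute `scale` as in
#'   [fit_kappa2_bfi()].
#' @export
process_scos <- function(stack, dark, medium, geometry, beta_assumed = 0.3,
                         window = 7, n_avg = NULL, gain = NULL,
                         spatial_correction = TRUE, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  cal <- if (inherits(dark, "camera_calibration")) dark else
    dark_calibration(dark, gain = gain %||% stack$gain,
                     n_avg = n_avg %||% 100)
  if (!is.null(gain)) cal$gain <- gain
  nf <- dim(stack$frames)[3]
  n_avg <- min(n_avg %||% cal$n_avg, nf)
  k_meas <- numeric(nf)
  k_f <- numeric(nf)
  spat <- NULL
  for (f in seq_len(nf)) {
    if (spatial_correction && ((f - 1) %% n_avg == 0)) {
      blk <- structure(
        list(frames = stack$frames[, , f:min(nf, f + n_avg - 1),
                                   drop = FALSE]),
        class = "frame_stack")
      spat <- tryCatch(
        suppressWarnings(spatial_variance(blk, cal, window = window,
                                          n_avg = min(n_avg, nf - f + 1))),
        error = function(e) NULL)
    }
    ct <- windowed_contrast(stack$frames[, , f], cal, window = window)
    rec <- noise_corrections(ct, cal, spatial = spat)
    ok_mu <- rec$mu > 0
    k_meas[f] <- mean(rec$kappa_meas_sq[ok_mu])
    k_f[f] <- mean(rec$kappa_f_sq[ok_mu])
  }
  fit <- fit_kappa2_bfi(k_f, t_exp = stack$t_exp, medium = medium,
                        geometry = geometry, beta_assumed = beta_assumed,
                        ...)
  out <- flow_series(
    time = (seq_len(nf) - 0.5) / stack$frame_rate,
    bfi = fit$bfi, modality = "SCOS", rate = stack$frame_rate,
    valid = fit$valid,
    extra = tibble::tibble(kappa_meas_sq = k_meas, kappa_f_sq = k_f)
  )
  attr(out, "scale") <- attr(fit, "scale")
  out
}

#' Camera-gain sensitivity sweep
#'
#' Re-runs the full SCOS pipeline on a cuff-protocol frame stack for each
#' assumed camera gain and tabulates the recovered baseline and peak flow.
#' Overestimating the gain underestimates the fundamental contrast and so
#' inflates the recovered flow; underestimation does the reverse.
#'
#' @inheritParams process_scos
#' @param gains Numeric vector of assumed gains to sweep.
#' @param baseline_idx Frame indices forming the baseline period.
#' @return A tibble with one row per gain: `gain`, `bfi_baseline`,
#'   `bfi_max`, `rbfi_max`, `min_kappa_f_sq`.
#' @export
gain_sensitivity_sweep <- function(stack, dark, medium, geometry, gains,
                                   baseline_idx, beta_assumed = 0.3,
                                   window = 7, ...) {
  purrr::map_dfr(gains, function(g) {
    fs <- process_scos(stack, dark, medium, geometry,
                       beta_assumed = beta_assumed, window = window,
                       gain = g, ...)
    ok <- fs$valid
    base <- mean(fs$bfi[baseline_idx][fs$valid[baseline_idx]], na.rm = TRUE)
    tibble::tibble(
      gain = g,
      bfi_baseline = base,
      bfi_max = if (any(ok)) max(fs$bfi[ok]) else NA_real_,
      rbfi_max = if (any(ok)) max(fs$bfi[ok]) / base else NA_real_,
      min_kappa_f_sq = min(fs$kappa_f_sq)
    )
  })
}
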