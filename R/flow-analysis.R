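# Cross-modality comparison layer: relative BFi, beat segmentation and
# waveform averaging, pulsatility index, nonparametric Bland-Altman and
# paired statistics.

#' Sampled BFi time series
#'
#' The common container produced by all three processing pipelines: a tibble
#' with `time` (s), `bfi` and `valid`, plus any modality-specific columns,
#' carrying the modality label and sampling rate as attributes.
#'
#' @param time Strictly increasing sample times (s).
#' @param bfi BFi values (cm^2/s, or relative after [relative_bfi()]).
#' @param modality Modality label (e.g. `"DCS"`).
#' @param rate Sampling rate (Hz).
#' @param valid Logical validity flags.
#' @param segment Optional segment labels.
#' @param extra Optional tibble of additional columns.
#' @return A tibble of class `flow_series`.
#' @export
flow_series <- function(time, bfi, modality = "unknown", rate = NA_real_,
                        valid = TRUE, segment = NULL, extra = NULL) {
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time = time, bfi = bfi,
                        valid = rep_len(valid, length(time)))
  if (!is.null(segment)) out$segment <- segment
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  class(out) <- c("flow_series", class(out))
  attr(out, "modality") <- modality
  attr(out, "rate") <- rate
  out
}

#' Normalize a flow series to its baseline mean
#'
#' Divides every sample by the mean valid BFi inside the baseline window, so
#' the baseline mean of the output is 1 (relative BFi).
#'
#' @param series A [flow_series()].
#' @param baseline Baseline window `c(t0, t1)` in seconds.
#' @return The series with `bfi` rescaled; attribute `baseline_mean` holds
#'   the divisor.
#' @export
relative_bfi <- function(series, baseline) {
  in_base <- series$time >= baseline[1] & series$time <= baseline[2] &
    series$valid & is.finite(series$bfi)
  if (!any(in_base)) {
    stop("baseline window contains no valid samples", call. = FALSE)
  }
  base_mean <- mean(series$bfi[in_base])
  series$bfi <- series$bfi / base_mean
  attr(series, "baseline_mean") <- base_mean
  series
}

#' Detect systolic peaks in a pulsatile flow series
#'
#' Estimates the cardiac frequency from the dominant periodogram peak in the
#' 0.5--3 Hz band, then finds local maxima separated by at least half a
#' cardiac period. The highest-rate modality (SCOS in the reference setup)
#' is used as the shared timing reference across modalities.
#'
#' @param series A [flow_series()] sampled at >= 4x the cardiac frequency.
#' @param band Cardiac frequency search band (Hz).
#' @return Numeric vector of systolic peak times (s).
#' @export
detect_beats <- function(series, band = c(0.5, 3)) {
  x <- series$bfi
  t <- series$time
  if (any(!is.finite(x))) {
    x <- stats::approx(t[is.finite(x)], x[is.finite(x)], xout = t,
                       rule = 2)$y
  }
  rate <- attr(series, "rate")
  if (!is.finite(rate)) rate <- 1 / stats::median(diff(t))
  if (stats::var(x) == 0) {
    stop("no cardiac-band spectral peak in a constant series", call. = FALSE)
  }
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = rate),
                          plot = FALSE, taper = 0, detrend = TRUE)
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(in_band)) stop("sampling too slow for the cardiac band",
                          call. = FALSE)
  pk <- max(sp$spec[in_band])
  if (pk < 3 * stats::median(sp$spec[in_band])) {
    stop("no dominant cardiac-band spectral peak", call. = FALSE)
  }
  f_card <- sp$freq[in_band][which.max(sp$spec[in_band])]
  if (rate < 4 * f_card) {
    stop("sampling rate below 4x the cardiac frequency", call. = FALSE)
  }
  min_sep <- 0.5 / f_card
  # quarter-period moving average so sample noise does not split or
  # displace maxima; peak times are then refined by a three-point parabola
  # on the smoothed series (sub-sample precision)
  w <- max(1L, round(rate / (4 * f_card)))
  xs <- x
  if (w > 1L) {
    sm <- stats::filter(x, rep(1 / w, w), sides = 2)
    xs <- ifelse(is.na(sm), x, as.numeric(sm))
  }
  is_max <- c(FALSE, diff(sign(diff(xs))) < 0, FALSE)
  cand <- which(is_max & xs > stats::median(xs))
  cand <- cand[order(xs[cand], decreasing = TRUE)]
  kept_idx <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept_idx]) >= min_sep)) {
      kept_idx <- c(kept_idx, i)
    }
  }
  kept_idx <- sort(kept_idx)
  s <- max(1L, round(w / 2))
  refine <- vapply(kept_idx, function(i) {
    if (i <= s || i + s > length(xs)) return(t[i])
    denom <- xs[i - s] - 2 * xs[i] + xs[i + s]
    if (denom >= 0) return(t[i])
    delta <- 0.5 * (xs[i - s] - xs[i + s]) / denom
    t[i] + max(min(delta, 1), -1) * s * (t[2L] - t[1L])
  }, numeric(1))
  refine
}

#' Beat-averaged pulsatile waveform
#'
#' Resamples each complete heartbeat onto a common phase grid, normalizes
#' each beat by its own mean (removing slow drifts such as respiration), and
#' summarizes across beats with the pointwise median and interquartile
#' range.
#'
#' @param series A [flow_series()].
#' @param peaks Systolic peak times from [detect_beats()].
#' @param n_phase Phase grid points per beat (default 64).
#' @param normalize Divide each beat by its mean (default TRUE).
#' @return A tibble of class `pulsatile_waveform` with `phase`, `value`
#'   (median), `q25`, `q75`; attribute `n_beats`.
#' @export
average_waveform <- function(series, peaks, n_phase = 64, normalize = TRUE) {
  if (length(peaks) < 4) {
    stop("need at least 3 complete beats", call. = FALSE)
  }
  phase <- (seq_len(n_phase) - 1) / n_phase
  beats <- purrr::map(seq_len(length(peaks) - 1), function(b) {
    t0 <- peaks[b]; t1 <- peaks[b + 1]
    sel <- series$time >= t0 - 1e-9 & series$time <= t1 + 1e-9 &
      is.finite(series$bfi)
    if (sum(sel) < 3) return(NULL)
    w <- stats::approx(series$time[sel], series$bfi[sel],
                       xout = t0 + phase * (t1 - t0), rule = 2)$y
    if (normalize) w <- w / mean(w)
    w
  })
  beats <- beats[!vapply(beats, is.null, logical(1))]
  if (length(beats) < 3) stop("need at least 3 complete beats", call. = FALSE)
  m <- do.call(rbind, beats)
  out <- tibble::tibble(
    phase = phase,
    value = apply(m, 2, stats::median),
    q25 = apply(m, 2, stats::quantile, 0.25),
    q75 = apply(m, 2, stats::quantile, 0.75)
  )
  class(out) <- c("pulsatile_waveform", class(out))
  attr(out, "n_beats") <- length(beats)
  attr(out, "beats") <- m
  out
}

#' Pulsatility index
#'
#' `PI = (max - min) / mean` of a waveform. Given a `pulsatile_waveform`,
#' returns the PI of the median waveform. Given a [flow_series()] plus
#' `peaks`, computes one PI per beat, removes outliers by the
#' median +/- 3 * scaled-MAD rule, and returns the mean of the kept beats
#' together with the per-beat values.
#'
#' @param x A `pulsatile_waveform` or [flow_series()].
#' @param peaks Systolic peak times (required for a series).
#' @param outlier_k MAD multiplier for per-beat outlier removal.
#' @return For a waveform, a scalar. For a series, a list with `pi`
#'   (mean over kept beats), `per_beat` and `kept`.
#' @export
pulsatility_index <- function(x, peaks = NULL, outlier_k = 3) {
  wf_pi <- function(w) {
    mu <- mean(w)
    if (!is.finite(mu) || mu <= 0) {
      stop("waveform mean must be positive", call. = FALSE)
    }
    (max(w) - min(w)) / mu
  }
  if (inherits(x, "pulsatile_waveform")) return(wf_pi(x$value))
  if (is.numeric(x)) return(wf_pi(x))
  if (is.null(peaks)) stop("`peaks` required for a flow series", call. = FALSE)
  if (length(peaks) < 4) stop("need at least 3 complete beats", call. = FALSE)
  per_beat <- vapply(seq_len(length(peaks) - 1), function(b) {
    sel <- x$time >= peaks[b] - 1e-9 & x$time <= peaks[b + 1] + 1e-9 &
      is.finite(x$bfi)
    if (sum(sel) < 3) return(NA_real_)
    wf_pi(x$bfi[sel])
  }, numeric(1))
  per_beat <- per_beat[is.finite(per_beat)]
  med <- stats::median(per_beat)
  s <- stats::mad(per_beat)
  kept <- if (s == 0) rep(TRUE, length(per_beat)) else
    abs(per_beat - med) <= outlier_k * s
  list(pi = mean(per_beat[kept]), per_beat = per_beat, kept = kept)
}

#' Block-average downsampling
#'
#' Non-overlapping block means (e.g. every six 120 Hz SCOS frames to reach
#' the 20 Hz DCS/iDWS rate); a trailing partial block is dropped.
#'
#' @param series A [flow_series()].
#' @param factor Block size (integer >= 1).
#' @return The downsampled [flow_series()].
#' @export
block_average_downsample <- function(series, factor = 6) {
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  n <- nrow(series) %/% factor
  if (n < 1) stop("series shorter than one block", call. = FALSE)
  idx <- rep(seq_len(n), each = factor)
  keep <- seq_len(n * factor)
  flow_series(
    time = as.numeric(tapply(series$time[keep], idx, mean)),
    bfi = as.numeric(tapply(series$bfi[keep], idx, mean)),
    modality = attr(series, "modality"),
    rate = attr(series, "rate") / factor,
    valid = as.logical(tapply(series$valid[keep], idx, all))
  )
}

#' Nonparametric Bland-Altman agreement analysis
#'
#' Differences are expressed as percent of the reference,
#' `d = 100 * (measured - reference) / reference`; the bias is the median
#' of `d`, the limits of agreement are its 2.5th and 97.5th percentiles,
#' and the reproducibility coefficient is half the inter-percentile range,
#' `RPC = (P97.5 - P2.5) / 2`. Pairs with a zero reference are dropped with
#' a count.
#'
#' @param measured Numeric vector of measurements.
#' @param reference Numeric vector of reference values (same length, >= 10
#'   pairs after dropping zero references).
#' @return An object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `rpc`, `n`, `n_dropped` and the per-pair `differences`.
#' @export
bland_altman_nonparametric <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("`measured` and `reference` must be paired", call. = FALSE)
  }
  ok <- is.finite(measured) & is.finite(reference) & reference != 0
  n_dropped <- sum(!ok)
  m <- measured[ok]; r <- reference[ok]
  if (length(m) < 10) stop("need at least 10 valid pairs", call. = FALSE)
  d <- 100 * (m - r) / r
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  structure(
    list(bias = stats::median(d), loa_low = q[1], loa_high = q[2],
         rpc = (q[2] - q[1]) / 2, n = length(d), n_dropped = n_dropped,
         differences = d),
    class = "bland_altman"
  )
}

#' Paired comparisons of a metric across modalities
#'
#' Runs a Friedman test for an overall modality effect on a paired
#' per-run metric, post hoc pairwise Wilcoxon signed-rank tests, and the
#' pairwise Pearson correlation and linear-fit table.
#'
#' @param data Long-format data frame with columns `run`, `modality`,
#'   `value`; runs missing a modality are excluded pairwise with a report.
#' @return An object of class `modality_comparison`: list with `friedman_p`,
#'   `pairwise` (tibble of Wilcoxon p-values), `correlation` (matrix),
#'   `fits` (tibble of slopes/intercepts) and `n_runs`.
#' @export
paired_group_tests <- function(data) {
  stopifnot(all(c("run", "modality", "value") %in% names(data)))
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(c("run", "modality", "value"))),
    names_from = "modality", values_from = "value")
  mods <- setdiff(names(wide), "run")
  complete <- stats::complete.cases(wide[mods])
  n_excluded <- sum(!complete)
  wide_c <- wide[complete, ]
  if (nrow(wide_c) < 3) {
    stop("need at least 3 complete paired runs", call. = FALSE)
  }
  mat <- as.matrix(wide_c[mods])
  fr <- stats::friedman.test(mat)
  pairs <- utils::combn(mods, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(p) {
    ok <- stats::complete.cases(wide[p])
    x <- wide[[p[1]]][ok]; y <- wide[[p[2]]][ok]
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    fit <- stats::lm(y ~ x)
    tibble::tibble(
      modality_a = p[1], modality_b = p[2], n = sum(ok),
      wilcoxon_p = wt$p.value,
      pearson_r = suppressWarnings(stats::cor(x, y)),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1])
    )
  })
  structure(
    list(friedman_p = fr$p.value, pairwise = pw,
         correlation = suppressWarnings(stats::cor(mat)),
         n_runs = nrow(wide_c), n_excluded = n_excluded),
    class = "modality_comparison"
  )
}
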