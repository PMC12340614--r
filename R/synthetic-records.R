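# Detector-level raw-record simulators: SPAD photon-count streams (DCS),
# heterodyne line-scan interferograms (iDWS) and exposure-integrated CMOS
# speckle frame stacks (SCOS). Statistics are imposed, not emergent: each
# simulator applies the detection physics (Poisson photodetection, heterodyne
# mixing, exposure integration, camera noise and quantization) to fields from
# [sample_correlated_field()].

#' Simulate SPAD photon-count streams for DCS
#'
#' One speckle per detector channel; photon counts per bin are Poisson with
#' rate proportional to the instantaneous speckle intensity,
#' `counts[k] ~ Poisson(mean_rate * dt * I(t_k) / <I>)`, independently per
#' channel given the field.
#'
#' @param field A `speckle_field`; each speckle row becomes one channel.
#' @param mean_rate Mean detected count rate per channel (counts/s).
#' @param seed Integer seed for the photodetection noise.
#' @return An object of class `photon_counts`: a list with `counts`
#'   (integer `n_channels x n_bins` matrix), `dt` and `n_channels`.
#' @export
simulate_dcs_counts <- function(field, mean_rate, seed = 1) {
  stopifnot(inherits(field, "speckle_field"))
  if (mean_rate <= 0) stop("`mean_rate` must be positive", call. = FALSE)
  dt <- field$dt
  if (mean_rate * dt > 1e3) {
    warning("mean_rate * dt exceeds 1e3 counts/bin; outside the SPAD regime",
            call. = FALSE)
  }
  i <- field_intensity(field)
  denom <- rowMeans(i)
  denom[denom == 0] <- 1  # dark channel: zero intensity, zero counts
  lam <- mean_rate * dt * i / denom
  counts <- with_seed(seed, {
    matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
  })
  structure(list(counts = counts, dt = dt, n_channels = nrow(counts)),
            class = "photon_counts")
}

#' Simulate a heterodyne line-scan interferogram for iDWS
#'
#' Pixels sample a spatially blurred speckle field mixed with a strong
#' constant reference beam. Per-pixel counts are
#' `Poisson(I_R + I_S |E|^2 + 2*sqrt(I_R*I_S)*Re E)` plus Gaussian read
#' noise, rounded and clipped to the camera bit depth. The fluctuation
#' autocorrelation is proportional to `Re g1`, and the spatial
#' autocorrelation of the fluctuation has the configured half width.
#'
#' @param field A `speckle_field` with one underlying speckle per pixel
#'   (white across pixels); the record blurs them to `spatial_hwhm`.
#' @param reference_level Mean reference intensity `<I_R>` (counts/bin).
#' @param sample_level Mean sample intensity `<I_S>` (counts/bin); must be
#'   well below `reference_level` (heterodyne regime).
#' @param spatial_hwhm Half-width at half maximum of the spatial
#'   autocorrelation of the fluctuation, in pixels.
#' @param read_sigma Gaussian read noise (counts).
#' @param bit_depth Camera bit depth; counts clip at `2^bit_depth - 1`.
#' @param seed Integer seed for detection noise.
#' @return An object of class `linescan_record`: list with `counts`
#'   (`n_pixels x n_time`), `dt`, `reference_level`, `sample_level`,
#'   `spatial_hwhm`.
#' @export
simulate_idws_record <- function(field, reference_level = 120,
                                 sample_level = 2, spatial_hwhm = 1.5,
                                 read_sigma = 1, bit_depth = 8, seed = 1) {
  stopifnot(inherits(field, "speckle_field"))
  if (reference_level < 10 * sample_level) {
    warning("reference_level below 10x sample intensity; heterodyne ",
            "approximation degraded", call. = FALSE)
  }
  # Blur the complex field across the pixel axis. The fluctuation spatial
  # autocorrelation equals the field correlation: a Gaussian blur of s.d.
  # sigma_b gives correlation HWHM = 2 * sigma_b * sqrt(ln 2).
  sigma_b <- spatial_hwhm / (2 * sqrt(log(2)))
  kern <- gaussian_kernel_peak1(sigma_b)
  e <- convolve_rows_reflect(Re(field$field), kern) +
    1i * convolve_rows_reflect(Im(field$field), kern)
  e <- e / sqrt(sum(kern^2))  # restore unit variance
  het <- 2 * sqrt(reference_level * sample_level) * Re(e)
  lam <- pmax(reference_level + sample_level * Re(e * Conj(e)) + het, 0)
  counts <- with_seed(seed, {
    x <- stats::rpois(length(lam), lam) +
      stats::rnorm(length(lam), sd = read_sigma)
    matrix(pmin(pmax(round(x), 0), 2^bit_depth - 1), nrow = nrow(lam))
  })
  structure(
    list(counts = counts, dt = field$dt, reference_level = reference_level,
         sample_level = sample_level, spatial_hwhm = spatial_hwhm),
    class = "linescan_record"
  )
}

# Gaussian blur s.d. (pixels) realizing a given speckle-to-pixel size ratio,
# defined as the FWHM (in pixels) of the intensity spatial autocovariance:
# blur sigma_b gives intensity correlation exp(-d^2 / (2 sigma_b^2)), so
# FWHM = 2 sqrt(2 ln 2) sigma_b.
.scos_blur_sigma <- function(speckle_pixel_ratio) {
  speckle_pixel_ratio / (2 * sqrt(2 * log(2)))
}

#' Effective coherence parameter of the synthetic SCOS speckle sampling
#'
#' Simulated SCOS pixels point-sample a Gaussian-blurred speckle field, so
#' intensities within a contrast window are spatially correlated and the
#' expected (unbiased) window variance is reduced by the mean pairwise
#' intensity correlation. The short-exposure squared contrast is therefore
#' `beta_eff = 1 - mean_{i != j} rho_I(d_ij)` with
#' `rho_I(d) = exp(-d^2 / (2 sigma_b^2))`. This plays the role the setup's
#' `beta_SCOS` plays for a physical camera and is a closed-form property of
#' the generator.
#'
#' @param speckle_pixel_ratio Speckle-to-pixel size ratio (FWHM of the
#'   intensity spatial autocovariance, in pixels).
#' @param window Contrast window side length (pixels).
#' @return Effective coherence parameter in `(0, 1]`.
#' @export
scos_effective_beta <- function(speckle_pixel_ratio, window = 7) {
  sigma_b <- .scos_blur_sigma(speckle_pixel_ratio)
  idx <- expand.grid(x = seq_len(window), y = seq_len(window))
  d2 <- outer(idx$x, idx$x, "-")^2 + outer(idx$y, idx$y, "-")^2
  rho <- exp(-d2 / (2 * sigma_b^2))
  n <- window^2
  1 - (sum(rho) - n) / (n * (n - 1))
}

# Circular 2-D Gaussian blur of an H x W x T complex array along the two
# spatial axes, variance-preserving. Circular wrap keeps the blurred field
# exactly stationary.
.blur_spatial_circular <- function(arr, sigma_b) {
  d <- dim(arr)
  h <- d[1]; w <- d[2]
  gh <- exp(-pmin(0:(h - 1), h - (0:(h - 1)))^2 / (2 * sigma_b^2))
  gw <- exp(-pmin(0:(w - 1), w - (0:(w - 1)))^2 / (2 * sigma_b^2))
  norm <- sqrt(sum(gh^2) * sum(gw^2))
  kf <- stats::fft(outer(gh, gw)) / norm
  for (t in seq_len(d[3])) {
    arr[, , t] <- stats::fft(stats::fft(arr[, , t]) * kf, inverse = TRUE) /
      (h * w)
  }
  arr
}

#' Simulate an exposure-integrated SCOS camera frame stack
#'
#' For each frame, a spatially blurred speckle field evolves over `substeps`
#' temporal sub-steps spanning the exposure; the per-pixel photoelectron
#' count is Poisson with mean `flux` times the normalized exposure-averaged
#' intensity, then scaled by the camera gain, perturbed by Gaussian read
#' noise, offset, rounded and clipped to the bit depth. Frames are generated
#' independently (the field decorrelates between frames).
#'
#' @param target_g1 Function of tau (or list of functions, one per frame)
#'   giving the field autocorrelation during each exposure.
#' @param t_exp Exposure time (s).
#' @param substeps Temporal sub-steps per exposure; should be at least 10
#'   per field decorrelation time (see [decorrelation_time()]).
#' @param dims Frame size `c(H, W)` in pixels.
#' @param n_frames Number of frames.
#' @param flux Mean photoelectrons per pixel per exposure (0 gives dark
#'   frames).
#' @param speckle_pixel_ratio Speckle-to-pixel size ratio (see
#'   [scos_effective_beta()]).
#' @param gain Camera gain (counts per photoelectron).
#' @param read_sigma Gaussian read noise (counts).
#' @param dark_offset Dark count offset (counts).
#' @param frame_rate Frame rate (Hz), stored as metadata.
#' @param bit_depth Camera bit depth; counts clip at `2^bit_depth - 1`.
#' @param speckle If `FALSE`, the illumination is spatially uniform
#'   (speckle-free), leaving only the camera noise sources; used for
#'   noise-model null checks.
#' @param seed Integer seed.
#' @return An object of class `frame_stack`: list with `frames` (integer
#'   `H x W x n_frames` array) and the acquisition parameters.
#' @export
simulate_scos_frames <- function(target_g1, t_exp, substeps = 32,
                                 dims = c(128, 128), n_frames = 1,
                                 flux = 100, speckle_pixel_ratio = 2.3,
                                 gain = 9.64, read_sigma = 2,
                                 dark_offset = 100, frame_rate = 120,
                                 bit_depth = 16, speckle = TRUE, seed = 1) {
  if (t_exp <= 0) stop("`t_exp` must be positive", call. = FALSE)
  if (substeps < 2) stop("`substeps` must be >= 2", call. = FALSE)
  h <- dims[1]; w <- dims[2]
  npix <- h * w
  dt_sub <- t_exp / substeps
  g1_list <- if (is.list(target_g1)) target_g1 else
    replicate(n_frames, target_g1, simplify = FALSE)
  if (length(g1_list) != n_frames) {
    stop("`target_g1` list must have one entry per frame", call. = FALSE)
  }
  sigma_b <- .scos_blur_sigma(speckle_pixel_ratio)
  clip_max <- 2^bit_depth - 1
  frames <- array(0L, dim = c(h, w, n_frames))
  n_sat <- 0
  for (f in seq_len(n_frames)) {
    if (flux > 0 && !speckle) {
      lam <- matrix(flux, h, w)
    } else if (flux > 0) {
      fld <- sample_correlated_field(g1_list[[f]], n_time = substeps,
                                     dt = dt_sub, n_speckles = npix,
                                     seed = seed + 7919L * f)
      e <- array(fld$field, dim = c(h, w, substeps))
      e <- .blur_spatial_circular(e, sigma_b)
      ibar <- apply(Re(e * Conj(e)), c(1, 2), mean)
      lam <- flux * ibar
    } else {
      lam <- matrix(0, h, w)
    }
    counts <- with_seed(seed + 7919L * f + 1L, {
      x <- gain * stats::rpois(npix, lam) +
        stats::rnorm(npix, sd = read_sigma) + dark_offset
      pmin(pmax(round(x), 0), clip_max)
    })
    n_sat <- n_sat + sum(counts >= clip_max)
    frames[, , f] <- as.integer(counts)
  }
  if (n_sat / (npix * n_frames) > 0.01) {
    warning(sprintf("%.1f%% of pixels saturated",
                    100 * n_sat / (npix * n_frames)), call. = FALSE)
  }
  structure(
    list(frames = frames, t_exp = t_exp, frame_rate = frame_rate,
         gain = gain, read_sigma = read_sigma, dark_offset = dark_offset,
         speckle_pixel_ratio = speckle_pixel_ratio, substeps = substeps,
         flux = flux, bit_depth = bit_depth, seed = seed),
    class = "frame_stack"
  )
}

#' @rdname simulate_scos_frames
#' @param ... Passed to [simulate_scos_frames()].
#' @export
simulate_scos_dark <- function(dims = c(128, 128), n_frames = 20, gain = 9.64,
                               read_sigma = 2, dark_offset = 100, seed = 1,
                               ...) {
  simulate_scos_frames(target_g1 = function(tau) exp(-tau), t_exp = 1e-3,
                       dims = dims, n_frames = n_frames, flux = 0,
                       gain = gain, read_sigma = read_sigma,
                       dark_offset = dark_offset, seed = seed, ...)
}
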