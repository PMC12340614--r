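# Ground-truth flow programs: the arm cuff-occlusion protocol (baseline /
# arterial occlusion / hyperemic recovery with cardiac pulsatility) and the
# temperature-ramped Brownian microsphere phantom.

# Mean-1 cardiac waveform: harmonic series scaled so the pulsatility index
# (peak-to-peak over mean) equals `pi_target` exactly by construction.
.cardiac_waveform <- function(phase, pi_target, harmonics = c(1, 0.3, 0.15)) {
  shape <- function(ph) {
    s <- 0
    for (k in seq_along(harmonics)) {
      s <- s + harmonics[k] * sin(2 * pi * k * ph)
    }
    s
  }
  fine <- shape((0:4095) / 4096)
  amp <- pi_target / (max(fine) - min(fine))
  1 + amp * shape(phase)
}

#' Ground-truth flow program
#'
#' Builds the true blood-flow-index time course driving the detector
#' simulators.
#'
#' For `protocol = "cuff"`: a baseline period with cardiac pulsatility, an
#' arterial occlusion during which flow decays exponentially to a floor
#' (cardiac modulation suppressed), and a recovery period with a hyperemic
#' overshoot returning to baseline. The baseline-segment pulsatility index
#' equals `pi` by construction of the harmonic cardiac waveform.
#'
#' For `protocol = "phantom_ramp"`: a linear water-temperature ramp; the
#' ground-truth `BFi(t)` is the Stokes-Einstein Brownian diffusion
#' coefficient at the instantaneous temperature.
#'
#' @param protocol `"cuff"` or `"phantom_ramp"`.
#' @param rate Sampling rate of the program grid (Hz).
#' @param baseline_bfi Baseline blood flow index (cm^2/s), cuff protocol.
#' @param occlusion_floor BFi floor during occlusion (cm^2/s).
#' @param hyperemia_peak_rbfi Peak relative BFi during reactive hyperemia
#'   (ratio to baseline, > 1).
#' @param cardiac_freq Cardiac frequency (Hz).
#' @param pi Pulsatility index of the baseline waveform.
#' @param harmonics Relative amplitudes of the cardiac harmonics
#'   (fundamental plus overtones); a single value gives a pure sinusoid.
#' @param respiration_depth Fractional amplitude of an optional 0.25 Hz
#'   respiration modulation (0 disables it).
#' @param durations Segment durations in seconds,
#'   `c(baseline, occlusion, recovery)`.
#' @param temp_range Temperature ramp endpoints in degrees C (phantom).
#' @param ramp_duration Ramp duration in seconds (phantom).
#' @param radius Microsphere radius in meters (phantom).
#' @return A tibble of class `flow_program` with columns `time`, `bfi`,
#'   `segment` (and `temperature` for the phantom ramp); attributes carry
#'   the configured rate, cardiac frequency and pulsatility index.
#' @export
make_flow_program <- function(protocol = c("cuff", "phantom_ramp"),
                              rate = 120,
                              baseline_bfi = 1e-8,
                              occlusion_floor = 1e-9,
                              hyperemia_peak_rbfi = 3,
                              cardiac_freq = 1,
                              pi = 0.4,
                              harmonics = c(1, 0.3, 0.15),
                              respiration_depth = 0,
                              durations = c(60, 120, 120),
                              temp_range = c(7, 22),
                              ramp_duration = 600,
                              radius = 97.5e-9) {
  protocol <- match.arg(protocol)
  if (protocol == "phantom_ramp") {
    time <- seq(0, ramp_duration, by = 1 / rate)
    temp_c <- temp_range[1] + (temp_range[2] - temp_range[1]) *
      time / ramp_duration
    out <- tibble::tibble(
      time = time,
      bfi = stokes_einstein_db(temp_c, radius, unit = "C"),
      segment = "ramp",
      temperature = temp_c
    )
  } else {
    if (baseline_bfi <= 0 || occlusion_floor <= 0) {
      stop("flow levels must be positive", call. = FALSE)
    }
    if (hyperemia_peak_rbfi <= 1) {
      stop("hyperemia peak must exceed baseline", call. = FALSE)
    }
    t_end <- cumsum(durations)
    time <- seq(0, t_end[3], by = 1 / rate)
    segment <- cut(time, c(-Inf, t_end[1], t_end[2], Inf),
                   labels = c("baseline", "occlusion", "recovery"))
    segment <- as.character(segment)
    card <- .cardiac_waveform(cardiac_freq * time, pi, harmonics)
    if (respiration_depth > 0) {
      card <- card * (1 + respiration_depth * sin(2 * base::pi * 0.25 * time))
    }
    base_lvl <- rep(baseline_bfi, length(time))
    occ <- segment == "occlusion"
    rec <- segment == "recovery"
    base_lvl[occ] <- occlusion_floor + (baseline_bfi - occlusion_floor) *
      exp(-(time[occ] - t_end[1]) / 5)
    f0 <- occlusion_floor / baseline_bfi
    dt_rec <- time[rec] - t_end[2]
    base_lvl[rec] <- baseline_bfi *
      (f0 + (1 - f0 + (hyperemia_peak_rbfi - 1) * exp(-dt_rec / 15)) *
         (1 - exp(-dt_rec / 2)))
    bfi <- base_lvl
    bfi[!occ] <- bfi[!occ] * card[!occ]
    out <- tibble::tibble(time = time, bfi = bfi, segment = segment)
  }
  class(out) <- c("flow_program", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "rate") <- rate
  attr(out, "cardiac_freq") <- if (protocol == "cuff") cardiac_freq else NA
  attr(out, "pi") <- if (protocol == "cuff") pi else NA
  out
}
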