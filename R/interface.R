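# Scenario configuration and the end-to-end runner tying simulation, the
# three pipelines, and the comparison analyses together, plus plain-text
# serialization (CSV with JSON sidecars).

#' Scenario configuration
#'
#' Validated configuration for [run_scenario()]. Every stochastic stage
#' receives its own seed, derived from the master seed by a fixed splitting
#' rule (`stage_seed = (seed * 7919 + stage_index) mod (2^31 - 1)`).
#'
#' @param scenario `"phantom_ramp"` or `"cuff"`.
#' @param seed Master integer seed (required).
#' @param medium An [optical_medium()]; defaults to the phantom properties
#'   (`mua = 0.104`, `musp = 6.30` 1/cm) for the phantom scenario and the
#'   assumed in-vivo properties (`0.1`, `6`) for the cuff scenario.
#' @param rho Source-detector separation (cm).
#' @param n_temps Temperature points for the phantom ramp.
#' @param temp_range Ramp endpoints (degrees C).
#' @param radius Microsphere radius (m).
#' @param baseline_bfi,hyperemia_peak_rbfi,cardiac_freq,pi Cuff-protocol
#'   parameters (see [make_flow_program()]).
#' @param durations Cuff segment durations (s); the bundled quick scenario
#'   uses a shortened protocol.
#' @param dcs,idws,scos Named lists of per-modality detector parameters;
#'   missing entries take scaled-down defaults.
#' @return An object of class `run_config`.
#' @export
scenario_config <- function(scenario = c("phantom_ramp", "cuff"),
                            seed = NULL,
                            medium = NULL, rho = 2.5,
                            n_temps = 10, temp_range = c(7, 22),
                            radius = 97.5e-9,
                            baseline_bfi = 1e-8, hyperemia_peak_rbfi = 3,
                            cardiac_freq = 1, pi = 0.4,
                            durations = c(8, 8, 10),
                            dcs = list(), idws = list(), scos = list()) {
  scenario <- match.arg(scenario)
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("configuration requires a single integer `seed`", call. = FALSE)
  }
  if (is.null(medium)) {
    medium <- if (scenario == "phantom_ramp") {
      optical_medium(0.104, 6.30)
    } else {
      optical_medium(0.1, 6.0)
    }
  }
  dcs <- utils::modifyList(list(n_bins = 6e4), dcs)
  idws <- utils::modifyList(list(n_pixels = 32, duration = 0.25), idws)
  scos <- utils::modifyList(
    list(dims = c(64, 64), t_exp = 2e-4, n_frames = 2, n_dark = 12), scos)
  structure(
    list(scenario = scenario, seed = as.integer(seed), medium = medium,
         rho = rho, n_temps = n_temps, temp_range = temp_range,
         radius = radius, baseline_bfi = baseline_bfi,
         hyperemia_peak_rbfi = hyperemia_peak_rbfi,
         cardiac_freq = cardiac_freq, pi = pi, durations = durations,
         dcs = dcs, idws = idws, scos = scos),
    class = "run_config"
  )
}

#' Deterministic per-stage seed splitting
#'
#' Derives the seed for one stochastic stage from a master seed:
#' `(seed * 7919 + stage_index) mod (2^31 - 1)`.
#'
#' @param seed Master integer seed.
#' @param stage_index Integer stage index.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index) %% (2^31 - 1))
}

#' Simulate and process one acquisition with all three modalities
#'
#' Generates detector-level raw records at a fixed true flow level for DCS,
#' iDWS and SCOS, runs each through its processing pipeline, and returns the
#' recovered BFi per modality. Record sizes default to the package's
#' scaled-down desk sizes (4 DCS channels with 1e5 bins, 64 iDWS pixels over
#' 0.5 s at 3 us sampling, 128 x 128 SCOS frames at 1 ms exposure). The
#' shared theoretical `g1` drives every simulator, so this is the
#' parameter-recovery harness for the whole package.
#'
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param bfi True blood flow index (cm^2/s).
#' @param seed Integer seed; stage seeds are split deterministically.
#' @param dcs,idws,scos Named lists overriding per-modality parameters:
#'   DCS `n_channels`, `n_bins`, `mean_rate`, `oversample` (bins per
#'   decorrelation time); iDWS `n_pixels`, `duration`, `dt`,
#'   `reference_level`, `sample_level`, `reference_duration`, `n_lags`;
#'   SCOS `dims`, `t_exp`, `n_frames`, `n_dark`, `flux`, `gain`,
#'   `read_sigma`, `dark_offset`, `speckle_pixel_ratio`.
#' @return Named numeric vector with the median recovered BFi for `DCS`,
#'   `iDWS` and `SCOS` (SCOS on its assumed-coherence absolute scale).
#' @export
acquire_all_modalities <- function(medium, geometry, bfi, seed,
                                   dcs = list(), idws = list(),
                                   scos = list()) {
  dcs <- utils::modifyList(
    list(n_channels = 4, n_bins = 1e5, mean_rate = 1e6, oversample = 25,
         duration = NULL, beta = NULL), dcs)
  idws <- utils::modifyList(
    list(n_pixels = 64, duration = 0.5, dt = 3e-6, reference_level = 120,
         sample_level = 2, reference_duration = 0.2, n_lags = 4000,
         reference = NULL), idws)
  scos <- utils::modifyList(
    list(dims = c(128, 128), t_exp = 1e-3, n_frames = 3, n_dark = 10,
         flux = 100, gain = 9.64, read_sigma = 2, dark_offset = 100,
         speckle_pixel_ratio = 2.3), scos)
  flow <- flow_params(bfi = bfi)
  g1f <- function(tau) .g1_values(medium, geometry, bfi, tau)
  tc <- decorrelation_time(medium, geometry, flow)

  # DCS: 4 channels, one speckle each; `duration` (s) overrides `n_bins`
  # so acquisitions stay equally long when the bin width tracks tau_c
  dt_dcs <- max(tc / dcs$oversample, 5e-7)
  if (!is.null(dcs$duration)) dcs$n_bins <- ceiling(dcs$duration / dt_dcs)
  fld <- sample_correlated_field(g1f, n_time = dcs$n_bins, dt = dt_dcs,
                                 n_speckles = dcs$n_channels,
                                 seed = stage_seed(seed, 1))
  counts <- simulate_dcs_counts(fld, mean_rate = dcs$mean_rate,
                                seed = stage_seed(seed, 2))
  # beta is calibrated from this record unless a session value is supplied
  dcs_fs <- process_dcs(counts, medium, geometry, beta = dcs$beta)
  dcs_bfi <- stats::median(dcs_fs$bfi[dcs_fs$valid])

  # iDWS: line camera record plus a shorter sample-blocked reference run
  n_t <- ceiling(idws$duration / idws$dt)
  fld_i <- sample_correlated_field(g1f, n_time = n_t, dt = idws$dt,
                                   n_speckles = idws$n_pixels,
                                   seed = stage_seed(seed, 3))
  rec <- simulate_idws_record(fld_i,
                              reference_level = idws$reference_level,
                              sample_level = idws$sample_level,
                              seed = stage_seed(seed, 4))
  # sample-blocked reference: one per session (reusable across trials via
  # `idws$reference`, a precomputed pixel-summed curve)
  ref <- idws$reference
  if (is.null(ref)) {
    n_ref <- ceiling(idws$reference_duration / idws$dt)
    fld_0 <- sample_correlated_field(g1f, n_time = n_ref, dt = idws$dt,
                                     n_speckles = idws$n_pixels,
                                     seed = stage_seed(seed, 5))
    fld_0$field[] <- 0
    ref <- simulate_idws_record(fld_0,
                                reference_level = idws$reference_level,
                                sample_level = 0,
                                seed = stage_seed(seed, 6))
  }
  idws_fs <- process_idws(rec, ref, medium, geometry, n_lags = idws$n_lags)
  idws_bfi <- stats::median(idws_fs$bfi[idws_fs$valid])

  # SCOS: exposure-integrated frames plus dark stack; the spatial-pattern
  # correction needs many decorrelated frames, so it is off for short stacks
  substeps <- max(64, ceiling(10 * scos$t_exp / tc))
  stack <- simulate_scos_frames(
    g1f, t_exp = scos$t_exp, substeps = substeps, dims = scos$dims,
    n_frames = scos$n_frames, flux = scos$flux,
    speckle_pixel_ratio = scos$speckle_pixel_ratio,
    gain = scos$gain, read_sigma = scos$read_sigma,
    dark_offset = scos$dark_offset, seed = stage_seed(seed, 7))
  dark <- simulate_scos_dark(dims = scos$dims, n_frames = scos$n_dark,
                             gain = scos$gain, read_sigma = scos$read_sigma,
                             dark_offset = scos$dark_offset,
                             seed = stage_seed(seed, 8))
  scos_fs <- process_scos(stack, dark, medium, geometry,
                          beta_assumed =
                            scos_effective_beta(scos$speckle_pixel_ratio),
                          spatial_correction = FALSE)
  scos_bfi <- stats::median(scos_fs$bfi[scos_fs$valid])

  c(DCS = dcs_bfi, iDWS = idws_bfi, SCOS = scos_bfi)
}

#' Run a full simulation-plus-analysis scenario
#'
#' For `"phantom_ramp"`: simulates all three modalities at each temperature
#' of a 7--22 C ramp of a Brownian microsphere phantom, recovers the
#' diffusion coefficient per modality (SCOS rescaled to theory at the
#' warmest point, as its absolute scale is not identifiable), and compares
#' against the Stokes-Einstein ground truth by linear regression and
#' nonparametric Bland-Altman.
#'
#' For `"cuff"`: simulates a shortened cuff-occlusion protocol, recovers a
#' relative-BFi time course per modality and the hyperemic peak, and reports
#' the pulsatility of the baseline segment.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional output directory; per-modality CSV time series
#'   and a JSON summary are written when given.
#' @return A list with `recovered` (tibble), `comparison` (tibble of
#'   per-modality slope, correlation and agreement statistics for the
#'   phantom; rBFi summaries for the cuff), and `config`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  geometry <- semi_infinite_geometry(config$rho, config$medium)
  if (config$scenario == "phantom_ramp") {
    temps <- seq(config$temp_range[1], config$temp_range[2],
                 length.out = config$n_temps)
    db_theo <- stokes_einstein_db(temps, config$radius, unit = "C")
    rec <- purrr::map_dfr(seq_along(temps), function(i) {
      r <- acquire_all_modalities(config$medium, geometry, db_theo[i],
                                  seed = stage_seed(config$seed, 100 + i),
                                  dcs = config$dcs, idws = config$idws,
                                  scos = config$scos)
      tibble::tibble(temperature = temps[i], db_theo = db_theo[i],
                     modality = names(r), db_recovered = unname(r))
    })
    # SCOS absolute scale: normalize to theory at the warmest temperature
    sc <- rec$modality == "SCOS"
    ref_row <- sc & rec$temperature == max(rec$temperature)
    rec$db_recovered[sc] <- rec$db_recovered[sc] *
      rec$db_theo[ref_row] / rec$db_recovered[ref_row]
    comparison <- rec |>
      dplyr::group_by(.data$modality) |>
      dplyr::summarise(
        slope = {
          y <- .data$db_recovered
          x <- .data$db_theo
          unname(stats::coef(stats::lm(y ~ x))[2])
        },
        r = stats::cor(.data$db_recovered, .data$db_theo),
        bias = if (dplyr::n() >= 10) {
          bland_altman_nonparametric(.data$db_recovered, .data$db_theo)$bias
        } else NA_real_,
        rpc = if (dplyr::n() >= 10) {
          bland_altman_nonparametric(.data$db_recovered, .data$db_theo)$rpc
        } else NA_real_,
        .groups = "drop"
      )
    out <- list(recovered = rec, comparison = comparison, config = config)
  } else {
    out <- .run_cuff_scenario(config, geometry)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$recovered,
                     file.path(out_dir, "recovered.csv"), row.names = FALSE)
    utils::write.csv(out$comparison,
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(scenario = config$scenario, seed = config$seed,
           comparison = out$comparison),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

# Shortened cuff protocol: acquisitions at a grid of time points, relative
# BFi per modality, hyperemic peak and baseline pulsatility summary.
.run_cuff_scenario <- function(config, geometry) {
  prog <- make_flow_program(
    "cuff", rate = 40, baseline_bfi = config$baseline_bfi,
    hyperemia_peak_rbfi = config$hyperemia_peak_rbfi,
    cardiac_freq = config$cardiac_freq, pi = config$pi,
    durations = config$durations)
  t_end <- sum(config$durations)
  t_grid <- seq(0.25, t_end - 0.25, by = 0.5)
  true_bfi <- stats::approx(prog$time, prog$bfi, xout = t_grid)$y
  rec <- purrr::map_dfr(seq_along(t_grid), function(i) {
    r <- acquire_all_modalities(config$medium, geometry, true_bfi[i],
                                seed = stage_seed(config$seed, 500 + i),
                                dcs = config$dcs, idws = config$idws,
                                scos = config$scos)
    tibble::tibble(time = t_grid[i], true_bfi = true_bfi[i],
                   modality = names(r), bfi = unname(r))
  })
  base_end <- config$durations[1]
  comparison <- rec |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      baseline_bfi = mean(.data$bfi[.data$time <= base_end]),
      rbfi_max = max(.data$bfi) /
        mean(.data$bfi[.data$time <= base_end]),
      r_vs_truth = stats::cor(.data$bfi, .data$true_bfi),
      .groups = "drop"
    )
  list(recovered = rec, comparison = comparison, config = config,
       program = prog)
}

#' Write and read a scenario configuration as JSON
#'
#' Configurations round-trip losslessly: the optical medium is stored by
#' its defining fields and rebuilt through [optical_medium()] on read.
#'
#' @param config A [scenario_config()].
#' @param path JSON path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- unclass(config)
  payload$medium <- payload$medium[c("mua", "musp", "n_in", "n_out",
                                     "wavelength")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has one number type; restore R's double storage throughout
  p <- rapply(p, function(x) if (is.integer(x)) as.numeric(x) else x,
              how = "replace")
  med <- do.call(optical_medium, p$medium)
  scenario_config(
    scenario = p$scenario, seed = p$seed, medium = med, rho = p$rho,
    n_temps = p$n_temps, temp_range = p$temp_range, radius = p$radius,
    baseline_bfi = p$baseline_bfi,
    hyperemia_peak_rbfi = p$hyperemia_peak_rbfi,
    cardiac_freq = p$cardiac_freq, pi = p$pi, durations = p$durations,
    dcs = as.list(p$dcs), idws = as.list(p$idws), scos = as.list(p$scos))
}

#' Write and read a correlation curve as CSV with a JSON sidecar
#'
#' Curves serialize to a two-column CSV (`tau_s`, `value`); the kind and
#' coherence parameter go to `<path>.json`.
#'
#' @param curve A [correlation_curve()].
#' @param path CSV path.
#' @return `write_correlation_curve()` returns `path` invisibly;
#'   `read_correlation_curve()` returns the curve.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  utils::write.csv(data.frame(tau_s = curve$tau, value = curve$value),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(kind = curve_kind(curve), beta = curve_beta(curve)),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_correlation_curve
#' @export
read_correlation_curve <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  correlation_curve(d$tau_s, d$value, kind = meta$kind,
                    beta = meta$beta %||% NULL)
}

#' Write and read a flow series as CSV
#'
#' Columns `time_s`, `bfi_cm2s`, `valid` plus any extra columns; modality
#' and rate go to a JSON sidecar.
#'
#' @param series A [flow_series()].
#' @param path CSV path.
#' @return `write_flow_series()` returns `path` invisibly;
#'   `read_flow_series()` returns the series.
#' @export
write_flow_series <- function(series, path) {
  stopifnot(inherits(series, "flow_series"))
  d <- as.data.frame(series)
  names(d)[names(d) == "time"] <- "time_s"
  names(d)[names(d) == "bfi"] <- "bfi_cm2s"
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(
    list(modality = attr(series, "modality"), rate = attr(series, "rate")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correlation_curve
#' @export
read_flow_series <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  extra_cols <- setdiff(names(d), c("time_s", "bfi_cm2s", "valid"))
  flow_series(d$time_s, d$bfi_cm2s, modality = meta$modality,
              rate = meta$rate, valid = as.logical(d$valid),
              extra = if (length(extra_cols)) d[extra_cols] else NULL)
}
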