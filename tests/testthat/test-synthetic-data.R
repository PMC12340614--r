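# Detector-level synthetic data: correlated field synthesis, photon counts,
# interferograms, frame stacks, and ground-truth flow programs.

test_that("synthesized field follows its target autocorrelation", {
  dt <- 1e-5
  tau_c <- 10 * dt
  fld <- sample_correlated_field(function(t) exp(-t / tau_c),
                                 n_time = 2e5, dt = dt, n_speckles = 1,
                                 seed = 42)
  emp <- empirical_field_g1(fld, c(0, 10, 20))
  expect_equal(emp$g1[2], exp(-1), tolerance = 0.02)
  i <- field_intensity(fld)
  # fully developed speckle: second intensity moment is 2
  expect_equal(mean(i^2) / mean(i)^2, 2, tolerance = 0.05)
  # zero-mean circular field (effective sample count reflects the
  # decorrelation time: ~n_time * dt / (2 tau_c) independent samples)
  n_eff <- 2e5 / (2 * 10)
  expect_lt(Mod(mean(fld$field)) / sqrt(mean(Mod(fld$field)^2)),
            3 / sqrt(n_eff))
})

test_that("field generation is deterministic and seeds are independent", {
  g1f <- function(t) exp(-t / 1e-4)
  a <- sample_correlated_field(g1f, 5000, 1e-5, n_speckles = 2, seed = 9)
  b <- sample_correlated_field(g1f, 5000, 1e-5, n_speckles = 2, seed = 9)
  expect_identical(a$field, b$field)
  c2 <- sample_correlated_field(g1f, 5000, 1e-5, n_speckles = 2, seed = 10)
  ia <- field_intensity(a)[1, ]; ic <- field_intensity(c2)[1, ]
  expect_lt(abs(stats::cor(ia, ic)), 0.05)
})

test_that("unrealizable correlation targets are rejected", {
  # a constant negative plateau is not a valid covariance sequence
  bad <- function(t) ifelse(t == 0, 1, -0.9)
  expect_error(
    sample_correlated_field(bad, 256, 1e-5, seed = 1),
    "not realizable")
})

test_that("photon counts follow the Poisson detection model", {
  g1f <- function(t) exp(-t / 1e-3)
  fld <- sample_correlated_field(g1f, 2e4, 1e-5, n_speckles = 1, seed = 3)
  # constant field: homogeneous Poisson, unit index of dispersion
  fld$field[] <- 1 + 0i
  counts <- simulate_dcs_counts(fld, mean_rate = 5e5, seed = 4)
  disp <- stats::var(as.numeric(counts$counts)) / mean(counts$counts)
  expect_equal(disp, 1, tolerance = 0.05)
  # zero intensity gives zero counts
  fld$field[] <- 0
  expect_true(all(simulate_dcs_counts(fld, 1e6, seed = 5)$counts == 0))
  # SPAD-regime guard
  fld$field[] <- 1 + 0i
  expect_warning(simulate_dcs_counts(fld, mean_rate = 2e8, seed = 6),
                 "SPAD")
})

test_that("simulated counts reproduce the Siegert intensity correlation", {
  med <- vivo_medium(); geo <- std_geometry(med)
  flow <- flow_params(bfi = 1e-8)
  g1f <- function(t) {
    g1_semi_infinite(med, geo, flow, t)$value
  }
  fld <- sample_correlated_field(g1f, 2e5, 2e-6, n_speckles = 4, seed = 11)
  counts <- simulate_dcs_counts(fld, mean_rate = 2e6, seed = 12)
  avg <- average_channels(software_autocorrelator(counts))
  g2m <- mean_curve(avg$curve[avg$valid])
  pred <- 1 + g1f(g2m$tau)^2  # single speckle per channel: beta = 1
  expect_lt(sqrt(mean((g2m$value - pred)^2)), 0.02)
})

test_that("interferogram has heterodyne statistics and spatial width", {
  g1f <- function(t) exp(-t / 5e-4)
  fld <- sample_correlated_field(g1f, 7e4, 3e-6, n_speckles = 64, seed = 21)
  rec <- simulate_idws_record(fld, seed = 22)
  # per-pixel temporal mean sits at the reference level (+ sample intensity)
  expect_equal(mean(rec$counts), rec$reference_level + rec$sample_level,
               tolerance = 0.02)
  # spatial autocorrelation half width of the fluctuation ~ 1.5 px
  fl <- rolling_mean_subtract(rec)
  d <- fl$delta[, fl$valid_time]
  ac <- vapply(0:6, function(k) {
    if (k == 0) return(1)
    p <- nrow(d)
    mean(d[seq_len(p - k), ] * d[seq_len(p - k) + k, ]) / mean(d^2)
  }, numeric(1))
  hwhm <- stats::approx(ac, 0:6, xout = 0.5)$y
  expect_equal(hwhm, 1.5, tolerance = 0.3)
  # zero sample field: reference plus noise only, no temporal correlation
  fld0 <- fld; fld0$field[] <- 0
  rec0 <- simulate_idws_record(fld0, sample_level = 0, seed = 23)
  fl0 <- rolling_mean_subtract(rec0)
  d0 <- fl0$delta[1, fl0$valid_time]
  n <- length(d0)
  lag_corr <- mean(d0[-n] * d0[-1]) / mean(d0^2)
  expect_lt(abs(lag_corr), 0.05)
  expect_warning(simulate_idws_record(fld, reference_level = 10,
                                      sample_level = 2, seed = 24),
                 "heterodyne")
})

test_that("frame stacks scale linearly and freeze for static speckle", {
  g1f <- function(t) rep(1, length(t))  # frozen speckle
  s1 <- simulate_scos_frames(g1f, t_exp = 1e-3, substeps = 8,
                             dims = c(32, 32), flux = 50, read_sigma = 0,
                             seed = 31)
  s2 <- simulate_scos_frames(g1f, t_exp = 1e-3, substeps = 8,
                             dims = c(32, 32), flux = 100, read_sigma = 0,
                             seed = 31)
  m1 <- mean(s1$frames) - s1$dark_offset
  m2 <- mean(s2$frames) - s2$dark_offset
  expect_equal(m2 / m1, 2, tolerance = 0.02)
  # static speckle, no camera noise: contrast independent of exposure time
  mk <- function(t_exp) {
    st <- simulate_scos_frames(g1f, t_exp = t_exp, substeps = 8,
                               dims = c(70, 70), flux = 1e4, gain = 1e-4,
                               read_sigma = 0, dark_offset = 0, seed = 33)
    f <- st$frames[, , 1]
    stats::sd(f)^2 / mean(f)^2
  }
  expect_equal(mk(1e-3), mk(4e-3), tolerance = 0.02)
  expect_true(all(s1$frames >= 0))
})

test_that("flow programs encode the protocol ground truth", {
  # pure sinusoid: baseline PI exact by construction
  prog <- make_flow_program("cuff", rate = 120, pi = 0.4, harmonics = 1)
  base <- prog[prog$segment == "baseline", ]
  expect_equal((max(base$bfi) - min(base$bfi)) / mean(base$bfi), 0.4,
               tolerance = 1e-10)
  expect_lt(mean(prog$bfi[prog$segment == "occlusion"]), mean(base$bfi))
  expect_error(make_flow_program("cuff", hyperemia_peak_rbfi = 0.9),
               "hyperemia")
  # phantom ramp endpoints equal the Stokes-Einstein values
  ramp <- make_flow_program("phantom_ramp", rate = 1, ramp_duration = 100)
  expect_equal(ramp$bfi[1], stokes_einstein_db(7, 97.5e-9, unit = "C"))
  expect_equal(ramp$bfi[nrow(ramp)],
               stokes_einstein_db(22, 97.5e-9, unit = "C"))
})

test_that("record generators are bit-reproducible under a fixed seed", {
  g1f <- function(t) exp(-t / 1e-4)
  fld <- sample_correlated_field(g1f, 2000, 1e-5, n_speckles = 4, seed = 1)
  expect_identical(simulate_dcs_counts(fld, 1e6, seed = 2)$counts,
                   simulate_dcs_counts(fld, 1e6, seed = 2)$counts)
  expect_identical(simulate_idws_record(fld, seed = 3)$counts,
                   simulate_idws_record(fld, seed = 3)$counts)
  expect_identical(
    simulate_scos_frames(g1f, 1e-3, substeps = 8, dims = c(16, 16),
                         seed = 4)$frames,
    simulate_scos_frames(g1f, 1e-3, substeps = 8, dims = c(16, 16),
                         seed = 4)$frames)
})
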