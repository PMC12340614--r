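# SCOS pipeline: dark calibration, windowed contrast, the noise-correction
# chain, spatial variance, and the contrast-model inversion.

mk_stack <- function(frames, gain = 9.64, t_exp = 1e-3) {
  structure(list(frames = frames, t_exp = t_exp, frame_rate = 120,
                 gain = gain, read_sigma = 2, dark_offset = 100,
                 speckle_pixel_ratio = 2.3),
            class = "frame_stack")
}

test_that("dark calibration recovers offset and read variance", {
  # noise-free darks: exact offset, zero variance
  clean <- mk_stack(array(100L, dim = c(14, 14, 12)))
  cal <- dark_calibration(clean)
  expect_true(all(cal$offset_map == 100))
  expect_true(all(cal$dark_var_map == 0))
  # Gaussian read noise sigma = 2: variance ~4 at 600 frames
  set.seed(3)
  noisy <- mk_stack(array(round(rnorm(16 * 16 * 600, 100, 2)),
                          dim = c(16, 16, 600)))
  cal2 <- dark_calibration(noisy)
  expect_equal(mean(cal2$dark_var_map), 4 + 1 / 12, tolerance = 0.1)
  expect_error(dark_calibration(mk_stack(array(0, dim = c(8, 8, 0)))),
               "empty|at least")
  expect_error(dark_calibration(mk_stack(array(100L, dim = c(8, 8, 5)))),
               "at least 10")
})

test_that("windowed contrast matches a hand-computed oracle", {
  cal <- structure(list(offset_map = matrix(0, 7, 7),
                        dark_var_map = matrix(0, 7, 7),
                        gain = 9.64, n_avg = 100),
                   class = "camera_calibration")
  # constant frame: zero contrast everywhere
  ct0 <- windowed_contrast(matrix(50, 7, 7), cal)
  expect_equal(ct0$kappa_meas_sq, 0)
  # single 7x7 block of 1..49: direct arithmetic oracle
  f <- matrix(1:49, 7, 7)
  ct <- windowed_contrast(f, cal)
  mu <- mean(1:49)
  v <- sum((1:49 - mu)^2) / 48
  expect_equal(ct$mu, mu)
  expect_equal(ct$kappa_meas_sq, v / mu^2)
  # nonpositive window mean is invalid
  ctn <- windowed_contrast(matrix(-1, 7, 7), cal)
  expect_false(ctn$valid)
})

test_that("noise terms take their closed-form values and sum exactly", {
  cal <- structure(list(offset_map = matrix(0, 7, 7),
                        dark_var_map = matrix(2.5, 7, 7),
                        gain = 9.64, n_avg = 100),
                   class = "camera_calibration")
  ct <- tibble::tibble(win_row = 1, win_col = 1, mu = 100,
                       kappa_meas_sq = 0.2, dark_var = 2.5, valid = TRUE)
  rec <- noise_corrections(ct, cal)
  expect_equal(rec$kappa_shot_sq, 9.64 / 100)
  expect_equal(rec$kappa_read_sq, 2.5 / 100^2)
  ct10 <- dplyr::mutate(ct, mu = 10, dark_var = 0)
  expect_equal(noise_corrections(ct10, cal)$kappa_quant_sq, 1 / 1200)
  # decomposition identity holds exactly
  expect_equal(rec$kappa_meas_sq,
               rec$kappa_f_sq + rec$kappa_read_sq + rec$kappa_shot_sq +
                 rec$kappa_quant_sq + rec$kappa_spatial_sq)
  # negative fundamental contrast is flagged invalid, never clipped
  ct_neg <- dplyr::mutate(ct, kappa_meas_sq = 0.01)
  rec_neg <- noise_corrections(ct_neg, cal)
  expect_lt(rec_neg$kappa_f_sq, 0)
  expect_false(rec_neg$valid)
})

test_that("spatial variance isolates static structure", {
  cal <- structure(list(offset_map = matrix(0, 14, 14),
                        dark_var_map = matrix(0, 14, 14),
                        gain = 1, n_avg = 100),
                   class = "camera_calibration")
  # identical frames with a fixed vignette, no noise, gain -> 0 shot term
  vignette <- outer(seq(80, 120, length.out = 14), rep(1, 14))
  cal0 <- cal; cal0$gain <- 1e-12
  stk <- mk_stack(array(rep(vignette, 10), dim = c(14, 14, 10)), gain = 1e-12)
  sv <- spatial_variance(stk, cal0, n_avg = 10)
  st <- speckleflow:::.window_stats(vignette, 7)
  expect_equal(sv$sigma_spatial_sq, st$var, tolerance = 1e-6)
  # flat field with pure shot noise: spatial variance consistent with zero
  set.seed(9)
  shot <- array(rpois(28 * 28 * 200, 100), dim = c(28, 28, 200))
  cal1 <- structure(list(offset_map = matrix(0, 28, 28),
                         dark_var_map = matrix(0, 28, 28),
                         gain = 1, n_avg = 200),
                    class = "camera_calibration")
  sv2 <- suppressWarnings(
    spatial_variance(mk_stack(shot, gain = 1), cal1, n_avg = 200))
  # small against the shot term it corrects (the zero clamp leaves a
  # half-normal residual of the window estimator noise)
  expect_lt(mean(sv2$sigma_spatial_sq), 0.2 * 100 / 200)
  expect_error(spatial_variance(mk_stack(shot, gain = 1), cal1, n_avg = 1),
               "n_avg")
})

test_that("contrast inversion round-trips against the forward model", {
  med <- vivo_medium(); geo <- std_geometry(med)
  k2 <- kappa_squared_theory(med, geo, flow_params(bfi = 1e-8), beta = 0.3,
                             t_exp = 1e-3)
  fit <- fit_kappa2_bfi(k2, t_exp = 1e-3, medium = med, geometry = geo,
                        beta_assumed = 0.3)
  expect_equal(fit$bfi, 1e-8, tolerance = 1e-3)
  # recovered BFi strictly decreasing in the fundamental contrast
  ks <- vapply(c(5e-9, 1e-8, 2e-8, 4e-8), function(b) {
    kappa_squared_theory(med, geo, flow_params(bfi = b), 0.3, 1e-3)
  }, numeric(1))
  fits <- fit_kappa2_bfi(ks, 1e-3, med, geo, beta_assumed = 0.3)
  expect_true(all(diff(fits$bfi[order(fits$kappa_f_sq)]) < 0))
  # unphysical contrasts are invalid, never fitted
  bad <- fit_kappa2_bfi(c(-0.01, 0, 0.35), 1e-3, med, geo,
                        beta_assumed = 0.3)
  expect_true(all(!bad$valid))
  expect_true(all(is.na(bad$bfi)))
})

test_that("relative flow is insensitive to the assumed coherence", {
  med <- vivo_medium(); geo <- std_geometry(med)
  true_beta <- 0.3
  bfis <- c(1e-8, 3e-8)  # baseline and hyperemic flow
  ks <- vapply(bfis, function(b) {
    kappa_squared_theory(med, geo, flow_params(bfi = b), true_beta, 1e-3)
  }, numeric(1))
  f_half <- fit_kappa2_bfi(ks, 1e-3, med, geo, beta_assumed = true_beta / 2)
  f_true <- fit_kappa2_bfi(ks, 1e-3, med, geo, beta_assumed = true_beta)
  # absolute scale shifts monotonically with the assumed beta
  expect_true(all(f_half$bfi < f_true$bfi))
  # but the flow ratio moves by a few percent only
  ratio_true <- f_true$bfi[2] / f_true$bfi[1]
  ratio_half <- f_half$bfi[2] / f_half$bfi[1]
  expect_lt(abs(ratio_half / ratio_true - 1), 0.25)
})

test_that("exposure-time choice has little effect on recovered flow", {
  med <- vivo_medium(); geo <- std_geometry(med)
  beta <- 0.3
  for (tx in c(2.5e-4, 5e-4, 1e-3, 2e-3)) {
    k <- kappa_squared_theory(med, geo, flow_params(bfi = 1e-8), beta, tx)
    fit <- fit_kappa2_bfi(k, tx, med, geo, beta_assumed = beta)
    expect_equal(fit$bfi, 1e-8, tolerance = 1e-3)
  }
})

test_that("full pipeline recovers flow from simulated frames", {
  med <- vivo_medium(); geo <- std_geometry(med)
  flow <- flow_params(bfi = 1e-8)
  g1f <- function(t) g1_semi_infinite(med, geo, flow, t)$value
  stack <- simulate_scos_frames(g1f, t_exp = 5e-4, substeps = 96,
                                dims = c(96, 96), n_frames = 2, flux = 150,
                                seed = 41)
  dark <- simulate_scos_dark(dims = c(96, 96), n_frames = 12, seed = 42)
  fs <- process_scos(stack, dark, med, geo,
                     beta_assumed = scos_effective_beta(2.3),
                     spatial_correction = FALSE)
  expect_true(all(fs$valid))
  expect_equal(stats::median(fs$bfi), 1e-8, tolerance = 0.12)
})
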