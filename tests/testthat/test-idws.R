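# iDWS pipeline: rolling-mean subtraction, spatial filtering,
# Wiener-Khinchin autocorrelation, reference correction, squared-G2 fit.

mk_record <- function(counts, dt = 3e-6) {
  structure(list(counts = counts, dt = dt, reference_level = 0,
                 sample_level = 0, spatial_hwhm = 1.5),
            class = "linescan_record")
}

test_that("rolling-mean subtraction removes slow components only", {
  dt <- 1e-3
  n <- 1000
  t <- (seq_len(n) - 1) * dt
  # constant input: exactly zero everywhere (full and shrinking windows)
  rec <- mk_record(matrix(5, nrow = 2, ncol = n), dt)
  fl <- rolling_mean_subtract(rec, window = 0.1)
  expect_true(all(abs(fl$delta) < 1e-12))
  # fast sinusoid (period 10 ms << 0.1 s window) passes nearly unchanged
  s <- sin(2 * pi * 100 * t)
  fl2 <- rolling_mean_subtract(mk_record(rbind(10 + s), dt), window = 0.1)
  keep <- fl2$valid_time
  expect_lt(max(abs(fl2$delta[1, keep] - s[keep])), 0.01 * max(abs(s)))
  # slow ramp: interior residual bounded by the moving-average response
  slope <- 2
  fl3 <- rolling_mean_subtract(mk_record(rbind(slope * t), dt), window = 0.1)
  expect_lt(max(abs(fl3$delta[1, fl3$valid_time])), slope * 0.1 / 2 + 1e-9)
  expect_error(rolling_mean_subtract(mk_record(matrix(1, 1, 10), dt), 0.1),
               "shorter")
})

test_that("spatial filter has the stated impulse and correlation response", {
  # impulse: the unnormalized kernel itself, peak value 1 at the centre
  n_px <- 31
  delta <- matrix(0, n_px, 1)
  delta[16, 1] <- 1
  fl <- structure(list(delta = delta, dt = 3e-6,
                       valid_time = TRUE), class = "idws_fluct")
  out <- spatial_filter(fl, sigma = 0.9669)
  expect_equal(out$delta[16, 1], 1)
  expect_equal(out$delta[17, 1], exp(-1 / (2 * 0.9669^2)))
  # spatially constant input scales by the kernel sum
  flc <- structure(list(delta = matrix(1, n_px, 2), dt = 3e-6,
                        valid_time = TRUE), class = "idws_fluct")
  ksum <- sum(exp(-(-4:4)^2 / (2 * 0.9669^2)))
  outc <- spatial_filter(flc, sigma = 0.9669)
  expect_equal(outc$delta[16, 1], ksum, tolerance = 1e-12)
  # white noise: output spatial autocorrelation = kernel self-correlation
  set.seed(7)
  w <- matrix(rnorm(64 * 4000), 64, 4000)
  flw <- structure(list(delta = w, dt = 3e-6, valid_time = TRUE),
                   class = "idws_fluct")
  outw <- spatial_filter(flw, sigma = 0.9669)$delta
  k <- exp(-(-4:4)^2 / (2 * 0.9669^2))
  self_corr <- vapply(0:3, function(d) {
    sum(k[1:(9 - d)] * k[(1 + d):9]) / sum(k^2)
  }, numeric(1))
  emp <- vapply(0:3, function(d) {
    p <- nrow(outw)
    mean(outw[seq_len(p - d), ] * outw[seq_len(p - d) + d, ]) /
      mean(outw^2)
  }, numeric(1))
  expect_equal(emp, self_corr, tolerance = 0.05)
})

test_that("Wiener-Khinchin autocorrelation equals the direct lag sums", {
  dt <- 3e-6
  set.seed(11)
  for (n_px in c(1, 3)) {
    x <- matrix(rnorm(n_px * 16667), n_px)
    fl <- structure(list(delta = x, dt = dt,
                         valid_time = rep(TRUE, ncol(x))),
                    class = "idws_fluct")
    tbl <- wk_autocorrelation(fl, segment = 0.05, n_lags = 200)
    g2 <- tbl$g2[[1]]
    lags <- 0:200
    for (px in seq_len(n_px)) {
      oracle <- direct_acsum_oracle(x[px, seq_len(16667)], lags)
      # relative to the zero-lag sum (tail sums of white noise are ~0)
      expect_lt(max(abs(g2[px, ] - oracle)) / abs(oracle[1]), 1e-10)
    }
  }
  # sinusoid: cosine autocorrelation at the same frequency
  f0 <- 5e3
  tt <- (0:16666) * dt
  xs <- rbind(sin(2 * pi * f0 * tt))
  fls <- structure(list(delta = xs, dt = dt,
                        valid_time = rep(TRUE, length(tt))),
                   class = "idws_fluct")
  tbl <- wk_autocorrelation(fls, segment = 0.05, n_lags = 100)
  ac <- tbl$g2[[1]][1, ]
  ac <- ac / ac[1]
  expect_equal(ac[1:50], cos(2 * pi * f0 * (0:49) * dt), tolerance = 0.01)
})

test_that("reference correction cancels an identical reference exactly", {
  set.seed(13)
  x <- matrix(rnorm(4 * 20000), 4)
  fl <- structure(list(delta = x, dt = 3e-6,
                       valid_time = rep(TRUE, ncol(x))),
                  class = "idws_fluct")
  tbl <- wk_autocorrelation(fl, segment = 0.05, n_lags = 100)
  ref <- rowMeans(vapply(tbl$g2, colSums, numeric(101)))
  attr(ref, "tau") <- attr(tbl, "tau")
  # a single-segment measurement against the mean of itself
  one <- tbl[1, ]
  attr(one, "tau") <- attr(tbl, "tau")
  corrected <- sum_and_reference_correct(one, colSums(tbl$g2[[1]]))
  expect_true(all(abs(corrected$curve[[1]]$value) < 1e-9 * sum(x^2)))
  # mismatched lag grids are an error
  bad <- tbl
  attr(bad, "tau") <- attr(tbl, "tau") * 2
  expect_error(sum_and_reference_correct(tbl, structure(ref[1:50])),
               "lag grid")
})

test_that("squared-G2 fit round-trips and is gain equivariant", {
  med <- vivo_medium(); geo <- std_geometry(med)
  tau <- (0:400) * 3e-6
  g1v <- g1_semi_infinite(med, geo, flow_params(bfi = 1e-8), tau)$value
  curve <- correlation_curve(tau, 7.5 * g1v, "G2_idws")
  fit <- fit_g2sq_bfi(curve, med, geo)
  expect_equal(fit$bfi, 1e-8, tolerance = 1e-3)
  expect_equal(fit$amplitude, 7.5, tolerance = 1e-3)
  # scaling G2 by k scales A by k and leaves BFi unchanged
  curve_k <- correlation_curve(tau, 3 * 7.5 * g1v, "G2_idws")
  fit_k <- fit_g2sq_bfi(curve_k, med, geo)
  expect_equal(fit_k$amplitude / fit$amplitude, 3, tolerance = 1e-6)
  expect_equal(fit_k$bfi, fit$bfi, tolerance = 1e-9)
  expect_gte(fit$fit_range_end, 2)
})

test_that("fit range stops at the first negative normalized lag", {
  med <- vivo_medium(); geo <- std_geometry(med)
  tau <- (0:100) * 3e-6
  g1v <- g1_semi_infinite(med, geo, flow_params(bfi = 1e-8), tau)$value
  v <- 5 * g1v
  v[41:101] <- -0.1
  fit <- fit_g2sq_bfi(correlation_curve(tau, v, "G2_idws"), med, geo)
  expect_equal(fit$fit_range_end, 41L)
})

test_that("squared-correlation fitting is more noise-robust than linear", {
  # low-SNR simulated record: per-segment fits under the pipeline's real
  # (correlated) noise structure
  med <- vivo_medium(); geo <- std_geometry(med)
  flow <- flow_params(bfi = 1e-8)
  g1f <- function(t) g1_semi_infinite(med, geo, flow, t)$value
  fld <- sample_correlated_field(g1f, 1e5, 3e-6, n_speckles = 16, seed = 51)
  rec <- simulate_idws_record(fld, sample_level = 0.5, seed = 52)
  fld0 <- fld; fld0$field[] <- 0
  ref <- simulate_idws_record(fld0, sample_level = 0, seed = 53)
  refc <- idws_reference_curve(ref, n_lags = 800)
  corrected <- rec |> rolling_mean_subtract() |> spatial_filter() |>
    wk_autocorrelation(n_lags = 800) |> sum_and_reference_correct(refc)
  fits <- vapply(corrected$curve, function(cc) {
    c(fit_g2sq_bfi(cc, med, geo, fit_mode = "g1sq_all")$bfi,
      fit_g2sq_bfi(cc, med, geo, fit_mode = "g1_all")$bfi)
  }, numeric(2))
  expect_lte(stats::var(fits[1, ]), stats::var(fits[2, ]))
})

test_that("full pipeline recovers flow from a simulated interferogram", {
  med <- vivo_medium(); geo <- std_geometry(med)
  flow <- flow_params(bfi = 1e-8)
  g1f <- function(t) g1_semi_infinite(med, geo, flow, t)$value
  n_t <- 70000
  fld <- sample_correlated_field(g1f, n_t, 3e-6, n_speckles = 32, seed = 19)
  rec <- simulate_idws_record(fld, seed = 20)
  fld0 <- fld; fld0$field[] <- 0
  ref <- simulate_idws_record(fld0, sample_level = 0, seed = 21)
  fs <- process_idws(rec, ref, med, geo, n_lags = 1000)
  expect_equal(stats::median(fs$bfi[fs$valid]), 1e-8, tolerance = 0.1)
})
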