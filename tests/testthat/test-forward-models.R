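# Closed-form theory layer: CDE field autocorrelation, Siegert relation,
# exposure-integrated contrast, Stokes-Einstein/Vogel ground truth.

test_that("effective reflection coefficient matches the polynomial oracle", {
  # matched boundary: no index mismatch, essentially no internal reflection
  expect_lt(abs(effective_reflection_coefficient(1.33, 1.33)), 0.01)
  # frozen value computed independently from the polynomial at n = 1.33
  expect_equal(effective_reflection_coefficient(1.33, 1.0), 0.4723573,
               tolerance = 1e-6)
  # monotone in the index ratio
  expect_gt(effective_reflection_coefficient(1.4),
            effective_reflection_coefficient(1.33))
  expect_error(effective_reflection_coefficient(-1), "positive")
})

test_that("semi-infinite g1 normalizes, decays, and matches the oracle", {
  med <- phantom_medium()
  geo <- std_geometry(med)
  flow <- flow_params(bfi = 1e-8)
  tau <- c(0, 10^seq(-7, -3, length.out = 30))
  g1 <- g1_semi_infinite(med, geo, flow, tau)
  expect_equal(g1$value[1], 1)
  # static medium: no decay at all
  g1_static <- g1_semi_infinite(med, geo, flow_params(bfi = 0), tau)
  expect_true(all(g1_static$value == 1))
  # frozen value from an independent numpy evaluation of the closed form
  g1_pt <- g1_semi_infinite(med, geo, flow, c(0, 1e-5))
  expect_equal(g1_pt$value[2], 0.8275436, tolerance = 1e-6)
  expect_error(g1_semi_infinite(med, geo, flow, c(-1e-6, 0)), "nonnegative")
})

test_that("g1 decreases monotonically in tau, flow, and scattering", {
  tau <- 10^seq(-6, -3.5, length.out = 15)
  for (bfi in c(3e-9, 1e-8, 3e-8)) {
    for (musp in c(5, 6, 8)) {
      med <- optical_medium(0.1, musp)
      geo <- std_geometry(med)
      v <- g1_semi_infinite(med, geo, flow_params(bfi = bfi), tau)$value
      expect_true(all(diff(v) < 0))
      expect_true(all(v > 0 & v <= 1))
    }
  }
  med <- vivo_medium(); geo <- std_geometry(med)
  at_tau <- function(bfi) {
    g1_semi_infinite(med, geo, flow_params(bfi = bfi), c(0, 1e-5))$value[2]
  }
  bfis <- c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7)
  expect_true(all(diff(vapply(bfis, at_tau, numeric(1))) < 0))
  musp_val <- function(musp) {
    m <- optical_medium(0.1, musp)
    g1_semi_infinite(m, std_geometry(m), flow_params(bfi = 1e-8),
                     c(0, 1e-5))$value[2]
  }
  expect_true(all(diff(vapply(c(4, 6, 8, 10), musp_val, numeric(1))) < 0))
})

test_that("Siegert relation maps and inverts exactly", {
  expect_equal(siegert_g2(1, 0.5)$value, 1.5)
  expect_equal(siegert_g2(0, 0.7)$value, 1)
  tau <- 10^seq(-6, -3, length.out = 20)
  med <- vivo_medium(); geo <- std_geometry(med)
  g1 <- g1_semi_infinite(med, geo, flow_params(bfi = 1e-8), tau)
  for (beta in c(0.1, 0.5, 1.0)) {
    back <- siegert_invert(siegert_g2(g1, beta), beta)
    expect_equal(back$value, g1$value, tolerance = 1e-12)
  }
  expect_error(siegert_g2(g1, 0), "beta")
  expect_error(siegert_g2(g1, 1.5), "beta")
})

test_that("contrast quadrature matches the exponential closed form", {
  gam <- 1e4
  for (t_exp in c(1e-4, 1e-3, 1e-2)) {
    x <- gam * t_exp
    analytic <- 0.5 * (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)
    quad <- kappa_squared_from_g1(function(t) exp(-gam * t), beta = 0.5,
                                  t_exp = t_exp)
    expect_equal(quad, analytic, tolerance = 1e-6)
  }
})

test_that("contrast model obeys its limits and monotonicity", {
  med <- vivo_medium(); geo <- std_geometry(med)
  # short-exposure limit recovers the coherence parameter
  k0 <- kappa_squared_theory(med, geo, flow_params(bfi = 1e-8), beta = 0.42,
                             t_exp = 1e-9)
  expect_equal(k0, 0.42, tolerance = 1e-3)
  k_by_texp <- vapply(c(2.5e-4, 5e-4, 1e-3, 2e-3), function(tx) {
    kappa_squared_theory(med, geo, flow_params(bfi = 1e-8), beta = 0.3,
                         t_exp = tx)
  }, numeric(1))
  expect_true(all(diff(k_by_texp) < 0))
  k1 <- kappa_squared_theory(med, geo, flow_params(bfi = 1e-8), 0.3, 1e-3)
  k2 <- kappa_squared_theory(med, geo, flow_params(bfi = 2e-8), 0.3, 1e-3)
  expect_lt(k2, k1)
  expect_true(k1 > 0 && k1 <= 0.3)
})

test_that("Vogel viscosity matches its oracle and domain", {
  # frozen value from independent evaluation at 20 C
  expect_equal(vogel_viscosity(293.15), 1.0016649e-3, tolerance = 1e-6)
  expect_equal(vogel_viscosity(20, unit = "C"), vogel_viscosity(293.15))
  t_grid <- seq(278, 300, by = 2)
  expect_true(all(diff(vogel_viscosity(t_grid)) < 0))
  expect_error(vogel_viscosity(137.0), "pole")
})

test_that("Stokes-Einstein diffusion matches its oracle and scalings", {
  # frozen value: 195 nm spheres at 22 C
  expect_equal(stokes_einstein_db(295.15, 97.5e-9), 2.3206100e-8,
               tolerance = 1e-6)
  expect_equal(stokes_einstein_db(295.15, 2 * 97.5e-9),
               stokes_einstein_db(295.15, 97.5e-9) / 2)
  expect_gt(stokes_einstein_db(22, 97.5e-9, unit = "C"),
            stokes_einstein_db(7, 97.5e-9, unit = "C"))
  # strictly increasing across the phantom ramp range
  db <- stokes_einstein_db(seq(280, 300, by = 1), 97.5e-9)
  expect_true(all(diff(db) > 0))
  expect_error(stokes_einstein_db(295, -1e-9), "radius")
})

test_that("optical-property extrapolation follows its models", {
  mua_tbl <- data.frame(wavelength = c(727, 750, 827),
                        mua = 0.05 + 1e-4 * c(727, 750, 827))
  out <- extrapolate_optical_properties(10, 1.2, mua_tbl, 500)
  expect_equal(out$musp, 10)
  out0 <- extrapolate_optical_properties(10, 0, mua_tbl, 900)
  expect_equal(out0$musp, 10)
  out785 <- extrapolate_optical_properties(10, 1.2, mua_tbl, 785)
  expect_equal(out785$mua, 0.05 + 1e-4 * 785, tolerance = 1e-10)
  expect_error(
    extrapolate_optical_properties(10, 1.2, mua_tbl[1, ], 785),
    "at least two")
})

test_that("type constructors enforce their invariants", {
  expect_error(optical_medium(-0.1, 6), "positive")
  expect_error(optical_medium(0.1, 6, n_in = 0.9), ">= 1")
  expect_error(flow_params(alpha = 1.5, db = 1e-8), "alpha")
  expect_error(flow_params(alpha = 0.5, db = -1), "db")
  expect_equal(flow_params(alpha = 0.5, db = 2e-8)$bfi, 1e-8)
  expect_error(correlation_curve(c(0, 0, 1e-5), c(1, 1, 1), "g1"),
               "strictly increasing")
  expect_error(semi_infinite_geometry(-1, vivo_medium()), "positive")
  geo <- std_geometry(vivo_medium())
  expect_lte(geo$r1, geo$r2)
})
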