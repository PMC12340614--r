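# Closed-form theory layer: semi-infinite correlation diffusion equation (CDE)
# field autocorrelation, Siegert relation, exposure-integrated speckle contrast,
# and Stokes-Einstein/Vogel phantom ground truth.

# speed of light in vacuum, cm/s
.c_cm_s <- 2.99792458e10
# Boltzmann constant, J/K
.k_boltzmann <- 1.380649e-23

#' Optical properties of the probed medium
#'
#' Bundles the absorption and reduced scattering coefficients with refractive
#' indices and wavelength, and derives the quantities entering the correlation
#' diffusion equation: the in-medium wave number `k0 = 2*pi*n_in/lambda` and
#' the photon diffusion coefficient `D = v / (3*(mua + musp))` with
#' `v = c/n_in`.
#'
#' @param mua Absorption coefficient (1/cm). Must be positive.
#' @param musp Reduced scattering coefficient (1/cm). Must be positive.
#' @param n_in Refractive index of the medium (>= 1).
#' @param n_out Refractive index of the external medium (>= 1).
#' @param wavelength Vacuum wavelength in nm.
#'
#' @return An object of class `optical_medium`: a list with the input fields
#'   plus `k0` (1/cm), `v` (cm/s) and `D` (cm^2/s).
#' @examples
#' optical_medium(mua = 0.104, musp = 6.30)
#' @export
optical_medium <- function(mua, musp, n_in = 1.33, n_out = 1.0,
                           wavelength = 785) {
  stopifnot(is.numeric(mua), is.numeric(musp), is.numeric(wavelength))
  if (mua <= 0 || musp <= 0 || wavelength <= 0) {
    stop("`mua`, `musp` and `wavelength` must be positive", call. = FALSE)
  }
  if (n_in < 1 || n_out < 1) {
    stop("refractive indices must be >= 1", call. = FALSE)
  }
  lambda_cm <- wavelength * 1e-7
  v <- .c_cm_s / n_in
  structure(
    list(
      mua = mua, musp = musp, n_in = n_in, n_out = n_out,
      wavelength = wavelength,
      k0 = 2 * pi * n_in / lambda_cm,
      v = v,
      D = v / (3 * (mua + musp))
    ),
    class = "optical_medium"
  )
}

#' Effective reflection coefficient at a refractive-index boundary
#'
#' Polynomial approximation (Egan--Hilgeman/Haskell form) to the effective
#' Fresnel reflection coefficient used in the extrapolated-boundary condition,
#' evaluated at the index ratio `n = n_in / n_out`:
#' `Reff = -1.440/n^2 + 0.710/n + 0.668 + 0.0636*n`.
#'
#' @param n_in Refractive index of the medium.
#' @param n_out Refractive index of the external medium (default 1, air).
#' @return Effective reflection coefficient in `[0, 1)`.
#' @examples
#' effective_reflection_coefficient(1.33) # ~0.472
#' @export
effective_reflection_coefficient <- function(n_in, n_out = 1.0) {
  if (!is.numeric(n_in) || !is.numeric(n_out) || n_in <= 0 || n_out <= 0) {
    stop("refractive indices must be positive numbers", call. = FALSE)
  }
  n <- n_in / n_out
  r <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  min(max(r, 0), 1 - 1e-12)
}

#' Semi-infinite measurement geometry
#'
#' Source and detector on the surface of a half space separated by `rho`,
#' solved with an image source across the extrapolated boundary:
#' `z0 = 1/musp`, `zb = 2*(1 + Reff) / (3*musp*(1 - Reff))`,
#' `r1 = sqrt(rho^2 + z0^2)`, `r2 = sqrt(rho^2 + (z0 + 2*zb)^2)`.
#'
#' @param rho Source-detector separation (cm).
#' @param medium An [optical_medium()].
#' @param reff Optional override of the effective reflection coefficient;
#'   by default computed from the medium's index ratio.
#' @return An object of class `semi_infinite_geometry` with fields
#'   `rho`, `z0`, `zb`, `reff`, `r1`, `r2`.
#' @export
semi_infinite_geometry <- function(rho, medium, reff = NULL) {
  stopifnot(inherits(medium, "optical_medium"))
  if (!is.numeric(rho) || rho <= 0) {
    stop("`rho` must be a positive separation in cm", call. = FALSE)
  }
  if (is.null(reff)) {
    reff <- effective_reflection_coefficient(medium$n_in, medium$n_out)
  }
  if (reff < 0 || reff >= 1) stop("`reff` must be in [0, 1)", call. = FALSE)
  z0 <- 1 / medium$musp
  zb <- 2 * (1 + reff) / (3 * medium$musp * (1 - reff))
  structure(
    list(
      rho = rho, z0 = z0, zb = zb, reff = reff,
      r1 = sqrt(rho^2 + z0^2),
      r2 = sqrt(rho^2 + (z0 + 2 * zb)^2)
    ),
    class = "semi_infinite_geometry"
  )
}

#' Dynamic-scatterer model parameters
#'
#' Moving-scatterer fraction `alpha` and effective Brownian diffusion
#' coefficient `Db` of the dynamic scatterers (red blood cells in vivo,
#' microspheres in phantoms), whose mean-square displacement is
#' `<dr^2(tau)> = 6*Db*tau`. The blood flow index is `BFi = alpha * Db`.
#'
#' @param alpha Fraction of scattering events from moving scatterers, in
#'   `[0, 1]`.
#' @param db Effective Brownian diffusion coefficient (cm^2/s), >= 0.
#' @param bfi Alternatively, specify the blood flow index directly
#'   (`alpha` is then taken as 1 and `db = bfi`).
#' @return An object of class `flow_params` with fields `alpha`, `db`, `bfi`.
#' @export
flow_params <- function(alpha = 1, db = NULL, bfi = NULL) {
  if (is.null(db) && is.null(bfi)) stop("supply `db` or `bfi`", call. = FALSE)
  if (is.null(db)) {
    alpha <- 1
    db <- bfi
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (db < 0) stop("`db` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, db = db, bfi = alpha * db),
            class = "flow_params")
}

#' Tau-grid autocorrelation record
#'
#' A tibble of delay times and autocorrelation values with the curve kind
#' (`g1`, `g2` or unnormalized interferometric `G2_idws`) and an optional
#' coherence parameter `beta` stored as attributes.
#'
#' @param tau Nonnegative, strictly increasing delay grid (s).
#' @param values Autocorrelation samples.
#' @param kind One of `"g1"`, `"g2"`, `"G2_idws"`.
#' @param beta Optional coherence parameter in `(0, 1]`.
#' @return A tibble of class `correlation_curve` with columns `tau`, `value`.
#' @export
correlation_curve <- function(tau, values, kind = c("g1", "g2", "G2_idws"),
                              beta = NULL) {
  kind <- match.arg(kind)
  if (length(tau) != length(values)) {
    stop("`tau` and `values` must have equal length", call. = FALSE)
  }
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  if (length(tau) > 1 && any(diff(tau) <= 0)) {
    stop("`tau` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(beta) && (beta <= 0 || beta > 1)) {
    stop("`beta` must be in (0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(tau = as.numeric(tau), value = as.numeric(values))
  class(out) <- c("correlation_curve", class(out))
  attr(out, "kind") <- kind
  attr(out, "beta") <- beta
  out
}

#' @rdname correlation_curve
#' @param x Object to query.
#' @export
curve_kind <- function(x) attr(x, "kind")

#' @rdname correlation_curve
#' @export
curve_beta <- function(x) attr(x, "beta")

# Decay argument of the semi-infinite CDE solution, 1/cm. The printed form of
# the dispersion relation is the square of this (K must carry 1/length).
.cde_k <- function(medium, flow, tau) {
  sqrt(3 * medium$mua * (medium$mua + medium$musp) +
         6 * (medium$mua + medium$musp) * medium$musp *
           medium$k0^2 * flow$bfi * tau)
}

# Unnormalized G1(tau) up to a constant prefactor (v / 4 pi D cancels on
# normalization).
.g1_unnorm <- function(medium, geometry, flow, tau) {
  k <- .cde_k(medium, flow, tau)
  exp(-k * geometry$r1) / geometry$r1 - exp(-k * geometry$r2) / geometry$r2
}

#' Normalized field autocorrelation for the semi-infinite CDE solution
#'
#' Evaluates `g1(tau) = G1(tau)/G1(0)` with
#' `G1(tau) = exp(-K*r1)/r1 - exp(-K*r2)/r2` and decay argument
#' `K(tau) = sqrt(3*mua*(mua+musp) + 6*(mua+musp)*musp*k0^2*alpha*Db*tau)`.
#'
#' @param medium An [optical_medium()].
#' @param geometry A [semi_infinite_geometry()].
#' @param flow A [flow_params()].
#' @param tau Nonnegative delay grid (s).
#' @return A [correlation_curve()] of kind `"g1"`.
#' @examples
#' med <- optical_medium(0.104, 6.30)
#' geo <- semi_infinite_geometry(2.5, med)
#' g1_semi_infinite(med, geo, flow_params(bfi = 1e-8), tau = c(0, 1e-5))
#' @export
g1_semi_infinite <- function(medium, geometry, flow, tau) {
  stopifnot(inherits(medium, "optical_medium"),
            inherits(geometry, "semi_infinite_geometry"),
            inherits(flow, "flow_params"))
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  g0 <- .g1_unnorm(medium, geometry, flow, 0)
  correlation_curve(tau, .g1_unnorm(medium, geometry, flow, tau) / g0,
                    kind = "g1")
}

# Fast path used inside fitting loops: plain numeric vector of g1 values.
.g1_values <- function(medium, geometry, bfi, tau) {
  fl <- list(bfi = bfi)
  g0 <- .g1_unnorm(medium, geometry, fl, 0)
  .g1_unnorm(medium, geometry, fl, tau) / g0
}

#' Siegert relation and its inverse
#'
#' `siegert_g2()` maps a field autocorrelation to the intensity
#' autocorrelation `g2 = 1 + beta * |g1|^2`; `siegert_invert()` recovers
#' `|g1| = sqrt(|g2 - 1| / beta)`.
#'
#' @param g1 A [correlation_curve()] of kind `"g1"` (or numeric vector).
#' @param g2 A [correlation_curve()] of kind `"g2"` (or numeric vector).
#' @param beta Coherence parameter in `(0, 1]`.
#' @return A [correlation_curve()] of the mapped kind.
#' @export
siegert_g2 <- function(g1, beta) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    stop("`beta` must be in (0, 1]", call. = FALSE)
  }
  tau <- if (inherits(g1, "correlation_curve")) g1$tau else seq_along(g1) - 1
  v <- if (inherits(g1, "correlation_curve")) g1$value else g1
  correlation_curve(tau, 1 + beta * abs(v)^2, kind = "g2", beta = beta)
}

#' @rdname siegert_g2
#' @export
siegert_invert <- function(g2, beta) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    stop("`beta` must be in (0, 1]", call. = FALSE)
  }
  tau <- if (inherits(g2, "correlation_curve")) g2$tau else seq_along(g2) - 1
  v <- if (inherits(g2, "correlation_curve")) g2$value else g2
  correlation_curve(tau, sqrt(abs(v - 1) / beta), kind = "g1")
}

# Composite Simpson quadrature on a (possibly non-uniform) node set: exact
# for quadratics on each consecutive node triple. Needs an odd number of
# nodes; the trailing interval (if any) falls back to trapezoid.
.simpson_nonuniform <- function(x, y) {
  n <- length(x)
  total <- 0
  i <- 1
  while (i + 2 <= n) {
    h1 <- x[i + 1] - x[i]
    h2 <- x[i + 2] - x[i + 1]
    h <- h1 + h2
    total <- total +
      (h / 6) * ((2 - h2 / h1) * y[i] +
                   (h^2 / (h1 * h2)) * y[i + 1] +
                   (2 - h1 / h2) * y[i + 2])
    i <- i + 2
  }
  if (i + 1 <= n) {
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  total
}

# log-spaced-plus-zero node grid on [0, t_exp]
.kappa_nodes <- function(t_exp, n_nodes) {
  c(0, 10^seq(log10(t_exp) - 9, log10(t_exp), length.out = n_nodes))
}

#' Exposure-integrated squared speckle contrast from a g1 model
#'
#' Evaluates the contrast model
#' `kappa^2 = (2*beta / T) * integral_0^T |g1(tau)|^2 (1 - tau/T) dtau`
#' by composite Simpson quadrature on a log-spaced node grid (plus the
#' origin), with an optional doubled-node convergence check.
#'
#' `kappa_squared_from_g1()` takes an arbitrary `g1` function of delay time;
#' `kappa_squared_theory()` uses the semi-infinite CDE solution.
#'
#' @param g1_fun Function of `tau` returning `g1` values.
#' @param beta Coherence parameter in `(0, 1]`.
#' @param t_exp Exposure time (s), positive.
#' @param n_nodes Number of log-spaced quadrature nodes (default 2048).
#' @param check If `TRUE`, re-evaluate with doubled nodes and raise an error
#'   if the two estimates differ by more than `1e-8` relative.
#' @return Squared speckle contrast, a scalar in `(0, beta]`.
#' @export
kappa_squared_from_g1 <- function(g1_fun, beta, t_exp, n_nodes = 2048,
                                  check = TRUE) {
  if (!is.numeric(t_exp) || t_exp <= 0) {
    stop("`t_exp` must be positive", call. = FALSE)
  }
  if (beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]", call. = FALSE)
  eval_quad <- function(n) {
    x <- .kappa_nodes(t_exp, n)
    y <- abs(g1_fun(x))^2 * (1 - x / t_exp)
    (2 * beta / t_exp) * .simpson_nonuniform(x, y)
  }
  k2 <- eval_quad(n_nodes)
  if (check) {
    k2b <- eval_quad(2L * n_nodes)
    if (abs(k2 - k2b) > 1e-8 * max(abs(k2b), .Machine$double.eps)) {
      stop(sprintf(
        "speckle-contrast quadrature did not converge (n=%d: %.10g, n=%d: %.10g)",
        n_nodes, k2, 2L * n_nodes, k2b), call. = FALSE)
    }
  }
  min(k2, beta)
}

#' @rdname kappa_squared_from_g1
#' @inheritParams g1_semi_infinite
#' @export
kappa_squared_theory <- function(medium, geometry, flow, beta, t_exp,
                                 n_nodes = 2048, check = TRUE) {
  kappa_squared_from_g1(
    function(tau) .g1_values(medium, geometry, flow$bfi, tau),
    beta = beta, t_exp = t_exp, n_nodes = n_nodes, check = check
  )
}

.to_kelvin <- function(temperature, unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature + 273.15 else temperature
}

#' Temperature-dependent viscosity of water (Vogel equation)
#'
#' `eta(T) = 1e-3 * exp(-3.7188 + 578.919 / (T - 137.546))` with `T` in
#' kelvin; valid above the 137.546 K pole.
#'
#' @param temperature Temperature, in kelvin by default.
#' @param unit `"K"` or `"C"`.
#' @return Dynamic viscosity in Pa s.
#' @examples
#' vogel_viscosity(20, unit = "C") # ~1.0e-3 Pa s
#' @export
vogel_viscosity <- function(temperature, unit = c("K", "C")) {
  t_k <- .to_kelvin(temperature, unit)
  if (any(t_k <= 137.546)) {
    stop("temperature must exceed the 137.546 K pole of the Vogel equation",
         call. = FALSE)
  }
  1e-3 * exp(-3.7188 + 578.919 / (-137.546 + t_k))
}

#' Stokes-Einstein Brownian diffusion coefficient of a sphere in water
#'
#' `Db = kB * T / (6 * pi * a * eta(T))`, with viscosity from
#' [vogel_viscosity()], converted to cm^2/s. This is the theoretical ground
#' truth for microsphere phantom experiments.
#'
#' @inheritParams vogel_viscosity
#' @param radius Particle radius in meters (e.g. `97.5e-9` for 195 nm
#'   diameter spheres).
#' @return Diffusion coefficient in cm^2/s.
#' @examples
#' stokes_einstein_db(295.15, 97.5e-9) # ~2.32e-8 cm^2/s
#' @export
stokes_einstein_db <- function(temperature, radius, unit = c("K", "C")) {
  if (any(radius <= 0)) stop("`radius` must be positive", call. = FALSE)
  t_k <- .to_kelvin(temperature, unit)
  eta <- vogel_viscosity(t_k)
  .k_boltzmann * t_k / (6 * pi * radius * eta) * 1e4
}

#' Extrapolate optical properties to a target wavelength
#'
#' Reduced scattering follows a power law `musp(lambda) = A * (lambda/500)^-b`
#' (lambda in nm); absorption is extrapolated with an ordinary linear fit of
#' `mua` against wavelength over the supplied samples.
#'
#' @param musp_amplitude Power-law amplitude `A` (1/cm) at 500 nm.
#' @param scatter_power Scattering power `b` (dimensionless).
#' @param mua_samples Data frame with columns `wavelength` (nm) and `mua`
#'   (1/cm); at least two rows.
#' @param target_wavelength Wavelength (nm) at which to evaluate.
#' @return A tibble with columns `wavelength`, `mua`, `musp`.
#' @export
extrapolate_optical_properties <- function(musp_amplitude, scatter_power,
                                           mua_samples, target_wavelength) {
  if (musp_amplitude <= 0) stop("`musp_amplitude` must be > 0", call. = FALSE)
  mua_samples <- as.data.frame(mua_samples)
  if (!all(c("wavelength", "mua") %in% names(mua_samples))) {
    stop("`mua_samples` needs columns `wavelength` and `mua`", call. = FALSE)
  }
  if (nrow(mua_samples) < 2) {
    stop("need at least two `mua` samples for the linear model", call. = FALSE)
  }
  fit <- stats::lm(mua ~ wavelength, data = mua_samples)
  mua_t <- unname(stats::predict(
    fit, newdata = data.frame(wavelength = target_wavelength)))
  tibble::tibble(
    wavelength = target_wavelength,
    mua = mua_t,
    musp = musp_amplitude * (target_wavelength / 500)^(-scatter_power)
  )
}

#' Delay time at which the field autocorrelation falls to 1/e
#'
#' Convenience scale used to size simulation time steps and exposure
#' sub-stepping.
#'
#' @inheritParams g1_semi_infinite
#' @return Decorrelation time in seconds.
#' @export
decorrelation_time <- function(medium, geometry, flow) {
  if (flow$bfi <= 0) return(Inf)
  f <- function(lt) .g1_values(medium, geometry, flow$bfi, 10^lt) - exp(-1)
  10^stats::uniroot(f, c(-12, 2), tol = 1e-10)$root
}
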