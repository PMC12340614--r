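---
title: "Models and methods for diffuse speckle flowmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diffuse speckle flowmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(speckleflow)
```

# The physical model

Coherent light diffusing through a turbid medium (tissue, a microsphere
suspension) acquires intensity fluctuations from moving scatterers — red
blood cells in vivo, Brownian microspheres in phantoms. All three
modalities in this package infer the *blood flow index* BFi = αDb, the
product of the moving-scatterer fraction α and an effective Brownian
diffusion coefficient Db (cm²/s), from those fluctuations; BFi has been
shown repeatedly to be proportional to perfusion.

The common theory layer is the correlation diffusion equation for the
electric-field temporal autocorrelation G1(τ). For a semi-infinite
homogeneous medium with source–detector separation ρ on the surface, the
solution is the image-source form

    G1(τ) ∝ exp(-K(τ) r1)/r1 - exp(-K(τ) r2)/r2,
    K(τ) = sqrt( 3 μa (μa + μs') + 6 (μa + μs') μs' k0² αDb τ ),

with z0 = 1/μs', an extrapolated boundary at zb = 2(1+Reff)/(3 μs'(1-Reff)),
r1 = sqrt(ρ² + z0²), r2 = sqrt(ρ² + (z0 + 2 zb)²), and k0 = 2π n/λ. The
dispersion argument K must carry units of 1/length to exponentiate
distances, hence the square root. `Reff` is the standard diffuse-optics
polynomial approximation in the index ratio (and can be overridden in
`semi_infinite_geometry()`).

Each modality connects to g1(τ) = G1(τ)/G1(0) differently:

* **DCS** measures the intensity autocorrelation of one speckle per photon
  counter and uses the Siegert relation g2 = 1 + β|g1|². β (source
  coherence, polarization, speckle sampling) is calibrated once per session
  by a joint (β, BFi) fit to the time-averaged curve and then frozen.
* **iDWS** mixes the weak diffuse field with a strong reference beam on a
  fast line camera; the autocorrelation of the mean-subtracted intensity is
  directly proportional to Re g1 (heterodyne gain 2√(IR·IS)). An amplitude
  parameter A absorbs the unknown coupling (including the coherence
  prefactor), so iDWS fits two parameters (A, BFi).
* **SCOS** integrates the speckle pattern over a camera exposure T and uses
  the spatial contrast κ² = σ²/μ² of 7×7 pixel windows, linked to the CDE by
  κ² = (2β/T)∫₀ᵀ |g1(τ)|² (1−τ/T) dτ. βSCOS is not identifiable from a
  single exposure, so SCOS output is flagged *relative* (or rescaled to a
  reference, as in phantom mode).

# Units and defaults

Lengths are cm, times seconds, Db and BFi cm²/s; wavelengths are entered in
nm and converted internally; temperatures are accepted in K or °C with an
explicit flag. Defaults follow the reference setup: λ = 785 nm, ρ = 2.5 cm,
assumed in-vivo properties μa = 0.1 cm⁻¹ and μs' = 6 cm⁻¹ (phantom:
0.104 and 6.30 cm⁻¹), camera gain 9.64 counts/photoelectron, 1 ms SCOS
exposure at 120 Hz, 3 μs line-scan sampling with a 0.1 s rolling mean and a
spatial Gaussian of σ = 0.9669 px (peak 1), 0.05 s correlator windows
(20 Hz output), and 195 nm microspheres (radius 97.5 nm) for the phantom
ground truth via Stokes–Einstein and Vogel's viscosity equation.

# Numerical choices

* **Contrast integral.** The exposure integral is evaluated by composite
  Simpson quadrature (quadratic through consecutive node triples) on 2048
  log-spaced nodes plus the origin, with a doubled-node convergence check
  at 1e-8 relative. |g1|² decays fastest near τ = 0, which the log grid
  resolves; against the exponential-g1 closed form the quadrature agrees to
  better than 1e-6 relative.
* **Correlators.** Both the DCS correlator and the iDWS Wiener–Khinchin
  autocorrelation are computed with zero-padded FFTs, which makes them
  *exactly* the linear (non-circular) lag-sum estimators up to float
  roundoff; the test suite pins them to a direct O(N·L) summation oracle at
  1e-10 relative. The DCS lag grid is multi-tau style (log-spaced, 16 lags
  per octave, first lag one bin); lags beyond a quarter window are dropped
  as unusably noisy.
* **Fits.** All model fits are scalar profile optimizations: the linear
  parameter (β for DCS calibration, A² for iDWS, none for SCOS) is profiled
  in closed form given BFi, and BFi is optimized over log10 BFi ∈ [−12, −4]
  by a coarse grid scan followed by golden-section refinement. The g2 fit
  range keeps lags whose amplitude exceeds three times the late-lag noise
  floor (all lags for noise-free curves); the iDWS sum runs to the first
  delay at which the measured normalized correlation goes negative — the
  theoretical g1 of this geometry is strictly positive, so the rule can
  only refer to the measured curve. The iDWS default fits the *squared*
  correlation: under the pipeline's correlated noise this roughly halves
  the variance of recovered BFi relative to the linear fit (the test suite
  demonstrates this on simulated records; independent Gaussian noise added
  directly to a curve does *not* reproduce the effect, which is why the
  comparison is run through the full pipeline).
* **SCOS inversion.** κ²(BFi) is strictly decreasing, so the inversion is a
  bisection root-find on log10 BFi. Windows with κf² ≤ 0 or ≥ β are marked
  invalid and never fitted; the per-window noise decomposition identity
  κMeas² = κf² + κRead² + κShot² + κQuant² + κSpatial² holds exactly by
  construction. Window variance uses the unbiased (n−1) convention.

# The synthetic-data generator

No experimental recordings are distributed, so every pipeline is validated
by parameter recovery from detector-level synthetic records whose
statistics follow the forward models.

* **Field synthesis.** `sample_correlated_field()` draws stationary
  circular complex Gaussian processes with a prescribed autocovariance by
  circulant spectral embedding: the symmetrized covariance is diagonalized
  by FFT, negative spectral mass is clipped (warning above 5%, error above
  20% — the target is then not realizable on that grid), and white complex
  Gaussian noise is filtered through the square-root spectrum. This was
  chosen over autoregressive approximations because the CDE g1 is
  non-exponential. Intensities are fully developed speckle
  (⟨I²⟩/⟨I⟩² = 2).
* **DCS records** apply Poisson photodetection to one speckle per channel
  (default rate 1e6 counts/s — high enough that shot noise is visible but
  not dominant; the reference instrument's photon budget is not published,
  so this is the package's choice).
* **iDWS records** blur the per-pixel fields to a spatial correlation HWHM
  of 1.5 px, add the heterodyne term ⟨IR⟩ + 2√(IR·IS)·Re E with a reference
  of 120 counts and sample level 2 counts, then apply Poisson shot noise,
  Gaussian read noise, and 8-bit quantization.
* **SCOS frames** integrate the speckle intensity over the exposure in
  discrete sub-steps (at least 10 per decorrelation time; the convergence
  of the discrete temporal factor to the continuous integral is better than
  0.3% at 192 sub-steps for the default in-vivo dynamics), blur to a
  speckle-to-pixel ratio of 2.3, and apply gain, Poisson, read, offset, and
  16-bit quantization. Because the simulated pixels *point-sample* a
  Gaussian-correlated field, the effective coherence of the windowed
  contrast is the closed-form `scos_effective_beta()` (≈ 0.92 at ratio 2.3
  with 7×7 windows) — the generator's analog of βSCOS.
* **Flow programs** encode the two study conditions: a cuff occlusion
  (1 min baseline with a mean-one harmonic cardiac waveform scaled to the
  configured pulsatility index, 2 min exponential occlusion decay, 2 min
  hyperemic recovery with an overshoot) and a 7→22 °C phantom ramp whose
  ground truth is Stokes–Einstein/Vogel. Time-varying flow is simulated
  piecewise-stationary: each 0.05 s analysis window or camera frame is
  generated at the program's instantaneous BFi. Statistics are imposed, not
  emergent: there is no physical-optics propagation, no motion artifact,
  and no layered-tissue heterogeneity, so passing recovery tests shows the
  *processing chains* are correct, not that real-tissue confounds are
  handled.

# What the end-to-end checks show

With record sizes scaled for a desk run (4 DCS channels × 1e5 bins, 64 iDWS
pixels × 0.5 s at 3 μs, 128×128 SCOS frames at 1 ms exposure), the median
recovered BFi over 20 seeded trials lands within 5% of the configured
1e-8 cm²/s for each modality. Two known small biases are documented rather
than corrected, because the reference analysis shares them: the contrast of
a 7×7 window holding ~9 independent speckles is a small-sample estimate
(≈3% low, inflating SCOS BFi by a similar amount), and the finite-frame
spatial-variance correction removes 1/n_avg of the speckle signal. The
simulated temperature ramp regenerates the Brownian ground truth with
regression slope within [0.95, 1.05] and r > 0.98 in a low-noise
configuration (4e6 counts/s DCS over 3.5 s per point — the four-speckle
correlator needs far more integration time than the parallel detectors for
comparable precision — iDWS sample level 4 over 0.25 s, SCOS flux 400
photoelectrons over twenty-four 96×96 frames at 0.5 ms exposure, with the
SCOS scale anchored to theory over the two warmest points, the analog of
normalizing on the final minute of a ramp), and repeated noisy acquisitions
of equal duration show the expected dispersion ordering — the four-speckle
DCS spreads most, the highly parallel detectors least.

```{r example, eval = FALSE}
med <- optical_medium(mua = 0.104, musp = 6.30)
geo <- semi_infinite_geometry(rho = 2.5, med)
out <- run_scenario(scenario_config("phantom_ramp", seed = 7))
out$comparison
```

# Known limitations

* Absolute SCOS flow requires an externally supplied coherence parameter;
  outputs carry a `"relative"`/`"rescaled"` flag accordingly.
* The beat detector assumes a dominant cardiac line between 0.5 and 3 Hz
  and at least 4 samples per cardiac cycle; its sub-sample peak refinement
  presumes a locally smooth (parabolic) systolic peak.
* Rolling-mean edges (half a window at each end of an iDWS record) are
  excluded from segments rather than extrapolated; segments are
  non-overlapping consecutive 0.05 s blocks.
* The cuff and ramp simulations share one seed-splitting rule
  (`stage_seed()`); reproducibility is bit-exact only for identical record
  sizes and R versions (RNG stream layout).
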