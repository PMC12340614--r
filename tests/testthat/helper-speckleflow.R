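# Shared fixtures and independent oracles for the test suite.

# Assumed in-vivo optical properties (mua = 0.1, musp = 6 1/cm, 785 nm)
vivo_medium <- function() optical_medium(0.1, 6.0)

# Microsphere-phantom properties recovered by frequency-domain spectroscopy
phantom_medium <- function() optical_medium(0.104, 6.30)

std_geometry <- function(medium) semi_infinite_geometry(2.5, medium)

# Direct O(N * L) lag-sum oracle for the normalized intensity
# autocorrelation g2(k) = <I(t) I(t+k)> / <I>^2 (same-pair normalization as
# the FFT correlator).
direct_g2_oracle <- function(x, lags) {
  n <- length(x)
  mu <- mean(x)
  vapply(lags, function(k) {
    mean(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / mu^2
  }, numeric(1))
}

# Direct lag-sum oracle for unnormalized autocorrelation sums
# ac(k) = sum_t x(t) x(t+k).
direct_acsum_oracle <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k])
  }, numeric(1))
}

# Noise-free g2 curve from the CDE model on a log tau grid.
model_g2_curve <- function(medium, geometry, bfi, beta,
                           tau = 10^seq(-6.5, -3, length.out = 50)) {
  g1 <- g1_semi_infinite(medium, geometry, flow_params(bfi = bfi), tau)
  siegert_g2(g1, beta)
}
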