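# Independent oracles and shared fixtures for the test suite.
# Oracles are coded from the defining formulas with explicit real/imaginary
# algebra, deliberately not reusing the package's code paths.

# total admittance 1/(2*Zp + Zs) via hand-written real/imag arithmetic
oracle_total_admittance <- function(Rp, Cp, Rs, Cs, omega) {
  # Zp = Rp - j/(omega*Cp)
  zp_re <- Rp
  zp_im <- if (is.infinite(Cp)) 0 else -1 / (omega * Cp)
  # Zs = Rs/(1 + (w Rs Cs)^2) - j * w Rs^2 Cs / (1 + (w Rs Cs)^2)
  if (is.infinite(Cs)) {
    zs_re <- 0; zs_im <- 0
  } else {
    d <- 1 + (omega * Rs * Cs)^2
    zs_re <- Rs / d
    zs_im <- -omega * Rs^2 * Cs / d
  }
  zre <- 2 * zp_re + zs_re
  zim <- 2 * zp_im + zs_im
  den <- zre^2 + zim^2
  c(G = zre / den, B = -zim / den)
}

# ordinary least squares by the normal equations
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Pearson correlation from the textbook formula
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# printed reference coefficient sets, typed here independently of the
# shipped JSON so the fixture file is cross-checked by the tests
ref_quadratic <- list(
  "5000_quadrature"  = c(-0.169, 0.438, 0.016, 0.519, 0.025),
  "5000_in_phase"    = c(0.684, 1.604, -0.120, 1.816, -0.117),
  "10000_quadrature" = c(-0.08, 0.236, 0.020, 0.309, 0.023),
  "10000_in_phase"   = c(0.367, 1.275, -0.083, 1.503, -0.089))
ref_linear <- list(
  "5000_quadrature"  = c(-0.246, 0.502, 0, 0.62, 0),
  "5000_in_phase"    = c(1.143, 1.110, 0, 1.333, 0),
  "10000_quadrature" = c(-0.163, 0.318, 0, 0.405, 0),
  "10000_in_phase"   = c(0.7, 0.932, 0, 1.137, 0))

# noise-free responses at one concentration, as the estimator's input frame
make_responses <- function(cal, x1, x2, form = "quadratic") {
  grid <- expand.grid(freq_hz = c(5e3, 1e4),
                      channel = c("quadrature", "in_phase"),
                      stringsAsFactors = FALSE)
  grid$response_v <- vapply(seq_len(nrow(grid)), function(i) {
    predict(get_surface(cal, grid$freq_hz[i], grid$channel[i], form), x1, x2)
  }, 0)
  grid
}
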