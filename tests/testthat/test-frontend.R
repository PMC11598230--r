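test_that("phase-shift network is all-pass with the expected phase points", {
  # omega*R2*C -> 0 limit: gain -> -1 (phase pi)
  g0 <- ps_gain(ps_network(R2 = 1, C = 1e-12), omega = 1e-3)
  expect_equal(g0, -1 + 0i, tolerance = 1e-9)
  # omega*R2*C = 1: (j - 1)/(j + 1) = +j
  w <- 2 * pi * 5e3
  g1 <- ps_gain(ps_network(R2 = 1e4, C = 1 / (w * 1e4)), w)
  expect_equal(g1, 0 + 1i, tolerance = 1e-12)
  # unit magnitude everywhere
  set.seed(411)
  for (i in 1:100) {
    g <- ps_gain(ps_network(R2 = 10^runif(1, 1, 6), C = 10^runif(1, -12, -6)),
                 omega = 2 * pi * 10^runif(1, 1, 6))
    expect_equal(Mod(g), 1, tolerance = 1e-12)
  }
})

test_that("amplifier output follows the phasor transfer law", {
  y0 <- admittance(1e-5, 0, 5e3)
  fb <- feedback_config()  # 200 kOhm || 100 pF
  # balanced bridge
  expect_equal(amplifier_output(admittance_delta(0, 0), y0,
                                drive_config(theta = 0), fb), 0 + 0i)
  # zero mismatch: exactly -dY*U/Yf
  dY <- admittance_delta(2e-6, -1e-6)
  out <- amplifier_output(dY, y0, drive_config(theta = 0), fb)
  yf <- feedback_admittance(fb, 2 * pi * 5e3)
  expect_equal(out, -(2e-6 - 1e-6i) * 0.5 / yf, tolerance = 1e-12)
  # amplification factor |U/Yf| at 5 kHz:
  # |Yf| = |5e-6 + j*2*pi*5000*1e-10| = 5.905049e-6 S  =>  0.5/|Yf| = 84673.3
  expect_equal(0.5 / Mod(yf), 84673.3, tolerance = 1e-5)
})

test_that("amplifier output is linear in the admittance change", {
  y0 <- admittance(8e-6, 3e-6, 1e4)
  dr <- drive_config(theta = 0.03, frequency = 1e4)
  fb <- feedback_config()
  base <- amplifier_output(admittance_delta(0, 0), y0, dr, fb)
  u1 <- amplifier_output(admittance_delta(1e-6, 2e-6), y0, dr, fb) - base
  for (alpha in c(-2, 0.5, 3, 10)) {
    ua <- amplifier_output(admittance_delta(alpha * 1e-6, alpha * 2e-6),
                           y0, dr, fb) - base
    expect_equal(ua, alpha * u1, tolerance = 1e-12)
  }
})

test_that("reference subtraction removes the phase-mismatch bias exactly", {
  y0 <- admittance(1e-5, 4e-6, 5e3)
  fb <- feedback_config()
  dY <- admittance_delta(3e-6, 1.5e-6)
  norm0 <- NULL
  for (th in c(0, 0.01, 0.05)) {
    dr <- drive_config(theta = th)
    normalized <- amplifier_output(dY, y0, dr, fb) -
      amplifier_output(admittance_delta(0, 0), y0, dr, fb)
    if (is.null(norm0)) norm0 <- normalized
    expect_identical(normalized, norm0)
  }
})

test_that("mismatch bias terms scale as theta^2/2 in phase and theta in quadrature", {
  y0 <- admittance(1e-5, 0, 5e3)
  b0 <- bias_terms(y0, 0)
  expect_identical(c(b0$dG, b0$dB), c(0, 0))
  b <- bias_terms(y0, 0.01)
  expect_equal(b$dG, 5e-10, tolerance = 1e-12)
  expect_equal(b$dB, 1e-7, tolerance = 1e-12)
  # parity: even in theta for the in-phase part, odd for the quadrature part
  bn <- bias_terms(y0, -0.01)
  expect_equal(bn$dG, b$dG)
  expect_equal(bn$dB, -b$dB)
})

test_that("waveform synthesis renders the phasor convention exactly", {
  wf <- synthesize_waveform(1 + 0i, 5e3, 1e6, n_cycles = 1)
  expect_length(wf$samples, 200)
  expect_equal(wf$samples[1], 0)
  expect_equal(max(wf$samples), 1, tolerance = 1e-4)
  wf0 <- synthesize_waveform(0 + 0i, 5e3, 1e6, n_cycles = 3)
  expect_true(all(wf0$samples == 0))
  expect_error(synthesize_waveform(1, 1e5, 1e6), "sampling_rate")
  expect_error(synthesize_waveform(1, 5e3, 1e6, n_cycles = 1.5), "n_cycles")
})

test_that("synthesize then detect is the identity on phasors", {
  set.seed(412)
  for (f in c(5e3, 1e4)) {
    for (i in 1:25) {
      ph <- complex(real = runif(1, -2, 2), imaginary = runif(1, -2, 2))
      wf <- synthesize_waveform(ph, f, 1e6, n_cycles = 10)
      iq <- coherent_detect(wf)
      expect_equal(iq[["I"]], Re(ph), tolerance = 1e-9)
      expect_equal(iq[["Q"]], Im(ph), tolerance = 1e-9)
    }
  }
  # convention anchors: sine -> I, cosine -> Q
  iq <- coherent_detect(synthesize_waveform(1.5 + 0i, 5e3, 1e6, 2))
  expect_equal(iq, c(I = 1.5, Q = 0), tolerance = 1e-9)
  iq <- coherent_detect(synthesize_waveform(0 + 0.7i, 5e3, 1e6, 2))
  expect_equal(iq, c(I = 0, Q = 0.7), tolerance = 1e-9)
})

test_that("detection of noisy records is unbiased with variance 2*sigma^2/N", {
  set.seed(413)
  ph <- 0.8 - 0.3i
  sigma <- 0.01
  n_seeds <- 200
  wf <- synthesize_waveform(ph, 5e3, 1e6, n_cycles = 100)
  n <- length(wf$samples)
  iq <- matrix(0, n_seeds, 2)
  for (i in seq_len(n_seeds)) {
    noisy <- wf$samples + rnorm(n, 0, sigma)
    iq[i, ] <- coherent_detect(noisy, 5e3, 1e6)
  }
  se_theory <- sigma * sqrt(2 / n)
  # mean within 5 standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(iq[, 1]) - Re(ph)), 5 * se_theory / sqrt(n_seeds))
  expect_lt(abs(mean(iq[, 2]) - Im(ph)), 5 * se_theory / sqrt(n_seeds))
  # empirical scatter consistent with the predicted standard error
  expect_gt(sd(iq[, 1]) / se_theory, 0.8)
  expect_lt(sd(iq[, 1]) / se_theory, 1.2)
})

test_that("non-integer period counts are flagged as leakage", {
  s <- sin(2 * pi * 5e3 * (0:149) / 1e6)  # 0.75 periods
  expect_warning(coherent_detect(s, 5e3, 1e6), "leakage")
})
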