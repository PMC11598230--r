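cal <- reference_calibration()

test_that("linear initialization solves the two-frequency quadrature system", {
  lq <- list(get_surface(cal, 5e3, "quadrature", "linear"),
             get_surface(cal, 1e4, "quadrature", "linear"))
  # forward responses at (1, 1) mM are the coefficient sums: (0.876, 0.560)
  y <- c(predict(lq[[1]], 1, 1), predict(lq[[2]], 1, 1))
  expect_equal(y, c(0.876, 0.560), tolerance = 1e-12)
  li <- linear_init(lq, y)
  expect_equal(li$x, c(1, 1), tolerance = 1e-9)
  # responses at the intercepts recover deionized water
  li0 <- linear_init(lq, c(-0.246, -0.163))
  expect_equal(li0$x, c(0, 0), tolerance = 1e-9)
})

test_that("the shipped quadrature slope matrix is flagged as ill-conditioned", {
  lq <- list(get_surface(cal, 5e3, "quadrature", "linear"),
             get_surface(cal, 1e4, "quadrature", "linear"))
  li <- linear_init(lq, c(0.876, 0.560))
  # exact 2-norm condition number of [[0.502, 0.62], [0.318, 0.405]]
  expect_equal(li$condition_number, 146.587, tolerance = 1e-4)
  expect_true(li$condition_warning)
  # a well-conditioned synthetic pair does not warn
  good <- list(response_surface(c(0, 1, 0, 0.1, 0), 5e3, "quadrature", "linear"),
               response_surface(c(0, 0.1, 0, 1, 0), 1e4, "quadrature", "linear"))
  expect_false(linear_init(good, c(1, 1))$condition_warning)
  # exactly collinear slopes are a hard error pointing at the fallback
  sing <- list(response_surface(c(0, 0.5, 0, 0.6, 0), 5e3, "quadrature", "linear"),
               response_surface(c(0, 1.0, 0, 1.2, 0), 1e4, "quadrature", "linear"))
  expect_error(linear_init(sing, c(1, 1)), "least-squares")
})

test_that("augmented four-surface initialization is exact on linear data", {
  la <- list(get_surface(cal, 5e3, "quadrature", "linear"),
             get_surface(cal, 1e4, "quadrature", "linear"),
             get_surface(cal, 5e3, "in_phase", "linear"),
             get_surface(cal, 1e4, "in_phase", "linear"))
  y <- vapply(la, function(s) predict(s, 2.5, 1.5), 0)
  li <- linear_init(la, y)
  expect_equal(li$x, c(2.5, 1.5), tolerance = 1e-9)
})

test_that("Gauss-Newton refinement recovers concentrations from exact data", {
  qs <- lapply(c("5000_quadrature", "5000_in_phase",
                 "10000_quadrature", "10000_in_phase"),
               function(k) cal$quadratic[[k]])
  y <- vapply(qs, function(s) predict(s, 2, 3), 0)
  est <- newton_refine(qs, y, init = c(2.5, 2.5))
  expect_true(est$converged)
  expect_equal(c(est$x1_hat, est$x2_hat), c(2, 3), tolerance = 1e-6)
  # starting at the solution requires no iterations
  y0 <- vapply(qs, function(s) predict(s, 0, 0), 0)
  est0 <- newton_refine(qs, y0, init = c(0, 0))
  expect_identical(est0$iterations, 0L)
  expect_true(est0$converged)
  expect_error(newton_refine(qs, y, init = c(-1, 2)), "admissible box")
})

test_that("the full estimator is exact on noise-free forward data", {
  e <- estimate_concentrations(cal, make_responses(cal, 0.5, 0.5))
  expect_equal(c(e$x1_hat, e$x2_hat), c(0.5, 0.5), tolerance = 1e-6)
  # deionized-water reference responses estimate (0, 0)
  e0 <- estimate_concentrations(cal, make_responses(cal, 0, 0))
  expect_equal(c(e0$x1_hat, e0$x2_hat), c(0, 0), tolerance = 1e-6)
  # audit trail: the initial point and diagnostics travel with the result
  expect_length(e$init, 2)
  expect_true(is.finite(e$residual_norm))
  expect_true(e$converged)
})

test_that("noise-free recovery holds across the calibrated plane", {
  for (x1 in seq(0.5, 4, 0.5)) {
    for (x2 in seq(0.5, 4, 0.5)) {
      e <- estimate_concentrations(cal, make_responses(cal, x1, x2))
      expect_lt(max(abs(c(e$x1_hat - x1, e$x2_hat - x2))), 1e-6)
    }
  }
})

test_that("alternative refinement modes invert their own model families", {
  # quadrature mode: exactly-determined Newton-Raphson on two surfaces.
  # The two quadrature surfaces are nearly parallel, so this 2x2 system
  # can admit several exact roots; from a start near the truth the mode
  # recovers it, and any return value must solve the system.
  yq <- make_responses(cal, 1, 2)
  eq <- estimate_concentrations(cal, yq, mode = "quadrature",
                                init = c(1.2, 1.8))
  expect_equal(c(eq$x1_hat, eq$x2_hat), c(1, 2), tolerance = 1e-6)
  eq2 <- estimate_concentrations(cal, yq, mode = "quadrature")
  expect_lt(eq2$residual_norm, 1e-8)
  # mixed mode: linear quadrature + quadratic in-phase equations
  ym <- make_responses(cal, 1, 2)
  lin_rows <- ym$channel == "quadrature"
  ym$response_v[lin_rows] <- vapply(which(lin_rows), function(i) {
    predict(get_surface(cal, ym$freq_hz[i], "quadrature", "linear"), 1, 2)
  }, 0)
  em <- estimate_concentrations(cal, ym, mode = "mixed")
  expect_equal(c(em$x1_hat, em$x2_hat), c(1, 2), tolerance = 1e-6)
})

test_that("incomplete or single-frequency inputs are rejected informatively", {
  y <- make_responses(cal, 1, 1)
  expect_error(estimate_concentrations(cal, y[-2, ]), "missing channel")
  single <- calibration_set(
    quadratic = list(get_surface(cal, 5e3, "quadrature"),
                     get_surface(cal, 5e3, "in_phase")),
    linear = list(get_surface(cal, 5e3, "quadrature", "linear"),
                  get_surface(cal, 5e3, "in_phase", "linear")))
  expect_error(estimate_concentrations(single, y), "single-frequency")
})

test_that("single-channel quadratic inversion is ambiguous where the two-frequency estimator is not", {
  s5 <- get_surface(cal, 5e3, "in_phase")
  # the 5 kHz in-phase surface peaks inside the admissible box, so a
  # response measured at 6 mM NaCl has a second admissible preimage
  y6 <- predict(s5, 6, 0)
  roots5 <- single_channel_roots(s5, y6, analyte = "NaCl", other = 0)
  expect_length(roots5, 2)
  expect_equal(min(roots5), 6, tolerance = 1e-9)
  # at 10 kHz the mirror root falls outside the box
  s10 <- get_surface(cal, 1e4, "in_phase")
  expect_length(single_channel_roots(s10, predict(s10, 6, 0), "NaCl"), 1)
  # the two-frequency estimator resolves the same sample uniquely
  e <- estimate_concentrations(cal, make_responses(cal, 6, 0))
  expect_equal(c(e$x1_hat, e$x2_hat), c(6, 0), tolerance = 1e-6)
})

test_that("linear initialization reduces the refinement work when its model holds", {
  # The initialization advantage is a statement about the workflow in which
  # the linear surfaces describe the data (they are fits of the same
  # responses): there the closed-form start is essentially exact and the
  # refinement converges immediately, whereas a midpoint start must iterate.
  cfg <- generator_config(noise_sigma = 0, replicates = 1,
                          truth_form = "linear")
  cal2 <- fit_calibration(simulate_measurements(cfg))
  qs2 <- lapply(c("5000_quadrature", "5000_in_phase",
                  "10000_quadrature", "10000_in_phase"),
                function(k) cal2$quadratic[[k]])
  lq2 <- list(get_surface(cal2, 5e3, "quadrature", "linear"),
              get_surface(cal2, 1e4, "quadrature", "linear"))
  set.seed(432)
  it_lin2 <- it_mid2 <- numeric(50)
  for (i in 1:50) {
    x <- runif(2, 0.5, 4)
    y <- vapply(qs2, function(s) predict(s, x[1], x[2]), 0)
    li <- linear_init(lq2, y[c(1, 3)], cond_threshold = Inf)
    it_lin2[i] <- newton_refine(qs2, y, pmin(pmax(li$x, 0), 8))$iterations
    it_mid2[i] <- newton_refine(qs2, y, c(2, 2))$iterations
  }
  expect_lt(mean(it_lin2), mean(it_mid2))
})

test_that("estimation error shrinks with the measurement noise", {
  yt <- make_responses(cal, 2, 3)
  set.seed(433)
  rmse <- vapply(c(0.1, 0.01), function(sg) {
    errs <- replicate(60, {
      y <- yt
      y$response_v <- y$response_v + rnorm(4, 0, sg)
      e <- estimate_concentrations(cal, y)
      c(e$x1_hat - 2, e$x2_hat - 3)
    })
    sqrt(mean(errs^2))
  }, 0)
  expect_lt(rmse[2], rmse[1])
})
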