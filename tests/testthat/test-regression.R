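test_that("surface prediction evaluates the calibrated polynomial", {
  s <- response_surface(ref_quadratic[["5000_quadrature"]], 5e3, "quadrature")
  expect_equal(predict(s, 0, 0), -0.169)
  # at (1,1) the prediction is the sum of the five coefficients
  expect_equal(predict(s, 1, 1), 0.829, tolerance = 1e-12)
  lin <- response_surface(ref_linear[["5000_quadrature"]], 5e3, "quadrature",
                          form = "linear")
  expect_equal(predict(lin, 2, 2), 1.998, tolerance = 1e-12)
  expect_error(predict(s, -1, 0), ">= 0")
  expect_error(response_surface(c(1, 2, 3, 4, 5), 5e3, "quadrature",
                                form = "linear"), "alpha2")
})

test_that("fitting noise-free data reproduces the generating coefficients", {
  # refit closure for every shipped quadratic and linear coefficient set
  for (form in c("quadratic", "linear")) {
    cfg <- generator_config(grid = seq(0, 4, 0.5), replicates = 1,
                            noise_sigma = 0, truth_form = form)
    df <- simulate_measurements(cfg)
    ref <- if (form == "quadratic") ref_quadratic else ref_linear
    for (key in names(ref)) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      f <- as.numeric(parts[1])
      ch <- paste(parts[-1], collapse = "_")
      fit <- fit_response_surface(df, f, ch, form = form)
      expect_equal(unname(coef(fit)), ref[[key]], tolerance = 1e-8)
      expect_equal(fit$R, 1, tolerance = 1e-9)
    }
  }
})

test_that("constant responses fit as a pure intercept", {
  df <- expand.grid(x1_mM = 0:4, x2_mM = 0:4)
  df$freq_hz <- 5e3
  df$channel <- "in_phase"
  df$response_v <- 0.42
  fit <- fit_response_surface(df, 5e3, "in_phase")
  expect_equal(unname(coef(fit)), c(0.42, 0, 0, 0, 0), tolerance = 1e-10)
})

test_that("noisy fits agree with the hand-coded normal-equations oracle", {
  set.seed(421)
  cfg <- generator_config(grid = seq(0.5, 4, 0.5), replicates = 3,
                          noise_sigma = 0.05, seed = 421)
  df <- simulate_measurements(cfg)
  sub <- df[df$freq_hz == 5e3 & df$channel == "quadrature", ]
  X <- cbind(1, sub$x1_mM, sub$x1_mM^2, sub$x2_mM, sub$x2_mM^2)
  fit <- fit_response_surface(df, 5e3, "quadrature")
  expect_equal(unname(coef(fit)), oracle_ols(X, sub$response_v),
               tolerance = 1e-10)
  # linear form drops the squared columns
  fitl <- fit_response_surface(df, 5e3, "quadrature", form = "linear")
  expect_equal(unname(coef(fitl))[c(1, 2, 4)],
               oracle_ols(X[, c(1, 2, 4)], sub$response_v), tolerance = 1e-10)
  expect_identical(unname(coef(fitl))[c(3, 5)], c(0, 0))
})

test_that("rank-deficient designs fail with the offending column named", {
  df <- data.frame(x1_mM = rep(0:4, 2), x2_mM = rep(0:4, 2), freq_hz = 5e3,
                   channel = "in_phase", response_v = rnorm(10))
  expect_error(fit_response_surface(df, 5e3, "in_phase"), "rank-deficient")
  # too few levels is caught before the solve
  df2 <- data.frame(x1_mM = c(0, 1, 2, 3), x2_mM = c(0, 0, 1, 1),
                    freq_hz = 5e3, channel = "in_phase",
                    response_v = rnorm(4))
  expect_error(fit_response_surface(df2, 5e3, "in_phase"), "levels")
})

test_that("fit diagnostics behave like a Pearson correlation", {
  set.seed(422)
  cfg <- generator_config(grid = seq(0.5, 4, 0.5), replicates = 2,
                          noise_sigma = 0.05, seed = 42)
  df <- simulate_measurements(cfg)
  s <- get_surface(reference_calibration(), 5e3, "quadrature")
  sub <- df[df$freq_hz == 5e3 & df$channel == "quadrature", ]
  pred <- predict(s, sub$x1_mM, sub$x2_mM)
  expect_equal(surface_correlation(s, df),
               oracle_pearson(pred, sub$response_v), tolerance = 1e-12)
  # perfect and perfectly anti-correlated cases
  df0 <- sub
  df0$response_v <- pred
  expect_equal(surface_correlation(s, df0), 1, tolerance = 1e-12)
  df0$response_v <- -pred
  expect_equal(surface_correlation(s, df0), -1, tolerance = 1e-12)
  # invariance under affine rescaling of the response
  df1 <- sub
  df1$response_v <- 3.7 * sub$response_v + 0.2
  expect_equal(surface_correlation(s, df1), surface_correlation(s, sub),
               tolerance = 1e-12)
  # degenerate input
  dfc <- sub
  dfc$response_v <- 1
  expect_error(surface_correlation(s, dfc), "zero variance")
})

test_that("linear quadrature surfaces increase strictly in each analyte", {
  for (key in c("5000_quadrature", "10000_quadrature")) {
    f <- as.numeric(strsplit(key, "_")[[1]][1])
    s <- response_surface(ref_linear[[key]], f, "quadrature", form = "linear")
    x <- seq(0, 4, 0.1)
    expect_true(all(diff(predict(s, x, 0)) > 0))
    expect_true(all(diff(predict(s, 0, x)) > 0))
  }
})

test_that("linear-form fits ignore redundant replicate copies", {
  cfg <- generator_config(grid = c(0, 1, 2, 3), replicates = 1,
                          noise_sigma = 0, truth_form = "linear")
  df <- simulate_measurements(cfg)
  fit1 <- fit_response_surface(df, 1e4, "in_phase", form = "linear")
  df2 <- rbind(df, df, df)
  fit2 <- fit_response_surface(df2, 1e4, "in_phase", form = "linear")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)
})

test_that("the optional interaction term is recovered when enabled", {
  grid <- expand.grid(x1_mM = seq(0, 4, 1), x2_mM = seq(0, 4, 1))
  truth <- c(0.1, 0.5, -0.02, 0.7, -0.03, 0.15)
  df <- data.frame(grid, freq_hz = 5e3, channel = "in_phase",
                   response_v = truth[1] + truth[2] * grid$x1_mM +
                     truth[3] * grid$x1_mM^2 + truth[4] * grid$x2_mM +
                     truth[5] * grid$x2_mM^2 +
                     truth[6] * grid$x1_mM * grid$x2_mM)
  fit <- fit_response_surface(df, 5e3, "in_phase", interaction = TRUE)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-8)
  # default design has no cross term
  fit0 <- fit_response_surface(df, 5e3, "in_phase")
  expect_length(coef(fit0), 5)
})
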