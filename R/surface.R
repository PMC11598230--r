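#' Construct a concentration-response surface from known coefficients
#'
#' A response surface maps the two electrolyte concentrations
#' (`x1` = NaCl, `x2` = KCl, both in mM) to one normalized sensor response
#' (deionized-water-referenced, volts) for one working frequency and one
#' detection channel:
#' \deqn{V = \alpha_0 + \alpha_1 x_1 + \alpha_2 x_1^2 + \alpha_3 x_2 + \alpha_4 x_2^2}
#' The linear form is the special case `alpha2 = alpha4 = 0`. There is no
#' cross term by default; see `interaction` in [fit_response_surface()].
#'
#' @param alpha Numeric vector of the five coefficients
#'   `(alpha0, alpha1, alpha2, alpha3, alpha4)`, in response units per mM
#'   power. For `form = "linear"`, `alpha2` and `alpha4` must be exactly 0.
#' @param frequency Working frequency in Hz.
#' @param channel `"in_phase"` or `"quadrature"`.
#' @param form `"quadratic"` or `"linear"`.
#' @param R Optional Pearson correlation of fitted vs observed responses
#'   (populated by [fit_response_surface()]).
#' @return An object of class `"response_surface"`.
#' @seealso [fit_response_surface()], [predict.response_surface()]
#' @examples
#' s <- response_surface(c(-0.169, 0.438, 0.016, 0.519, 0.025),
#'                       frequency = 5e3, channel = "quadrature")
#' predict(s, x1 = 1, x2 = 1)
#' @export
response_surface <- function(alpha, frequency, channel,
                             form = c("quadratic", "linear"), R = NULL) {
  form <- match.arg(form)
  channel <- match.arg(channel, c("in_phase", "quadrature"))
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  if (length(alpha) == 5L) {
    names(alpha) <- c("a0", "a1", "a2", "a3", "a4")
  } else if (length(alpha) == 6L) {
    names(alpha) <- c("a0", "a1", "a2", "a3", "a4", "a5")
  } else {
    stop("`alpha` must have 5 coefficients (6 with the interaction term)",
         call. = FALSE)
  }
  if (form == "linear" && (alpha[["a2"]] != 0 || alpha[["a4"]] != 0)) {
    stop("linear form requires alpha2 = alpha4 = 0", call. = FALSE)
  }
  check_frequency(frequency)
  if (!is.null(R)) {
    stopifnot(is.numeric(R), length(R) == 1L, R >= -1, R <= 1)
  }
  structure(list(alpha = alpha, frequency = as.numeric(frequency),
                 channel = channel, form = form, R = R),
            class = "response_surface")
}

#' Fit a response surface to measurement records
#'
#' Ordinary least squares over the design `[1, x1, x1^2, x2, x2^2]`
#' (the squared columns are dropped for `form = "linear"`), restricted to
#' the records at the requested frequency and channel. The fit is
#' unweighted; the Pearson correlation between fitted and observed
#' responses is stored as the `R` diagnostic.
#'
#' @param data A data frame of measurement records with columns `x1_mM`,
#'   `x2_mM`, `freq_hz`, `channel`, `response_v` (the layout written by
#'   [simulate_measurements()] and [read_measurements()]).
#' @param frequency Working frequency (Hz) to fit.
#' @param channel Detection channel to fit, `"in_phase"` or `"quadrature"`.
#' @param form `"quadratic"` (needs >= 5 records with >= 3 distinct levels
#'   of each concentration) or `"linear"` (needs >= 3 records with >= 2
#'   distinct levels of each).
#' @param interaction If `TRUE`, adds an `x1*x2` cross term to the design
#'   (off by default; the standard surface has none).
#' @return A fitted [response_surface] with `R` populated; the underlying
#'   records, fitted values and residuals are attached for the `summary`
#'   and `residuals` methods.
#' @export
fit_response_surface <- function(data, frequency, channel,
                                 form = c("quadratic", "linear"),
                                 interaction = FALSE) {
  form <- match.arg(form)
  channel <- match.arg(channel, c("in_phase", "quadrature"))
  check_frequency(frequency)
  data <- check_measurement_frame(data)
  sub <- data[data$freq_hz == frequency & data$channel == channel, ,
              drop = FALSE]
  n <- nrow(sub)
  lev1 <- length(unique(sub$x1_mM))
  lev2 <- length(unique(sub$x2_mM))
  if (form == "quadratic" && (n < 5L || lev1 < 3L || lev2 < 3L)) {
    stop(sprintf(paste0(
      "quadratic fit needs >= 5 records with >= 3 distinct levels of each ",
      "concentration (got %d records, %d x1 levels, %d x2 levels)"),
      n, lev1, lev2), call. = FALSE)
  }
  if (form == "linear" && (n < 3L || lev1 < 2L || lev2 < 2L)) {
    stop(sprintf(paste0(
      "linear fit needs >= 3 records with >= 2 distinct levels of each ",
      "concentration (got %d records, %d x1 levels, %d x2 levels)"),
      n, lev1, lev2), call. = FALSE)
  }

  fml <- if (form == "quadratic") {
    response_v ~ x1_mM + I(x1_mM^2) + x2_mM + I(x2_mM^2)
  } else {
    response_v ~ x1_mM + x2_mM
  }
  if (interaction) fml <- stats::update(fml, . ~ . + I(x1_mM * x2_mM))
  fit <- stats::lm(fml, data = sub)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop(sprintf("rank-deficient design: column(s) %s are not estimable",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  alpha <- if (form == "quadratic") {
    c(cf[["(Intercept)"]], cf[["x1_mM"]], cf[["I(x1_mM^2)"]],
      cf[["x2_mM"]], cf[["I(x2_mM^2)"]])
  } else {
    c(cf[["(Intercept)"]], cf[["x1_mM"]], 0, cf[["x2_mM"]], 0)
  }
  if (interaction) alpha <- c(alpha, cf[["I(x1_mM * x2_mM)"]])

  fitted_v <- as.numeric(stats::fitted(fit))
  R <- if (stats::sd(fitted_v) > 0 && stats::sd(sub$response_v) > 0) {
    stats::cor(fitted_v, sub$response_v)
  } else if (all(abs(stats::residuals(fit)) < 1e-12)) 1 else NA_real_
  out <- response_surface(alpha, frequency, channel, form,
                          R = if (is.na(R)) NULL else R)
  attr(out, "records") <- sub
  attr(out, "fitted") <- fitted_v
  out
}

#' Predict normalized responses from a surface
#'
#' Evaluates the calibrated polynomial at given concentrations. `x1` and
#' `x2` are recycled to a common length; negative concentrations are a
#' domain error.
#'
#' @param object A [response_surface].
#' @param x1,x2 NaCl and KCl concentrations in mM (`>= 0`).
#' @param ... Unused.
#' @return Numeric vector of normalized responses (volts).
#' @export
predict.response_surface <- function(object, x1, x2, ...) {
  stopifnot(is.numeric(x1), is.numeric(x2))
  if (any(x1 < 0) || any(x2 < 0)) {
    stop("concentrations must be >= 0 mM", call. = FALSE)
  }
  k <- max(length(x1), length(x2))
  x1 <- rep_len(x1, k); x2 <- rep_len(x2, k)
  a <- object$alpha
  v <- a[["a0"]] + a[["a1"]] * x1 + a[["a2"]] * x1^2 +
    a[["a3"]] * x2 + a[["a4"]] * x2^2
  if (length(a) == 6L) v <- v + a[["a5"]] * x1 * x2
  v
}

#' Analytic gradient of a response surface
#'
#' Partial derivatives of the calibrated polynomial with respect to the two
#' concentrations, used as the Jacobian rows of the Gauss-Newton inversion.
#'
#' @param object A [response_surface].
#' @param x1,x2 Concentrations in mM.
#' @return Numeric vector `c(dV/dx1, dV/dx2)` in response units per mM.
#' @export
surface_gradient <- function(object, x1, x2) {
  stopifnot(inherits(object, "response_surface"))
  a <- object$alpha
  g <- c(a[["a1"]] + 2 * a[["a2"]] * x1, a[["a3"]] + 2 * a[["a4"]] * x2)
  if (length(a) == 6L) g <- g + a[["a5"]] * c(x2, x1)
  g
}

#' Pearson correlation between surface predictions and observations
#'
#' The fit diagnostic reported alongside each coefficient set: the Pearson
#' correlation between the responses predicted by the surface and the
#' observed responses. It equals 1 for a perfect fit and is invariant to
#' affine rescaling of the response.
#'
#' @param object A [response_surface].
#' @param data Measurement records (same layout as in
#'   [fit_response_surface()]); only rows matching the surface's frequency
#'   and channel are used.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
surface_correlation <- function(object, data) {
  stopifnot(inherits(object, "response_surface"))
  data <- check_measurement_frame(data)
  sub <- data[data$freq_hz == object$frequency &
                data$channel == object$channel, , drop = FALSE]
  if (nrow(sub) < 3L) stop("need >= 3 matching records", call. = FALSE)
  pred <- predict(object, sub$x1_mM, sub$x2_mM)
  if (stats::sd(pred) == 0 || stats::sd(sub$response_v) == 0) {
    stop("correlation undefined: zero variance in predictions or observations",
         call. = FALSE)
  }
  stats::cor(pred, sub$response_v)
}

#' @export
coef.response_surface <- function(object, ...) object$alpha

#' @export
residuals.response_surface <- function(object, ...) {
  rec <- attr(object, "records")
  if (is.null(rec)) {
    stop("surface was not fitted to data: no residuals available",
         call. = FALSE)
  }
  rec$response_v - attr(object, "fitted")
}

#' @export
print.response_surface <- function(x, digits = 3, ...) {
  cat(sprintf("%s response surface, %g Hz, %s channel\n",
              x$form, x$frequency, x$channel))
  cat("  coefficients (a0, a1, a2, a3, a4",
      if (length(x$alpha) == 6L) ", a5" else "", "):\n", sep = "")
  cat("   ", paste(format(round(x$alpha, digits), nsmall = digits),
                   collapse = "  "), "\n")
  if (!is.null(x$R)) cat(sprintf("  R = %.3f\n", x$R))
  invisible(x)
}

#' @export
summary.response_surface <- function(object, ...) {
  rec <- attr(object, "records")
  out <- list(surface = object,
              n = if (is.null(rec)) 0L else nrow(rec),
              rmse = if (is.null(rec)) NA_real_ else
                sqrt(mean(residuals(object)^2)))
  class(out) <- "summary.response_surface"
  out
}

#' @export
print.summary.response_surface <- function(x, ...) {
  print(x$surface)
  if (x$n > 0) {
    cat(sprintf("  fitted to %d records, residual RMSE = %.4g\n", x$n, x$rmse))
  } else {
    cat("  constructed from known coefficients (no fit data attached)\n")
  }
  invisible(x)
}

# keys used to index surfaces inside a calibration set
surface_key <- function(frequency, channel) {
  paste0(format(frequency, scientific = FALSE, trim = TRUE), "_", channel)
}
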