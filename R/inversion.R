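#' Closed-form initialization from the linear quadrature surfaces
#'
#' With two working frequencies, the linear quadrature surfaces give two
#' equations linear in the two concentrations, so a direct solve yields an
#' estimate without iteration. The 2x2 slope matrix built from the shipped
#' reference coefficients is nearly singular (the quadrature response of
#' the device is almost equally sensitive to Na+ and K+), so the solve
#' monitors its 2-norm condition number and flags `condition_warning` above
#' `cond_threshold`. Supplying four linear surfaces (both channels at both
#' frequencies) with four responses instead solves the 4x2 system in the
#' least-squares sense, which is the recommended fallback when the warning
#' fires.
#'
#' @param models List of linear [response_surface] objects: either the two
#'   quadrature surfaces (one per frequency) or four surfaces covering both
#'   channels.
#' @param y Numeric vector of measured normalized responses, one per
#'   surface, in the same order as `models`.
#' @param cond_threshold Condition-number threshold above which
#'   `condition_warning` is set. Default 100, which the shipped reference
#'   quadrature pair (condition number about 147) exceeds.
#' @return List with `x` (the estimate, mM), `condition_number` and
#'   `condition_warning`.
#' @export
linear_init <- function(models, y, cond_threshold = 100) {
  stopifnot(is.list(models), length(models) %in% c(2L, 4L),
            is.numeric(y), length(y) == length(models))
  for (m in models) {
    stopifnot(inherits(m, "response_surface"))
    if (m$form != "linear") {
      stop("`linear_init` requires linear-form surfaces", call. = FALSE)
    }
  }
  A <- t(vapply(models, function(m) m$alpha[c("a1", "a3")], numeric(2)))
  b <- y - vapply(models, function(m) m$alpha[["a0"]], 0)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2] <= .Machine$double.eps * sv[1]) {
    stop(paste("singular slope matrix: the linear surfaces cannot separate",
               "the two concentrations; augment with the in-phase linear",
               "surfaces and use the 4x2 least-squares path"), call. = FALSE)
  }
  kappa <- sv[1] / sv[2]
  x <- qr.solve(A, b)
  list(x = as.numeric(x), condition_number = kappa,
       condition_warning = kappa > cond_threshold)
}

#' Gauss-Newton refinement of a concentration estimate
#'
#' Iteratively refines `(x1, x2)` against a set of calibrated surfaces by
#' minimizing the stacked residuals `r_k(x) = predict(model_k, x) - y_k`
#' in the least-squares sense, using the analytic Jacobian
#' `dr_k/dx_i = alpha_{1|3} + 2 * alpha_{2|4} * x_i`. With exactly two
#' surfaces this is plain Newton-Raphson on the 2x2 system. Iterates are
#' projected onto the admissible box `[0, xmax]^2`; a Levenberg-style
#' damped step is taken when the normal equations are singular at an
#' iterate. Iteration stops when the step norm falls below `tol_step`,
#' when the residual norm falls below `tol_resid`, when the gradient norm
#' `||J'r||` falls below `tol_grad` (a first-order stationarity check that
#' matters under measurement noise, where the residual floor is set by the
#' noise), or at `max_iter`.
#'
#' @param models List of [response_surface] objects (two or more).
#' @param y Measured normalized responses, one per surface.
#' @param init Length-2 starting point `(x1, x2)` in mM, inside the box.
#' @param xmax Upper edge of the admissible box in mM. Default 8 (twice
#'   the calibrated range); negative concentrations are never returned.
#' @param tol_step Step-norm stopping tolerance in mM. Default 1e-10.
#' @param tol_resid Residual-norm stopping tolerance. Default 1e-8.
#' @param tol_grad Gradient-norm stopping tolerance. Default 1e-12.
#' @param max_iter Maximum number of iterations. Default 50.
#' @return An object of class `"concentration_estimate"`; see
#'   [estimate_concentrations()] for the fields. Non-convergence is
#'   reported via `converged = FALSE`, never as an error.
#' @export
newton_refine <- function(models, y, init, xmax = 8, tol_step = 1e-10,
                          tol_resid = 1e-8, tol_grad = 1e-12,
                          max_iter = 50) {
  stopifnot(is.list(models), length(models) >= 2L,
            is.numeric(y), length(y) == length(models),
            is.numeric(init), length(init) == 2L, all(is.finite(init)))
  for (m in models) stopifnot(inherits(m, "response_surface"))
  if (any(init < 0) || any(init > xmax)) {
    stop(sprintf("`init` must lie inside the admissible box [0, %g]^2", xmax),
         call. = FALSE)
  }
  clip <- function(x) pmin(pmax(x, 0), xmax)
  resid_at <- function(x) {
    vapply(models, function(m) predict(m, x[1], x[2]), 0) - y
  }
  jac_at <- function(x) {
    t(vapply(models, function(m) surface_gradient(m, x[1], x[2]), numeric(2)))
  }

  x <- clip(init)
  r <- resid_at(x)
  converged <- sqrt(sum(r^2)) < tol_resid
  iterations <- 0L
  damping_failed <- FALSE
  lambda <- 0  # pure Gauss-Newton until a step fails to descend
  if (!converged) {
    for (k in seq_len(max_iter)) {
      J <- jac_at(x)
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      if (sqrt(sum(g^2)) < tol_grad) {
        converged <- TRUE
        break
      }
      # Levenberg-Marquardt step control: inflate the normal-equation
      # diagonal until the solve succeeds AND the (projected) step does
      # not increase the residual
      scale <- max(diag(JtJ), .Machine$double.eps)
      x_new <- NULL
      for (j in 1:40) {
        step <- tryCatch(
          as.numeric(solve(JtJ + lambda * diag(2), -g)),
          error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          cand <- clip(x + step)
          r_cand <- resid_at(cand)
          if (sum(r_cand^2) <= sum(r^2) || lambda > 1e12 * scale) {
            x_new <- cand
            r_new <- r_cand
            break
          }
        }
        # clamp from below so a long pure-GN run (lambda decayed towards 0)
        # re-enters the meaningful damping range immediately
        lambda <- if (lambda < 1e-8 * scale) 1e-8 * scale else lambda * 10
      }
      if (is.null(x_new)) {
        damping_failed <- TRUE
        iterations <- k
        break
      }
      lambda <- lambda / 10
      moved <- sqrt(sum((x_new - x)^2))
      x <- x_new
      r <- r_new
      iterations <- k
      if (moved < tol_step || sqrt(sum(r^2)) < tol_resid) {
        converged <- TRUE
        break
      }
    }
  }
  if (damping_failed) {
    stop("normal equations remained singular under damping", call. = FALSE)
  }
  structure(list(x1_hat = x[1], x2_hat = x[2],
                 init = clip(init),
                 iterations = iterations,
                 converged = converged,
                 residual_norm = sqrt(sum(r^2)),
                 condition_warning = FALSE,
                 box_warning = any(x <= 0 | x >= xmax) &&
                   sqrt(sum(r^2)) > tol_resid,
                 mode = NA_character_),
            class = "concentration_estimate")
}

#' Estimate mixed-electrolyte concentrations from measured responses
#'
#' The full two-frequency estimator: a closed-form solve of the linear
#' quadrature surfaces supplies the starting point ([linear_init]; when its
#' condition warning fires and the calibration carries linear in-phase
#' surfaces, the initialization is redone as a 4x2 least-squares solve over
#' all four linear surfaces), which is then refined by Gauss-Newton against
#' the quadratic surfaces ([newton_refine]). Using both frequencies removes
#' the root ambiguity a single-frequency quadratic inversion can exhibit
#' (see [single_channel_roots()]).
#'
#' @param cal An `admittance_calibration` covering both working frequencies
#'   and both channels (quadratic surfaces; linear surfaces required unless
#'   `init` is supplied).
#' @param responses Measured normalized responses: a data frame with
#'   columns `freq_hz`, `channel`, `response_v` (one row per channel), or a
#'   numeric vector named `"<frequency>_<channel>"`.
#' @param mode Which surfaces feed the refinement:
#'   `"quadratic"` (default) uses all four quadratic surfaces;
#'   `"mixed"` pairs the linear quadrature surfaces with the quadratic
#'   in-phase surfaces; `"quadrature"` uses only the two quadratic
#'   quadrature surfaces (an exactly-determined Newton-Raphson solve).
#' @param init Optional length-2 starting point overriding the linear
#'   initialization.
#' @param xmax,tol_step,tol_resid,max_iter Passed to [newton_refine()].
#' @param cond_threshold Passed to [linear_init()].
#' @param global_search The least-squares objective of the quadratic
#'   surfaces has a long, gently curved valley (the device is almost
#'   equally sensitive to both ions) and can hold spurious local minima,
#'   which a poorly conditioned initialization may select. With
#'   `global_search = TRUE` (default), whenever the refined residual norm
#'   stays above `retry_threshold` the estimator also refines from the
#'   best point of a coarse lattice over the admissible box and returns
#'   whichever result has the smaller residual.
#' @param retry_threshold Residual norm above which the lattice safeguard
#'   runs. Default 1e-7.
#' @return A `"concentration_estimate"`: list with `x1_hat`, `x2_hat` (mM),
#'   `init` (the audit copy of the starting point), `iterations`,
#'   `converged`, `residual_norm`, `condition_warning`, `box_warning` and
#'   `mode`.
#' @examples
#' cal <- reference_calibration()
#' y <- data.frame(
#'   freq_hz = c(5e3, 5e3, 1e4, 1e4),
#'   channel = c("quadrature", "in_phase", "quadrature", "in_phase"),
#'   response_v = c(predict(get_surface(cal, 5e3, "quadrature"), 2, 3),
#'                  predict(get_surface(cal, 5e3, "in_phase"), 2, 3),
#'                  predict(get_surface(cal, 1e4, "quadrature"), 2, 3),
#'                  predict(get_surface(cal, 1e4, "in_phase"), 2, 3)))
#' estimate_concentrations(cal, y)
#' @export
estimate_concentrations <- function(cal, responses,
                                    mode = c("quadratic", "mixed",
                                             "quadrature"),
                                    init = NULL, xmax = 8,
                                    tol_step = 1e-10, tol_resid = 1e-8,
                                    max_iter = 50, cond_threshold = 100,
                                    global_search = TRUE,
                                    retry_threshold = 1e-7) {
  stopifnot(inherits(cal, "admittance_calibration"))
  mode <- match.arg(mode)
  y <- as_response_vector(responses)
  cov <- calibration_coverage(cal)
  freqs <- cov$frequencies
  if (length(freqs) < 2L) {
    stop(paste("single-frequency calibration is not supported: one",
               "frequency can leave the two concentrations non-unique;",
               "provide surfaces at two working frequencies"), call. = FALSE)
  }
  needed <- as.vector(outer(freqs, c("quadrature", "in_phase"), surface_key))
  missing <- setdiff(needed, names(y))
  if (length(missing)) {
    stop(sprintf("responses are missing channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  cond_warn <- FALSE
  if (is.null(init)) {
    if (is.null(cal$linear)) {
      stop("calibration has no linear surfaces: supply `init` explicitly",
           call. = FALSE)
    }
    lin_q <- lapply(freqs, function(f) get_surface(cal, f, "quadrature", "linear"))
    li <- linear_init(lin_q,
                      y[vapply(freqs, surface_key, "", channel = "quadrature")],
                      cond_threshold = cond_threshold)
    cond_warn <- li$condition_warning
    if (cond_warn) {
      # ill-conditioned quadrature pair: fall back to the 4x2 solve over
      # all four linear surfaces
      keys <- c(vapply(freqs, surface_key, "", channel = "quadrature"),
                vapply(freqs, surface_key, "", channel = "in_phase"))
      lin_all <- c(lin_q,
                   lapply(freqs, function(f) get_surface(cal, f, "in_phase", "linear")))
      li <- linear_init(lin_all, y[keys], cond_threshold = cond_threshold)
      li$condition_warning <- TRUE
    }
    init <- pmin(pmax(li$x, 0), xmax)
  }

  models <- switch(mode,
    quadratic = {
      keys <- as.vector(outer(freqs, c("quadrature", "in_phase"), surface_key))
      lapply(keys, function(k) cal$quadratic[[k]])
    },
    mixed = c(
      lapply(freqs, function(f) get_surface(cal, f, "quadrature", "linear")),
      lapply(freqs, function(f) get_surface(cal, f, "in_phase", "quadratic"))),
    quadrature = lapply(freqs, function(f)
      get_surface(cal, f, "quadrature", "quadratic")))
  keys <- vapply(models, function(m) surface_key(m$frequency, m$channel), "")
  yk <- y[keys]
  est <- newton_refine(models, yk, init = init, xmax = xmax,
                       tol_step = tol_step, tol_resid = tol_resid,
                       max_iter = max_iter)
  if (global_search && est$residual_norm > retry_threshold) {
    start <- lattice_best_start(models, yk, xmax)
    est2 <- newton_refine(models, yk, init = start, xmax = xmax,
                          tol_step = tol_step, tol_resid = tol_resid,
                          max_iter = max_iter)
    if (est2$residual_norm < est$residual_norm) {
      est2$init <- est$init  # keep the audit trail of the primary init
      est <- est2
    }
  }
  est$condition_warning <- cond_warn
  est$mode <- mode
  est
}

# best point of a coarse lattice over the admissible box, by stacked
# squared residual (vectorized over the lattice; 0.25 mM steps)
lattice_best_start <- function(models, y, xmax) {
  g <- seq(0, xmax, by = 0.25)
  x1 <- rep(g, times = length(g))
  x2 <- rep(g, each = length(g))
  sq <- 0
  for (k in seq_along(models)) {
    sq <- sq + (predict(models[[k]], x1, x2) - y[k])^2
  }
  i <- which.min(sq)
  c(x1[i], x2[i])
}

#' @export
print.concentration_estimate <- function(x, digits = 4, ...) {
  cat("Mixed-electrolyte concentration estimate\n")
  cat(sprintf("  NaCl: %s mM   KCl: %s mM\n",
              format(x$x1_hat, digits = digits),
              format(x$x2_hat, digits = digits)))
  cat(sprintf("  init (%s, %s) mM -> %d iteration(s), %sconverged, residual %.3g\n",
              format(x$init[1], digits = digits),
              format(x$init[2], digits = digits),
              x$iterations, if (x$converged) "" else "NOT ", x$residual_norm))
  if (isTRUE(x$condition_warning)) {
    cat("  warning: ill-conditioned linear initialization (augmented solve used)\n")
  }
  if (isTRUE(x$box_warning)) {
    cat("  warning: estimate pinned to the admissible box\n")
  }
  if (!is.na(x$mode)) cat(sprintf("  refinement mode: %s\n", x$mode))
  invisible(x)
}

#' Admissible roots of a single-channel, single-analyte inversion
#'
#' With one frequency and one channel, a single-electrolyte concentration
#' solves the scalar quadratic
#' `alpha0 + alpha1*x + alpha2*x^2 (+ terms in the fixed other analyte) = y`,
#' which can admit two roots inside the admissible box `[0, xmax]` — the
#' non-uniqueness that motivates two-frequency measurement. This helper
#' enumerates those roots.
#'
#' @param object A [response_surface].
#' @param y Measured normalized response.
#' @param analyte Which concentration to solve for (`"NaCl"` = x1,
#'   `"KCl"` = x2).
#' @param other Fixed concentration of the other analyte in mM.
#' @param xmax Upper edge of the admissible box in mM.
#' @return Sorted numeric vector of admissible roots (possibly empty).
#' @export
single_channel_roots <- function(object, y, analyte = c("NaCl", "KCl"),
                                 other = 0, xmax = 8) {
  stopifnot(inherits(object, "response_surface"),
            is.numeric(y), length(y) == 1L,
            is.numeric(other), length(other) == 1L, other >= 0)
  analyte <- match.arg(analyte)
  a <- object$alpha
  if (length(a) == 6L && a[["a5"]] != 0 && other != 0) {
    stop("interaction surfaces are not supported here", call. = FALSE)
  }
  if (analyte == "NaCl") {
    c0 <- a[["a0"]] + a[["a3"]] * other + a[["a4"]] * other^2 - y
    c1 <- a[["a1"]]; c2 <- a[["a2"]]
  } else {
    c0 <- a[["a0"]] + a[["a1"]] * other + a[["a2"]] * other^2 - y
    c1 <- a[["a3"]]; c2 <- a[["a4"]]
  }
  roots <- if (c2 == 0) {
    if (c1 == 0) numeric(0) else -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) numeric(0) else (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  }
  sort(roots[roots >= 0 & roots <= xmax])
}

# Coerce measured responses into a vector named by surface key ---------------

as_response_vector <- function(responses) {
  if (is.data.frame(responses)) {
    need <- c("freq_hz", "channel", "response_v")
    miss <- setdiff(need, names(responses))
    if (length(miss)) {
      stop(sprintf("response frame is missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    y <- responses$response_v
    names(y) <- surface_key(responses$freq_hz, responses$channel)
    if (anyDuplicated(names(y))) {
      stop("duplicate (frequency, channel) rows in responses", call. = FALSE)
    }
    return(y)
  }
  if (is.numeric(responses) && !is.null(names(responses))) return(responses)
  stop(paste("`responses` must be a data frame with freq_hz/channel/response_v",
             "or a named numeric vector"), call. = FALSE)
}
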