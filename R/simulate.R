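#' Configuration of the synthetic measurement generator
#'
#' Describes a measurement campaign with the structure of the mixed
#' NaCl/KCl experiments the package models: a concentration grid per
#' analyte, a replicate count per solution, per-channel additive Gaussian
#' noise on the normalized responses, and a ground-truth calibration whose
#' surfaces generate the noise-free responses. Deionized water (0, 0) is
#' always measured as the normalization reference.
#'
#' @param grid Concentration levels per analyte in mM. Default
#'   `c(0, 0.5, 1, 2, 3, 4)`: the 0.5-4 mM range plus the deionized-water
#'   reference level.
#' @param replicates Samples prepared per solution. Default 5.
#' @param noise_sigma Per-channel Gaussian standard deviation of the
#'   normalized response, in response units. Default 0.02.
#' @param seed Integer RNG seed; a fixed seed makes the generated records
#'   identical across runs. `NULL` leaves the RNG state alone.
#' @param truth Ground-truth calibration (an `admittance_calibration`).
#'   Default: the shipped [reference_calibration()]. Its quadratic surfaces
#'   generate the responses unless `truth_form = "linear"`.
#' @param truth_form Which form of the truth calibration generates
#'   responses. Default `"quadratic"`.
#' @param mode `"mixed"` measures the full Cartesian grid of both analytes;
#'   `"single_NaCl"` / `"single_KCl"` sweep one analyte with the other held
#'   at zero.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(grid = c(0, 0.5, 1, 2, 3, 4), replicates = 5,
                             noise_sigma = 0.02, seed = NULL, truth = NULL,
                             truth_form = c("quadratic", "linear"),
                             mode = c("mixed", "single_NaCl", "single_KCl")) {
  mode <- match.arg(mode)
  truth_form <- match.arg(truth_form)
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(is.finite(grid)),
            is.numeric(replicates), length(replicates) == 1L,
            replicates >= 1, replicates == round(replicates),
            is.numeric(noise_sigma), length(noise_sigma) == 1L,
            is.finite(noise_sigma))
  if (any(grid < 0)) stop("grid concentrations must be >= 0 mM", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  }
  if (is.null(truth)) truth <- reference_calibration()
  stopifnot(inherits(truth, "admittance_calibration"))
  structure(list(grid = sort(unique(grid)), replicates = as.integer(replicates),
                 noise_sigma = noise_sigma,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 truth = truth, truth_form = truth_form, mode = mode),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic measurement design (%s):\n", x$mode))
  cat(sprintf("  grid: {%s} mM, %d replicate(s), noise sigma = %g\n",
              paste(x$grid, collapse = ", "), x$replicates, x$noise_sigma))
  cat(sprintf("  truth: %s surfaces at %s Hz, seed = %s\n", x$truth_form,
              paste(calibration_coverage(x$truth)$frequencies, collapse = "/"),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# concentration design points implied by a generator config
design_points <- function(cfg) {
  pts <- switch(cfg$mode,
    mixed = expand.grid(x1_mM = cfg$grid, x2_mM = cfg$grid,
                        KEEP.OUT.ATTRS = FALSE),
    single_NaCl = data.frame(x1_mM = cfg$grid, x2_mM = 0),
    single_KCl = data.frame(x1_mM = 0, x2_mM = cfg$grid))
  # deionized-water reference always present
  if (!any(pts$x1_mM == 0 & pts$x2_mM == 0)) {
    pts <- rbind(data.frame(x1_mM = 0, x2_mM = 0), pts)
  }
  pts[order(pts$x1_mM, pts$x2_mM), , drop = FALSE]
}

#' Generate synthetic measurement records
#'
#' For every design concentration, working frequency, channel and
#' replicate, draws
#' `response = predict(truth surface, x1, x2) + N(0, noise_sigma^2)`.
#' Responses are already in normalized (deionized-water-referenced) units
#' because the truth surfaces are; the (0, 0) reference rows are included
#' in the output like any other solution. With a fixed `seed` the output is
#' identical across runs.
#'
#' @param cfg A [generator_config].
#' @return A measurement data frame with columns `x1_mM`, `x2_mM`,
#'   `freq_hz`, `channel`, `response_v`, `replicate`.
#' @examples
#' cfg <- generator_config(grid = c(0, 1, 2), replicates = 2, seed = 7)
#' head(simulate_measurements(cfg))
#' @export
simulate_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pts <- design_points(cfg)
  cov <- calibration_coverage(cfg$truth)
  cells <- expand.grid(replicate = seq_len(cfg$replicates),
                       channel = c("in_phase", "quadrature"),
                       freq_hz = cov$frequencies,
                       point = seq_len(nrow(pts)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(x1_mM = pts$x1_mM[cells$point],
                   x2_mM = pts$x2_mM[cells$point],
                   freq_hz = cells$freq_hz,
                   channel = cells$channel,
                   response_v = NA_real_,
                   replicate = cells$replicate)
  for (f in cov$frequencies) {
    for (ch in c("in_phase", "quadrature")) {
      s <- get_surface(cfg$truth, f, ch, cfg$truth_form)
      idx <- df$freq_hz == f & df$channel == ch
      df$response_v[idx] <- predict(s, df$x1_mM[idx], df$x2_mM[idx])
    }
  }
  if (cfg$noise_sigma > 0) {
    df$response_v <- df$response_v + stats::rnorm(nrow(df), 0, cfg$noise_sigma)
  }
  rownames(df) <- NULL
  df
}

#' Generate a time-domain waveform dataset through the analog chain
#'
#' The second, end-to-end generation path: instead of drawing normalized
#' responses directly, each design point's response is converted to the
#' admittance change that would produce it, pushed through the
#' comparator-based amplifier ([amplifier_output()]) including the
#' configured phase mismatch, and rendered as a sampled waveform
#' ([synthesize_waveform()]). A clean reference (deionized water,
#' zero admittance change) waveform is included per frequency.
#' [detect_waveform_dataset()] demodulates the records and subtracts the
#' reference, reproducing the phasor-level dataset of
#' [simulate_measurements()].
#'
#' `cfg$noise_sigma` keeps its meaning on this path: sample noise with
#' standard deviation `noise_sigma * sqrt(N/2)` is added to each target
#' waveform (N samples), which makes the detected I/Q components scatter
#' with standard deviation `noise_sigma`.
#'
#' @param cfg A [generator_config].
#' @param drive A [drive_config] (its `frequency` field is overridden per
#'   working frequency).
#' @param fb A [feedback_config].
#' @param baseline A [circuit_params] whose [total_admittance()] serves as
#'   the balanced baseline admittance `Y0` at each frequency.
#' @param sampling_rate Samples per second. Default 1 MHz.
#' @param n_cycles Carrier periods per record. Default 100.
#' @return An object of class `"waveform_dataset"`: list with `records`
#'   (one entry per design point x frequency x replicate, each holding the
#'   concentrations and the waveform), `references` (per frequency) and the
#'   configuration echo.
#' @export
simulate_waveforms <- function(cfg, drive = drive_config(),
                               fb = feedback_config(),
                               baseline = circuit_params(),
                               sampling_rate = 1e6, n_cycles = 100) {
  stopifnot(inherits(cfg, "generator_config"), inherits(drive, "drive_config"),
            inherits(fb, "feedback_config"),
            inherits(baseline, "circuit_params"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pts <- design_points(cfg)
  freqs <- calibration_coverage(cfg$truth)$frequencies

  references <- list()
  for (f in freqs) {
    y0 <- total_admittance(baseline, 2 * pi * f)
    dr <- drive_config(U = drive$U, a = drive$a, theta = drive$theta,
                       frequency = f, amplitude_trim = drive$amplitude_trim)
    ph <- amplifier_output(admittance_delta(0, 0), y0, dr, fb)
    references[[surface_key(f, "reference")]] <-
      list(freq_hz = f, phasor = ph,
           waveform = synthesize_waveform(ph, f, sampling_rate, n_cycles))
  }

  records <- vector("list", nrow(pts) * length(freqs) * cfg$replicates)
  k <- 0L
  for (i in seq_len(nrow(pts))) {
    for (f in freqs) {
      y0 <- total_admittance(baseline, 2 * pi * f)
      dr <- drive_config(U = drive$U, a = drive$a, theta = drive$theta,
                         frequency = f, amplitude_trim = drive$amplitude_trim)
      yf <- feedback_admittance(fb, 2 * pi * f)
      vi <- predict(get_surface(cfg$truth, f, "in_phase", cfg$truth_form),
                    pts$x1_mM[i], pts$x2_mM[i])
      vq <- predict(get_surface(cfg$truth, f, "quadrature", cfg$truth_form),
                    pts$x1_mM[i], pts$x2_mM[i])
      # admittance change that yields the target normalized response:
      # Vnorm = -dY * U / Yf  =>  dY = -Vnorm * Yf / U
      dy <- -complex(real = vi, imaginary = vq) * yf / dr$U
      delta <- admittance_delta(Re(dy), Im(dy))
      ph <- amplifier_output(delta, y0, dr, fb)
      for (r in seq_len(cfg$replicates)) {
        wf <- synthesize_waveform(ph, f, sampling_rate, n_cycles)
        if (cfg$noise_sigma > 0) {
          n <- length(wf$samples)
          wf$samples <- wf$samples +
            stats::rnorm(n, 0, cfg$noise_sigma * sqrt(n / 2))
        }
        k <- k + 1L
        records[[k]] <- list(x1_mM = pts$x1_mM[i], x2_mM = pts$x2_mM[i],
                             freq_hz = f, replicate = r, waveform = wf)
      }
    }
  }
  structure(list(records = records, references = references,
                 drive = drive, feedback = fb, baseline = baseline,
                 config = cfg),
            class = "waveform_dataset")
}

#' @export
print.waveform_dataset <- function(x, ...) {
  cat(sprintf("Waveform dataset: %d records, %d reference(s), theta = %g rad\n",
              length(x$records), length(x$references), x$drive$theta))
  invisible(x)
}

#' Demodulate a waveform dataset into normalized measurement records
#'
#' Runs [coherent_detect()] on every record and on the per-frequency
#' deionized-water reference, subtracts the reference phasor, and maps the
#' difference back to normalized in-phase/quadrature responses. By the
#' structure of the amplifier output, the subtraction cancels the phase
#' mismatch bias exactly, so the result is independent of `theta`.
#'
#' @param wd A [simulate_waveforms()] result.
#' @return A measurement data frame in the layout of
#'   [simulate_measurements()].
#' @export
detect_waveform_dataset <- function(wd) {
  stopifnot(inherits(wd, "waveform_dataset"))
  ref_iq <- lapply(wd$references, function(r) coherent_detect(r$waveform))
  n <- length(wd$records)
  out <- data.frame(x1_mM = numeric(2 * n), x2_mM = numeric(2 * n),
                    freq_hz = numeric(2 * n), channel = character(2 * n),
                    response_v = numeric(2 * n), replicate = integer(2 * n))
  for (i in seq_len(n)) {
    rec <- wd$records[[i]]
    iq <- coherent_detect(rec$waveform)
    ref <- ref_iq[[surface_key(rec$freq_hz, "reference")]]
    dphasor <- complex(real = iq[["I"]] - ref[["I"]],
                       imaginary = iq[["Q"]] - ref[["Q"]])
    # Vnorm = Uout(target) - Uout(reference) = -dY * U / Yf = vi + j*vq
    rows <- c(2 * i - 1, 2 * i)
    out$x1_mM[rows] <- rec$x1_mM
    out$x2_mM[rows] <- rec$x2_mM
    out$freq_hz[rows] <- rec$freq_hz
    out$replicate[rows] <- rec$replicate
    out$channel[rows] <- c("in_phase", "quadrature")
    out$response_v[rows] <- c(Re(dphasor), Im(dphasor))
  }
  out
}
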