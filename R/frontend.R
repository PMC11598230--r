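#' Drive-signal configuration
#'
#' The signal generator produces the two-phase drive pair
#' `U*sin(omega*t)` and `a*U*sin(omega*t + pi - theta)`: a non-inverted
#' drive of amplitude `U` and an inverted drive of amplitude `a*U` whose
#' residual phase mismatch `theta` is trimmed by the phase-shift networks.
#' The analysis of the amplifier output assumes the small-mismatch regime,
#' so `|theta| < 0.2` rad is enforced.
#'
#' @param U Drive amplitude in volts (`> 0`). Default 0.5 V.
#' @param a Amplitude ratio of the inverted drive (`> 0`), set so that the
#'   reference admittance balances the target baseline (`Y0 = a*Y1`).
#' @param theta Residual phase mismatch in radians, `|theta| < 0.2`.
#' @param frequency Working frequency in Hz. Default 5 kHz.
#' @param amplitude_trim Dimensionless surrogate for the variable resistor
#'   that trims the inverted-drive amplitude; recorded for provenance, the
#'   phasor model consumes `a` directly.
#' @return An object of class `"drive_config"`.
#' @export
drive_config <- function(U = 0.5, a = 1, theta = 0, frequency = 5e3,
                         amplitude_trim = 1) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (U <= 0) stop("`U` must be positive (volts)", call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (abs(theta) >= 0.2) {
    stop("|theta| must be < 0.2 rad (small-mismatch regime)", call. = FALSE)
  }
  check_frequency(frequency)
  structure(list(U = U, a = a, theta = theta, frequency = frequency,
                 amplitude_trim = amplitude_trim),
            class = "drive_config")
}

#' Phase-shift network configuration
#'
#' First-order all-pass network used to trim the phase of each drive
#' signal: a variable resistance `R2` and a fixed capacitance `C`.
#'
#' @param R2 Phase-trim resistance in ohms (`> 0`).
#' @param C Phase-shift capacitance in farads (`> 0`).
#' @return An object of class `"ps_network"`.
#' @export
ps_network <- function(R2, C) {
  stopifnot(is.numeric(R2), length(R2) == 1L, is.finite(R2),
            is.numeric(C), length(C) == 1L, is.finite(C))
  if (R2 <= 0 || C <= 0) stop("`R2` and `C` must be positive", call. = FALSE)
  structure(list(R2 = R2, C = C), class = "ps_network")
}

#' Voltage gain of the phase-shift network
#'
#' Phasor transfer function of the first-order all-pass:
#' `Vo/Vi = (j*omega*R2*C - 1) / (j*omega*R2*C + 1)`.
#' Its magnitude is exactly 1 at every frequency; only the phase varies
#' (from pi at DC towards 0 at high frequency), which is what lets the
#' network null the drive phase mismatch without touching amplitudes.
#'
#' @param cfg A [ps_network] configuration.
#' @param omega Angular frequency in rad/s.
#' @return A complex dimensionless gain with `Mod(gain) == 1`.
#' @examples
#' g <- ps_gain(ps_network(R2 = 1e4, C = 1 / (2 * pi * 5e3 * 1e4)), 2 * pi * 5e3)
#' Mod(g)  # 1
#' @export
ps_gain <- function(cfg, omega) {
  stopifnot(inherits(cfg, "ps_network"))
  check_omega(omega)
  x <- complex(real = 0, imaginary = omega * cfg$R2 * cfg$C)
  (x - 1) / (x + 1)
}

#' Feedback network configuration
#'
#' Feedback admittance of the comparator-based amplifier: a resistance `Rf`
#' in parallel with a capacitance `Cf`, giving `Yf = 1/Rf + j*omega*Cf`.
#' Defaults are the prototype operating point (200 kOhm, 100 pF).
#'
#' @param Rf Feedback resistance in ohms (`> 0`).
#' @param Cf Feedback capacitance in farads (`>= 0`).
#' @return An object of class `"feedback_config"`.
#' @export
feedback_config <- function(Rf = 200e3, Cf = 100e-12) {
  stopifnot(is.numeric(Rf), length(Rf) == 1L, is.finite(Rf),
            is.numeric(Cf), length(Cf) == 1L, is.finite(Cf))
  if (Rf <= 0) stop("`Rf` must be positive", call. = FALSE)
  if (Cf < 0) stop("`Cf` must be >= 0", call. = FALSE)
  structure(list(Rf = Rf, Cf = Cf), class = "feedback_config")
}

#' Feedback admittance at a working frequency
#'
#' @param fb A [feedback_config].
#' @param omega Angular frequency in rad/s.
#' @return A complex admittance in siemens.
#' @export
feedback_admittance <- function(fb, omega) {
  stopifnot(inherits(fb, "feedback_config"))
  check_omega(omega)
  complex(real = 1 / fb$Rf, imaginary = omega * fb$Cf)
}

#' Admittance change between target and reference
#'
#' The amplifier responds to the difference `dY = dG + j*dB` between the
#' target admittance and the balanced baseline. Both components may be
#' negative.
#'
#' @param dG Conductance change in siemens.
#' @param dB Susceptance change in siemens.
#' @return An object of class `"admittance_delta"`.
#' @export
admittance_delta <- function(dG = 0, dB = 0) {
  stopifnot(is.numeric(dG), length(dG) == 1L, is.finite(dG),
            is.numeric(dB), length(dB) == 1L, is.finite(dB))
  structure(list(dG = dG, dB = dB), class = "admittance_delta")
}

#' @export
print.admittance_delta <- function(x, ...) {
  cat(sprintf("Admittance change: dG = %g S, dB = %g S\n", x$dG, x$dB))
  invisible(x)
}

#' Output phasor of the comparator-based amplifier
#'
#' With the two-phase drive balanced up to a small mismatch `theta`, the
#' differential transimpedance stage outputs
#' `Uout = -(dY + Y0*(theta^2/2 + j*theta)) * U / Yf`,
#' where `dY = dG + j*dB` is the target-vs-baseline admittance change,
#' `Y0` the (complex) baseline admittance and `Yf` the feedback admittance
#' at the working frequency. The output is linear in `dY` at fixed `theta`;
#' the `theta`-dependent terms are a fixed bias that the deionized-water
#' reference measurement removes.
#'
#' @param delta An [admittance_delta].
#' @param Y0 Baseline admittance, an [admittance] object (its `frequency`
#'   is taken as the working frequency).
#' @param drive A [drive_config].
#' @param fb A [feedback_config].
#' @return A complex output phasor in volts.
#' @examples
#' out <- amplifier_output(admittance_delta(1e-6, 0),
#'                         admittance(1e-5, 0, 5e3),
#'                         drive_config(), feedback_config())
#' Mod(out)  # about 8.5e4 V/S times 1e-6 S
#' @export
amplifier_output <- function(delta, Y0, drive = drive_config(),
                             fb = feedback_config()) {
  stopifnot(inherits(delta, "admittance_delta"), inherits(Y0, "admittance"),
            inherits(drive, "drive_config"), inherits(fb, "feedback_config"))
  omega <- 2 * pi * Y0$frequency
  yf <- feedback_admittance(fb, omega)
  if (Mod(yf) == 0) stop("feedback admittance is zero: output is singular",
                         call. = FALSE)
  dy <- complex(real = delta$dG, imaginary = delta$dB)
  th <- drive$theta
  y0 <- as.complex(Y0)
  # the dY term and the mismatch bias are scaled separately so that
  # subtracting a reference measurement cancels the bias exactly, not just
  # to rounding
  -dy * drive$U / yf - y0 * complex(real = th^2 / 2, imaginary = th) *
    drive$U / yf
}

#' Fixed mismatch bias of the amplifier output
#'
#' The residual drive phase mismatch `theta` adds the admittance-equivalent
#' bias `Y0 * (theta^2/2 + j*theta)` to the measured change. Referencing
#' every measurement against deionized water subtracts this bias exactly,
#' which is why normalized responses are independent of `theta`.
#'
#' @param Y0 Baseline admittance, an [admittance] object.
#' @param theta Phase mismatch in radians.
#' @return An [admittance_delta] holding the bias components (the in-phase
#'   part scales with `theta^2/2`, the quadrature part with `theta`).
#' @export
bias_terms <- function(Y0, theta) {
  stopifnot(inherits(Y0, "admittance"), is.numeric(theta),
            length(theta) == 1L, is.finite(theta))
  b <- as.complex(Y0) * complex(real = theta^2 / 2, imaginary = theta)
  admittance_delta(dG = Re(b), dB = Im(b))
}

#' Sample a phasor as a time-domain waveform
#'
#' Renders the sinusoid `|phasor| * sin(omega*t + Arg(phasor))` at a given
#' sampling rate over an exact integer number of periods, the record
#' structure coherent detection expects. Equivalently the waveform is
#' `I*sin(omega*t) + Q*cos(omega*t)` with `I = Re(phasor)`,
#' `Q = Im(phasor)` — the I/Q convention used throughout the package.
#'
#' @param phasor Complex amplitude in volts.
#' @param frequency Working frequency in Hz.
#' @param sampling_rate Samples per second; must be at least 20x the
#'   working frequency to stay comfortably clear of aliasing. Default 1 MHz.
#' @param n_cycles Positive integer number of periods to render.
#' @return An object of class `"waveform"`: list with `t` (seconds),
#'   `samples` (volts), `frequency` and `sampling_rate`.
#' @export
synthesize_waveform <- function(phasor, frequency, sampling_rate = 1e6,
                                n_cycles = 100) {
  stopifnot(length(phasor) == 1L, is.numeric(phasor) || is.complex(phasor))
  check_frequency(frequency)
  check_frequency(sampling_rate)
  if (sampling_rate < 20 * frequency) {
    stop("`sampling_rate` must be >= 20x `frequency`", call. = FALSE)
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L ||
      n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  }
  phasor <- as.complex(phasor)
  n <- round(n_cycles * sampling_rate / frequency)
  t <- (seq_len(n) - 1) / sampling_rate
  wt <- 2 * pi * frequency * t
  s <- Re(phasor) * sin(wt) + Im(phasor) * cos(wt)
  structure(list(t = t, samples = s, frequency = frequency,
                 sampling_rate = sampling_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples at %g Hz sampling, carrier %g Hz (%g cycles)\n",
              length(x$samples), x$sampling_rate, x$frequency,
              length(x$samples) * x$frequency / x$sampling_rate))
  invisible(x)
}

#' Coherent in-phase/quadrature detection
#'
#' Correlates a sampled record against reference sinusoids at the known
#' working frequency:
#' `I = (2/N) * sum(s[n] * sin(omega*t_n))`,
#' `Q = (2/N) * sum(s[n] * cos(omega*t_n))`.
#' For a clean sinusoid spanning an integer number of periods this returns
#' the rectangular components of its phasor exactly. I is the component in
#' phase with the non-inverted drive `sin(omega*t)`; Q leads it by 90
#' degrees. A non-integer period count leaves spectral leakage in the
#' estimates and raises a warning.
#'
#' @param waveform A [synthesize_waveform()] result, or a numeric vector of
#'   samples (then `frequency` and `sampling_rate` must be given).
#' @param frequency Working frequency in Hz (ignored for `"waveform"` input).
#' @param sampling_rate Samples per second (ignored for `"waveform"` input).
#' @return Named numeric vector `c(I = , Q = )` in volts.
#' @export
coherent_detect <- function(waveform, frequency = NULL, sampling_rate = NULL) {
  if (inherits(waveform, "waveform")) {
    s <- waveform$samples
    frequency <- waveform$frequency
    sampling_rate <- waveform$sampling_rate
  } else {
    s <- as.numeric(waveform)
    if (is.null(frequency) || is.null(sampling_rate)) {
      stop("`frequency` and `sampling_rate` are required for raw samples",
           call. = FALSE)
    }
  }
  check_frequency(frequency)
  check_frequency(sampling_rate)
  n <- length(s)
  cycles <- n * frequency / sampling_rate
  if (abs(cycles - round(cycles)) > 1e-8) {
    warning(sprintf(
      "record spans %.6g periods (not an integer): I/Q estimates carry leakage bias",
      cycles), call. = FALSE)
  }
  wt <- 2 * pi * frequency * (seq_len(n) - 1) / sampling_rate
  c(I = 2 * sum(s * sin(wt)) / n, Q = 2 * sum(s * cos(wt)) / n)
}
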