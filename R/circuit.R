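#' Lumped equivalent circuit of an electrolyte sample between two electrodes
#'
#' When an AC voltage is applied across two identical insulated coplanar
#' electrodes, ions accumulate at each electrode interface and form an
#' electrical double layer. Each electrode's polarization is modelled as a
#' resistance `Rp` in series with a capacitance `Cp`; the bulk sample between
#' them is a resistance `Rs` in parallel with a capacitance `Cs`. The two
#' (identical) polarization impedances are in series with the sample
#' impedance.
#'
#' Limit cases are expressed with IEEE sentinels rather than near-zero or
#' huge magic numbers: `Cp = Inf` means negligible polarization reactance
#' (the series capacitor becomes a short), `Cs = 0` an absent sample
#' capacitance (open), and `Cs = Inf` a shorted sample. The corresponding
#' limits are evaluated analytically, so no overflow can occur.
#'
#' @param Rp Polarization resistance per electrode, ohms (`>= 0`).
#' @param Cp Polarization capacitance per electrode, farads (`> 0` or `Inf`).
#' @param Rs Sample (bulk solution) resistance, ohms (`> 0`).
#' @param Cs Sample capacitance, farads (`>= 0`, `Inf` allowed).
#'
#' @return An object of class `"circuit_params"`.
#' @examples
#' p <- circuit_params(Rp = 100, Cp = 1e-6, Rs = 1e4, Cs = 1e-8)
#' total_admittance(p, omega = 2 * pi * 5e3)
#' @export
circuit_params <- function(Rp = 100, Cp = 1e-6, Rs = 1e4, Cs = 1e-8) {
  for (nm in c("Rp", "Cp", "Rs", "Cs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("`%s` must be a single number", nm), call. = FALSE)
    }
  }
  if (Rp < 0 || !is.finite(Rp)) stop("`Rp` must be finite and >= 0", call. = FALSE)
  if (Cp <= 0) stop("`Cp` must be > 0 (Inf allowed)", call. = FALSE)
  if (Rs <= 0 || !is.finite(Rs)) stop("`Rs` must be finite and > 0", call. = FALSE)
  if (Cs < 0) stop("`Cs` must be >= 0 (Inf allowed)", call. = FALSE)
  structure(list(Rp = as.numeric(Rp), Cp = as.numeric(Cp),
                 Rs = as.numeric(Rs), Cs = as.numeric(Cs)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters:\n")
  cat(sprintf("  polarization: Rp = %g ohm, Cp = %g F (per electrode)\n",
              x$Rp, x$Cp))
  cat(sprintf("  sample:       Rs = %g ohm, Cs = %g F\n", x$Rs, x$Cs))
  invisible(x)
}

#' Polarization impedance of one electrode
#'
#' Series RC impedance of the electrical double layer at one electrode:
#' `Zp = Rp + 1/(j*omega*Cp)`. With the `Cp = Inf` sentinel the reactive
#' term vanishes and `Zp = Rp` exactly.
#'
#' @param p A [circuit_params] object.
#' @param omega Angular frequency in rad/s, strictly positive.
#' @return A complex impedance in ohms.
#' @export
polarization_impedance <- function(p, omega) {
  stopifnot(inherits(p, "circuit_params"))
  check_omega(omega)
  if (is.infinite(p$Cp)) {
    return(complex(real = p$Rp, imaginary = 0))
  }
  complex(real = p$Rp, imaginary = -1 / (omega * p$Cp))
}

#' Sample impedance of the bulk solution
#'
#' Parallel RC impedance of the solution between the electrodes:
#' `Zs = Rs / (1 + j*omega*Rs*Cs)`. `Cs = 0` gives `Zs = Rs` (open
#' capacitor); `Cs = Inf` gives `Zs = 0` (short).
#'
#' @inheritParams polarization_impedance
#' @return A complex impedance in ohms; its magnitude never exceeds `Rs`.
#' @export
sample_impedance <- function(p, omega) {
  stopifnot(inherits(p, "circuit_params"))
  check_omega(omega)
  if (is.infinite(p$Cs)) return(complex(real = 0, imaginary = 0))
  p$Rs / complex(real = 1, imaginary = omega * p$Rs * p$Cs)
}

#' Total admittance of the electrode/sample series network
#'
#' The two identical electrode polarization impedances are in series with
#' the sample impedance, so the one-port admittance seen by the driving
#' circuit is `Y = 1 / (2*Zp + Zs)`. Passivity guarantees `Re(Y) >= 0` for
#' any valid parameter set.
#'
#' @inheritParams polarization_impedance
#' @return An [admittance] object at `frequency = omega / (2*pi)`.
#' @export
total_admittance <- function(p, omega) {
  stopifnot(inherits(p, "circuit_params"))
  check_omega(omega)
  z <- 2 * polarization_impedance(p, omega) + sample_impedance(p, omega)
  if (Mod(z) == 0) {
    stop("total impedance is zero: admittance is singular", call. = FALSE)
  }
  y <- 1 / z
  admittance(G = Re(y), B = Im(y), frequency = omega / (2 * pi))
}
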