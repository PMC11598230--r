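#' Complex admittance at a working frequency
#'
#' Container for an admittance value `Y = G + jB` evaluated at a single
#' working frequency. Conductance `G` and susceptance `B` are in siemens.
#' For a capacitive element `B = omega * C`, so the same object also carries
#' the equivalent-capacitance view via [admittance_to_GC()].
#'
#' @param G Conductance in siemens. Must be finite; non-negative for any
#'   passive network.
#' @param B Susceptance in siemens (may be negative).
#' @param frequency Working frequency in Hz, strictly positive.
#'
#' @return An object of class `"admittance"`: a list with elements `G`, `B`
#'   and `frequency`.
#' @seealso [total_admittance()], [admittance_to_GC()]
#' @examples
#' y <- admittance(G = 1e-5, B = 2 * pi * 5e3 * 100e-12, frequency = 5e3)
#' as.complex(y)
#' @export
admittance <- function(G, B, frequency) {
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G),
            is.numeric(B), length(B) == 1L, is.finite(B))
  check_frequency(frequency)
  structure(list(G = as.numeric(G), B = as.numeric(B),
                 frequency = as.numeric(frequency)),
            class = "admittance")
}

#' @export
as.complex.admittance <- function(x, ...) complex(real = x$G, imaginary = x$B)

#' @export
print.admittance <- function(x, digits = 4, ...) {
  cat(sprintf("Admittance at %g Hz: G = %s S, B = %s S (C = %s F)\n",
              x$frequency,
              format(x$G, digits = digits), format(x$B, digits = digits),
              format(x$B / (2 * pi * x$frequency), digits = digits)))
  invisible(x)
}

#' Reduce an admittance to its conductance/capacitance pair
#'
#' The simplified one-port view of the sample between the electrodes is a
#' conductance `GT` in parallel with a capacitance `CT`. At angular frequency
#' `omega = 2*pi*frequency` these relate to the admittance by `GT = G` and
#' `CT = B / omega`.
#'
#' @param y An [admittance] object.
#' @return A list with elements `GT` (siemens) and `CT` (farads).
#' @examples
#' y <- admittance(1e-5, 2 * pi * 1e4 * 100e-12, 1e4)
#' admittance_to_GC(y)$CT  # 100 pF
#' @export
admittance_to_GC <- function(y) {
  stopifnot(inherits(y, "admittance"))
  list(GT = y$G, CT = y$B / (2 * pi * y$frequency))
}

#' Build an admittance from a conductance/capacitance pair
#'
#' Inverse of [admittance_to_GC()]: `B = 2*pi*frequency*CT`.
#'
#' @param GT Conductance in siemens.
#' @param CT Capacitance in farads.
#' @param frequency Working frequency in Hz.
#' @return An [admittance] object.
#' @export
GC_to_admittance <- function(GT, CT, frequency) {
  check_frequency(frequency)
  admittance(G = GT, B = 2 * pi * frequency * CT, frequency = frequency)
}

# shared validators ----------------------------------------------------------

check_frequency <- function(frequency) {
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    stop("`frequency` must be a single positive finite number (Hz)",
         call. = FALSE)
  }
  invisible(frequency)
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || length(omega) != 1L ||
      !is.finite(omega) || omega <= 0) {
    stop("`omega` must be a single positive finite angular frequency (rad/s)",
         call. = FALSE)
  }
  invisible(omega)
}
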