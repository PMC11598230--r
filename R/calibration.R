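#' Assemble a calibration set from response surfaces
#'
#' A calibration set bundles the response surfaces for every
#' (frequency, channel) pair the estimator needs: the quadratic surfaces
#' used by the Gauss-Newton refinement and (optionally) the linear
#' surfaces whose quadrature pair provides the closed-form initialization.
#'
#' @param quadratic List of quadratic [response_surface] objects.
#' @param linear Optional list of linear [response_surface] objects.
#' @return An object of class `"admittance_calibration"` with surfaces
#'   indexed by `"<frequency>_<channel>"`.
#' @seealso [fit_calibration()], [reference_calibration()]
#' @export
calibration_set <- function(quadratic, linear = NULL) {
  index <- function(surfs, form) {
    stopifnot(is.list(surfs), length(surfs) > 0)
    for (s in surfs) {
      stopifnot(inherits(s, "response_surface"))
      if (s$form != form) {
        stop(sprintf("expected %s surfaces in the `%s` slot", form, form),
             call. = FALSE)
      }
    }
    names(surfs) <- vapply(surfs, function(s) surface_key(s$frequency, s$channel), "")
    if (anyDuplicated(names(surfs))) {
      stop("duplicate (frequency, channel) surface", call. = FALSE)
    }
    surfs
  }
  structure(list(quadratic = index(quadratic, "quadratic"),
                 linear = if (!is.null(linear)) index(linear, "linear")),
            class = "admittance_calibration")
}

#' Retrieve one surface from a calibration set
#'
#' @param cal An `admittance_calibration`.
#' @param frequency Working frequency in Hz.
#' @param channel `"in_phase"` or `"quadrature"`.
#' @param form `"quadratic"` or `"linear"`.
#' @return The matching [response_surface], or an error naming the missing
#'   (frequency, channel) pair.
#' @export
get_surface <- function(cal, frequency, channel,
                        form = c("quadratic", "linear")) {
  stopifnot(inherits(cal, "admittance_calibration"))
  form <- match.arg(form)
  surfs <- cal[[form]]
  if (is.null(surfs)) {
    stop(sprintf("calibration has no %s surfaces", form), call. = FALSE)
  }
  key <- surface_key(frequency, channel)
  if (is.null(surfs[[key]])) {
    stop(sprintf("calibration is missing the (%g Hz, %s) %s surface",
                 frequency, channel, form), call. = FALSE)
  }
  surfs[[key]]
}

#' Calibration frequencies and channels
#'
#' @param cal An `admittance_calibration`.
#' @return List with the sorted `frequencies` (Hz) and `channels` covered
#'   by the quadratic surfaces.
#' @export
calibration_coverage <- function(cal) {
  stopifnot(inherits(cal, "admittance_calibration"))
  fr <- sort(unique(vapply(cal$quadratic, function(s) s$frequency, 0)))
  ch <- unique(vapply(cal$quadratic, function(s) s$channel, ""))
  list(frequencies = fr, channels = ch)
}

#' Fit a full calibration from measurement records
#'
#' Fits one surface per (frequency, channel) pair present in the data, in
#' both the quadratic and the linear form, and bundles them into a
#' calibration set ready for [estimate_concentrations()].
#'
#' @param data Measurement records (layout of [simulate_measurements()]).
#' @param frequencies Working frequencies to calibrate; default: all
#'   frequencies present in `data`.
#' @param interaction Passed to [fit_response_surface()] for the quadratic
#'   surfaces.
#' @return An `admittance_calibration`.
#' @export
fit_calibration <- function(data, frequencies = NULL, interaction = FALSE) {
  data <- check_measurement_frame(data)
  if (is.null(frequencies)) frequencies <- sort(unique(data$freq_hz))
  channels <- intersect(c("in_phase", "quadrature"), unique(data$channel))
  grid <- expand.grid(frequency = frequencies, channel = channels,
                      stringsAsFactors = FALSE)
  quad <- lapply(seq_len(nrow(grid)), function(i) {
    fit_response_surface(data, grid$frequency[i], grid$channel[i],
                         form = "quadratic", interaction = interaction)
  })
  lin <- lapply(seq_len(nrow(grid)), function(i) {
    fit_response_surface(data, grid$frequency[i], grid$channel[i],
                         form = "linear")
  })
  calibration_set(quadratic = quad, linear = lin)
}

#' Reference calibration shipped with the package
#'
#' The package ships a reference coefficient set for NaCl/KCl mixtures on
#' 0.5-4 mM at 5 and 10 kHz (quadratic and linear forms, both channels),
#' stored as plain JSON under `inst/extdata/`. It is the default ground
#' truth of the synthetic generator and the worked calibration example of
#' the documentation.
#'
#' @return An `admittance_calibration` holding the shipped quadratic and
#'   linear surfaces.
#' @examples
#' cal <- reference_calibration()
#' predict(get_surface(cal, 5e3, "quadrature"), 1, 1)
#' @export
reference_calibration <- function() {
  read_calibration(
    system.file("extdata", "reference_calibration.json", package = "admittr",
                mustWork = TRUE))
}

#' Write a calibration set to JSON
#'
#' Coefficients are serialized at full double precision; the 3-decimal
#' rounding seen in printed summaries is display-only.
#'
#' @param cal An `admittance_calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "admittance_calibration"))
  ser <- function(surfs) lapply(unname(surfs), function(s) {
    list(frequency_hz = s$frequency, channel = s$channel, form = s$form,
         alpha = as.numeric(s$alpha),
         R = if (is.null(s$R)) NULL else s$R)
  })
  doc <- list(format = "admittr-calibration",
              version = 1L,
              quadratic = ser(cal$quadratic),
              linear = if (!is.null(cal$linear)) ser(cal$linear))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a calibration set from JSON
#'
#' @param path Path to a file written by [write_calibration()] (or the
#'   shipped reference file).
#' @return An `admittance_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path),
                               call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  de <- function(entries) lapply(entries, function(e) {
    response_surface(as.numeric(e$alpha), frequency = e$frequency_hz,
                     channel = e$channel, form = e$form,
                     R = if (is.null(e$R)) NULL else e$R)
  })
  calibration_set(quadratic = de(doc$quadratic),
                  linear = if (!is.null(doc$linear)) de(doc$linear))
}

#' @export
print.admittance_calibration <- function(x, ...) {
  cov <- calibration_coverage(x)
  cat(sprintf("Admittance calibration: %s Hz x {%s}\n",
              paste(cov$frequencies, collapse = ", "),
              paste(cov$channels, collapse = ", ")))
  for (s in x$quadratic) {
    cat(sprintf("  quadratic %6g Hz %-10s [%s]%s\n", s$frequency, s$channel,
                paste(format(round(s$alpha, 3), nsmall = 3, trim = TRUE),
                      collapse = ", "),
                if (!is.null(s$R)) sprintf("  R = %.3f", s$R) else ""))
  }
  if (!is.null(x$linear)) {
    for (s in x$linear) {
      cat(sprintf("  linear    %6g Hz %-10s [%s]%s\n", s$frequency, s$channel,
                  paste(format(round(s$alpha, 3), nsmall = 3, trim = TRUE),
                        collapse = ", "),
                  if (!is.null(s$R)) sprintf("  R = %.3f", s$R) else ""))
    }
  }
  invisible(x)
}
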