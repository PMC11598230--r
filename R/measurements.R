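#' Validate and normalize a measurement-record table
#'
#' Internal contract used across the package: a measurement table is a
#' data frame with columns `x1_mM`, `x2_mM` (concentrations, mM, >= 0),
#' `freq_hz`, `channel` (`"in_phase"`/`"quadrature"`), `response_v`
#' (normalized response, volts) and optionally `replicate` (defaults to 1).
#' Column order is free; extra columns are preserved.
#'
#' @param data A data frame.
#' @return The validated data frame with canonical column order.
#' @keywords internal
check_measurement_frame <- function(data) {
  if (!is.data.frame(data)) stop("measurement records must be a data frame",
                                 call. = FALSE)
  need <- c("x1_mM", "x2_mM", "freq_hz", "channel", "response_v")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("measurement table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  for (col in c("x1_mM", "x2_mM", "freq_hz", "response_v")) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("malformed value in column `%s` at row(s): %s",
                     col, paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      data[[col]] <- vn
    }
    if (anyNA(data[[col]])) {
      stop(sprintf("missing values in column `%s` at row(s): %s", col,
                   paste(utils::head(which(is.na(data[[col]])), 5),
                         collapse = ", ")), call. = FALSE)
    }
  }
  if (any(data$x1_mM < 0) || any(data$x2_mM < 0)) {
    stop("concentrations must be >= 0 mM", call. = FALSE)
  }
  bad_ch <- which(!data$channel %in% c("in_phase", "quadrature"))
  if (length(bad_ch)) {
    stop(sprintf("unknown channel at row(s): %s (expected in_phase/quadrature)",
                 paste(utils::head(bad_ch, 5), collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(data), c(need, "replicate"))
  data[, c("x1_mM", "x2_mM", "freq_hz", "channel", "response_v",
           "replicate", extra), drop = FALSE]
}

#' Read measurement records from CSV
#'
#' Comma-separated, UTF-8, header required, `.` decimal separator.
#' Columns are matched by name, so any column order is accepted; malformed
#' rows are rejected with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated measurement data frame.
#' @seealso [write_measurements()], [simulate_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("measurement file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_measurement_frame(df)
}

#' Write measurement records to CSV
#'
#' Full double precision (no display rounding), comma-separated, with
#' header. A fixed row order plus fixed formatting makes repeated writes of
#' the same records byte-identical.
#'
#' @param data A measurement data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  data <- check_measurement_frame(data)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) {
                    stop(sprintf("cannot write to path: %s", path),
                         call. = FALSE)
                  })
  on.exit(close(con))
  out <- data
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      # %.17g round-trips doubles exactly
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
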