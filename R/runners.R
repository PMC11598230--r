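#' Estimate concentrations for every observation in a measurement table
#'
#' Groups a measurement table by `(x1_mM, x2_mM, replicate)` — each group
#' must contain one response per (frequency, channel) pair of the
#' calibration — and runs [estimate_concentrations()] on each group.
#'
#' @param cal An `admittance_calibration`.
#' @param data A measurement data frame (layout of
#'   [simulate_measurements()]). The `x1_mM`/`x2_mM` columns are treated as
#'   the true labels and echoed in the result; use `NA` columns for
#'   unlabeled field data.
#' @param ... Passed to [estimate_concentrations()].
#' @return A data frame with one row per observation: the labels, the
#'   estimates (`x1_hat`, `x2_hat`), the audit initial point
#'   (`x1_init`, `x2_init`), `iterations`, `converged`, `residual_norm`
#'   and the warning flags.
#' @export
estimate_table <- function(cal, data, ...) {
  stopifnot(inherits(cal, "admittance_calibration"))
  data <- check_measurement_frame(data)
  key <- interaction(data$x1_mM, data$x2_mM, data$replicate, drop = TRUE)
  groups <- split(seq_len(nrow(data)), key)
  rows <- lapply(groups, function(idx) {
    sub <- data[idx, , drop = FALSE]
    est <- estimate_concentrations(cal, sub[, c("freq_hz", "channel",
                                                "response_v")], ...)
    data.frame(x1_mM = sub$x1_mM[1], x2_mM = sub$x2_mM[1],
               replicate = sub$replicate[1],
               x1_hat = est$x1_hat, x2_hat = est$x2_hat,
               x1_init = est$init[1], x2_init = est$init[2],
               iterations = est$iterations, converged = est$converged,
               residual_norm = est$residual_norm,
               condition_warning = est$condition_warning,
               box_warning = est$box_warning)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$x1_mM, out$x2_mM, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a measurement campaign and write it to disk
#'
#' Workflow entry point behind the `simulate` CLI command: generates
#' records with [simulate_measurements()], writes them as CSV and writes a
#' provenance JSON next to it (configuration echo, seed, config hash,
#' package version, and the fixed device geometry metadata).
#'
#' @param cfg A [generator_config].
#' @param out_csv Output CSV path.
#' @param provenance_json Output provenance path; default: `out_csv` with a
#'   `.provenance.json` suffix.
#' @return The measurement data frame, invisibly.
#' @export
run_simulate <- function(cfg, out_csv,
                         provenance_json = paste0(out_csv,
                                                  ".provenance.json")) {
  stopifnot(inherits(cfg, "generator_config"))
  df <- simulate_measurements(cfg)
  write_measurements(df, out_csv)
  write_provenance(provenance_json, command = "simulate",
                   config = config_echo(cfg), seed = cfg$seed,
                   outputs = out_csv)
  invisible(df)
}

#' Fit a calibration from a measurement file and write it to JSON
#'
#' Workflow entry point behind the `fit` CLI command. Fits one quadratic
#' and one linear surface per (frequency, channel) pair and serializes the
#' calibration (full precision; printed summaries round to 3 decimals).
#'
#' @param data A measurement data frame or a path to a measurement CSV.
#' @param out_json Output calibration path.
#' @param interaction Passed to [fit_calibration()].
#' @return The fitted `admittance_calibration`, invisibly.
#' @export
run_fit <- function(data, out_json, interaction = FALSE) {
  if (is.character(data)) data <- read_measurements(data)
  cal <- fit_calibration(data, interaction = interaction)
  write_calibration(cal, out_json)
  write_provenance(paste0(out_json, ".provenance.json"), command = "fit",
                   config = list(interaction = interaction,
                                 n_records = nrow(data)),
                   seed = NULL, outputs = out_json)
  invisible(cal)
}

#' Estimate concentrations from files and write the results
#'
#' Workflow entry point behind the `estimate` CLI command: loads a
#' calibration and a measurement table, estimates every observation with
#' [estimate_table()], and writes a JSON result document carrying the
#' inputs, the initial and refined estimates, iteration counts, residuals
#' and warnings per observation.
#'
#' @param cal An `admittance_calibration` or a path to a calibration JSON.
#' @param data A measurement data frame or a path to a measurement CSV.
#' @param out_json Output results path.
#' @param ... Passed to [estimate_concentrations()].
#' @return The estimates data frame, invisibly.
#' @export
run_estimate <- function(cal, data, out_json, ...) {
  if (is.character(cal)) cal <- read_calibration(cal)
  if (is.character(data)) data <- read_measurements(data)
  est <- estimate_table(cal, data, ...)
  doc <- list(format = "admittr-estimates", version = 1L,
              n_observations = nrow(est), estimates = est)
  dir.create(dirname(out_json), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(doc, out_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  write_provenance(paste0(out_json, ".provenance.json"), command = "estimate",
                   config = list(n_observations = nrow(est)), seed = NULL,
                   outputs = out_json)
  invisible(est)
}

# provenance -----------------------------------------------------------------

config_echo <- function(cfg) {
  list(grid = cfg$grid, replicates = cfg$replicates,
       noise_sigma = cfg$noise_sigma, mode = cfg$mode,
       truth_form = cfg$truth_form,
       truth_frequencies = calibration_coverage(cfg$truth)$frequencies)
}

# 32-bit FNV-1a over the serialized configuration, reported in hex.
# The multiply is split into 16-bit limbs so every intermediate stays
# exactly representable in a double.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- (lo * m + ((hi * m) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

write_provenance <- function(path, command, config, seed, outputs) {
  doc <- list(
    format = "admittr-provenance", version = 1L,
    command = command,
    package_version = as.character(utils::packageVersion("admittr")),
    seed = if (is.null(seed)) NA else seed,
    config = config,
    config_hash = config_hash(config),
    device_metadata = device_metadata(),
    # file names only, so identical runs in different directories produce
    # identical provenance
    outputs = basename(outputs),
    timestamp = NA)  # left NA so reruns are bit-identical
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Device geometry metadata
#'
#' The fixed geometry of the coplanar sensing electrodes, recorded in
#' provenance output only; no computation consumes it.
#'
#' @return A list of geometry constants.
#' @export
device_metadata <- function() {
  list(electrode_width_um = 900, electrode_length_um = 1800,
       electrode_gap_um = 200, insulation = "PSR-2000",
       insulation_depth_um = 10, substrate = "PCB copper foil")
}
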