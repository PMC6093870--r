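# External interfaces: flat little-endian float32 arrays with JSON sidecars
# for continuous recordings and epochs, CSV for tables, JSON for configs,
# specs and QC reports.

write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
}

read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4, endian = "little")
}

#' Write / read a continuous recording (float32 + JSON sidecar)
#'
#' The binary file holds the channel x sample array in column-major order
#' (all channels of sample 1, then sample 2, ...), as little-endian 32-bit
#' floats; the sidecar (`<stem>.json`) records shape, sampling rate, labels
#' and reference.
#'
#' @param rec A `continuous_recording`.
#' @param stem Output path without extension; writes `<stem>.bin` and
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "continuous_recording"))
  write_f32(rec$data, paste0(stem, ".bin"))
  jsonlite::write_json(
    list(shape = dim(rec$data), order = "channel_major",
         dtype = "float32_le", sfreq_hz = rec$sfreq_hz,
         labels = rec$labels, reference = rec$reference),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  data <- matrix(read_f32(paste0(stem, ".bin"), prod(meta$shape)),
                 nrow = meta$shape[1], ncol = meta$shape[2],
                 dimnames = list(meta$labels, NULL))
  structure(
    list(data = data, sfreq_hz = meta$sfreq_hz, labels = meta$labels,
         reference = meta$reference),
    class = "continuous_recording"
  )
}

#' Write / read an epochs set (float32 + JSON sidecar + metadata CSV)
#'
#' Writes `<stem>.bin` (trial x channel x sample array, R array order:
#' trial index fastest), `<stem>.json` (shape, time axis, labels, flags) and
#' `<stem>_metadata.csv` (per-trial metadata).
#'
#' @param epochs An `epochs_set`.
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epochs_set"))
  write_f32(epochs$data, paste0(stem, ".bin"))
  jsonlite::write_json(
    list(shape = dim(epochs$data), order = "trial_major_array",
         dtype = "float32_le", sfreq_hz = epochs$sfreq_hz,
         tmin_ms = epochs$tmin_ms, labels = epochs$labels,
         baseline_corrected = epochs$baseline_corrected,
         rejected_mask = epochs$rejected_mask,
         metadata = paste0(basename(stem), "_metadata.csv")),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(epochs$metadata, paste0(stem, "_metadata.csv"))
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  data <- array(read_f32(paste0(stem, ".bin"), prod(meta$shape)),
                dim = meta$shape)
  md <- readr::read_csv(file.path(dirname(stem), meta$metadata),
                        show_col_types = FALSE)
  new_epochs_set(data, tmin_ms = meta$tmin_ms, sfreq_hz = meta$sfreq_hz,
                 labels = meta$labels, metadata = md,
                 baseline_corrected = meta$baseline_corrected,
                 rejected_mask = meta$rejected_mask)
}

#' Persist a t-max permutation result
#'
#' Writes the observed t map and permutation null distribution as float32
#' binaries plus a JSON summary (`critical_t`, `alpha`, `B`, `seed`).
#'
#' @param result A `tmax_result`.
#' @param stem Output path without extension.
#' @return `stem`, invisibly.
#' @export
write_tmax_result <- function(result, stem) {
  stopifnot(inherits(result, "tmax_result"))
  write_f32(result$t_obs, paste0(stem, "_tobs.bin"))
  write_f32(result$null_tmax, paste0(stem, "_null.bin"))
  jsonlite::write_json(
    list(shape = dim(result$t_obs), labels = result$labels,
         times_ms = result$times_ms, critical_t = result$critical_t,
         alpha = result$alpha, B = result$B, seed = result$seed,
         method = result$method, n_subjects = result$n_subjects,
         n_tests = result$n_tests, mode = result$mode),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Write / read a component spec as JSON
#' @param spec A [component_spec()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_component_spec` returns the spec.
#' @export
write_component_spec <- function(spec, path) {
  stopifnot(inherits(spec, "component_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_component_spec
#' @export
read_component_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  component_spec(x$name, x$polarity, x$window_ms, x$electrodes, x$mode,
                 source = x$source %||% "reference")
}

#' Write a study report to a directory
#'
#' Emits the report's tables as CSV, the component specs and provenance as
#' JSON, and a plain-text summary, so any table can be regenerated
#' bit-identically from the same configuration and seed.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$qc, file.path(dir, "qc.csv"))
  readr::write_csv(report$cell_means, file.path(dir, "cell_means.csv"))
  readr::write_csv(report$amplitudes, file.path(dir, "amplitudes.csv"))
  readr::write_csv(report$model_comparison,
                   file.path(dir, "model_comparison.csv"))
  readr::write_csv(report$omission, file.path(dir, "omission.csv"))
  readr::write_csv(report$posthoc, file.path(dir, "posthoc.csv"))
  for (nm in names(report$component_specs)) {
    write_component_spec(report$component_specs[[nm]],
                         file.path(dir, paste0("component_", nm, ".json")))
  }
  if (!is.null(report$sequential)) {
    readr::write_csv(report$sequential$checks,
                     file.path(dir, "sequential_checks.csv"))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    "erpfactor study report",
    sprintf("subjects simulated: %d, included: %d",
            nrow(report$qc), report$provenance$n_included),
    sprintf("components: %s", paste(names(report$component_specs),
                                    collapse = ", ")),
    if (!is.null(report$sequential)) {
      sprintf("sequential decision: stop at n = %d (%s rule)",
              report$sequential$stopped_at_n, report$sequential$reason)
    },
    sprintf("provenance hash: %s", report$provenance$hash)
  )
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
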