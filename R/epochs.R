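# epochs_set: the pipeline's central container.  A trial x channel x sample
# numeric array (microvolts) plus per-trial metadata (a schedule-derived
# tibble with subject_id), the epoch time axis and bookkeeping flags.

new_epochs_set <- function(data, tmin_ms, sfreq_hz, labels, metadata,
                           baseline_corrected = FALSE,
                           rejected_mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  stopifnot(dim(data)[1] == nrow(metadata), dim(data)[2] == length(labels))
  structure(
    list(
      data = data,
      tmin_ms = tmin_ms,
      sfreq_hz = sfreq_hz,
      labels = labels,
      metadata = as_tibble(metadata),
      baseline_corrected = baseline_corrected,
      rejected_mask = rejected_mask %||% rep(FALSE, dim(data)[1])
    ),
    class = "epochs_set"
  )
}

#' Epoch time axis in milliseconds
#'
#' @param epochs An `epochs_set`.
#' @return Numeric vector, one value per sample.
#' @export
epoch_times_ms <- function(epochs) {
  stopifnot(inherits(epochs, "epochs_set"))
  s0 <- round(epochs$tmin_ms / 1000 * epochs$sfreq_hz)
  (s0 + seq_len(dim(epochs$data)[3]) - 1) / epochs$sfreq_hz * 1000
}

#' Number of epochs, channels and samples of an epochs set
#' @param epochs An `epochs_set`.
#' @return Named integer vector `(trials, channels, samples)`.
#' @export
epoch_dims <- function(epochs) {
  d <- dim(epochs$data)
  c(trials = d[1], channels = d[2], samples = d[3])
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs_set> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g) ms\n",
    d[1], d[2], d[3], x$sfreq_hz, x$tmin_ms,
    x$tmin_ms + d[3] / x$sfreq_hz * 1000
  ))
  cat(sprintf(
    "  baseline corrected: %s; rejected: %d/%d\n",
    x$baseline_corrected, sum(x$rejected_mask), d[1]
  ))
  invisible(x)
}

#' Convert an epochs set to a long tibble
#'
#' One row per trial x channel x sample, suitable for dplyr/ggplot2 work on
#' small epoch sets.
#'
#' @param x An `epochs_set`.
#' @param ... Unused.
#' @return A tibble with trial metadata, `channel`, `time_ms`, `amplitude_uV`.
#' @export
tidy.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  times <- epoch_times_ms(x)
  out <- tibble(
    trial_index = rep(x$metadata$trial_index, times = d[2] * d[3]),
    channel = rep(rep(x$labels, each = d[1]), times = d[3]),
    time_ms = rep(times, each = d[1] * d[2]),
    amplitude_uV = as.vector(x$data)
  )
  meta <- x$metadata[, intersect(c("trial_index", "subject_id", "kind",
                                   "emotion", "size", "contrast"),
                                 names(x$metadata))]
  left_join(out, meta, by = "trial_index")
}

# subset trials (logical or integer index), keeping metadata aligned
epochs_subset <- function(epochs, idx) {
  new_epochs_set(
    epochs$data[idx, , , drop = FALSE],
    epochs$tmin_ms, epochs$sfreq_hz, epochs$labels,
    epochs$metadata[idx, ],
    baseline_corrected = epochs$baseline_corrected,
    rejected_mask = epochs$rejected_mask[idx]
  )
}

# retained (non-rejected) target trials of one subject's epochs
target_epochs <- function(epochs) {
  keep <- epochs$metadata$kind == "target" & !epochs$rejected_mask
  epochs_subset(epochs, keep)
}
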