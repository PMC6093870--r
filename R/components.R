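# Component definitions: ground-truth generative specs for the simulator and
# the packaged reference windows/clusters used for reproduction runs.

#' Ground truth for one simulated ERP component
#'
#' Describes a component the generator injects into synthetic recordings: a
#' smooth scalp topography (spherical Gaussian bump over an electrode
#' cluster, max |weight| = 1), a unit-peak Gaussian temporal kernel, and
#' per-cell mean amplitudes with between-subject and between-trial
#' variability.  Amplitudes are calibrated so that the standard extraction
#' (mean over `window_ms` samples and `electrodes`) of a noiseless trial
#' recovers the configured amplitude exactly; the waveform peak is therefore
#' higher than the window mean, as in real ERPs.
#'
#' @param name Component name (e.g. `"P1"`).
#' @param cell_means_uV Eight cell means in microvolts, in the canonical cell
#'   order of [design_cells()].
#' @param window_ms Length-2 analysis window (ms post-onset).
#' @param electrodes Electrode cluster the component is centred on.
#' @param polarity `"positive"` or `"negative"`: direction of the deflection
#'   this component is searched with (for the EPN this refers to the
#'   negative-minus-neutral difference wave).
#' @param subject_sd_uV Between-subject SD of a shared amplitude offset.
#' @param trial_sd_uV Trial-to-trial amplitude SD.
#' @param latency_center_ms Centre of the temporal Gaussian kernel; defaults
#'   to the window midpoint.
#' @param latency_width_ms Kernel SD in ms; defaults to a quarter of the
#'   window width.
#' @param topography_width_deg Angular SD of the spatial bump (degrees).
#' @param topography Optional named weight vector (one weight per montage
#'   channel, max |weight| = 1) overriding the Gaussian bump, e.g. an
#'   indicator topography confined to the cluster for recovery tests.
#' @return A `component_truth` object (a list).
#' @export
component_truth <- function(name, cell_means_uV, window_ms, electrodes,
                            polarity = c("positive", "negative"),
                            subject_sd_uV = 0, trial_sd_uV = 0,
                            latency_center_ms = mean(window_ms),
                            latency_width_ms = diff(window_ms) / 4,
                            topography_width_deg = 35,
                            topography = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(cell_means_uV) == 8, length(window_ms) == 2,
            window_ms[1] < window_ms[2], length(electrodes) >= 1,
            subject_sd_uV >= 0, trial_sd_uV >= 0, latency_width_ms > 0)
  structure(
    list(
      name = name, cell_means_uV = as.numeric(cell_means_uV),
      window_ms = as.numeric(window_ms), electrodes = electrodes,
      polarity = polarity, subject_sd_uV = subject_sd_uV,
      trial_sd_uV = trial_sd_uV, latency_center_ms = latency_center_ms,
      latency_width_ms = latency_width_ms,
      topography_width_deg = topography_width_deg,
      topography = topography
    ),
    class = "component_truth"
  )
}

# Reference windows (ms) and electrode clusters of the four components as
# identified on the original dataset; packaged for reproduction runs and as
# the generative defaults.
REFERENCE_COMPONENTS <- list(
  P1 = list(
    window_ms = c(66, 148), polarity = "positive", mode = "localizer_average",
    electrodes = c("P7", "P9", "PO7", "O1", "O2", "PO8", "P8", "P10")
  ),
  N1 = list(
    window_ms = c(150, 260), polarity = "negative", mode = "localizer_average",
    electrodes = c("TP7", "P7", "P9", "TP8", "P8", "P10")
  ),
  EPN = list(
    window_ms = c(300, 500), polarity = "negative", mode = "emotion_difference",
    electrodes = c("P7", "P9", "PO7", "PO3", "O1", "Oz", "Iz", "O2",
                   "PO4", "PO8", "P8", "P10")
  ),
  LPP = list(
    window_ms = c(402, 684), polarity = "positive", mode = "localizer_average",
    electrodes = c("P1", "Pz", "P2", "P4", "P6", "P8", "P10",
                   "POz", "PO4", "PO8")
  )
)

# Published per-cell window-mean amplitudes (microvolts), canonical cell
# order (emotion slowest, contrast fastest), and the average of the printed
# per-cell SDs used as the default total amplitude SD.
TABLE1_MEANS <- list(
  P1  = c(1.00, 1.21, 1.09, 0.34, 1.06, 1.34, 0.92, 0.38),
  N1  = c(-1.36, -1.03, -1.39, -0.03, -1.38, -1.13, -1.45, -0.09),
  EPN = c(0.33, 0.27, 1.04, 1.15, 0.53, 0.58, 1.37, 1.09),
  LPP = c(0.61, 0.71, 0.76, 1.35, 0.60, 0.81, 0.79, 1.17)
)
TABLE1_TOTAL_SD <- c(P1 = 3.79, N1 = 3.72, EPN = 3.90, LPP = 3.11)

#' Default generative component set calibrated to the published cell means
#'
#' Four components (P1, N1, EPN, LPP) with cell means equal to the published
#' amplitude table and total amplitude variance split between a
#' between-subject offset and trial-to-trial noise.
#'
#' @param variance_split Fraction of total amplitude variance assigned to the
#'   between-subject offset (default 0.5; the published per-cell SDs conflate
#'   the two sources).
#' @param sd_scale Multiplier on both SDs, e.g. 0 for noiseless ground truth.
#' @return A named list of [component_truth()] objects.
#' @export
default_component_truths <- function(variance_split = 0.5, sd_scale = 1) {
  stopifnot(variance_split >= 0, variance_split <= 1, sd_scale >= 0)
  purrr::imap(REFERENCE_COMPONENTS, function(ref, nm) {
    tot <- TABLE1_TOTAL_SD[[nm]]
    component_truth(
      name = nm,
      cell_means_uV = TABLE1_MEANS[[nm]],
      window_ms = ref$window_ms,
      electrodes = ref$electrodes,
      polarity = ref$polarity,
      subject_sd_uV = sd_scale * tot * sqrt(variance_split),
      trial_sd_uV = sd_scale * tot * sqrt(1 - variance_split)
    )
  })
}

#' Packaged reference component specifications
#'
#' The final analysis windows and electrode clusters of the four components,
#' as [component_spec()] objects, for reproduction runs that bypass automated
#' localization.
#'
#' @return Named list of `component_spec` objects.
#' @export
reference_component_specs <- function() {
  purrr::imap(REFERENCE_COMPONENTS, function(ref, nm) {
    component_spec(nm, ref$polarity, ref$window_ms, ref$electrodes, ref$mode)
  })
}
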