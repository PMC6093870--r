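# Continuous-signal conditioning, bad-channel interpolation, epoching,
# artifact rejection and participant-level quality control.

#' Remove linear trends and re-reference a recording
#'
#' Re-references first (subtracting the `Cz` trace or the instantaneous
#' cross-channel mean), then removes a per-channel least-squares linear
#' trend.
#'
#' @param rec A `continuous_recording`.
#' @param reference `"Cz"`, `"average"`, or `"none"` (detrend only).
#' @return The processed `continuous_recording` with its `reference` field
#'   updated.
#' @export
detrend_and_rereference <- function(rec, reference = c("Cz", "average", "none")) {
  stopifnot(inherits(rec, "continuous_recording"))
  reference <- match.arg(reference)
  out <- rec
  if (reference == "Cz") {
    if (!"Cz" %in% rec$labels) abort("reference channel Cz not present")
    out$data <- sweep(out$data, 2, out$data["Cz", ])
    out$reference <- "Cz"
  } else if (reference == "average") {
    out$data <- sweep(out$data, 2, colMeans(out$data))
    out$reference <- "average"
  }
  n <- ncol(out$data)
  t_c <- seq_len(n) - (n + 1) / 2                   # centred time regressor
  slope <- (out$data %*% t_c) / sum(t_c^2)
  out$data <- out$data - tcrossprod(slope, t_c) -
    rowMeans(out$data - tcrossprod(slope, t_c))
  out
}

# spherical spline basis function g(cos theta), Perrin-style
spline_g <- function(cosang, m, n_terms) {
  lg <- (2 * seq_len(n_terms) + 1) /
    (seq_len(n_terms)^m * (seq_len(n_terms) + 1)^m)
  # Legendre recurrence evaluated for all entries at once
  p_prev <- array(1, dim = dim(cosang) %||% length(cosang))
  p_cur <- cosang
  acc <- lg[1] * p_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    acc <- acc + lg[n] * p_new
    p_prev <- p_cur
    p_cur <- p_new
  }
  acc / (4 * pi)
}

# solve the spline system on good channels and predict at bad positions
spline_interpolate_matrix <- function(v_good, pos_good, pos_bad,
                                      m, n_terms, lambda) {
  ng <- nrow(pos_good)
  G <- spline_g(tcrossprod(pos_good), m, n_terms)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(v_good, 0)
  sol <- solve(A, rhs)
  c_coef <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, , drop = FALSE]
  Gb <- spline_g(tcrossprod(pos_bad, pos_good), m, n_terms)
  Gb %*% c_coef + rep(1, nrow(pos_bad)) %*% c0
}

#' Interpolate bad channels with spherical splines
#'
#' Replaces the listed channels with the spherical-spline estimate built from
#' the remaining good channels, using the Perrin-style basis
#' `g(x) = sum_n (2n+1) / (n^m (n+1)^m) P_n(x) / (4 pi)` with a small ridge
#' term on the diagonal.  Good channels are returned bit-exactly unchanged.
#'
#' @param x A `continuous_recording` or `epochs_set`.
#' @param bad_labels Channels to interpolate.
#' @param montage Montage tibble providing unit-sphere positions.
#' @param m Spline stiffness (default 4).
#' @param n_terms Number of Legendre terms (default 50).
#' @param lambda Ridge regularization (default 1e-5).
#' @return Object of the same class with bad channels replaced.
#' @export
interpolate_spherical_spline <- function(x, bad_labels, montage, m = 4,
                                         n_terms = 50, lambda = 1e-5) {
  if (length(bad_labels) == 0) return(x)
  labels <- if (inherits(x, "epochs_set")) x$labels else x$labels
  if (!all(bad_labels %in% labels)) abort("bad_labels not all present in data")
  good <- setdiff(labels, bad_labels)
  if (length(good) < 4) abort("need at least 4 good channels to interpolate")
  pos <- montage_matrix(montage)[labels, , drop = FALSE]
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad_labels, , drop = FALSE]
  gi <- match(good, labels)
  bi <- match(bad_labels, labels)
  if (inherits(x, "continuous_recording")) {
    est <- spline_interpolate_matrix(x$data[gi, , drop = FALSE], pg, pb,
                                     m, n_terms, lambda)
    x$data[bi, ] <- est
    x
  } else if (inherits(x, "epochs_set")) {
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2]) # ch x (trial*sample)
    est <- spline_interpolate_matrix(flat[gi, , drop = FALSE], pg, pb,
                                     m, n_terms, lambda)
    flat[bi, ] <- est
    x$data <- aperm(array(flat, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
    x
  } else {
    abort("x must be a continuous_recording or epochs_set")
  }
}

#' Cut epochs around word onsets and baseline-correct
#'
#' Extracts one epoch per schedule row over the half-open window
#' `[tmin_ms, tmax_ms)` (tmin snapped to the nearest sample) and subtracts
#' the per-trial, per-channel mean over the baseline interval (all samples
#' with t < 0 by default).
#'
#' @param rec A `continuous_recording`.
#' @param schedule Trial schedule tibble ([build_trial_schedule()]).
#' @param tmin_ms,tmax_ms Epoch bounds in ms relative to onset.
#' @param baseline_ms Length-2 baseline interval; samples with
#'   `t >= baseline_ms[1]` and `t < baseline_ms[2]` are used.
#' @param subject_id Optional subject id stored in the metadata.
#' @return An `epochs_set` with `baseline_corrected = TRUE`.
#' @export
epoch_and_baseline <- function(rec, schedule, tmin_ms = -200, tmax_ms = 1000,
                               baseline_ms = c(tmin_ms, 0), subject_id = NA) {
  stopifnot(inherits(rec, "continuous_recording"), tmin_ms < tmax_ms)
  sf <- rec$sfreq_hz
  s0 <- round(tmin_ms / 1000 * sf)
  n_samp <- round((tmax_ms - tmin_ms) / 1000 * sf)
  rel <- s0 + seq_len(n_samp) - 1
  t_ms <- rel / sf * 1000
  n_tr <- nrow(schedule)
  lo <- schedule$onset_sample + rel[1] + 1L
  hi <- schedule$onset_sample + rel[n_samp] + 1L
  outside <- which(lo < 1 | hi > ncol(rec$data))
  if (length(outside) > 0) {
    abort(sprintf("epoch window exceeds recording bounds for trial(s): %s",
                  paste(schedule$trial_index[outside], collapse = ", ")))
  }
  n_ch <- nrow(rec$data)
  data <- array(0, dim = c(n_tr, n_ch, n_samp))
  for (i in seq_len(n_tr)) {
    data[i, , ] <- rec$data[, lo[i]:hi[i]]
  }
  bl <- t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]
  if (any(bl)) {
    blmean <- rowMeans(data[, , bl, drop = FALSE], dims = 2)
    data <- data - array(blmean, dim = dim(data))
  }
  meta <- schedule
  meta$subject_id <- subject_id
  new_epochs_set(data, tmin_ms = rel[1] / sf * 1000, sfreq_hz = sf,
                 labels = rec$labels, metadata = meta,
                 baseline_corrected = TRUE)
}

#' Flag epochs exceeding an absolute amplitude threshold
#'
#' Simple threshold rejector standing in for burst-correction on synthetic
#' data: any epoch containing a sample with `|amplitude| > threshold_uV` on
#' any channel is marked in `rejected_mask`; the data are left unchanged.
#'
#' @param epochs An `epochs_set`.
#' @param threshold_uV Positive rejection threshold (default 250).
#' @return The `epochs_set` with an updated `rejected_mask`.
#' @export
reject_artifacts_threshold <- function(epochs, threshold_uV = 250) {
  stopifnot(inherits(epochs, "epochs_set"), threshold_uV > 0)
  mx <- apply(abs(epochs$data), 1, max)
  epochs$rejected_mask <- epochs$rejected_mask | (mx > threshold_uV)
  epochs
}

#' Participant-level quality control
#'
#' Applies the two pre-registered exclusion rules: more than
#' `max_bad_channels` noisy channels, or probe accuracy below `min_accuracy`
#' in any size x contrast cell (strict inequalities; a participant at
#' exactly 10 bad channels and 80% accuracy is retained).
#'
#' @param epochs The participant's `epochs_set` (provides the subject id).
#' @param behavioral Behavioural table with one row per size x contrast cell.
#' @param n_bad_channels Number of noisy channels detected for this subject.
#' @param max_bad_channels,min_accuracy Rule thresholds (defaults 10, 0.80).
#' @return A `qc_report` list: `subject_id`, `n_bad_channels`,
#'   `min_cell_accuracy`, `excluded`, `reasons`.
#' @export
qc_dataset <- function(epochs, behavioral, n_bad_channels,
                       max_bad_channels = 10, min_accuracy = 0.80) {
  cells <- unique(design_cells()[, c("size", "contrast")])
  have <- paste(behavioral$size, behavioral$contrast)
  missing <- setdiff(paste(cells$size, cells$contrast), have)
  if (length(missing) > 0) {
    abort(paste0("behavioral table misses size x contrast cell(s): ",
                 paste(missing, collapse = "; ")))
  }
  min_acc <- min(behavioral$accuracy)
  reasons <- character(0)
  if (min_acc < min_accuracy) reasons <- c(reasons, "accuracy")
  if (n_bad_channels > max_bad_channels) reasons <- c(reasons, "bad channels")
  structure(
    list(
      subject_id = epochs$metadata$subject_id[1],
      n_bad_channels = n_bad_channels,
      min_cell_accuracy = min_acc,
      excluded = length(reasons) > 0,
      reasons = reasons
    ),
    class = "qc_report"
  )
}

#' Full preprocessing chain for one session
#'
#' Runs the standard signal chain in order: re-reference to `Cz` and
#' detrend, high-pass filter, low-pass filter, spherical-spline
#' interpolation of flagged bad channels, average re-reference, epoching
#' with baseline correction, and threshold-based artifact flagging.
#'
#' @param session List with `recording` and `schedule`
#'   (as returned by [simulate_session()]).
#' @param montage Montage tibble for interpolation.
#' @param bad_labels Channels to interpolate (default none).
#' @param hp,lp Optional `fir_kernel`s; `NULL` skips the stage.
#' @param reject_uV Rejection threshold, `NULL` to skip.
#' @param tmin_ms,tmax_ms Epoch window.
#' @param subject_id Subject id recorded in the metadata.
#' @return An `epochs_set`.
#' @export
preprocess_session <- function(session, montage, bad_labels = character(0),
                               hp = NULL, lp = NULL, reject_uV = 250,
                               tmin_ms = -200, tmax_ms = 1000,
                               subject_id = NA) {
  rec <- detrend_and_rereference(session$recording, "Cz")
  if (!is.null(hp)) rec <- apply_fir(rec, hp)
  if (!is.null(lp)) rec <- apply_fir(rec, lp)
  if (length(bad_labels) > 0) {
    rec <- interpolate_spherical_spline(rec, bad_labels, montage)
  }
  rec <- detrend_and_rereference(rec, "average")
  ep <- epoch_and_baseline(rec, session$schedule, tmin_ms, tmax_ms,
                           subject_id = subject_id)
  if (!is.null(reject_uV)) ep <- reject_artifacts_threshold(ep, reject_uV)
  ep
}
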