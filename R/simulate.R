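# Synthetic ERP study generator: continuous recordings with injected
# components, 1/f background + sensor noise, bad channels, artifact bursts,
# and probe-task behaviour, all deterministic given (config seed, subject).

#' Configuration of a synthetic ERP study
#'
#' Bundles everything needed to simulate a complete multi-subject study.
#' Defaults reproduce the full-scale study layout: 40 subjects, 64 channels
#' at 256 Hz, 60 target trials per design cell plus 20 probes per size x
#' contrast cell in 8 runs, components calibrated to the published amplitude
#' table.
#'
#' @param n_subjects Number of simulated participants.
#' @param trials_per_cell Target trials per design cell.
#' @param probes_per_cell Probe trials per size x contrast cell.
#' @param n_runs Runs per session.
#' @param sfreq_hz Sampling rate (Hz).
#' @param montage Sensor montage tibble ([default_montage()]).
#' @param components Named list of [component_truth()] objects.
#' @param noise_pink_sd_uV Per-channel SD of the spatially mixed 1/f
#'   background (0 disables it).
#' @param noise_pink_exponent Spectral exponent beta of the 1/f^beta sources.
#' @param noise_spatial_mixing Number of latent pink-noise sources mixed into
#'   the channels.
#' @param noise_sensor_sd_uV SD of white sensor noise per channel.
#' @param artifact_rate Fraction of epochs receiving a high-amplitude burst.
#' @param artifact_amplitude_uV Peak amplitude of injected bursts.
#' @param bad_channel_labels List (indexed by subject) of channel labels to
#'   replace with high-variance noise; empty list for none.
#' @param behavior_accuracy Length-4 probe hit probability per size x
#'   contrast cell, order (large/high, large/low, small/high, small/low).
#' @param iti_range_ms Inter-trial-interval range (ms).
#' @param seed Master seed; every subject derives its own stream from it.
#' @return A validated `simulation_config` object (a list).
#' @export
simulation_config <- function(n_subjects = 40, trials_per_cell = 60,
                              probes_per_cell = 20, n_runs = 8,
                              sfreq_hz = 256, montage = default_montage(),
                              components = default_component_truths(),
                              noise_pink_sd_uV = 5, noise_pink_exponent = 1,
                              noise_spatial_mixing = 8,
                              noise_sensor_sd_uV = 2,
                              artifact_rate = 0, artifact_amplitude_uV = 400,
                              bad_channel_labels = list(),
                              behavior_accuracy = rep(0.98, 4),
                              iti_range_ms = c(1000, 1500), seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_cell >= 1, probes_per_cell >= 0,
            sfreq_hz > 0, noise_pink_sd_uV >= 0, noise_sensor_sd_uV >= 0,
            artifact_rate >= 0, artifact_rate <= 1,
            length(behavior_accuracy) == 4,
            all(behavior_accuracy >= 0 & behavior_accuracy <= 1))
  if (nrow(montage) < 1) abort("montage must contain at least one channel")
  for (comp in components) {
    missing <- setdiff(comp$electrodes, montage$label)
    if (length(missing) > 0) {
      abort(sprintf("component %s uses electrodes absent from the montage: %s",
                    comp$name, paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      trials_per_cell = as.integer(trials_per_cell),
      probes_per_cell = as.integer(probes_per_cell),
      n_runs = as.integer(n_runs), sfreq_hz = sfreq_hz, montage = montage,
      components = components, noise_pink_sd_uV = noise_pink_sd_uV,
      noise_pink_exponent = noise_pink_exponent,
      noise_spatial_mixing = as.integer(noise_spatial_mixing),
      noise_sensor_sd_uV = noise_sensor_sd_uV,
      artifact_rate = artifact_rate,
      artifact_amplitude_uV = artifact_amplitude_uV,
      bad_channel_labels = bad_channel_labels,
      behavior_accuracy = behavior_accuracy,
      iti_range_ms = iti_range_ms, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Reduced desk-scale configuration
#'
#' A 32-channel, 16-subject configuration (20 target trials per cell, 5
#' probes per size x contrast cell, 4 runs) that keeps all component
#' electrode clusters while running quickly; intended for tests and examples.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
desk_simulation_config <- function(...) {
  cluster_union <- unique(unlist(lapply(REFERENCE_COMPONENTS, `[[`, "electrodes")))
  extra <- c("Fpz", "Fp1", "Fp2", "Fz", "F3", "F4", "FCz", "C3", "Cz", "C4",
             "CPz", "CP3")
  labels <- BIOSEMI64_LABELS[BIOSEMI64_LABELS %in% union(cluster_union, extra)]
  args <- list(...)
  defaults <- list(
    n_subjects = 16, trials_per_cell = 20, probes_per_cell = 5, n_runs = 4,
    montage = default_montage(labels)
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# topography used by the generator: explicit weights when given, else a
# spherical Gaussian bump over the component's cluster
component_topography <- function(comp, montage) {
  if (!is.null(comp$topography)) {
    w <- comp$topography[montage$label]
    w[is.na(w)] <- 0
    names(w) <- montage$label
    return(w)
  }
  topography_bump(montage, comp$electrodes, comp$topography_width_deg)
}

subject_seed <- function(config, subject_id) {
  (config$seed %% 100000L) * 20011L + subject_id * 127L
}

# one column of 1/f^(beta) noise, unit SD, via spectral shaping of white noise
# k rows of unit-SD 1/f^exponent noise, generated in one batched FFT pass
# (padded to a highly composite length: mixed-radix FFTs of lengths with
# large prime factors are quadratic-time)
pink_sources <- function(n, k, exponent, sfreq_hz) {
  X <- matrix(rnorm(n * k), nrow = n)
  if (exponent == 0) return(t(X))
  nf <- stats::nextn(n, c(2, 3, 5))
  Xp <- rbind(X, matrix(0, nf - n, k))
  f <- seq(0, nf - 1) / nf * sfreq_hz
  f <- pmin(f, sfreq_hz - f)           # two-sided frequency magnitude
  scale <- c(0, 1 / f[-1]^(exponent / 2))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * scale, inverse = TRUE))
  Y <- Y[seq_len(n), , drop = FALSE] / nf
  t(Y) / apply(Y, 2, sd)
}

pink_noise <- function(n, exponent, sfreq_hz) {
  drop(pink_sources(n, 1, exponent, sfreq_hz))
}

gaussian_kernel_samples <- function(comp, sfreq_hz) {
  # unit-peak temporal kernel evaluated on the sample grid, center +/- 4 SD
  halfwidth <- 4 * comp$latency_width_ms
  rng <- comp$latency_center_ms + c(-1, 1) * halfwidth
  offs <- seq(floor(rng[1] / 1000 * sfreq_hz), ceiling(rng[2] / 1000 * sfreq_hz))
  t_ms <- offs / sfreq_hz * 1000
  list(offsets = offs,
       values = exp(-(t_ms - comp$latency_center_ms)^2 /
                      (2 * comp$latency_width_ms^2)))
}

# calibration gain: 1 / (mean cluster weight x mean kernel value over the
# analysis window on the sample grid), so the window-cluster mean of a
# unit-amplitude noiseless trial is exactly 1
component_gain <- function(comp, topo, kern, sfreq_hz) {
  mean_k <- window_kernel_mean(comp$window_ms, kern, sfreq_hz)
  mean_w <- mean(topo[comp$electrodes])
  1 / (mean_k * mean_w)
}

# mean of a sampled kernel over the analysis-window sample grid
window_kernel_mean <- function(window_ms, kern, sfreq_hz) {
  win_samples <- seq(ceiling(window_ms[1] / 1000 * sfreq_hz),
                     floor(window_ms[2] / 1000 * sfreq_hz))
  kvals <- rep(0, length(win_samples))
  m <- match(win_samples, kern$offsets)
  kvals[!is.na(m)] <- kern$values[m[!is.na(m)]]
  mean(kvals)
}

#' Simulate one subject's session
#'
#' Generates the continuous recording, trial schedule and behavioural table
#' of a single synthetic participant.  Each target trial adds, for every
#' configured component, `cell mean + subject offset + trial noise` (uV)
#' times its scalp topography times a unit-peak temporal Gaussian at word
#' onset; spatially mixed 1/f background and white sensor noise are then
#' added, flagged bad channels are replaced by high-variance noise, and
#' artifact bursts are injected into a random subset of epochs.  Probe hits
#' are Bernoulli draws with the configured per-cell accuracy.  The result is
#' deterministic given `(config$seed, subject_id)`.
#'
#' @param config A [simulation_config()].
#' @param subject_id Positive integer subject identifier.
#' @return A list with elements `recording` (`continuous_recording`),
#'   `schedule` (tibble), `behavior` (tibble) and `truth` (list with the
#'   subject's component offsets, injected artifact trial indices and bad
#'   channels).
#' @export
simulate_session <- function(config, subject_id) {
  stopifnot(inherits(config, "simulation_config"), subject_id >= 1)
  set.seed(subject_seed(config, subject_id))
  sched <- build_trial_schedule(
    trials_per_cell = config$trials_per_cell,
    probes_per_cell = config$probes_per_cell,
    n_runs = config$n_runs, iti_range_ms = config$iti_range_ms,
    seed = subject_seed(config, subject_id) + 1L,
    sfreq_hz = config$sfreq_hz
  )
  labels <- config$montage$label
  n_ch <- length(labels)
  n_samp <- max(sched$onset_sample) + ceiling(1.5 * config$sfreq_hz) + 1L
  data <- matrix(0, nrow = n_ch, ncol = n_samp, dimnames = list(labels, NULL))

  targets <- which(sched$kind == "target")
  cell_of <- cell_index(sched$emotion[targets], sched$size[targets],
                        sched$contrast[targets])
  comps <- config$components
  nc <- length(comps)
  topo <- lapply(comps, component_topography, montage = config$montage)
  kern <- lapply(comps, gaussian_kernel_samples, sfreq_hz = config$sfreq_hz)
  gain <- mapply(component_gain, comps, topo, kern,
                 MoreArgs = list(sfreq_hz = config$sfreq_hz))
  # cross-talk calibration: crosstalk[i, j] is what standard extraction in
  # component i's window/cluster reads from a unit-amplitude component j;
  # injecting solve(crosstalk, a) makes extraction return a exactly even
  # with overlapping kernels
  crosstalk <- diag(1, nc)
  if (nc > 1) {
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      crosstalk[i, j] <- gain[j] *
        mean(topo[[j]][comps[[i]]$electrodes]) *
        window_kernel_mean(comps[[i]]$window_ms, kern[[j]], config$sfreq_hz)
    }
  }
  subject_offsets <- numeric(nc)
  names(subject_offsets) <- vapply(comps, `[[`, "", "name")
  amps <- matrix(0, length(targets), nc)
  for (j in seq_len(nc)) {
    s_off <- rnorm(1, 0, comps[[j]]$subject_sd_uV)
    subject_offsets[j] <- s_off
    amps[, j] <- comps[[j]]$cell_means_uV[cell_of] + s_off +
      rnorm(length(targets), 0, comps[[j]]$trial_sd_uV)
  }
  alpha <- t(solve(crosstalk, t(amps)))
  # one amplitude time series per component (impulse train convolved with
  # the kernel), applied with the pink-noise sources in a single rank-k
  # update: fast and allocation-light on long recordings
  series <- matrix(0, nc, n_samp)
  for (j in seq_len(nc)) {
    row <- numeric(n_samp)
    kv <- gain[j] * kern[[j]]$values
    for (i in seq_along(targets)) {
      idx <- sched$onset_sample[targets[i]] + kern[[j]]$offsets + 1L
      ok <- idx >= 1 & idx <= n_samp
      row[idx[ok]] <- row[idx[ok]] + alpha[i, j] * kv[ok]
    }
    series[j, ] <- row
  }
  basis <- if (nc > 0) do.call(cbind, topo) else matrix(0, n_ch, 0)

  if (config$noise_pink_sd_uV > 0 && config$noise_spatial_mixing > 0) {
    src <- pink_sources(n_samp, config$noise_spatial_mixing,
                        config$noise_pink_exponent, config$sfreq_hz)
    mix <- matrix(rnorm(n_ch * nrow(src)), nrow = n_ch)
    mix <- config$noise_pink_sd_uV * mix / sqrt(rowSums(mix^2))
    basis <- cbind(basis, mix)
    series <- rbind(series, src)
  }
  if (config$noise_sensor_sd_uV > 0) {
    data <- data + rnorm(n_ch * n_samp, 0, config$noise_sensor_sd_uV)
  }
  if (ncol(basis) > 0) data <- data + basis %*% series

  bad <- character(0)
  if (length(config$bad_channel_labels) >= subject_id) {
    bad <- intersect(config$bad_channel_labels[[subject_id]], labels)
    for (b in bad) data[b, ] <- rnorm(n_samp, 0, 100)
  }

  artifact_trials <- integer(0)
  if (config$artifact_rate > 0) {
    hit <- runif(nrow(sched)) < config$artifact_rate
    artifact_trials <- which(hit)
    burst_len <- round(0.1 * config$sfreq_hz)
    burst <- config$artifact_amplitude_uV * sin(pi * seq_len(burst_len) / burst_len)
    good_ch <- setdiff(labels, bad)
    for (tr in artifact_trials) {
      ch <- sample(good_ch, 1)
      start <- sched$onset_sample[tr] +
        round(runif(1, 0.1, 0.8) * config$sfreq_hz) + 1L
      idx <- start:(start + burst_len - 1L)
      idx <- idx[idx <= n_samp]
      data[ch, idx] <- data[ch, idx] + burst[seq_along(idx)]
    }
  }

  probes <- sched[sched$kind == "probe", ]
  behavior <- design_cells()[, c("size", "contrast")] |>
    unique() |>
    mutate(subject_id = subject_id, .before = 1)
  behavior$n_probes <- mapply(function(s, k) {
    sum(probes$size == s & probes$contrast == k)
  }, behavior$size, behavior$contrast)
  behavior$n_hits <- rbinom(4, behavior$n_probes, config$behavior_accuracy)
  behavior$accuracy <- ifelse(behavior$n_probes > 0,
                              behavior$n_hits / behavior$n_probes, NA_real_)

  recording <- structure(
    list(data = data, sfreq_hz = config$sfreq_hz, labels = labels,
         reference = "raw"),
    class = "continuous_recording"
  )
  list(
    recording = recording,
    schedule = sched,
    behavior = as_tibble(behavior),
    truth = list(subject_id = subject_id, subject_offsets = subject_offsets,
                 artifact_trials = artifact_trials, bad_channels = bad)
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (ref: %s)\n",
              nrow(x$data), ncol(x$data), x$sfreq_hz, x$reference))
  invisible(x)
}

#' Simulate already-epoched data for every subject
#'
#' Convenience path that runs [simulate_session()] followed by
#' [epoch_and_baseline()] for each subject, bypassing filtering.  Ground
#' truth is attached to each epochs set as attribute `"truth"`, and the
#' behavioural tables are attached to the returned list as attribute
#' `"behavior"`.
#'
#' @param config A [simulation_config()].
#' @param subjects Subject ids to simulate (default all).
#' @param tmin_ms,tmax_ms Epoch window passed to [epoch_and_baseline()].
#' @return Named list of `epochs_set`, one per subject.
#' @export
simulate_epochs <- function(config, subjects = seq_len(config$n_subjects),
                            tmin_ms = -200, tmax_ms = 1000) {
  behavior <- list()
  out <- lapply(subjects, function(sid) {
    ses <- simulate_session(config, sid)
    ep <- epoch_and_baseline(ses$recording, ses$schedule,
                             tmin_ms = tmin_ms, tmax_ms = tmax_ms,
                             subject_id = sid)
    attr(ep, "truth") <- ses$truth
    behavior[[as.character(sid)]] <<- ses$behavior
    ep
  })
  names(out) <- as.character(subjects)
  attr(out, "behavior") <- bind_rows(behavior)
  out
}
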