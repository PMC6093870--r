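# Shared fixtures: small recordings, noiseless configs, synthetic amplitude
# tables with known effect structure.

make_recording <- function(data, labels = paste0("ch", seq_len(nrow(data))),
                           sfreq_hz = 256, reference = "raw") {
  structure(list(data = data, sfreq_hz = sfreq_hz, labels = labels,
                 reference = reference),
            class = "continuous_recording")
}

make_maps <- function(values, ...) as_contrast_maps(values, ...)

# single-component noiseless configuration on the reduced montage
quiet_config <- function(components, n_subjects = 1, trials_per_cell = 2,
                         probes_per_cell = 1, n_runs = 1, seed = 7, ...) {
  desk_simulation_config(
    n_subjects = n_subjects, trials_per_cell = trials_per_cell,
    probes_per_cell = probes_per_cell, n_runs = n_runs,
    components = components, noise_pink_sd_uV = 0, noise_sensor_sd_uV = 0,
    behavior_accuracy = rep(1, 4), seed = seed, ...
  )
}

# amplitude table with additive effects, shared subject offsets and iid
# trial noise; effects are full-level differences (level1 - level2)
make_amplitude_table <- function(n_subjects = 20, trials_per_cell = 10,
                                 emotion_effect = 0, size_effect = 0,
                                 contrast_effect = 0, subject_sd = 1,
                                 sigma = 1, seed = 1,
                                 component = "X") {
  set.seed(seed)
  cells <- design_cells()
  offsets <- rnorm(n_subjects, 0, subject_sd)
  grid <- expand.grid(subject_id = seq_len(n_subjects), cell = 1:8,
                      trial = seq_len(trials_per_cell))
  grid <- cbind(grid, cells[grid$cell, c("emotion", "size", "contrast")])
  mu <- emotion_effect / 2 * ifelse(grid$emotion == "negative", 1, -1) +
    size_effect / 2 * ifelse(grid$size == "large", 1, -1) +
    contrast_effect / 2 * ifelse(grid$contrast == "high", 1, -1)
  tibble::tibble(
    subject_id = grid$subject_id,
    trial_index = seq_len(nrow(grid)),
    emotion = grid$emotion, size = grid$size, contrast = grid$contrast,
    component = component,
    amplitude_uV = mu + offsets[grid$subject_id] +
      rnorm(nrow(grid), 0, sigma)
  )
}

# brute-force one-sample t statistic
t_stat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))

# paired two-condition design: one row per subject x emotion
make_paired_table <- function(n, effect, seed, subject_sd = 1.2, sigma = 1) {
  set.seed(seed)
  off <- rnorm(n, 0, subject_sd)
  tibble::tibble(
    subject_id = rep(seq_len(n), each = 2),
    emotion = rep(c("negative", "neutral"), n),
    size = "large", contrast = "high", component = "X",
    amplitude_uV = off[rep(seq_len(n), each = 2)] +
      ifelse(rep(c(TRUE, FALSE), n), effect / 2, -effect / 2) +
      rnorm(2 * n, 0, sigma)
  )
}

# oracle: exact log BF of the paired-design g-prior linear model versus the
# participant-only null, by deterministic 2-D quadrature over (log gf, log gs)
lm_paired_logbf_exact <- function(tab, r_f = 0.707, r_r = 1) {
  y <- tab$amplitude_uV
  n <- length(y)
  ns <- length(unique(tab$subject_id))
  xe <- ifelse(tab$emotion == "negative", 1, -1) / sqrt(2)
  H <- cbind(1 / sqrt(ns), stats::contr.helmert(ns))
  H[, -1] <- sweep(H[, -1, drop = FALSE], 2,
                   sqrt(colSums(H[, -1, drop = FALSE]^2)), "/")
  Xs <- H[as.integer(factor(tab$subject_id)), -1, drop = FALSE]
  yc <- y - mean(y)
  X <- cbind(xe, Xs)
  X <- sweep(X, 2, colMeans(X))
  XtX <- crossprod(X); Xty <- crossprod(X, yc); yty <- sum(yc^2)
  p <- ncol(X)
  ig <- function(g, r) {
    0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
  }
  logm_full <- function(lgf, lgs) {
    gf <- exp(lgf); gs <- exp(lgs)
    gcol <- c(gf, rep(gs, p - 1))
    R <- chol(XtX + diag(1 / gcol, p))
    q <- backsolve(R, forwardsolve(t(R), Xty))
    -0.5 * (sum(log(gcol)) + 2 * sum(log(diag(R)))) -
      ((n - 1) / 2) * log((yty - sum(Xty * q)) / yty) +
      ig(gf, r_f) + lgf + ig(gs, r_r) + lgs
  }
  Xsc <- sweep(Xs, 2, colMeans(Xs))
  XtXs <- crossprod(Xsc); Xtys <- crossprod(Xsc, yc)
  logm_null <- function(lgs) {
    gs <- exp(lgs)
    R <- chol(XtXs + diag(1 / gs, p - 1))
    q <- backsolve(R, forwardsolve(t(R), Xtys))
    -0.5 * ((p - 1) * log(gs) + 2 * sum(log(diag(R)))) -
      ((n - 1) / 2) * log((yty - sum(Xtys * q)) / yty) +
      ig(gs, r_r) + lgs
  }
  grid <- seq(-12, 8, 0.5)
  m2 <- max(outer(grid, grid, Vectorize(logm_full)))
  I2 <- pracma::integral2(Vectorize(function(a, b) exp(logm_full(a, b) - m2)),
                          -15, 10, -15, 10, reltol = 1e-8)$Q
  m1 <- max(vapply(grid, logm_null, numeric(1)))
  I1 <- pracma::integral(Vectorize(function(a) exp(logm_null(a) - m1)),
                         -15, 10, reltol = 1e-10)
  (m2 + log(I2)) - (m1 + log(I1))
}
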