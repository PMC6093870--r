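test_that("contrast maps reduce trivial epoch sets correctly", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 1)
  n <- max(sched$onset_sample) + 400
  rec <- make_recording(matrix(rnorm(2 * n), 2, n), c("a", "b"))
  ep <- epoch_and_baseline(rec, sched, subject_id = 1)
  one <- epochs_subset(ep, 1)
  maps <- subject_contrast_maps(list(one), "localizer_average")
  expect_equal(maps$values[1, , ], one$data[1, , ])
  # negative trials at +1, neutral at -1 -> difference map of +2 everywhere
  ep2 <- ep
  neg <- ep2$metadata$emotion == "negative"
  ep2$data[neg, , ] <- 1
  ep2$data[!neg, , ] <- -1
  ep2$baseline_corrected <- FALSE
  dmap <- subject_contrast_maps(list(ep2), "emotion_difference")
  expect_true(all(abs(dmap$values - 2) < 1e-12))
})

test_that("emotion-difference map energy concentrates in the true ROI", {
  epn_cluster <- reference_component_specs()$EPN$electrodes
  comps <- list(component_truth(
    "EPN", c(-1.5, -1.5, -1.5, -1.5, 1.5, 1.5, 1.5, 1.5), c(300, 500),
    epn_cluster, "negative", trial_sd_uV = 0.5))
  cfg <- quiet_config(comps, n_subjects = 3, trials_per_cell = 4,
                      noise_sensor_sd_uV = 0.2, seed = 12)
  eps <- simulate_epochs(cfg)
  maps <- subject_contrast_maps(eps, "emotion_difference")
  mean_map <- apply(maps$values, c(2, 3), mean)
  peak <- which(abs(mean_map) == max(abs(mean_map)), arr.ind = TRUE)
  expect_true(maps$labels[peak[1]] %in% epn_cluster)
  expect_true(maps$times_ms[peak[2]] >= 300 && maps$times_ms[peak[2]] <= 500)
})

test_that("a 64 x 256 grid performs 16384 tests", {
  set.seed(3)
  maps <- make_maps(array(rnorm(4 * 64 * 256), c(4, 64, 256)),
                    labels = default_montage()$label,
                    times_ms = seq(0, by = 1000 / 256, length.out = 256))
  res <- tmax_permutation_test(maps, B = 20, seed = 1)
  expect_equal(res$n_tests, 16384)
  expect_equal(length(res$t_obs), 16384)
})

test_that("all-zero data produce t = 0 and p = 1 everywhere", {
  maps <- make_maps(array(0, c(6, 3, 4)))
  res <- tmax_permutation_test(maps, B = 100, seed = 2)
  expect_true(all(res$t_obs == 0))
  expect_true(all(res$p_map == 1))
  expect_false(any(res$sig_mask))
})

test_that("exact enumeration reproduces the brute-force sign-flip p-value", {
  set.seed(42)
  n <- 12
  x <- rnorm(n, 0.6)
  maps <- make_maps(array(x, c(n, 1, 1)))
  res <- tmax_permutation_test(maps, method = "exact")
  expect_equal(res$B, 4096)
  # oracle: enumerate all 2^12 sign assignments with plain loops
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(grid, 1, function(s) abs(t_stat(s * x)))
  expect_equal(unname(res$p_map[1, 1]), mean(null >= abs(t_stat(x))))
  # multichannel exact case agrees too (max over grid per pattern)
  y <- matrix(rnorm(8 * 6, 0.4), 8, 6)
  maps2 <- make_maps(array(y, c(8, 2, 3)))
  res2 <- tmax_permutation_test(maps2, method = "exact")
  grid8 <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  null2 <- apply(grid8, 1, function(s) {
    max(abs(apply(s * y, 2, t_stat)))
  })
  p_oracle <- vapply(seq_len(6), function(j) {
    mean(null2 >= abs(t_stat(y[, j])))
  }, numeric(1))
  expect_equal(as.vector(res2$p_map), p_oracle)
})

test_that("p-values are invariant to channel order and positive scaling", {
  set.seed(9)
  v <- array(rnorm(10 * 4 * 6, 0.3), c(10, 4, 6))
  maps <- make_maps(v, labels = paste0("c", 1:4))
  res <- tmax_permutation_test(maps, B = 400, seed = 5)
  perm <- c(3, 1, 4, 2)
  maps_p <- make_maps(v[, perm, , drop = FALSE], labels = paste0("c", perm))
  res_p <- tmax_permutation_test(maps_p, B = 400, seed = 5)
  expect_equal(res_p$p_map, res$p_map[perm, ])
  maps_s <- make_maps(v * 7.3, labels = paste0("c", 1:4))
  res_s <- tmax_permutation_test(maps_s, B = 400, seed = 5)
  expect_equal(res_s$p_map, res$p_map)
})

test_that("critical_t is non-increasing in alpha and errors with one subject", {
  set.seed(4)
  maps <- make_maps(array(rnorm(8 * 2 * 5), c(8, 2, 5)))
  alphas <- c(0.01, 0.05, 0.2)
  crit <- vapply(alphas, function(a) {
    tmax_permutation_test(maps, B = 300, alpha = a, seed = 3)$critical_t
  }, numeric(1))
  expect_true(all(diff(crit) <= 0))
  expect_error(tmax_permutation_test(make_maps(array(1, c(1, 2, 2)))),
               "2 subjects")
})

test_that("an injected component is re-localized with cluster and window", {
  cluster <- reference_component_specs()$P1$electrodes
  m <- desk_simulation_config()$montage
  topo <- setNames(as.numeric(m$label %in% cluster), m$label)
  comps <- list(component_truth("P1", rep(3, 8), c(66, 148), cluster,
                                "positive", subject_sd_uV = 0.4,
                                trial_sd_uV = 1, topography = topo))
  cfg <- quiet_config(comps, n_subjects = 10, trials_per_cell = 5,
                      noise_sensor_sd_uV = 1, seed = 31)
  eps <- simulate_epochs(cfg)
  maps <- subject_contrast_maps(eps, "localizer_average")
  res <- tmax_permutation_test(maps, B = 800, seed = 7)
  spec <- select_component_roi(res, default_component_priors()$P1, maps)
  expect_setequal(spec$electrodes, cluster)
  # window overlap with ground truth of at least 80%
  ov <- min(spec$window_ms[2], 148) - max(spec$window_ms[1], 66)
  expect_gte(ov / (148 - 66), 0.8)
  expect_equal(spec$source, "localized")
})

test_that("localization failure and mode bookkeeping behave as specified", {
  maps <- make_maps(array(0, c(6, 3, 10)), times_ms = seq(0, 900, 100))
  res <- tmax_permutation_test(maps, B = 100, seed = 1)
  prior <- component_prior("P1", "positive", c(0, 900))
  expect_error(select_component_roi(res, prior, maps), "not localized",
               class = "erpfactor_not_localized")
  # EPN prior carries the emotion-difference mode into the spec
  expect_equal(default_component_priors()$EPN$mode, "emotion_difference")
  expect_equal(reference_component_specs()$EPN$mode, "emotion_difference")
})

test_that("amplitude extraction is the window-cluster mean of each trial", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 2)
  n <- max(sched$onset_sample) + 400
  rec <- make_recording(matrix(0, 2, n), c("a", "b"))
  ep <- epoch_and_baseline(rec, sched, subject_id = 3)
  ep$data[] <- 3          # constant 3 uV after baseline flagging
  ep$baseline_corrected <- FALSE
  spec <- component_spec("X", "positive", c(100, 300), c("a", "b"))
  amp <- extract_single_trial_amplitudes(list(ep), spec)
  expect_equal(amp$amplitude_uV, rep(3, 8))
  expect_equal(amp$subject_id, rep(3, 8))
  # cell mean of single-trial amplitudes equals the cell-average ERP mean
  set.seed(8)
  ep$data[] <- rnorm(length(ep$data))
  amp2 <- extract_single_trial_amplitudes(list(ep), spec)
  cell <- amp2[amp2$emotion == "negative" & amp2$size == "large" &
                 amp2$contrast == "high", ]
  tr <- which(ep$metadata$emotion == "negative" & ep$metadata$size == "large" &
                ep$metadata$contrast == "high")
  times <- epoch_times_ms(ep)
  wsel <- times >= 100 & times <= 300
  erp <- apply(ep$data[tr, , wsel, drop = FALSE], c(2, 3), mean)
  expect_equal(mean(cell$amplitude_uV), mean(erp), tolerance = 1e-9)
})

test_that("rejected trials never contribute amplitudes", {
  cfg <- desk_simulation_config(n_subjects = 1, trials_per_cell = 5,
                                probes_per_cell = 1, n_runs = 1,
                                artifact_rate = 0.3, seed = 17)
  ep <- simulate_epochs(cfg, 1)[[1]]
  ep <- reject_artifacts_threshold(ep, 250)
  amp <- extract_single_trial_amplitudes(list(ep),
                                         reference_component_specs()$P1)
  expect_false(any(amp$trial_index %in% which(ep$rejected_mask)))
})

test_that("peak extraction finds height, latency, polarity and ties", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 2)
  n <- max(sched$onset_sample) + 400
  rec <- make_recording(matrix(0, 1, n), "a")
  ep <- epoch_and_baseline(rec, sched, subject_id = 1)
  times <- epoch_times_ms(ep)
  bump <- 5 * exp(-(times - 100)^2 / (2 * 15^2))
  for (i in seq_len(8)) ep$data[i, 1, ] <- bump
  spec <- component_spec("X", "positive", c(50, 200), "a")
  pk <- extract_peaks(list(ep), spec)
  expect_equal(nrow(pk), 8)
  # sample-grid discretization can miss the analytic peak by < 2 ms
  expect_equal(pk$peak_amplitude_uV, rep(5, 8), tolerance = 0.01)
  expect_true(all(abs(pk$peak_latency_ms - 100) <= 1000 / 256))
  # negative polarity on inverted data finds the trough at the same latency
  ep$data <- -ep$data
  spec_n <- component_spec("X", "negative", c(50, 200), "a")
  pk_n <- extract_peaks(list(ep), spec_n)
  expect_equal(pk_n$peak_amplitude_uV, rep(-5, 8), tolerance = 0.01)
  # noisy bump: latency matches a direct argmax oracle on the same average
  set.seed(11)
  for (i in seq_len(8)) ep$data[i, 1, ] <- bump + rnorm(length(bump), 0, 0.5)
  pk2 <- extract_peaks(list(ep), spec)
  md <- ep$metadata
  for (ci in 1:2) {
    cell <- design_cells()[ci, ]
    tr <- which(md$emotion == cell$emotion & md$size == cell$size &
                  md$contrast == cell$contrast)
    wsel <- which(times >= 50 & times <= 200)
    wave <- apply(ep$data[tr, 1, wsel, drop = FALSE], 3, mean)
    oracle_lat <- times[wsel[which.max(wave)]]
    got <- pk2$peak_latency_ms[pk2$emotion == cell$emotion &
                                 pk2$size == cell$size &
                                 pk2$contrast == cell$contrast]
    expect_lte(abs(got - oracle_lat), 1000 / 256)
  }
  # flat segment ties resolve to the earliest sample
  ep$data[, 1, ] <- 0
  ep$data[, 1, 100:110] <- 1
  pk3 <- extract_peaks(list(ep), component_spec("X", "positive",
                                                c(-100, 900), "a"))
  expect_equal(unique(pk3$peak_latency_ms), times[100])
})
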