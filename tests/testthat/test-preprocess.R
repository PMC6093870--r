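test_that("re-referencing obeys its defining identities", {
  set.seed(2)
  m <- default_montage(c("Cz", "Pz", "Oz", "P7", "P8"))
  x <- matrix(rnorm(5 * 500), 5, dimnames = list(m$label, NULL))
  rec <- make_recording(x, labels = m$label)
  avg <- detrend_and_rereference(rec, "average")
  expect_lt(max(abs(colMeans(avg$data))), 1e-9)
  cz <- detrend_and_rereference(rec, "Cz")
  expect_true(all(abs(cz$data["Cz", ]) < 1e-9))
  expect_error(detrend_and_rereference(make_recording(x[2:5, ],
                                                      labels = m$label[2:5]),
                                       "Cz"), "Cz")
})

test_that("linear trends are removed to least-squares precision", {
  n <- 400
  tt <- seq_len(n)
  x <- rbind(2 + 0.03 * tt, -1 - 0.01 * tt)
  out <- detrend_and_rereference(make_recording(x, c("a", "b")), "none")
  # oracle: refit a line per channel, slope and level must vanish
  for (i in 1:2) {
    fit <- stats::lm.fit(cbind(1, tt), out$data[i, ])
    expect_lt(max(abs(fit$coefficients)), 1e-9)
  }
})

test_that("spherical splines reproduce constants and smooth fields", {
  m <- default_montage()
  rec <- make_recording(matrix(3.5, 64, 5), labels = m$label)
  out <- interpolate_spherical_spline(rec, c("PO7", "C3"), m)
  expect_lt(max(abs(out$data - 3.5)), 1e-6)
  # leave-one-out on the analytic field v = z at interior channels
  v <- m$z
  for (ch in c("Cz", "C3", "Pz", "CP1", "FC2")) {
    r2 <- make_recording(matrix(v, 64, 1), labels = m$label)
    o <- interpolate_spherical_spline(r2, ch, m)
    truth <- v[m$label == ch]
    expect_lt(abs(o$data[m$label == ch, 1] - truth) / abs(truth), 0.05)
  }
})

test_that("interpolation never touches good channels and clears all flags", {
  set.seed(5)
  m <- default_montage()
  x <- matrix(rnorm(64 * 50), 64, dimnames = list(m$label, NULL))
  bad <- c("P7", "F3", "Oz", "C4")
  out <- interpolate_spherical_spline(make_recording(x, labels = m$label),
                                      bad, m)
  good <- setdiff(m$label, bad)
  expect_identical(out$data[match(good, m$label), ],
                   x[match(good, m$label), ])
  expect_false(any(out$data[match(bad, m$label), ] ==
                     x[match(bad, m$label), ]))
  expect_error(interpolate_spherical_spline(
    make_recording(x, labels = m$label), m$label, m), "at least 4")
})

test_that("epoching yields the half-open 307-sample window with zero baseline", {
  sched <- build_trial_schedule(2, 1, 1, c(1000, 1200), seed = 4)
  n <- max(sched$onset_sample) + 400
  set.seed(6)
  rec <- make_recording(matrix(rnorm(3 * n) + 10, 3, n), c("a", "b", "c"))
  ep <- epoch_and_baseline(rec, sched)
  expect_equal(unname(epoch_dims(ep)), c(20, 3, 307))
  times <- epoch_times_ms(ep)
  expect_true(all(times >= -200 & times < 1000))
  bl <- apply(ep$data[, , times < 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
})

test_that("epoching is idempotent on baseline-corrected data", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 1)
  n <- max(sched$onset_sample) + 400
  rec <- make_recording(matrix(sin(seq_len(n) / 10), 1, n), "a")
  ep1 <- epoch_and_baseline(rec, sched)
  # re-running baseline correction on already-corrected epochs changes nothing
  times <- epoch_times_ms(ep1)
  bl <- apply(ep1$data[, , times < 0, drop = FALSE], c(1, 2), mean)
  ep2 <- ep1
  ep2$data <- ep1$data - array(bl, dim = dim(ep1$data))
  expect_equal(ep2$data, ep1$data, tolerance = 1e-12)
})

test_that("epochs beyond the recording bounds raise an error naming trials", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 1)
  rec <- make_recording(matrix(0, 1, max(sched$onset_sample) + 10), "a")
  expect_error(epoch_and_baseline(rec, sched), "trial")
})

test_that("threshold rejection flags exactly the exceeding epochs", {
  sched <- build_trial_schedule(1, 0, 1, c(1000, 1000), seed = 1)
  n <- max(sched$onset_sample) + 400
  rec <- make_recording(matrix(0, 2, n), c("a", "b"))
  rec$data[2, sched$onset_sample[3] + 100] <- 500
  ep <- epoch_and_baseline(rec, sched)
  out <- reject_artifacts_threshold(ep, 250)
  expect_equal(which(out$rejected_mask), 3L)
  expect_identical(out$data, ep$data)
  none <- reject_artifacts_threshold(ep, Inf)
  expect_false(any(none$rejected_mask))
})

test_that("QC applies the strict accuracy and bad-channel rules", {
  ep <- structure(list(metadata = tibble::tibble(subject_id = 5)),
                  class = "epochs_set")
  beh <- tibble::tibble(size = rep(c("large", "small"), each = 2),
                        contrast = rep(c("high", "low"), 2),
                        accuracy = c(0.79, 0.95, 0.95, 0.95))
  qc <- qc_dataset(ep, beh, n_bad_channels = 2)
  expect_true(qc$excluded)
  expect_equal(qc$reasons, "accuracy")
  beh$accuracy <- 1
  qc2 <- qc_dataset(ep, beh, n_bad_channels = 11)
  expect_true(qc2$excluded)
  expect_equal(qc2$reasons, "bad channels")
  # boundary: exactly 10 bad channels and exactly 80% accuracy pass
  beh$accuracy <- 0.80
  qc3 <- qc_dataset(ep, beh, n_bad_channels = 10)
  expect_false(qc3$excluded)
  expect_error(qc_dataset(ep, beh[1:3, ], 0), "cell")
})

test_that("the full chain preserves injected window means within 2 percent", {
  comps <- default_component_truths(sd_scale = 0)
  cfg <- quiet_config(comps, trials_per_cell = 1, probes_per_cell = 0)
  ses <- simulate_session(cfg, 1)
  hp <- design_windowed_sinc_fir("highpass", 0.5, 0.5, 1690)
  lp <- design_windowed_sinc_fir("lowpass", 30, 7.4, 114)
  ep <- preprocess_session(ses, cfg$montage, hp = hp, lp = lp,
                           subject_id = 1)
  # average reference shifts all channels; compare against the noiseless
  # epoched path run through the same reference
  raw <- epoch_and_baseline(detrend_and_rereference(ses$recording, "average"),
                            ses$schedule, subject_id = 1)
  for (nm in c("P1", "N1", "EPN", "LPP")) {
    sp <- reference_component_specs()[[nm]]
    a_f <- extract_single_trial_amplitudes(list(ep), sp)$amplitude_uV
    a_r <- extract_single_trial_amplitudes(list(raw), sp)$amplitude_uV
    expect_lt(sqrt(mean((a_f - a_r)^2) / mean(a_r^2)), 0.02)
  }
})
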