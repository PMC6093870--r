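# End-to-end study orchestration: sequential Bayes-factor monitoring with
# the pre-registered stopping rules, and the reproducible study report.

#' Pre-registered sequential stopping rules
#'
#' @param start_n First sample size at which Bayes factors are monitored
#'   (default 20).
#' @param step Monitoring interval in participants (default 3).
#' @param bf_threshold Natural-scale evidence threshold (default 10).
#' @param max_n Pragmatic maximum sample size (default 40); the final check
#'   is clipped to `max_n` even when the step grid overshoots it.
#' @return A `sequential_rules` object.
#' @export
sequential_rules <- function(start_n = 20, step = 3, bf_threshold = 10,
                             max_n = 40) {
  stopifnot(start_n >= 2, step >= 1, bf_threshold > 1, max_n >= start_n)
  structure(
    list(start_n = as.integer(start_n), step = as.integer(step),
         bf_threshold = bf_threshold, max_n = as.integer(max_n)),
    class = "sequential_rules"
  )
}

#' Monitoring schedule implied by a set of sequential rules
#' @param rules A [sequential_rules()].
#' @return Integer vector of check sample sizes; always ends at `max_n`.
#' @export
sequential_check_schedule <- function(rules) {
  checks <- seq(rules$start_n, rules$max_n, by = rules$step)
  if (tail(checks, 1) != rules$max_n) checks <- c(checks, rules$max_n)
  checks
}

#' Sequential Bayes-factor monitor
#'
#' Replays the pre-registered optional-stopping procedure over an amplitude
#' table: at each check sample size, the six candidate models are compared
#' on the first `n` participants (in arrival order) and the statistical rule
#' fires when the best model beats the null by `bf_threshold` (or the null
#' beats the best model by the same factor) *and* beats the second-best
#' model by `bf_threshold`.  With several components, the study-level stop
#' requires the rule to fire for all monitored components; components listed
#' in `defer_components` (e.g. not yet localized) defer stopping.  If no
#' check fires, the pragmatic rule stops at `max_n`.  The monitor never
#' inspects participants beyond the current check.
#'
#' @param table Amplitude tibble covering all subjects seen so far.
#' @param rules A [sequential_rules()].
#' @param prior A [prior_spec()] used at every check.
#' @param n_iterations,seed Monte-Carlo settings per model fit.
#' @param models Candidate model list (default [candidate_models()]).
#' @param defer_components Character vector of component names whose
#'   localization has not succeeded; the statistical rule cannot fire while
#'   any monitored component is deferred.
#' @param require_all Stop only when every component fires (default TRUE);
#'   otherwise any single component suffices.
#' @return A `sequential_decision`: tibble `checks` (one row per check x
#'   component), `stopped_at_n`, `reason` (`"statistical"` or
#'   `"pragmatic"`).
#' @export
sequential_bf_monitor <- function(table, rules = sequential_rules(),
                                  prior = prior_spec(),
                                  n_iterations = 10000, seed = 1,
                                  models = candidate_models(),
                                  defer_components = character(0),
                                  require_all = TRUE) {
  stopifnot(inherits(rules, "sequential_rules"))
  if (!"component" %in% names(table)) table$component <- "amplitude"
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < rules$start_n) {
    abort(sprintf("monitoring starts at n = %d but only %d subjects are available",
                  rules$start_n, length(subjects)))
  }
  checks <- sequential_check_schedule(rules)
  checks <- checks[checks <= length(subjects)]
  log_thr <- log(rules$bf_threshold)
  rows <- list()
  stopped_at <- NA_integer_
  reason <- NA_character_
  for (n in checks) {
    sub <- table[table$subject_id %in% subjects[seq_len(n)], ]
    fired_all <- TRUE
    fired_any <- FALSE
    for (comp in unique(sub$component)) {
      cmp <- compare_candidate_models(sub[sub$component == comp, ],
                                      r_fixed = prior$r_fixed,
                                      r_random = prior$r_random,
                                      n_iterations = n_iterations,
                                      seed = seed, models = models)
      best <- cmp[cmp$rank == 1, ]
      localized <- !(comp %in% defer_components)
      fired <- localized &&
        (best$log_bf10 > log_thr || best$log_bf10 < -log_thr) &&
        best$log_bf_best_vs_second > log_thr
      fired_all <- fired_all && fired
      fired_any <- fired_any || fired
      rows[[length(rows) + 1]] <- tibble(
        n = n, component = comp, best_model = best$model,
        log_bf_best_vs_null = best$log_bf10,
        log_bf_best_vs_second = best$log_bf_best_vs_second,
        localized = localized,
        fired_rule = if (fired) "statistical" else "none"
      )
    }
    stop_now <- if (require_all) fired_all else fired_any
    if (stop_now) {
      stopped_at <- n
      reason <- "statistical"
      break
    }
    if (n >= rules$max_n) {
      stopped_at <- n
      reason <- "pragmatic"
    }
  }
  if (is.na(stopped_at)) {
    stopped_at <- tail(checks, 1)
    reason <- "pragmatic"
  }
  structure(
    list(checks = bind_rows(rows), stopped_at_n = stopped_at,
         reason = reason, rules = rules),
    class = "sequential_decision"
  )
}

#' @export
print.sequential_decision <- function(x, ...) {
  cat(sprintf("<sequential_decision> stopped at n = %d (%s rule)\n",
              x$stopped_at_n, x$reason))
  print(x$checks)
  invisible(x)
}

#' Configuration for an end-to-end study run
#'
#' @param simulation A [simulation_config()].
#' @param filter Logical: run the FIR filtering chain (high-pass 0.5 Hz /
#'   order 1690, low-pass 30 Hz / order 114) on the continuous data.  When
#'   `FALSE`, epochs come straight from the generator.
#' @param reject_uV Artifact rejection threshold (µV).
#' @param localization `"auto"` (t-max selection, error when a component is
#'   not found), `"reference"` (packaged windows/clusters), or
#'   `"auto_fallback"` (default: t-max selection, falling back to the
#'   packaged reference spec for components the localizer cannot find).
#' @param B,alpha Permutation count and FWER level for the localizer.
#' @param priors Search priors for localization
#'   ([default_component_priors()]).
#' @param r_fixed Prior scales for the Bayes-factor tables.
#' @param r_random Participant-batch prior scale.
#' @param n_iterations Monte-Carlo draws per model marginal.
#' @param sequential A [sequential_rules()] or `NULL` to skip monitoring.
#' @param monitor_r Prior scale used by the sequential monitor (the most
#'   conservative scale by default, r = 0.5).
#' @param seed Master analysis seed (localizer permutations, Monte-Carlo).
#' @return A `study_config` list.
#' @export
study_config <- function(simulation = desk_simulation_config(),
                         filter = FALSE, reject_uV = 250,
                         localization = c("auto_fallback", "auto", "reference"),
                         B = 1000, alpha = 0.05,
                         priors = default_component_priors(),
                         r_fixed = c(0.5, 0.707, 1), r_random = 1,
                         n_iterations = 10000,
                         sequential = sequential_rules(),
                         monitor_r = 0.5, seed = 1) {
  localization <- match.arg(localization)
  structure(
    list(simulation = simulation, filter = filter, reject_uV = reject_uV,
         localization = localization, B = B, alpha = alpha, priors = priors,
         r_fixed = r_fixed, r_random = r_random,
         n_iterations = n_iterations, sequential = sequential,
         monitor_r = monitor_r, seed = as.integer(seed)),
    class = "study_config"
  )
}

# per-subject preprocessing for run_study
run_study_subject <- function(config, sid) {
  sim <- config$simulation
  ses <- simulate_session(sim, sid)
  if (config$filter) {
    hp <- design_windowed_sinc_fir("highpass", 0.5, 0.5, 1690, sim$sfreq_hz)
    lp <- design_windowed_sinc_fir("lowpass", 30, 7.4, 114, sim$sfreq_hz)
    ep <- preprocess_session(ses, sim$montage,
                             bad_labels = ses$truth$bad_channels,
                             hp = hp, lp = lp, reject_uV = config$reject_uV,
                             subject_id = sid)
  } else {
    ep <- epoch_and_baseline(ses$recording, ses$schedule, subject_id = sid)
    if (length(ses$truth$bad_channels) > 0) {
      ep <- interpolate_spherical_spline(ep, ses$truth$bad_channels,
                                         sim$montage)
    }
    if (!is.null(config$reject_uV)) {
      ep <- reject_artifacts_threshold(ep, config$reject_uV)
    }
  }
  qc <- qc_dataset(ep, ses$behavior,
                   n_bad_channels = length(ses$truth$bad_channels))
  list(epochs = ep, behavior = ses$behavior, qc = qc, truth = ses$truth)
}

#' Run a complete synthetic study end to end
#'
#' Simulates (or consumes) every subject, preprocesses and quality-controls
#' the data, localizes the four components (P1, N1, LPP on the pooled
#' localizer average; EPN on the negative-minus-neutral difference),
#' extracts single-trial amplitudes, produces the cell-mean summary and the
#' three Bayes-factor tables (model comparison, top-down omission, post-hoc
#' contrasts), and replays the sequential stopping rule.  Fully reproducible
#' from `(config, seed)`.
#'
#' @param config A [study_config()].
#' @return A `study_report` list with elements `qc`, `component_specs`,
#'   `cell_means`, `amplitudes`, `model_comparison`, `omission`, `posthoc`,
#'   `sequential`, `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sim <- config$simulation
  subjects <- seq_len(sim$n_subjects)
  prep <- lapply(subjects, function(sid) run_study_subject(config, sid))
  qc <- lapply(prep, `[[`, "qc")
  included <- !vapply(qc, `[[`, logical(1), "excluded")
  if (!any(included)) abort("run_study: every subject was excluded by QC")
  epochs <- lapply(prep[included], `[[`, "epochs")

  maps <- list(
    localizer_average = subject_contrast_maps(epochs, "localizer_average"),
    emotion_difference = subject_contrast_maps(epochs, "emotion_difference")
  )
  specs <- list()
  tmax <- list()
  if (config$localization == "reference") {
    specs <- reference_component_specs()
  } else {
    for (nm in names(config$priors)) {
      prior <- config$priors[[nm]]
      mp <- maps[[prior$mode]]
      res <- tmax_permutation_test(mp, B = config$B, alpha = config$alpha,
                                   seed = config$seed)
      tmax[[nm]] <- res
      spec <- tryCatch(
        select_component_roi(res, prior, mp),
        erpfactor_not_localized = function(cnd) {
          if (config$localization == "auto") rlang::cnd_signal(cnd)
          NULL
        }
      )
      specs[[nm]] <- spec %||% reference_component_specs()[[nm]]
    }
  }

  amplitudes <- bind_rows(lapply(specs, function(sp) {
    extract_single_trial_amplitudes(epochs, sp)
  }))
  cell_means <- amplitudes |>
    group_by(.data$component, .data$subject_id, .data$emotion, .data$size,
             .data$contrast) |>
    summarise(m = mean(.data$amplitude_uV), .groups = "drop") |>
    group_by(.data$component, .data$emotion, .data$size, .data$contrast) |>
    summarise(mean_uV = mean(.data$m), sd_uV = sd(.data$m), .groups = "drop")

  model_comparison <- compare_candidate_models(
    amplitudes, r_fixed = config$r_fixed, r_random = config$r_random,
    n_iterations = config$n_iterations, seed = config$seed)
  omission <- topdown_term_omission(
    amplitudes, r_fixed = config$r_fixed, r_random = config$r_random,
    n_iterations = config$n_iterations, seed = config$seed)
  posthoc <- posthoc_emotion_contrasts(amplitudes, r = config$r_fixed)

  sequential <- NULL
  if (!is.null(config$sequential) &&
      length(unique(amplitudes$subject_id)) >= config$sequential$start_n) {
    not_localized <- names(specs)[vapply(specs, function(sp) {
      sp$source == "reference" && config$localization != "reference"
    }, logical(1))]
    sequential <- sequential_bf_monitor(
      amplitudes, rules = config$sequential,
      prior = prior_spec(r_fixed = config$monitor_r,
                         r_random = config$r_random),
      n_iterations = config$n_iterations, seed = config$seed,
      defer_components = not_localized
    )
  }

  report <- structure(
    list(
      qc = tibble(
        subject_id = subjects,
        n_bad_channels = vapply(qc, `[[`, numeric(1), "n_bad_channels"),
        min_cell_accuracy = vapply(qc, `[[`, numeric(1), "min_cell_accuracy"),
        excluded = !included,
        reasons = vapply(qc, function(q) paste(q$reasons, collapse = ";"),
                         character(1))
      ),
      component_specs = specs,
      cell_means = cell_means,
      amplitudes = amplitudes,
      model_comparison = model_comparison,
      omission = omission,
      posthoc = posthoc,
      sequential = sequential,
      provenance = list(
        seed = config$seed, simulation_seed = sim$seed,
        n_subjects = sim$n_subjects, n_included = sum(included),
        localization = config$localization,
        package_version = as.character(utils::packageVersion("erpfactor"))
      )
    ),
    class = "study_report"
  )
  report$provenance$hash <- rlang::hash(report[c(
    "qc", "cell_means", "amplitudes", "model_comparison", "omission",
    "posthoc"
  )])
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  subjects: %d simulated, %d included\n",
              nrow(x$qc), x$provenance$n_included))
  cat(sprintf("  components: %s\n",
              paste(names(x$component_specs), collapse = ", ")))
  if (!is.null(x$sequential)) {
    cat(sprintf("  sequential decision: stop at n = %d (%s)\n",
                x$sequential$stopped_at_n, x$sequential$reason))
  }
  cat(sprintf("  provenance hash: %s\n", x$provenance$hash))
  invisible(x)
}
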