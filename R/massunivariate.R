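# Mass-univariate localization: per-subject contrast maps, the t-max
# permutation test with family-wise error control, automated component
# window/cluster selection, and single-trial amplitude / peak extraction.

#' Per-subject contrast maps
#'
#' Reduces each subject's epochs to one channel x sample map.  In
#' `localizer_average` mode the map is the mean over all retained target
#' trials (all conditions pooled); in `emotion_difference` mode it is the
#' mean over negative trials minus the mean over neutral trials, collapsing
#' size and contrast.
#'
#' @param epochs_by_subject List of `epochs_set`, one per subject.
#' @param mode `"localizer_average"` or `"emotion_difference"`.
#' @return A `contrast_maps` object: array `values` (subject x channel x
#'   sample), `labels`, `times_ms`, `mode`, `subject_ids`.
#' @export
subject_contrast_maps <- function(epochs_by_subject,
                                  mode = c("localizer_average",
                                           "emotion_difference")) {
  mode <- match.arg(mode)
  stopifnot(length(epochs_by_subject) >= 1)
  first <- epochs_by_subject[[1]]
  times <- epoch_times_ms(first)
  maps <- lapply(epochs_by_subject, function(ep) {
    tgt <- target_epochs(ep)
    sid <- ep$metadata$subject_id[1]
    if (mode == "localizer_average") {
      if (nrow(tgt$metadata) == 0) {
        abort(sprintf("subject %s has no retained target trials", sid))
      }
      colMeans(tgt$data)
    } else {
      neg <- tgt$metadata$emotion == "negative"
      neu <- tgt$metadata$emotion == "neutral"
      if (!any(neg) || !any(neu)) {
        abort(sprintf("subject %s lacks trials in an emotion level", sid))
      }
      colMeans(tgt$data[neg, , , drop = FALSE]) -
        colMeans(tgt$data[neu, , , drop = FALSE])
    }
  })
  values <- aperm(simplify2array(maps), c(3, 1, 2))
  structure(
    list(values = values, labels = first$labels, times_ms = times,
         mode = mode,
         subject_ids = vapply(epochs_by_subject,
                              function(ep) ep$metadata$subject_id[1],
                              numeric(1))),
    class = "contrast_maps"
  )
}

#' Construct contrast maps from a subject x channel x sample array
#'
#' Low-level constructor for feeding externally computed per-subject maps
#' (e.g. simulated null data) straight into [tmax_permutation_test()].
#'
#' @param values Numeric array, subject x channel x sample.
#' @param labels Channel labels (default `ch1..chK`).
#' @param times_ms Sample times in ms (default sample index).
#' @param mode Contrast mode label.
#' @param subject_ids Subject identifiers.
#' @return A `contrast_maps` object.
#' @export
as_contrast_maps <- function(values,
                             labels = paste0("ch", seq_len(dim(values)[2])),
                             times_ms = seq_len(dim(values)[3]),
                             mode = "localizer_average",
                             subject_ids = seq_len(dim(values)[1])) {
  stopifnot(length(dim(values)) == 3, length(labels) == dim(values)[2],
            length(times_ms) == dim(values)[3])
  structure(
    list(values = values, labels = labels, times_ms = times_ms,
         mode = mode, subject_ids = subject_ids),
    class = "contrast_maps"
  )
}

# sign-flipped one-sample t statistics for a block of sign vectors.
# X: n x k data matrix; signs: b x n matrix of +/-1.  Returns b x k t values
# (0 where the flipped sample variance is 0).
signflip_t <- function(X, signs, ss) {
  n <- nrow(X)
  M <- (signs %*% X) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  T <- M / sqrt(V / n)
  T[!is.finite(T)] <- 0
  T
}

#' t-max permutation test against zero
#'
#' One-sample t tests of the per-subject maps against zero at every channel
#' x sample point, with family-wise error control by the permutation
#' distribution of the maximum absolute t over the whole grid.  The null is
#' built by per-subject sign flips (assigning each subject's map its actual
#' value or its negation, the paired-difference form of the value-or-zero
#' label swap).  P-values use the add-one correction
#' `p = (1 + #(null >= |t|)) / (1 + B)`; with `method = "exact"` all `2^n`
#' sign patterns are enumerated instead and `p = #(null >= |t|) / 2^n`.
#' Zero-variance points are assigned t = 0.
#'
#' @param maps A `contrast_maps` object.
#' @param B Number of random permutations (default 5000).
#' @param alpha Family-wise error rate (default 0.05).
#' @param seed Integer seed for the permutation draws.
#' @param method `"monte_carlo"` (default) or `"exact"` enumeration.
#' @return A `tmax_result`: `t_obs` (channel x sample), `null_tmax`,
#'   `critical_t` (the `1 - alpha` quantile of `null_tmax`), `p_map`,
#'   `sig_mask` (`|t_obs| > critical_t`), `alpha`, `B`, `seed`, `n_tests`.
#' @export
tmax_permutation_test <- function(maps, B = 5000, alpha = 0.05, seed = 1,
                                  method = c("monte_carlo", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "contrast_maps"), B >= 1, alpha > 0, alpha < 1)
  d <- dim(maps$values)
  n <- d[1]
  if (n < 2) abort("at least 2 subjects are required to build a permutation distribution")
  X <- matrix(maps$values, nrow = n)       # n x (channels*samples)
  ss <- colSums(X^2)
  t_obs_flat <- signflip_t(X, matrix(1, 1, n), ss)[1, ]

  if (method == "exact") {
    if (n > 20) abort("exact enumeration limited to n <= 20 subjects")
    B <- 2L^n
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    grid <- NULL
  }

  null_tmax <- numeric(B)
  chunk <- max(1L, min(B, floor(2e6 / length(t_obs_flat))))
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    signs <- if (is.null(grid)) {
      matrix(sample(c(-1, 1), nb * n, replace = TRUE), nrow = nb)
    } else {
      grid[done + seq_len(nb), , drop = FALSE]
    }
    Tb <- abs(signflip_t(X, signs, ss))
    null_tmax[done + seq_len(nb)] <- apply(Tb, 1, max)
    done <- done + nb
  }

  abs_t <- abs(t_obs_flat)
  exceed <- vapply(abs_t, function(a) sum(null_tmax >= a), numeric(1))
  p_flat <- if (method == "exact") exceed / B else (1 + exceed) / (1 + B)
  critical_t <- unname(quantile(null_tmax, 1 - alpha))

  shape <- function(v) {
    matrix(v, nrow = d[2], ncol = d[3],
           dimnames = list(maps$labels, NULL))
  }
  structure(
    list(t_obs = shape(t_obs_flat), null_tmax = null_tmax,
         critical_t = critical_t, p_map = shape(p_flat),
         sig_mask = shape(abs_t > critical_t),
         times_ms = maps$times_ms, labels = maps$labels,
         mode = maps$mode, alpha = alpha, B = B,
         seed = if (method == "exact") NA_integer_ else seed,
         method = method, n_subjects = n,
         n_tests = d[2] * d[3]),
    class = "tmax_result"
  )
}

#' @export
print.tmax_result <- function(x, ...) {
  cat(sprintf(
    "<tmax_result> %d tests (%d channels x %d samples), n = %d subjects\n",
    x$n_tests, nrow(x$t_obs), ncol(x$t_obs), x$n_subjects))
  cat(sprintf("  B = %d (%s), alpha = %g, critical |t| = %.3f, %d significant points\n",
              x$B, x$method, x$alpha, x$critical_t, sum(x$sig_mask)))
  invisible(x)
}

#' Search prior for automated component selection
#'
#' Encodes the well-known characteristics (polarity, latency range,
#' topographic extent) a localized component must match.
#'
#' @param name Component name.
#' @param polarity Expected deflection polarity.
#' @param search_range_ms Latency window to search.
#' @param min_duration_ms Minimum duration of the significant run.
#' @param min_electrodes Minimum simultaneously significant electrodes.
#' @param mode Contrast the component is localized on.
#' @return A `component_prior` object.
#' @export
component_prior <- function(name, polarity = c("positive", "negative"),
                            search_range_ms, min_duration_ms = 20,
                            min_electrodes = 2,
                            mode = c("localizer_average",
                                     "emotion_difference")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  stopifnot(length(search_range_ms) == 2,
            search_range_ms[1] < search_range_ms[2],
            min_duration_ms >= 0, min_electrodes >= 1)
  structure(
    list(name = name, polarity = polarity,
         search_range_ms = as.numeric(search_range_ms),
         min_duration_ms = min_duration_ms,
         min_electrodes = as.integer(min_electrodes), mode = mode),
    class = "component_prior"
  )
}

#' Default search priors for the four components
#' @return Named list of [component_prior()] objects.
#' @export
default_component_priors <- function() {
  list(
    P1 = component_prior("P1", "positive", c(50, 200)),
    N1 = component_prior("N1", "negative", c(120, 300)),
    EPN = component_prior("EPN", "negative", c(200, 600),
                          mode = "emotion_difference"),
    LPP = component_prior("LPP", "positive", c(350, 800))
  )
}

#' A localized component specification
#'
#' @param name Component name.
#' @param polarity `"positive"` or `"negative"`.
#' @param window_ms Length-2 analysis window.
#' @param electrodes Electrode cluster (non-empty).
#' @param mode Contrast the component was localized on.
#' @param source `"localized"` or `"reference"` (packaged windows).
#' @return A `component_spec` object.
#' @export
component_spec <- function(name, polarity, window_ms, electrodes,
                           mode = c("localizer_average", "emotion_difference"),
                           source = "reference") {
  mode <- match.arg(mode)
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2],
            length(electrodes) >= 1)
  structure(
    list(name = name, polarity = polarity,
         window_ms = as.numeric(window_ms),
         electrodes = electrodes, mode = mode, source = source),
    class = "component_spec"
  )
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("<component_spec> %s (%s, %s): %g-%g ms, %d electrodes [%s]\n",
              x$name, x$polarity, x$mode, x$window_ms[1], x$window_ms[2],
              length(x$electrodes), x$source))
  invisible(x)
}

#' Select a component window and electrode cluster from a t-max result
#'
#' Deterministic replacement for visual curation: within the prior's latency
#' range, keep grid points that are significant and whose mean map matches
#' the expected polarity; find the longest run of consecutive samples during
#' which at least `min_electrodes` such points coexist; the component window
#' is that run and the cluster contains the electrodes significant in at
#' least half of the run's samples.
#'
#' @param result A `tmax_result`.
#' @param prior A [component_prior()].
#' @param maps The `contrast_maps` the result was computed from (provides
#'   the mean map used for polarity matching).
#' @return A [component_spec()] with `source = "localized"`.
#' @export
select_component_roi <- function(result, prior, maps) {
  stopifnot(inherits(result, "tmax_result"), inherits(prior, "component_prior"))
  times <- result$times_ms
  mean_map <- apply(maps$values, c(2, 3), mean)
  pol <- if (prior$polarity == "positive") 1 else -1
  ok <- result$sig_mask & (pol * mean_map > 0)
  in_range <- times >= prior$search_range_ms[1] &
    times <= prior$search_range_ms[2]
  counts <- colSums(ok) * in_range
  qual <- counts >= prior$min_electrodes
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) > 0) {
    lens <- r$lengths[runs]
    best <- runs[which.max(lens)]           # longest run, earliest on ties
    i1 <- starts[best]; i2 <- ends[best]
    dur_ms <- (i2 - i1 + 1) * diff(times[1:2])
    if (dur_ms >= prior$min_duration_ms) {
      frac <- rowMeans(ok[, i1:i2, drop = FALSE])
      electrodes <- result$labels[frac >= 0.5]
      if (length(electrodes) >= 1) {
        return(component_spec(prior$name, prior$polarity,
                              c(times[i1], times[i2]), electrodes,
                              mode = prior$mode, source = "localized"))
      }
    }
  }
  abort(sprintf("component not localized: %s", prior$name),
        class = "erpfactor_not_localized")
}

#' Extract single-trial mean amplitudes for a component
#'
#' For every retained (non-rejected) target trial of every subject, the
#' amplitude is the mean over the component's window samples and electrode
#' cluster.
#'
#' @param epochs_by_subject List of `epochs_set`.
#' @param spec A [component_spec()].
#' @return A tibble with columns `subject_id`, `trial_index`, `emotion`,
#'   `size`, `contrast`, `component`, `amplitude_uV`.
#' @export
extract_single_trial_amplitudes <- function(epochs_by_subject, spec) {
  stopifnot(inherits(spec, "component_spec"))
  rows <- lapply(epochs_by_subject, function(ep) {
    missing <- setdiff(spec$electrodes, ep$labels)
    if (length(missing) > 0) {
      abort(paste0("epochs lack spec electrodes: ", paste(missing, collapse = ", ")))
    }
    tgt <- target_epochs(ep)
    if (nrow(tgt$metadata) == 0) {
      abort(sprintf("subject %s has no retained target trials",
                    ep$metadata$subject_id[1]))
    }
    times <- epoch_times_ms(tgt)
    wsel <- times >= spec$window_ms[1] & times <= spec$window_ms[2]
    csel <- match(spec$electrodes, tgt$labels)
    amp <- rowMeans(matrix(tgt$data[, csel, wsel], nrow = dim(tgt$data)[1]))
    tibble(
      subject_id = tgt$metadata$subject_id,
      trial_index = tgt$metadata$trial_index,
      emotion = tgt$metadata$emotion,
      size = tgt$metadata$size,
      contrast = tgt$metadata$contrast,
      component = spec$name,
      amplitude_uV = amp
    )
  })
  bind_rows(rows)
}

#' Extract per-condition peak amplitude and latency
#'
#' For each subject and design cell, averages the retained target epochs
#' over the component's electrode cluster and finds the extremum (maximum
#' for positive, minimum for negative polarity) within the component window;
#' ties resolve to the earliest sample.
#'
#' @inheritParams extract_single_trial_amplitudes
#' @return A tibble: `subject_id`, `emotion`, `size`, `contrast`,
#'   `component`, `peak_amplitude_uV`, `peak_latency_ms`.
#' @export
extract_peaks <- function(epochs_by_subject, spec) {
  stopifnot(inherits(spec, "component_spec"))
  rows <- lapply(epochs_by_subject, function(ep) {
    tgt <- target_epochs(ep)
    times <- epoch_times_ms(tgt)
    wsel <- which(times >= spec$window_ms[1] & times <= spec$window_ms[2])
    csel <- match(spec$electrodes, tgt$labels)
    md <- tgt$metadata
    cells <- design_cells()
    out <- lapply(seq_len(8), function(ci) {
      sel <- md$emotion == cells$emotion[ci] & md$size == cells$size[ci] &
        md$contrast == cells$contrast[ci]
      if (!any(sel)) return(NULL)
      wave <- colMeans(matrix(
        aperm(tgt$data[sel, csel, wsel, drop = FALSE], c(2, 1, 3)),
        ncol = length(wsel)
      ))
      idx <- if (spec$polarity == "positive") which.max(wave) else which.min(wave)
      tibble(
        subject_id = md$subject_id[1],
        emotion = cells$emotion[ci], size = cells$size[ci],
        contrast = cells$contrast[ci], component = spec$name,
        peak_amplitude_uV = wave[idx],
        peak_latency_ms = times[wsel[idx]]
      )
    })
    bind_rows(out)
  })
  bind_rows(rows)
}
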