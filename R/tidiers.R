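# broom-style tidiers and ggplot2 methods for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   geom_hline geom_vline facet_wrap labs scale_fill_gradient2 geom_jitter
#'   theme_minimal position_jitter
#' @export
ggplot2::autoplot

#' Tidy a t-max permutation result
#'
#' @param x A `tmax_result`.
#' @param ... Unused.
#' @return A tibble with one row per channel x sample: `channel`, `time_ms`,
#'   `t`, `p`, `significant`.
#' @export
tidy.tmax_result <- function(x, ...) {
  tibble(
    channel = rep(x$labels, times = ncol(x$t_obs)),
    time_ms = rep(x$times_ms, each = nrow(x$t_obs)),
    t = as.vector(x$t_obs),
    p = as.vector(x$p_map),
    significant = as.vector(x$sig_mask)
  )
}

#' @rdname tidy.tmax_result
#' @export
glance.tmax_result <- function(x, ...) {
  tibble(
    n_tests = x$n_tests, n_subjects = x$n_subjects, B = x$B,
    alpha = x$alpha, critical_t = x$critical_t,
    n_significant = sum(x$sig_mask), method = x$method
  )
}

#' @export
autoplot.tmax_result <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = rev(object$labels))
  ggplot(df, aes(x = .data$time_ms, y = .data$channel, fill = .data$t)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    geom_point(data = df[df$significant, ], size = 0.3, shape = 15,
               colour = "black") +
    labs(x = "time (ms)", y = NULL, fill = "t",
         title = sprintf("t-max localization (critical |t| = %.2f)",
                         object$critical_t)) +
    theme_minimal()
}

#' Tidy / summarise a sequential monitoring decision
#' @param x A `sequential_decision`.
#' @param ... Unused.
#' @return `tidy`: the per-check tibble; `glance`: one row with the stop.
#' @export
tidy.sequential_decision <- function(x, ...) x$checks

#' @rdname tidy.sequential_decision
#' @export
glance.sequential_decision <- function(x, ...) {
  tibble(stopped_at_n = x$stopped_at_n, reason = x$reason,
         bf_threshold = x$rules$bf_threshold)
}

#' Summarise a model-comparison table
#' @param x A `bf_comparison` tibble.
#' @param ... Unused.
#' @return One row per component x prior scale with the winning model and
#'   its evidence margins (natural-scale best-vs-second ratio included).
#' @export
glance.bf_comparison <- function(x, ...) {
  x |>
    filter(.data$rank == 1) |>
    mutate(bf_best_vs_second = exp(.data$log_bf_best_vs_second)) |>
    select("component", "r", best_model = "model", "log_bf10",
           "log_bf_best_vs_second", "bf_best_vs_second")
}

#' @export
autoplot.bf_comparison <- function(object, ...) {
  ggplot(object, aes(x = .data$log_bf10,
                     y = stats::reorder(.data$model, .data$log_bf10),
                     colour = factor(.data$r))) +
    geom_point() +
    facet_wrap(~component, scales = "free_x") +
    labs(x = "log BF10 vs null", y = NULL, colour = "r") +
    theme_minimal()
}

#' @export
autoplot.bf_omission <- function(object, ...) {
  ggplot(object, aes(x = .data$log_bf_omission,
                     y = stats::reorder(.data$omitted_term,
                                        .data$log_bf_omission),
                     colour = factor(.data$r))) +
    geom_point() +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~component, scales = "free_x") +
    labs(x = "log BF (reduced vs full)", y = "omitted term", colour = "r") +
    theme_minimal()
}

#' Grand-average ERP plot of an epochs set
#'
#' @param object An `epochs_set`.
#' @param electrodes Channels to average over (default all).
#' @param by Optional metadata column to split the average by
#'   (e.g. `"emotion"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epochs_set <- function(object, electrodes = object$labels,
                                by = NULL, ...) {
  tgt <- target_epochs(object)
  csel <- match(electrodes, tgt$labels)
  times <- epoch_times_ms(tgt)
  groups <- if (is.null(by)) rep("all", nrow(tgt$metadata)) else
    tgt$metadata[[by]]
  df <- bind_rows(lapply(unique(groups), function(gr) {
    sel <- groups == gr
    wave <- apply(tgt$data[sel, csel, , drop = FALSE], 3, mean)
    tibble(time_ms = times, amplitude_uV = wave, group = gr)
  }))
  ggplot(df, aes(x = .data$time_ms, y = .data$amplitude_uV,
                 colour = .data$group)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 3) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "time (ms)", y = "amplitude (µV)", colour = by %||% NULL) +
    theme_minimal()
}

#' Per-condition amplitude dot plot
#'
#' @param amplitudes Amplitude tibble from
#'   [extract_single_trial_amplitudes()].
#' @return A ggplot object: subject-level cell means by condition.
#' @export
plot_amplitudes <- function(amplitudes) {
  df <- amplitudes |>
    group_by(.data$component, .data$subject_id, .data$emotion, .data$size,
             .data$contrast) |>
    summarise(m = mean(.data$amplitude_uV), .groups = "drop") |>
    mutate(cell = paste(.data$size, .data$contrast))
  ggplot(df, aes(x = .data$cell, y = .data$m, colour = .data$emotion)) +
    geom_jitter(position = position_jitter(width = 0.15), alpha = 0.5) +
    facet_wrap(~component, scales = "free_y") +
    labs(x = NULL, y = "mean amplitude (µV)") +
    theme_minimal()
}
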