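#' Build a randomized factorial trial schedule
#'
#' Generates the presentation schedule of one experimental session: target
#' words fully crossed over the 2 (emotion) x 2 (size) x 2 (contrast) design
#' plus colour-word probe trials shown once in every size x contrast
#' combination.  Words are randomly assigned to cells and trial order is
#' shuffled, both driven by `seed`.  Each word is on screen for 1,000 ms and
#' followed by an inter-trial interval drawn uniformly from `iti_range_ms`,
#' so consecutive onsets are 1,000 ms + ITI apart.
#'
#' @param trials_per_cell Number of target words per design cell (default 60,
#'   i.e. 480 targets).
#' @param probes_per_cell Number of probe words per size x contrast cell
#'   (default 20, i.e. 80 probes; each probe word appears once per cell).
#' @param n_runs Number of runs the session is split into; must divide the
#'   total trial count. Default 8.
#' @param iti_range_ms Length-2 numeric, uniform inter-trial-interval range in
#'   milliseconds. Default `c(1000, 1500)`.
#' @param seed Integer seed controlling word assignment, trial order and ITIs.
#' @param sfreq_hz Sampling rate used to express onsets in samples.
#' @param presentation_ms Word presentation duration. Default 1000.
#' @return A tibble with one row per trial: `trial_index`, `run`,
#'   `onset_sample`, `kind` (`"target"`/`"probe"`), `emotion` (`"none"` for
#'   probes), `size`, `contrast`, `word_id`.
#' @export
#' @examples
#' sched <- build_trial_schedule(seed = 7)
#' nrow(sched)                       # 560
#' table(sched$run)                  # 70 per run
build_trial_schedule <- function(trials_per_cell = 60, probes_per_cell = 20,
                                 n_runs = 8, iti_range_ms = c(1000, 1500),
                                 seed = 1, sfreq_hz = 256,
                                 presentation_ms = 1000) {
  stopifnot(trials_per_cell >= 1, probes_per_cell >= 0, n_runs >= 1,
            length(iti_range_ms) == 2, iti_range_ms[1] <= iti_range_ms[2],
            sfreq_hz > 0)
  n_targets <- 8L * as.integer(trials_per_cell)
  n_probes <- 4L * as.integer(probes_per_cell)
  n_total <- n_targets + n_probes
  if (n_total %% n_runs != 0) {
    abort(sprintf(
      "total trial count %d (%d targets + %d probes) is not divisible by %d runs",
      n_total, n_targets, n_probes, n_runs
    ))
  }

  set.seed(seed)
  cells <- design_cells()
  targets <- cells[rep(seq_len(8L), each = trials_per_cell), ]
  # random word-to-cell assignment: shuffle which word id lands in which cell
  targets$word_id <- sample.int(n_targets)
  targets$kind <- "target"

  if (probes_per_cell > 0) {
    sc <- unique(cells[, c("size", "contrast")])
    probes <- sc[rep(seq_len(4L), each = probes_per_cell), ]
    probes$emotion <- "none"
    # each probe word is shown once in every size x contrast cell
    probes$word_id <- n_targets + rep(seq_len(probes_per_cell), times = 4L)
    probes$kind <- "probe"
    rows <- bind_rows(targets[, c("kind", "emotion", "size", "contrast", "word_id")],
                      probes[, c("kind", "emotion", "size", "contrast", "word_id")])
  } else {
    rows <- targets[, c("kind", "emotion", "size", "contrast", "word_id")]
  }

  rows <- rows[sample.int(n_total), ]
  iti <- runif(n_total, iti_range_ms[1], iti_range_ms[2])
  gap_ms <- presentation_ms + iti
  # 2 s lead-in so pre-stimulus baselines of the first epoch are recorded
  onset_ms <- 2000 + cumsum(c(0, gap_ms[-n_total]))

  tibble(
    trial_index = seq_len(n_total),
    run = rep(seq_len(n_runs), each = n_total %/% n_runs),
    onset_sample = as.integer(round(onset_ms / 1000 * sfreq_hz)),
    kind = rows$kind,
    emotion = rows$emotion,
    size = rows$size,
    contrast = rows$contrast,
    word_id = rows$word_id
  )
}
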