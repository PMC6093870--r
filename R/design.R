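#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across n all_of desc row_number
#' @importFrom stats rnorm runif rbinom rgamma sd quantile fft uniroot
#'   integrate setNames
#' @importFrom utils head tail
NULL

# Factor levels of the 2 x 2 x 2 within-subject design.  Level order is part
# of the package contract: the first level of each factor is listed first in
# every 8-cell vector.
EMOTION_LEVELS  <- c("negative", "neutral")
SIZE_LEVELS     <- c("large", "small")
CONTRAST_LEVELS <- c("high", "low")

#' Canonical ordering of the eight design cells
#'
#' All 8-element cell vectors in this package (e.g. `cell_means_uV` of a
#' [component_truth()]) follow one fixed ordering: emotion varies slowest,
#' then font size, then contrast fastest, with levels
#' (negative, neutral) x (large, small) x (high, low).
#'
#' @return A tibble with columns `cell` (1..8), `emotion`, `size`, `contrast`.
#' @export
#' @examples
#' design_cells()
design_cells <- function() {
  grid <- expand.grid(
    contrast = CONTRAST_LEVELS,
    size = SIZE_LEVELS,
    emotion = EMOTION_LEVELS,
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  tibble(
    cell = seq_len(8L),
    emotion = grid$emotion,
    size = grid$size,
    contrast = grid$contrast
  )
}

# Map emotion/size/contrast character vectors to the canonical cell index.
cell_index <- function(emotion, size, contrast) {
  e <- match(emotion, EMOTION_LEVELS)
  s <- match(size, SIZE_LEVELS)
  k <- match(contrast, CONTRAST_LEVELS)
  if (anyNA(e) || anyNA(s) || anyNA(k)) {
    abort("unknown factor level in emotion/size/contrast")
  }
  (e - 1L) * 4L + (s - 1L) * 2L + k
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
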