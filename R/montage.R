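# 64-channel sensor montage on the unit sphere.
#
# The layout reproduces the idealized geometry of a 64-electrode active cap
# in which electrode sites are radially equidistant from the vertex (Cz):
# the outermost ring (Fpz, T7, Oz, T8, ...) lies on the equator of the unit
# sphere at 18-degree azimuthal steps, midline sites step down the sagittal
# arc in 22.5-degree increments, and lateral sites are placed at equal arc
# fractions along the great circle joining their midline site to their ring
# site.  P9/P10 extend the parietal arc one step beyond the ring and Iz sits
# one midline step below Oz.

# labels in cap order: left hemisphere + posterior midline first, then
# anterior midline + right hemisphere.
BIOSEMI64_LABELS <- c(
  "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
  "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5", "P7",
  "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
  "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
  "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
  "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
)

# Spherical helpers: positions are unit vectors with x = right, y = front,
# z = up.  `polar` is the angle from the vertex, `azimuth` is measured
# counterclockwise (seen from above) from +x, so the nasion is at 90 degrees.
sph_point <- function(polar_deg, azimuth_deg) {
  p <- polar_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
}

# great-circle interpolation; t may exceed 1 to extrapolate along the arc
slerp <- function(u, v, t) {
  omega <- acos(max(-1, min(1, sum(u * v))))
  (sin((1 - t) * omega) * u + sin(t * omega) * v) / sin(omega)
}

# per-row geometry: sagittal polar angle of the midline site, ring azimuth
# offset (in 18-degree steps from Fpz), number of arc intervals from midline
# to ring site, and lateral member names (left side; right side mirrors).
MONTAGE_ROWS <- list(
  Fp = list(mid = "Fpz", polar = 90,    step = 1, lateral = c("Fp1")),
  AF = list(mid = "AFz", polar = 67.5,  step = 2, lateral = c("AF3", "AF7")),
  F  = list(mid = "Fz",  polar = 45,    step = 3, lateral = c("F1", "F3", "F5", "F7")),
  FC = list(mid = "FCz", polar = 22.5,  step = 4, lateral = c("FC1", "FC3", "FC5", "FT7")),
  C  = list(mid = "Cz",  polar = 0,     step = 5, lateral = c("C1", "C3", "C5", "T7")),
  CP = list(mid = "CPz", polar = -22.5, step = 6, lateral = c("CP1", "CP3", "CP5", "TP7")),
  P  = list(mid = "Pz",  polar = -45,   step = 7, lateral = c("P1", "P3", "P5", "P7", "P9")),
  PO = list(mid = "POz", polar = -67.5, step = 8, lateral = c("PO3", "PO7")),
  O  = list(mid = "Oz",  polar = -90,   step = 9, lateral = c("O1"))
)

mirror_label <- function(label) {
  # left-hemisphere label -> right-hemisphere partner (odd -> odd + 1)
  num <- as.integer(sub("^[A-Za-z]+", "", label))
  paste0(sub("[0-9]+$", "", label), num + 1L)
}

build_montage_positions <- function() {
  pos <- list()
  for (row in MONTAGE_ROWS) {
    mid_polar <- abs(row$polar)
    mid_az <- if (row$polar >= 0) 90 else 270
    m <- sph_point(mid_polar, mid_az)
    pos[[row$mid]] <- m
    n_lat <- length(row$lateral)
    # ring site for this row, left side
    ring_left <- sph_point(90, 90 + 18 * row$step)
    ring_right <- sph_point(90, 90 - 18 * row$step)
    # arc intervals between midline and ring site (P9/P10 extrapolate)
    n_arc <- min(n_lat, sum(!grepl("9$", row$lateral)))
    for (j in seq_len(n_lat)) {
      f <- j / n_arc
      lab <- row$lateral[[j]]
      pos[[lab]] <- slerp(m, ring_left, f)
      pos[[mirror_label(lab)]] <- slerp(m, ring_right, f)
    }
  }
  pos[["Iz"]] <- sph_point(112.5, 270)
  pos
}

#' Default 64-channel sensor montage
#'
#' Returns the packaged 64-channel scalp layout with idealized unit-sphere
#' electrode coordinates (sites radially equidistant from `Cz`).  The layout
#' contains every electrode used by the packaged component clusters
#' (occipito-temporal, temporal, and parietal sets for P1, N1, EPN and LPP).
#'
#' @param labels Optional subset of channel labels to keep (in the given
#'   order), e.g. to run reduced desk-scale simulations.  Defaults to the full
#'   64-channel set.
#' @return A tibble with columns `label`, `x`, `y`, `z`; every row has unit
#'   norm (`x` right, `y` front, `z` up).
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m)                      # 64
#' all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-9)
default_montage <- function(labels = NULL) {
  pos <- build_montage_positions()
  stopifnot(setequal(names(pos), BIOSEMI64_LABELS))
  keep <- labels %||% BIOSEMI64_LABELS
  missing <- setdiff(keep, BIOSEMI64_LABELS)
  if (length(missing) > 0) {
    abort(paste0("unknown channel label(s): ", paste(missing, collapse = ", ")))
  }
  xyz <- do.call(rbind, pos[keep])
  tibble(
    label = keep,
    x = xyz[, 1],
    y = xyz[, 2],
    z = xyz[, 3]
  )
}

# matrix of positions (channels x 3) from a montage tibble
montage_matrix <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

# great-circle (angular) distance in radians between rows of two position sets
angular_distance <- function(pos_a, pos_b) {
  ip <- tcrossprod(pos_a, pos_b)
  ip[] <- pmax(-1, pmin(1, ip))
  acos(ip)
}

#' Smooth scalp topography centred on an electrode cluster
#'
#' Builds a spherical Gaussian weight map peaking at the (normalized)
#' centroid of an electrode cluster, the standard smooth-field phantom for
#' simulated ERP components.  Weights are scaled so the maximum absolute
#' weight is 1.
#'
#' @param montage A montage tibble from [default_montage()].
#' @param electrodes Cluster labels defining the bump centre.
#' @param width_deg Gaussian width (standard deviation) of the bump in
#'   degrees of arc. Default 35.
#' @return Named numeric vector of weights, one per montage channel.
#' @export
topography_bump <- function(montage, electrodes, width_deg = 35) {
  stopifnot(all(electrodes %in% montage$label), width_deg > 0)
  pos <- montage_matrix(montage)
  centroid <- colMeans(pos[electrodes, , drop = FALSE])
  centroid <- centroid / sqrt(sum(centroid^2))
  d <- angular_distance(pos, matrix(centroid, nrow = 1))[, 1]
  w <- exp(-(d * 180 / pi)^2 / (2 * width_deg^2))
  w <- w / max(abs(w))
  names(w) <- montage$label
  w
}
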