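#' Lumbar angle time series
#'
#' Container for a fixed-rate time series of the three relative lumbar Euler
#' angles. Column order is the anatomical decomposition order used throughout:
#' flexion-extension (`fe`), lateral-bending (`lb`), axial-rotation (`ar`),
#' in degrees. Flexion is positive for forward bending.
#'
#' @param angles numeric matrix, one row per sample, 3 columns
#'   (flexion-extension, lateral-bending, axial-rotation), degrees.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `angle_series`: the matrix with attributes
#'   `sample_rate` and `axis_order`.
#' @export
angle_series <- function(angles, sample_rate) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L)
    stop("`angles` must have exactly 3 columns (fe, lb, ar)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive scalar (Hz)")
  if (anyNA(angles)) stop("angle series may not contain missing samples")
  colnames(angles) <- c("fe", "lb", "ar")
  structure(angles,
            sample_rate = sample_rate,
            axis_order = c("flexion_extension", "lateral_bending",
                           "axial_rotation"),
            class = c("angle_series", "matrix", "array"))
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples @ %g Hz (%.1f s)\n",
              nrow(x), attr(x, "sample_rate"),
              (nrow(x) - 1L) / attr(x, "sample_rate")))
  rng <- apply(x, 2, range)
  cat(sprintf("  fe [%.2f, %.2f]  lb [%.2f, %.2f]  ar [%.2f, %.2f] deg\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

sample_rate_of <- function(x) attr(x, "sample_rate")

#' Marker-cluster trial
#'
#' Time-indexed 3-D positions of the six markers: three on the thorax cluster
#' (T8) and three on the pelvis cluster (S1), in meters.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param positions numeric matrix with `length(time)` rows and 18 columns
#'   named `<marker>_<x|y|z>` for markers `thorax_1..3`, `pelvis_1..3`.
#' @param nominal_rate nominal sampling rate in Hz (may fluctuate).
#' @return An object of class `marker_trial`.
#' @export
marker_trial <- function(time, positions, nominal_rate = 100) {
  positions <- as.matrix(positions)
  if (length(time) < 2L) stop("a marker trial needs at least 2 samples")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (nrow(positions) != length(time))
    stop("`positions` must have one row per timestamp")
  expected <- marker_columns()
  if (is.null(colnames(positions)) ||
      !all(expected %in% colnames(positions)))
    stop("`positions` must contain columns: ",
         paste(expected, collapse = ", "))
  positions <- positions[, expected, drop = FALSE]
  structure(list(time = as.numeric(time), positions = positions,
                 nominal_rate = nominal_rate),
            class = "marker_trial")
}

marker_names <- function() c(paste0("thorax_", 1:3), paste0("pelvis_", 1:3))

marker_columns <- function() {
  as.vector(t(outer(marker_names(), c("x", "y", "z"), paste, sep = "_")))
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial> %d samples, %.1f s span, nominal %g Hz\n",
              length(x$time), diff(range(x$time)), x$nominal_rate))
  invisible(x)
}
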