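# Local dynamic stability: delay embedding, nearest-neighbor divergence
# tracking and the local divergence exponent (LDE). Higher LDE = faster
# divergence of initially neighboring trajectories = lower stability.

#' Embedding and divergence configuration
#'
#' Defaults reproduce the standard analysis for this task: cycles resampled
#' to 300 samples each, a 6-dimensional state space from the three lumbar
#' angles plus one 30-sample (10% of a cycle) time-delayed copy, divergence
#' tracked over 15 nearest neighbors, and the exponent fitted over the first
#' 0.25 cycle of the divergence curve.
#'
#' @param samples_per_cycle samples per cycle after resampling (300).
#' @param delay embedding delay in samples (30).
#' @param n_delayed_copies number of delayed copies (1 -> dimension 6).
#' @param n_neighbors nearest neighbors tracked per reference point (15).
#' @param fit_fraction fraction of a cycle over which the divergence slope is
#'   fitted (0.25).
#' @param theiler_window temporal exclusion half-width for neighbor search,
#'   samples (150 = half a cycle).
#' @param horizon divergence tracking horizon, samples (300 = one cycle).
#' @param distance_floor smallest distance admitted before the log transform.
#' @return An `embedding_config` list; `dimension` is derived.
#' @export
embedding_config <- function(samples_per_cycle = 300, delay = 30,
                             n_delayed_copies = 1, n_neighbors = 15,
                             fit_fraction = 0.25, theiler_window = 150,
                             horizon = 300, distance_floor = 1e-12) {
  if (delay < 1) stop("`delay` must be at least 1 sample")
  if (n_delayed_copies < 1) stop("`n_delayed_copies` must be at least 1")
  if (fit_fraction <= 0 || fit_fraction > 1)
    stop("`fit_fraction` must lie in (0, 1]")
  if (n_neighbors < 1) stop("`n_neighbors` must be at least 1")
  if (theiler_window < 0) stop("`theiler_window` must be non-negative")
  structure(list(samples_per_cycle = as.integer(samples_per_cycle),
                 delay = as.integer(delay),
                 n_delayed_copies = as.integer(n_delayed_copies),
                 dimension = 3L * (1L + as.integer(n_delayed_copies)),
                 n_neighbors = as.integer(n_neighbors),
                 fit_fraction = fit_fraction,
                 theiler_window = as.integer(theiler_window),
                 horizon = as.integer(horizon),
                 distance_floor = distance_floor),
            class = "embedding_config")
}

#' Resample an angle series to a fixed number of samples per cycle
#'
#' The divergence exponent depends on series length, so the angle series
#' covering the analyzed cycles is cubic-spline resampled to exactly
#' `samples_per_cycle * n_cycles` points (12000 for 40 cycles at 300).
#'
#' @param angles an [angle_series()] or 3-column matrix spanning the
#'   analyzed cycles.
#' @param n_cycles number of cycles the series covers.
#' @param samples_per_cycle target samples per cycle.
#' @return Numeric matrix `samples_per_cycle * n_cycles` x 3.
#' @export
resample_for_lde <- function(angles, n_cycles, samples_per_cycle = 300) {
  n <- nrow(angles)
  if (is.null(n) || n < 4L) stop("angle series too short to resample")
  if (n_cycles < 1L) stop("`n_cycles` must be positive")
  m <- as.integer(samples_per_cycle * n_cycles)
  grid <- seq(1L, n, length.out = m)
  out <- matrix(NA_real_, m, 3L)
  colnames(out) <- c("fe", "lb", "ar")
  for (j in 1:3)
    out[, j] <- splinefun(seq_len(n), angles[, j], method = "fmm")(grid)
  out
}

#' Delay-embed a three-channel series into state space
#'
#' Row `t` of the state space is
#' `(fe_t, lb_t, ar_t, fe_{t+d}, lb_{t+d}, ar_{t+d}, ...)` for delay `d` and
#' the configured number of delayed copies; `N = length - copies * d` rows.
#'
#' @param series numeric matrix, samples x 3.
#' @param config an [embedding_config()].
#' @return Numeric matrix `N x dimension` of class `state_space`.
#' @export
embed_delay <- function(series, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  series <- as.matrix(series)
  d <- config$delay
  copies <- config$n_delayed_copies
  n <- nrow(series)
  if (n <= copies * d)
    stop("series length ", n, " not greater than total delay ", copies * d)
  N <- n - copies * d
  blocks <- lapply(0:copies, function(k)
    series[(1L + k * d):(N + k * d), , drop = FALSE])
  x <- do.call(cbind, blocks)
  structure(x, class = c("state_space", "matrix", "array"),
            source_length = n, config = config)
}

#' Mean logarithmic divergence curve
#'
#' For each reference point, finds its nearest neighbors by Euclidean
#' distance, excluding points within `theiler_window` samples in time. For
#' each lag 0..`horizon`, the log Euclidean distance between the forward
#' images of each reference-neighbor pair is averaged over the neighbors per
#' reference point, then over reference points; pairs whose images run past
#' the series end are dropped at that lag. Distances are floored at
#' `distance_floor` before the log.
#'
#' @param space a `state_space` from [embed_delay()] (or plain matrix).
#' @param config an [embedding_config()].
#' @return A `divergence_curve` list: `lag` (0..horizon),
#'   `mean_log_divergence`, `n_pairs_per_lag`, `n_skipped` reference points
#'   with too few admissible neighbors.
#' @export
divergence_curve <- function(space, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  x <- unclass(space)
  attr(x, "source_length") <- NULL
  attr(x, "config") <- NULL
  N <- nrow(x)
  if (N <= config$theiler_window + config$horizon)
    stop("state space too short for theiler window + horizon")
  nbrs <- nn_theiler(x, config$n_neighbors, config$theiler_window)
  n_skipped <- sum(is.na(nbrs[, 1L]))
  if (n_skipped > 0L)
    message("divergence_curve: ", n_skipped,
            " reference point(s) skipped (too few admissible neighbors)")
  if (n_skipped == N)
    stop("no reference point has enough admissible neighbors")
  dv <- div_curve(x, nbrs, config$horizon, config$distance_floor)
  structure(list(lag = 0:config$horizon,
                 mean_log_divergence = dv$mean_log_divergence,
                 n_pairs_per_lag = dv$n_pairs_per_lag,
                 n_skipped = n_skipped,
                 neighbors = nbrs,
                 config = config),
            class = "divergence_curve")
}

#' Local divergence exponent
#'
#' Ordinary least-squares slope of the mean log divergence over lags 0 to
#' `fit_fraction * samples_per_cycle` inclusive (0..75 by default), scaled by
#' `samples_per_cycle` to express log divergence per cycle. The per-sample
#' slope is attached as attribute `slope_per_sample`.
#'
#' @param curve a `divergence_curve` from [divergence_curve()].
#' @param config an [embedding_config()].
#' @return Scalar LDE (log divergence per cycle).
#' @export
lde <- function(curve, config = embedding_config()) {
  n_fit <- as.integer(floor(config$fit_fraction * config$samples_per_cycle))
  y <- curve$mean_log_divergence
  if (length(y) < n_fit + 1L)
    stop("divergence curve shorter than the fit range (", n_fit + 1L,
         " lags needed)")
  lag <- 0:n_fit
  yy <- y[seq_len(n_fit + 1L)]
  if (anyNA(yy)) stop("divergence curve contains missing values in fit range")
  slope <- sum((lag - mean(lag)) * (yy - mean(yy))) / sum((lag - mean(lag))^2)
  structure(slope * config$samples_per_cycle, slope_per_sample = slope)
}

#' Compute the LDE of an angle series covering the analyzed cycles
#'
#' Convenience wrapper chaining [resample_for_lde()], [embed_delay()],
#' [divergence_curve()] and [lde()].
#'
#' @param angles angle series or matrix spanning the analyzed cycles.
#' @param n_cycles number of cycles covered.
#' @param config an [embedding_config()].
#' @return Scalar LDE with attributes `slope_per_sample` and `curve`.
#' @export
lde_from_angles <- function(angles, n_cycles, config = embedding_config()) {
  series <- resample_for_lde(angles, n_cycles, config$samples_per_cycle)
  space <- embed_delay(series, config)
  curve <- divergence_curve(space, config)
  out <- lde(curve, config)
  attr(out, "curve") <- curve[c("lag", "mean_log_divergence",
                                "n_pairs_per_lag", "n_skipped")]
  out
}
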