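# Cycle segmentation and the linear movement-pattern metrics: temporal
# variability (CyclSD), spatial variability (MeanSD), range of motion and
# movement velocity.

#' Detect reaching cycles from the thorax sagittal-plane orientation
#'
#' One peak per reaching cycle: local maxima of the (flexion-extension)
#' signal, kept if their topographic prominence is at least
#' `prominence_frac` of the signal's interquartile range and separated by at
#' least `separation_frac` of the dominant period. The dominant period is the
#' lag of the first local maximum of the autocorrelation function.
#'
#' @param x numeric vector: thorax sagittal orientation, or an
#'   [angle_series()] (its `fe` channel is used), degrees.
#' @param rate sample rate in Hz (taken from the series if available).
#' @param expected optional expected number of peaks; a different count is an
#'   error listing the peaks found.
#' @param prominence_frac minimum peak prominence as a fraction of the IQR.
#' @param separation_frac minimum peak separation as a fraction of the
#'   dominant period.
#' @param height_quantile minimum peak height as a quantile of the signal;
#'   a "most forward" orientation is by definition in the upper range, so
#'   the default 0.5 discards noise bumps on the valley floor without ever
#'   touching a genuine reaching peak.
#' @param presmooth logical: detect on a zero-phase low-pass-filtered copy
#'   of the signal (cutoff four times the dominant movement frequency).
#'   Measurement noise displaces the apparent maximum on the flat top of a
#'   reaching cycle by far more than it perturbs the underlying movement;
#'   smoothing removes that jitter while leaving true peak timing intact.
#' @return Integer vector of peak sample indices, strictly increasing.
#' @export
detect_cycles <- function(x, rate = NULL, expected = NULL,
                          prominence_frac = 0.25, separation_frac = 0.5,
                          height_quantile = 0.5, presmooth = TRUE) {
  if (inherits(x, "angle_series")) {
    if (is.null(rate)) rate <- sample_rate_of(x)
    x <- x[, "fe"]
  }
  x <- as.numeric(x)
  raw <- x
  n <- length(x)
  if (n < 8L || diff(range(x)) == 0)
    stop("no peaks found: signal is constant or too short")

  period <- dominant_period(x)
  min_sep <- max(2L, floor(separation_frac * period))

  refine <- 0L
  if (presmooth && period >= 16L) {
    # cutoff 4 x movement frequency, as a fraction of Nyquist: 8 / period
    bf <- signal::butter(2, min(8 / period, 0.9), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
    refine <- 5L  # snap back to the raw maximum in a small window
  }
  min_prom <- prominence_frac * IQR(x)

  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) stop("no peaks found: signal has no local maxima")
  cand <- cand[x[cand] >= quantile(x, height_quantile)]
  if (!length(cand)) stop("no peaks found above the height floor")
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  cand <- cand[prom >= min_prom]
  prom <- prom[prom >= min_prom]

  # enforce separation greedily by descending height
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])
  if (refine > 0L) {
    peaks <- vapply(peaks, function(i) {
      win <- max(1L, i - refine):min(n, i + refine)
      win[which.max(raw[win])]
    }, integer(1))
    peaks <- sort(unique(peaks))
  }

  if (length(peaks) < 5L)
    stop("cycle detection found only ", length(peaks),
         " peak(s) at indices [", paste(peaks, collapse = ", "),
         "]; at least 5 required")
  if (!is.null(expected) && length(peaks) != expected)
    stop("cycle detection found ", length(peaks), " peaks, expected ",
         expected, "; indices [", paste(peaks, collapse = ", "), "]")
  peaks
}

# Lag (samples) of the first local maximum of the autocorrelation function.
dominant_period <- function(x, max_lag = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 2L, 2000L)
  ac <- as.numeric(acf(x - mean(x), lag.max = max_lag, plot = FALSE,
                       demean = FALSE)$acf)
  # ac[1] is lag 0; find first interior local max with positive correlation
  for (k in 3:(length(ac) - 1L)) {
    if (ac[k] > ac[k - 1L] && ac[k] >= ac[k + 1L] && ac[k] > 0)
      return(k - 1L)
  }
  stop("no dominant period found in signal autocorrelation")
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two minima separating it from the nearest higher terrain.
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(x[1:i])
  right_min <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  if (j > n) right_min <- min(x[i:n])
  x[i] - max(left_min, right_min)
}

#' Select the final analysis cycles
#'
#' Discards early cycles as transients and keeps the last `n_keep` inter-peak
#' cycles; `n_keep + 1` peak boundaries are required.
#'
#' @param peaks integer vector of peak indices from [detect_cycles()].
#' @param n_keep number of cycles to retain (default 40).
#' @return Integer vector of `n_keep + 1` cycle boundaries (peak indices).
#' @export
select_analysis_cycles <- function(peaks, n_keep = 40) {
  if (length(peaks) < n_keep + 1L)
    stop("need at least ", n_keep + 1L, " peaks for ", n_keep,
         " analysis cycles, got ", length(peaks))
  tail(peaks, n_keep + 1L)
}

#' Temporal variability: standard deviation of cycle durations
#'
#' @param durations numeric vector of cycle durations in seconds (>= 2).
#' @return Sample standard deviation (n-1 denominator), seconds.
#' @export
cycl_sd <- function(durations) {
  if (length(durations) < 2L)
    stop("CyclSD needs at least 2 cycle durations")
  sd(durations)
}

#' Time-normalize cycles to the 0-100% grid
#'
#' Re-evaluates each cycle's three angle channels by cubic spline at 101
#' equispaced phase points (0-100%); endpoints are preserved exactly.
#'
#' @param angles an [angle_series()] or plain 3-column matrix.
#' @param boundaries integer cycle boundaries (length `n_cycles + 1`),
#'   e.g. from [select_analysis_cycles()].
#' @param n_points points per normalized cycle (101 = 0-100% in 1% steps).
#' @return Array `n_cycles x n_points x 3`.
#' @export
normalize_cycles <- function(angles, boundaries, n_points = 101) {
  nc <- length(boundaries) - 1L
  if (nc < 1L) stop("need at least one cycle boundary pair")
  out <- array(NA_real_, dim = c(nc, n_points, 3L),
               dimnames = list(NULL, NULL, c("fe", "lb", "ar")))
  for (i in seq_len(nc)) {
    a <- boundaries[i]
    b <- boundaries[i + 1L]
    if (b - a + 1L < 4L)
      stop("cycle ", i, " has fewer than 4 samples; cannot spline")
    idx <- a:b
    grid <- seq(a, b, length.out = n_points)
    for (j in 1:3)
      out[i, , j] <- splinefun(idx, angles[idx, j], method = "fmm")(grid)
  }
  out
}

# circular shift of a vector: positive s delays the waveform by s samples
circ_shift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1L - s) %% n) + 1L]
}

#' Align normalized cycles by circular cross-correlation
#'
#' Each cycle is circularly shifted by an integer number of phase samples
#' (bounded by `max_shift`) to maximize the cross-correlation of its
#' flexion-extension trace with the ensemble mean; the shift found on
#' flexion-extension is applied to all three axes so intersegmental coupling
#' is preserved. One refinement pass repeats the search against the updated
#' ensemble mean. A zero shift is always admissible, and maximizing the
#' circular cross-correlation with the mean is equivalent to minimizing each
#' cycle's squared deviation from it.
#'
#' @param cycles array `n x p x 3` from [normalize_cycles()].
#' @param max_shift shift search bound in phase samples (default 10); a
#'   best shift at the bound is clamped and reported via a message.
#' @return List with `cycles` (aligned array) and `shifts` (integer vector).
#' @export
align_cycles <- function(cycles, max_shift = 10) {
  nc <- dim(cycles)[1L]
  if (nc < 2L) stop("alignment needs at least 2 cycles")
  shifts <- integer(nc)
  fe0 <- cycles[, , 1L]
  cand <- seq.int(-max_shift, max_shift)
  for (pass in 1:2) {
    fe_cur <- t(vapply(seq_len(nc),
                       function(i) circ_shift(fe0[i, ], shifts[i]),
                       numeric(ncol(fe0))))
    m <- colMeans(fe_cur)
    for (i in seq_len(nc)) {
      score <- vapply(cand,
                      function(s) sum(circ_shift(fe0[i, ], s) * m),
                      numeric(1))
      shifts[i] <- cand[which.max(score)]
    }
  }
  if (any(abs(shifts) == max_shift))
    message("align_cycles: ", sum(abs(shifts) == max_shift),
            " shift(s) clamped at the +/-", max_shift, " sample bound")
  out <- cycles
  for (i in seq_len(nc)) {
    if (shifts[i] != 0L)
      for (j in 1:3) out[i, , j] <- circ_shift(cycles[i, , j], shifts[i])
  }
  list(cycles = out, shifts = shifts)
}

#' Spatial variability: MeanSD
#'
#' For each axis, the sample standard deviation (n-1) across cycles at each
#' normalized time point, averaged over the time points.
#'
#' @param cycles array `n x p x 3` of (aligned) normalized cycles.
#' @return Named numeric vector `c(fe, lb, ar)`, degrees.
#' @export
mean_sd <- function(cycles) {
  if (dim(cycles)[1L] < 2L) stop("MeanSD needs at least 2 cycles")
  vapply(1:3, function(j) mean(apply(cycles[, , j], 2L, sd)),
         numeric(1)) |> setNames(c("fe", "lb", "ar"))
}

#' Range of motion per axis
#'
#' Mean over cycles of the per-cycle maximum minus mean over cycles of the
#' per-cycle minimum.
#'
#' @param cycles either an array `n x p x 3` or a list of per-cycle
#'   matrices (samples x 3).
#' @return Named numeric vector `c(fe, lb, ar)`, degrees.
#' @export
amplitude <- function(cycles) {
  if (is.list(cycles)) {
    mx <- sapply(cycles, function(m) apply(m, 2L, max))
    mn <- sapply(cycles, function(m) apply(m, 2L, min))
    out <- rowMeans(mx) - rowMeans(mn)
  } else {
    out <- vapply(1:3, function(j) {
      mean(apply(cycles[, , j, drop = TRUE], 1L, max)) -
        mean(apply(cycles[, , j, drop = TRUE], 1L, min))
    }, numeric(1))
  }
  setNames(as.numeric(out), c("fe", "lb", "ar"))
}

#' Movement velocity in repetitions per second
#'
#' @param n_repetitions number of analyzed repetitions.
#' @param trial_duration time span of the analyzed cycles, seconds.
#' @return Repetitions per second.
#' @export
velocity <- function(n_repetitions, trial_duration) {
  if (trial_duration <= 0) stop("trial duration must be positive")
  n_repetitions / trial_duration
}
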