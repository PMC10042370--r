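# Synthetic-data generator: angle-level trials, marker-level trials and whole
# cohorts with known ground truth, so every downstream stage is testable
# without recorded data.

#' Configuration of a synthetic reaching trial
#'
#' Defaults reproduce the seated repetitive reaching task: 45 approximately
#' periodic cycles at ~0.38 cycles/s (2.6 s period), primary
#' flexion-extension amplitude 20 deg with ~8 deg lateral-bending and
#' axial-rotation, sampled at 100 Hz.
#'
#' Three noise sources are controllable independently:
#' * `spatial_noise_sd` -- additive kinematic noise per axis (deg). The noise
#'   is low-pass filtered (Butterworth, `noise_cutoff` Hz) and rescaled so
#'   its marginal SD equals the requested value exactly.
#' * `temporal_jitter_sd` -- SD (s) of the per-cycle durations drawn as
#'   `mean_period + N(0, temporal_jitter_sd)`.
#' * `process_noise_sd` -- multiplicative white noise on the instantaneous
#'   phase velocity; produces genuine trajectory divergence that the local
#'   divergence exponent detects, unlike purely additive measurement noise.
#'
#' @param n_cycles number of reaching cycles (>= 2).
#' @param mean_period mean cycle duration, seconds.
#' @param amp_fe,amp_lb,amp_ar per-axis peak-to-peak amplitudes, degrees.
#' @param spatial_noise_sd additive noise SD per axis, degrees.
#' @param temporal_jitter_sd SD of per-cycle durations, seconds.
#' @param process_noise_sd dimensionless phase-velocity noise SD.
#' @param sample_rate sampling rate, Hz.
#' @param peak_fraction within-cycle phase of peak flexion (slight asymmetry:
#'   the reach is faster than the return).
#' @param noise_cutoff low-pass cutoff of the additive noise, Hz.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_cycles = 45, mean_period = 2.6,
                         amp_fe = 20, amp_lb = 8, amp_ar = 8,
                         spatial_noise_sd = 1.0,
                         temporal_jitter_sd = 0.10,
                         process_noise_sd = 0.02,
                         sample_rate = 100,
                         peak_fraction = 0.45,
                         noise_cutoff = 10,
                         seed = NULL) {
  if (n_cycles < 2) stop("`n_cycles` must be at least 2")
  if (mean_period <= 0) stop("`mean_period` must be positive")
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  sds <- c(spatial_noise_sd, temporal_jitter_sd, process_noise_sd)
  if (any(sds < 0)) stop("noise SDs must be non-negative")
  if (mean_period - 6 * temporal_jitter_sd <= 0)
    stop("`temporal_jitter_sd` so large that non-positive cycle durations ",
         "become plausible; reduce the jitter or lengthen the period")
  if (peak_fraction <= 0 || peak_fraction >= 1)
    stop("`peak_fraction` must lie strictly inside (0, 1)")
  structure(list(n_cycles = as.integer(n_cycles), mean_period = mean_period,
                 amp_fe = amp_fe, amp_lb = amp_lb, amp_ar = amp_ar,
                 spatial_noise_sd = spatial_noise_sd,
                 temporal_jitter_sd = temporal_jitter_sd,
                 process_noise_sd = process_noise_sd,
                 sample_rate = sample_rate,
                 peak_fraction = peak_fraction,
                 noise_cutoff = noise_cutoff, seed = seed),
            class = "trial_config")
}

# Asymmetric raised-cosine base cycle on phase u in [0, 1): rises from 0 to
# `amp` over [0, peak] and returns over [peak, 1); C1-smooth and periodic.
raised_cosine_cycle <- function(u, amp, peak) {
  up <- u <= peak
  y <- numeric(length(u))
  y[up] <- amp / 2 * (1 - cos(pi * u[up] / peak))
  y[!up] <- amp / 2 * (1 + cos(pi * (u[!up] - peak) / (1 - peak)))
  y
}

#' Generate a synthetic lumbar angle trial
#'
#' Builds a quasi-periodic three-axis angle series: per axis, a smooth base
#' cycle waveform traversed with per-cycle durations drawn around
#' `mean_period`, phase advanced with multiplicative process noise, plus
#' low-pass-filtered additive noise. Identical seed implies bit-identical
#' output.
#'
#' The flexion-extension axis uses an asymmetric raised cosine from upright
#' (0 deg) to peak flexion (`amp_fe`) and back; the secondary axes use
#' phase-locked sinusoids of the configured amplitudes.
#'
#' @param config a [trial_config()].
#' @return An [angle_series()] with attribute `ground_truth`: a list holding
#'   the drawn cycle durations, the true peak-flexion sample indices, and the
#'   injected noise SDs.
#' @export
generate_angle_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  with_preserved_seed(config$seed, {
    k <- config$n_cycles
    p <- config$peak_fraction
    durations <- config$mean_period +
      rnorm(k, 0, config$temporal_jitter_sd)
    if (any(durations <= 0.05 * config$mean_period))
      stop("drawn cycle duration not positive; temporal jitter too large")
    fs <- config$sample_rate
    dt <- 1 / fs

    # The drawn durations are anchored peak-to-peak, because that is what
    # cycle segmentation measures: segment i between peaks i and i+1 (phase
    # [i-1+p, i+p)) is traversed in durations[i] seconds; the lead-in before
    # the first peak runs at the mean period and the tail after the last
    # peak at durations[k].
    upper <- c(p, seq_len(k - 1L) + p, k)          # segment phase bounds
    taus <- c(config$mean_period, durations)       # seconds per unit phase
    total <- p * config$mean_period + sum(durations[seq_len(k - 1L)]) +
      (1 - p) * durations[k]
    n <- floor(total * fs) + 1L

    # phase trajectory: piecewise rate 1/tau per segment, optionally
    # perturbed by multiplicative white noise on the phase velocity
    phase <- numeric(n)
    eps <- if (config$process_noise_sd > 0) rnorm(n) else numeric(n)
    seg <- 1L
    nseg <- length(upper)
    for (i in 2:n) {
      dphi <- dt / taus[seg] * (1 + config$process_noise_sd * eps[i])
      phase[i] <- phase[i - 1L] + max(dphi, 0)
      while (seg < nseg && phase[i] >= upper[seg]) seg <- seg + 1L
    }
    phase <- pmin(phase, k - 1e-9)

    u <- phase %% 1
    fe <- raised_cosine_cycle(u, config$amp_fe, config$peak_fraction)
    lb <- config$amp_lb / 2 * sin(2 * pi * u)
    ar <- config$amp_ar / 2 * sin(2 * pi * u - 0.6 * pi)
    ang <- cbind(fe, lb, ar)

    if (config$spatial_noise_sd > 0) {
      bf <- signal::butter(2, min(config$noise_cutoff / (fs / 2), 0.99),
                           type = "low")
      for (j in 1:3) {
        w <- signal::filtfilt(bf, rnorm(n))
        ang[, j] <- ang[, j] + w / sd(w) * config$spatial_noise_sd
      }
    }

    # true peak-flexion samples: first sample at/after phase (c-1)+peak
    targets <- (seq_len(k) - 1) + config$peak_fraction
    lo <- findInterval(targets, phase)
    hi <- pmin(lo + 1L, n)
    peak_idx <- ifelse(abs(phase[pmax(lo, 1L)] - targets) <=
                         abs(phase[hi] - targets), pmax(lo, 1L), hi)
    peak_idx <- peak_idx[peak_idx <= n]

    out <- angle_series(ang, sample_rate = fs)
    attr(out, "ground_truth") <- list(
      durations = durations,
      peak_index = peak_idx,
      spatial_noise_sd = config$spatial_noise_sd,
      temporal_jitter_sd = config$temporal_jitter_sd,
      process_noise_sd = config$process_noise_sd,
      config = config)
    out
  })
}

#' Marker-cluster geometry
#'
#' Offsets of the three markers of each cluster in its segment frame, meters.
#' The defaults are right triangles whose deterministic cluster frame (see
#' [cluster_orientation()]) coincides with the segment frame, so the forward
#' model and the kinematics chain are exact mutual inverses.
#'
#' @param thorax_markers,pelvis_markers 3x3 matrices, one marker offset per
#'   row, segment-frame coordinates (m). Must be non-collinear.
#' @param thorax_origin,pelvis_origin segment origins in the global frame (m).
#' @return A `cluster_geometry` list.
#' @export
cluster_geometry <- function(
    thorax_markers = rbind(c(0, 0, 0), c(0.08, 0, 0), c(0, 0.06, 0)),
    pelvis_markers = rbind(c(0, 0, 0), c(0.09, 0, 0), c(0, 0.05, 0)),
    thorax_origin = c(0, 0, 0.45),
    pelvis_origin = c(0, 0, 0)) {
  check_cluster <- function(m, what) {
    m <- as.matrix(m)
    if (any(dim(m) != c(3L, 3L))) stop(what, " must be a 3x3 matrix")
    v1 <- m[2L, ] - m[1L, ]
    v2 <- m[3L, ] - m[1L, ]
    cr <- cross3(v1, v2)
    if (sqrt(sum(cr^2)) < 1e-10 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)) ||
        all(cr == 0))
      stop(what, ": marker offsets are collinear")
    m
  }
  structure(list(thorax_markers = check_cluster(thorax_markers,
                                                "thorax_markers"),
                 pelvis_markers = check_cluster(pelvis_markers,
                                                "pelvis_markers"),
                 thorax_origin = thorax_origin,
                 pelvis_origin = pelvis_origin),
            class = "cluster_geometry")
}

#' Forward model: angle series to marker trajectories
#'
#' Places the pelvis cluster with fixed global orientation and the thorax
#' cluster rotated by `euler_compose(fe, lb, ar)` at every sample.
#' Within-cluster rigid-body distances are constant over time, and the
#' kinematics chain recovers the input angles.
#'
#' @param angles an [angle_series()].
#' @param geometry a [cluster_geometry()].
#' @return A [marker_trial()] at the angle series' sample rate.
#' @export
generate_marker_trial <- function(angles, geometry = cluster_geometry()) {
  stopifnot(inherits(angles, "angle_series"),
            inherits(geometry, "cluster_geometry"))
  fs <- sample_rate_of(angles)
  n <- nrow(angles)
  time <- (seq_len(n) - 1L) / fs
  pos <- matrix(NA_real_, n, 18L, dimnames = list(NULL, marker_columns()))
  for (m in 1:3) {
    off <- geometry$pelvis_markers[m, ] + geometry$pelvis_origin
    pos[, paste0("pelvis_", m, "_", c("x", "y", "z"))] <-
      matrix(off, n, 3L, byrow = TRUE)
  }
  # R(t) applied to thorax offsets, vectorized: column j of R(t) in terms of
  # the angle series
  a <- angles[, "fe"] / DEG; b <- angles[, "lb"] / DEG; cc <- angles[, "ar"] / DEG
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(cc); sg <- sin(cc)
  R <- list(
    r11 = cb * cg, r12 = -cb * sg, r13 = sb,
    r21 = ca * sg + sa * sb * cg, r22 = ca * cg - sa * sb * sg, r23 = -sa * cb,
    r31 = sa * sg - ca * sb * cg, r32 = sa * cg + ca * sb * sg, r33 = ca * cb)
  for (m in 1:3) {
    o <- geometry$thorax_markers[m, ]
    gx <- R$r11 * o[1L] + R$r12 * o[2L] + R$r13 * o[3L]
    gy <- R$r21 * o[1L] + R$r22 * o[2L] + R$r23 * o[3L]
    gz <- R$r31 * o[1L] + R$r32 * o[2L] + R$r33 * o[3L]
    pos[, paste0("thorax_", m, "_x")] <- gx + geometry$thorax_origin[1L]
    pos[, paste0("thorax_", m, "_y")] <- gy + geometry$thorax_origin[2L]
    pos[, paste0("thorax_", m, "_z")] <- gz + geometry$thorax_origin[3L]
  }
  marker_trial(time, pos, nominal_rate = fs)
}
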