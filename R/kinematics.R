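# Kinematics: marker clusters -> segment orientations -> relative lumbar
# Euler angles.
#
# Axis convention (documented, configurable only through the data): the pelvis
# frame approximately coincides with the global anatomical axes in the upright
# starting posture -- x mediolateral (flexion-extension axis), y
# anteroposterior (lateral-bending axis), z vertical (axial-rotation axis).
# Rotations are right-handed; flexion is positive for forward bending.

DEG <- 180 / pi

#' Resample a marker trial to a fixed rate by cubic splines
#'
#' Motion-capture recordings often arrive at a fluctuating 102/103 Hz with
#' occasional dropped samples. Every marker coordinate is re-evaluated on a
#' uniform grid by cubic spline interpolation; missing samples are bridged by
#' the spline provided no gap exceeds `max_gap` seconds.
#'
#' @param trial a [marker_trial()].
#' @param rate target rate in Hz (default 100).
#' @param max_gap largest bridgeable gap in seconds (default 0.1); a longer
#'   gap in any coordinate is an error naming the marker and interval.
#' @return A [marker_trial()] on a uniform grid spanning the original trial.
#' @export
resample_to_rate <- function(trial, rate = 100, max_gap = 0.1) {
  stopifnot(inherits(trial, "marker_trial"))
  t_in <- trial$time
  grid <- seq(t_in[1L], t_in[length(t_in)], by = 1 / rate)
  out <- matrix(NA_real_, nrow = length(grid), ncol = ncol(trial$positions),
                dimnames = list(NULL, colnames(trial$positions)))
  for (col in colnames(trial$positions)) {
    y <- trial$positions[, col]
    ok <- !is.na(y)
    if (sum(ok) < 4L)
      stop("marker coordinate ", col, ": fewer than 4 valid samples")
    gaps <- diff(t_in[ok])
    if (any(gaps > max_gap)) {
      i <- which.max(gaps > max_gap)
      tt <- t_in[ok]
      stop(sprintf(
        "marker coordinate %s: gap of %.3f s in [%.3f, %.3f] exceeds %.3f s",
        col, gaps[i], tt[i], tt[i + 1L], max_gap))
    }
    out[, col] <- splinefun(t_in[ok], y[ok], method = "fmm")(grid)
  }
  marker_trial(grid, out, nominal_rate = rate)
}

#' Orientation of a three-marker cluster
#'
#' Builds a deterministic orthonormal right-handed frame from three marker
#' positions: axis 1 along `p1 -> p2` (normalized), axis 3 along the
#' normalized cross product of `p1 -> p2` with `p1 -> p3`, axis 2 completing
#' the right-handed triad. The axes are the columns of the returned matrix,
#' so it maps cluster-frame coordinates into the global frame.
#'
#' @param p1,p2,p3 numeric length-3 global positions of the cluster markers.
#' @param tol collinearity tolerance on the normalized triangle area.
#' @return 3x3 proper orthogonal rotation matrix.
#' @export
cluster_orientation <- function(p1, p2, p3, tol = 1e-8) {
  v1 <- p2 - p1
  v2 <- p3 - p1
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate cluster: coincident markers")
  cr <- cross3(v1, v2)
  area <- sqrt(sum(cr^2)) / (n1 * n2)
  if (area < tol)
    stop("degenerate cluster: markers are (near-)collinear")
  e1 <- v1 / n1
  e3 <- cr / sqrt(sum(cr^2))
  e2 <- cross3(e3, e1)
  cbind(e1, e2, e3, deparse.level = 0)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Relative rotation between thorax and pelvis
#'
#' Expresses the thorax frame in the pelvis frame: `t(R_pelvis) %*% R_thorax`.
#'
#' @param r_thorax,r_pelvis 3x3 proper orthogonal matrices (global frames).
#' @param tol orthogonality tolerance on `||R'R - I||` (Frobenius).
#' @return 3x3 rotation of the thorax relative to the pelvis.
#' @export
relative_rotation <- function(r_thorax, r_pelvis, tol = 1e-6) {
  check_rotation(r_thorax, tol)
  check_rotation(r_pelvis, tol)
  crossprod(r_pelvis, r_thorax)
}

check_rotation <- function(r, tol = 1e-6) {
  if (!is.matrix(r) || any(dim(r) != 3L))
    stop("rotation must be a 3x3 matrix")
  dev <- crossprod(r) - diag(3)
  if (sqrt(sum(dev^2)) > tol)
    stop("matrix is not orthogonal within tolerance ", format(tol))
  if (det(r) < 0) stop("matrix is a reflection, not a proper rotation")
  invisible(r)
}

#' Compose a rotation from lumbar Euler angles
#'
#' Rotation order: flexion-extension about x, then lateral-bending about y,
#' then axial-rotation about z (intrinsic), i.e.
#' `R = Rx(fe) %*% Ry(lb) %*% Rz(ar)`.
#'
#' @param fe,lb,ar angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_compose <- function(fe, lb, ar) {
  a <- fe / DEG; b <- lb / DEG; c <- ar / DEG
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  matrix(c(
    cb * cc,                  -cb * sc,                  sb,
    ca * sc + sa * sb * cc,    ca * cc - sa * sb * sc,  -sa * cb,
    sa * sc - ca * sb * cc,    sa * cc + ca * sb * sc,   ca * cb),
    nrow = 3, byrow = TRUE)
}

#' Decompose a rotation into lumbar Euler angles
#'
#' Inverse of [euler_compose()]: extracts (flexion-extension,
#' lateral-bending, axial-rotation) in degrees in the fixed anatomical order.
#' The decomposition is singular when lateral-bending approaches +/-90
#' degrees; a guard rejects rotations within `gimbal_margin` degrees of the
#' singularity (the reaching task never comes close).
#'
#' @param r 3x3 proper orthogonal matrix.
#' @param gimbal_margin guard band around +/-90 deg lateral-bending, degrees.
#' @return Named numeric vector `c(fe, lb, ar)` in degrees.
#' @export
euler_decompose <- function(r, gimbal_margin = 1) {
  check_rotation(r)
  if (abs(r[1L, 3L]) > sin((90 - gimbal_margin) / DEG))
    stop("lateral-bending within ", gimbal_margin,
         " deg of gimbal lock; decomposition unreliable")
  c(fe = atan2(-r[2L, 3L], r[3L, 3L]) * DEG,
    lb = asin(r[1L, 3L]) * DEG,
    ar = atan2(-r[1L, 2L], r[1L, 1L]) * DEG)
}

#' Full kinematic chain: marker trial to lumbar angle series
#'
#' Resamples to a fixed rate, builds thorax and pelvis cluster frames at every
#' sample, forms the relative (pelvis-to-thorax) rotation and decomposes it in
#' the flexion-extension, lateral-bending, axial-rotation order.
#'
#' Cluster frames are built directly from the markers; if the physical marker
#' placement does not align the cluster frames with the anatomical segment
#' frames, supply `reference` rotations (one per cluster, e.g. from an upright
#' calibration sample) that are right-multiplied away before decomposition.
#'
#' @param trial a [marker_trial()].
#' @param rate target sample rate, Hz.
#' @param reference optional list with 3x3 matrices `thorax` and `pelvis`
#'   giving each cluster frame in its segment frame at calibration.
#' @param max_gap see [resample_to_rate()].
#' @return An [angle_series()] at `rate` Hz.
#' @export
markers_to_angles <- function(trial, rate = 100, reference = NULL,
                              max_gap = 0.1) {
  trial <- resample_to_rate(trial, rate = rate, max_gap = max_gap)
  p <- trial$positions
  thorax <- vector_frames(p, "thorax")
  pelvis <- vector_frames(p, "pelvis")
  if (!is.null(reference)) {
    thorax <- lapply_frames(thorax, reference$thorax)
    pelvis <- lapply_frames(pelvis, reference$pelvis)
  }
  # relative rotation elements r_ij = <pelvis axis i, thorax axis j>,
  # vectorized across samples
  r13 <- rowSums(pelvis$e1 * thorax$e3)
  r23 <- rowSums(pelvis$e2 * thorax$e3)
  r33 <- rowSums(pelvis$e3 * thorax$e3)
  r11 <- rowSums(pelvis$e1 * thorax$e1)
  r12 <- rowSums(pelvis$e1 * thorax$e2)
  guard <- sin((90 - 1) / DEG)
  if (any(abs(r13) > guard))
    stop("lateral-bending within 1 deg of gimbal lock in trial")
  ang <- cbind(fe = atan2(-r23, r33) * DEG,
               lb = asin(pmin(pmax(r13, -1), 1)) * DEG,
               ar = atan2(-r12, r11) * DEG)
  angle_series(ang, sample_rate = rate)
}

# Per-sample orthonormal frames for one cluster, vectorized over samples.
# Returns list of n x 3 matrices e1, e2, e3 (global coordinates of the axes).
vector_frames <- function(positions, cluster) {
  cols <- function(i) positions[, paste0(cluster, "_", i, "_", c("x", "y", "z")),
                                drop = FALSE]
  p1 <- cols(1); p2 <- cols(2); p3 <- cols(3)
  v1 <- p2 - p1
  v2 <- p3 - p1
  n1 <- sqrt(rowSums(v1^2))
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  ncr <- sqrt(rowSums(cr^2))
  if (any(n1 == 0) || any(ncr / (n1 * sqrt(rowSums(v2^2))) < 1e-8))
    stop("degenerate ", cluster, " cluster in at least one sample")
  e1 <- v1 / n1
  e3 <- cr / ncr
  e2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Right-multiply every per-sample frame by t(ref): R_seg = R_cluster %*% t(ref)
lapply_frames <- function(frames, ref) {
  if (is.null(ref)) return(frames)
  # columns of R are e1,e2,e3; R_new = R %*% t(ref) means
  # e_new_j = sum_k e_k * ref[j, k]
  mk <- function(j) {
    frames$e1 * ref[j, 1] + frames$e2 * ref[j, 2] + frames$e3 * ref[j, 3]
  }
  list(e1 = mk(1), e2 = mk(2), e3 = mk(3))
}
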