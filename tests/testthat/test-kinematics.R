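test_that("resampling a uniform 100 Hz trial is the identity", {
  tr <- generate_marker_trial(generate_angle_trial(
    trial_config(n_cycles = 2, seed = 1)))
  rs <- resample_to_rate(tr, 100)
  expect_equal(rs$time, tr$time, tolerance = 1e-12)
  expect_lt(max(abs(rs$positions - tr$positions)), 1e-12)
})

test_that("cubic polynomials sampled at 102 Hz are reconstructed exactly", {
  t_in <- seq(0, 2, by = 1 / 102)
  poly <- function(t) 0.2 - 0.1 * t + 0.05 * t^2 - 0.01 * t^3
  pos <- matrix(poly(t_in), length(t_in), 18,
                dimnames = list(NULL, lumovar:::marker_columns()))
  # displace columns so clusters are non-degenerate (constant offsets keep
  # each coordinate cubic in time)
  pos <- sweep(pos, 2, seq(0, 1.7, by = 0.1), "+")
  tr <- marker_trial(t_in, pos, nominal_rate = 102)
  rs <- resample_to_rate(tr, 100)
  truth <- outer(poly(rs$time), rep(1, 18)) +
    matrix(seq(0, 1.7, by = 0.1), length(rs$time), 18, byrow = TRUE)
  expect_lt(max(abs(rs$positions - truth)), 1e-9)
})

test_that("jittered 102/103 Hz sine sampling resamples to < 1e-5 m error", {
  set.seed(7)
  t_in <- cumsum(1 / sample(c(102, 103), 400, replace = TRUE))
  y <- 0.1 * sin(2 * pi * 1 * t_in)
  pos <- matrix(rep(y, 18), ncol = 18,
                dimnames = list(NULL, lumovar:::marker_columns()))
  pos <- sweep(pos, 2, seq(0, 1.7, by = 0.1), "+")
  tr <- marker_trial(t_in, pos, nominal_rate = 102)
  rs <- resample_to_rate(tr, 100)
  truth <- 0.1 * sin(2 * pi * rs$time)
  expect_lt(max(abs(rs$positions[, 1] - seq(0, 1.7, by = 0.1)[1] - truth)),
            1e-5)
})

test_that("gaps longer than the bridge limit raise an error naming the marker", {
  t_in <- seq(0, 2, by = 0.01)
  pos <- matrix(rnorm(length(t_in) * 18, sd = 0.001), ncol = 18,
                dimnames = list(NULL, lumovar:::marker_columns()))
  pos <- sweep(pos, 2, seq(0, 1.7, by = 0.1), "+")
  pos[80:95, "thorax_2_y"] <- NA  # 0.15 s dropout
  tr <- marker_trial(t_in, pos)
  expect_error(resample_to_rate(tr), "thorax_2_y")
})

test_that("cluster orientation is the expected frame and rejects degeneracy", {
  R <- cluster_orientation(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(R, diag(3), tolerance = 1e-14)
  expect_error(cluster_orientation(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("cluster orientation is equivariant under rotations and invariant
           under translation and scaling", {
  set.seed(11)
  for (rep in 1:20) {
    p <- list(rnorm(3), rnorm(3), rnorm(3))
    base <- tryCatch(cluster_orientation(p[[1]], p[[2]], p[[3]]),
                     error = function(e) NULL)
    if (is.null(base)) next
    a <- random_angles(170)
    Q <- euler_compose(a[1], a[2], a[3])
    rot <- cluster_orientation(Q %*% p[[1]], Q %*% p[[2]], Q %*% p[[3]])
    expect_equal(rot, Q %*% base, tolerance = 1e-10)
    shift <- rnorm(3)
    s <- runif(1, 0.5, 3)
    tra <- cluster_orientation(s * p[[1]] + shift, s * p[[2]] + shift,
                               s * p[[3]] + shift)
    expect_equal(tra, base, tolerance = 1e-10)
  }
})

test_that("relative rotation satisfies the group identities", {
  set.seed(5)
  for (rep in 1:20) {
    a <- random_angles(60); b <- random_angles(60)
    Rt <- euler_compose(a[1], a[2], a[3])
    Rp <- euler_compose(b[1], b[2], b[3])
    expect_equal(relative_rotation(Rt, Rt), diag(3), tolerance = 1e-12)
    expect_equal(relative_rotation(Rt, diag(3)), Rt, tolerance = 1e-12)
    rel <- relative_rotation(Rt, Rp)
    expect_equal(Rp %*% rel, Rt, tolerance = 1e-12)
  }
  expect_error(relative_rotation(matrix(1:9 / 10, 3), diag(3)),
               "orthogonal")
})

test_that("euler decompose inverts compose for gimbal-safe rotations", {
  set.seed(2)
  worst <- 0
  for (rep in 1:1000) {
    a <- random_angles(60)
    rec <- euler_decompose(euler_compose(a[1], a[2], a[3]))
    worst <- max(worst, max(abs(rec - a)))
  }
  expect_lt(worst, 1e-9)
  expect_equal(euler_decompose(diag(3)), c(fe = 0, lb = 0, ar = 0))
  expect_equal(euler_decompose(euler_compose(20, 0, 0)),
               c(fe = 20, lb = 0, ar = 0), tolerance = 1e-12)
  expect_error(euler_decompose(euler_compose(0, 89.8, 0)), "gimbal")
})

test_that("full kinematic chain recovers injected angles", {
  # constant pure flexion
  const <- angle_series(matrix(rep(c(20, 0, 0), each = 50), ncol = 3),
                        sample_rate = 100)
  rec <- markers_to_angles(generate_marker_trial(const))
  expect_lt(max(abs(rec[, "fe"] - 20)), 1e-9)
  expect_lt(max(abs(rec[, c("lb", "ar")])), 1e-9)
  # zero angles give parallel frames
  zero <- angle_series(matrix(0, 50, 3), sample_rate = 100)
  rec0 <- markers_to_angles(generate_marker_trial(zero))
  expect_lt(max(abs(rec0)), 1e-9)
  # smooth random series round-trips below a micro-degree
  tr <- generate_angle_trial(trial_config(n_cycles = 4, amp_fe = 40,
                                          spatial_noise_sd = 1, seed = 6))
  rec2 <- markers_to_angles(generate_marker_trial(tr))
  expect_lt(max(abs(rec2 - tr[seq_len(nrow(rec2)), ])), 1e-6)
})
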