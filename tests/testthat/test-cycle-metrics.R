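test_that("peak detection matches generator ground truth on clean trials", {
  tr <- generate_angle_trial(noiseless_config(seed = 3))
  gt <- attr(tr, "ground_truth")
  peaks <- detect_cycles(tr)
  expect_length(peaks, 45L)
  expect_lte(max(abs(peaks - gt$peak_index)), 1L)
})

test_that("constant or periodic-free signals raise detection errors", {
  expect_error(detect_cycles(rep(1, 1000)), "constant")
  expect_error(detect_cycles(seq(0, 1, length.out = 500)))
})

test_that("an unexpected peak count raises an error listing the peaks", {
  tr <- generate_angle_trial(noiseless_config(seed = 3))
  expect_error(detect_cycles(tr, expected = 44), "expected 44")
})

test_that("analysis-cycle selection keeps the final cycles", {
  expect_equal(select_analysis_cycles(1:46), 6:46)   # cycles 6..45 retained
  expect_equal(select_analysis_cycles(1:41), 1:41)   # boundary: all kept
  expect_error(select_analysis_cycles(1:30), "at least 41")
})

test_that("CyclSD matches closed forms", {
  expect_identical(cycl_sd(rep(2.6, 40)), 0)
  expect_equal(cycl_sd(c(2.5, 2.7)), sqrt(2 * 0.01 / 1), tolerance = 1e-12)
  expect_error(cycl_sd(2.6), "at least 2")
})

test_that("cycle normalization preserves endpoints, linearity and shape", {
  # identity on a cycle already sampled at 101 uniform points
  y <- sin(seq(0, 2 * pi, length.out = 101))
  ang <- cbind(y, y, y)
  out <- normalize_cycles(ang, c(1L, 101L))
  expect_lt(max(abs(out[1, , 1] - y)), 1e-12)
  # linear ramps stay exactly linear in phase
  ramp <- cbind(seq(0, 5, length.out = 61), 0, 0)
  out2 <- normalize_cycles(ramp, c(1L, 61L))
  expect_lt(max(abs(out2[1, , 1] - seq(0, 5, length.out = 101))), 1e-10)
  # time-warp invariance: same shape at double duration
  u1 <- seq(0, 1, length.out = 201)
  u2 <- seq(0, 1, length.out = 401)
  shape <- function(u) 10 * (1 - cos(2 * pi * u))
  a1 <- cbind(shape(u1), 0, 0)
  a2 <- cbind(shape(u2), 0, 0)
  n1 <- normalize_cycles(a1, c(1L, 201L))
  n2 <- normalize_cycles(a2, c(1L, 401L))
  expect_lt(max(abs(n1 - n2)), 1e-6)
  expect_error(normalize_cycles(ramp, c(1L, 3L)), "fewer than 4")
})

test_that("alignment recovers a constructed shift and reduces variability", {
  base <- 10 * (1 - cos(2 * pi * seq(0, 1, length.out = 101)))
  cyc <- array(0, dim = c(3, 101, 3))
  for (i in 1:3) cyc[i, , 1] <- base
  cyc[2, , 1] <- lumovar:::circ_shift(base, 3L)   # pre-shift by +3
  ali <- align_cycles(cyc)
  expect_equal(ali$shifts[2] - ali$shifts[1], -3L)
  expect_lt(mean_sd(ali$cycles)[["fe"]], 1e-9)
})

test_that("alignment never increases flexion-extension MeanSD", {
  for (s in 1:5) {
    tr <- generate_angle_trial(trial_config(n_cycles = 12,
                                            spatial_noise_sd = 1,
                                            seed = 20 + s))
    peaks <- detect_cycles(tr)
    cyc <- normalize_cycles(tr, peaks)
    ali <- align_cycles(cyc)
    expect_lte(mean_sd(ali$cycles)[["fe"]], mean_sd(cyc)[["fe"]] + 1e-12)
  }
})

test_that("shifts beyond the search bound are clamped", {
  base <- 10 * (1 - cos(2 * pi * seq(0, 1, length.out = 101)))
  cyc <- array(0, dim = c(4, 101, 3))
  for (i in 1:4) cyc[i, , 1] <- base
  cyc[2, , 1] <- lumovar:::circ_shift(base, 15L)
  expect_message(ali <- align_cycles(cyc), "clamped")
  expect_lte(max(abs(ali$shifts)), 10L)
})

test_that("MeanSD matches closed forms and invariances", {
  # identical cycles -> 0
  cyc <- array(rep(sin(seq(0, 2 * pi, length.out = 101)), 6),
               dim = c(101, 2, 3))
  cyc <- aperm(cyc, c(2, 1, 3))
  expect_equal(unname(mean_sd(cyc)), c(0, 0, 0))
  # constant 1-degree offset on one axis: SD of {a, a+1} = 1/sqrt(2)
  cyc[2, , 1] <- cyc[2, , 1] + 1
  ms <- mean_sd(cyc)
  expect_equal(ms[["fe"]], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(ms[["lb"]], 0)
  # shift invariance and linear scaling about the mean
  cyc2 <- cyc
  cyc2[, , 1] <- cyc2[, , 1] + 100
  expect_equal(mean_sd(cyc2)[["fe"]], ms[["fe"]], tolerance = 1e-12)
  m <- apply(cyc[, , 1], 2, mean)
  cyc3 <- cyc
  cyc3[, , 1] <- sweep(sweep(cyc[, , 1], 2, m), 1, rep(3, 2), "*")
  cyc3[, , 1] <- sweep(cyc3[, , 1], 2, m, "+")
  expect_equal(mean_sd(cyc3)[["fe"]], 3 * ms[["fe"]], tolerance = 1e-12)
  expect_error(mean_sd(cyc[1, , , drop = FALSE]), "at least 2")
})

test_that("MeanSD recovers injected independent noise", {
  msd <- vapply(1:15, function(s) {
    tr <- generate_angle_trial(trial_config(spatial_noise_sd = 1,
                                            temporal_jitter_sd = 0,
                                            process_noise_sd = 0, seed = s))
    run_trial_pipeline(tr, pipeline_config(compute_lde = FALSE))$mean_sd_fe
  }, numeric(1))
  expect_gt(mean(msd), 0.9)
  expect_lt(mean(msd), 1.1)
})

test_that("amplitude matches arithmetic and known extrema", {
  # cycles with maxima {21, 19} and minima {1, -1} -> (21+19)/2 - (1-1)/2
  c1 <- cbind(seq(1, 21, length.out = 50), 0, 0)
  c2 <- cbind(seq(-1, 19, length.out = 50), 0, 0)
  expect_equal(amplitude(list(c1, c2))[["fe"]], 20)
  # constant signal -> 0
  expect_equal(amplitude(list(cbind(rep(1, 10), 1, 1)))[["fe"]], 0)
  # raised cosine 0 -> 20 -> 0
  tr <- generate_angle_trial(noiseless_config(seed = 1))
  row <- run_trial_pipeline(tr, pipeline_config(compute_lde = FALSE))
  expect_equal(row$amplitude_fe, 20, tolerance = 1e-3)
})

test_that("velocity is repetitions over analyzed span", {
  expect_equal(velocity(45, 150), 0.30)
  expect_equal(velocity(40, 105.3), 0.3799, tolerance = 1e-4)
  expect_error(velocity(40, 0), "positive")
  # protocol-rate trials land near 0.38 repetitions/s
  tr <- generate_angle_trial(noiseless_config(seed = 2))
  row <- run_trial_pipeline(tr, pipeline_config(compute_lde = FALSE))
  expect_equal(row$velocity, 1 / 2.6, tolerance = 1e-6)
})
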