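# Shared fixtures: tiny deterministic trials and independent oracles used
# across test files.

# quiet trial configs ------------------------------------------------------

noiseless_config <- function(n_cycles = 45, seed = 1, ...) {
  trial_config(n_cycles = n_cycles, spatial_noise_sd = 0,
               temporal_jitter_sd = 0, process_noise_sd = 0, seed = seed, ...)
}

# short embedding config for fast LDE computation in bulk simulations; the
# fit range (0..75 lags) is unaffected by the shorter tracking horizon
fast_embedding <- function() embedding_config(horizon = 80)

# random gimbal-safe rotation ---------------------------------------------

random_angles <- function(max_deg = 60) runif(3, -max_deg, max_deg)

# independent oracles ------------------------------------------------------

# brute-force nearest neighbors with a Theiler exclusion, via the full
# distance matrix
nn_oracle <- function(X, k, theiler) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  t(vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[abs(seq_len(n) - i) <= theiler] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}

# direct transcription of the divergence-curve definition
divergence_oracle <- function(X, nbrs, horizon, floor_d = 1e-12) {
  n <- nrow(X)
  vapply(0:horizon, function(tau) {
    per_ref <- c()
    for (i in seq_len(n - tau)) {
      logs <- c()
      for (j in nbrs[i, ]) {
        if (j + tau > n) next
        d <- sqrt(sum((X[i + tau, ] - X[j + tau, ])^2))
        logs <- c(logs, log(max(d, floor_d)))
      }
      if (length(logs)) per_ref <- c(per_ref, mean(logs))
    }
    mean(per_ref)
  }, numeric(1))
}

# Mann-Whitney U by exhaustive pair counting
u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
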