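# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately written as plain loops over the documented
# seed protocols; they must stay independent of the package internals.

# Oracle for sample_null_windows(): per group, per trial window, one uniform
# draw placing a duration-matched window in the session; spikes counted by
# direct logical comparison.
oracle_null_windows <- function(times, span, durations, n_groups, seed) {
  set.seed(seed)
  out <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    rates <- numeric(length(durations))
    for (k in seq_along(durations)) {
      u <- stats::runif(1)
      a <- span[1] + u * (diff(span) - durations[k])
      b <- a + durations[k]
      rates[k] <- sum(times >= a & times < b) / durations[k]
    }
    out[g] <- mean(rates)
  }
  out
}

# Oracle for resampled_trial_null(): per group one coin flip, then
# sample.int() per type; group curve = population average of z-scored mean
# rates over the drawn trials.
oracle_variation_null <- function(peths1, peths2, mu, sdv, n_groups, seed) {
  n1 <- nrow(peths1[[1]]); n2 <- nrow(peths2[[1]])
  n_draw <- min(n1, n2)
  half <- n_draw %/% 2L
  odd <- n_draw %% 2L == 1L
  nb <- ncol(peths1[[1]])
  out <- matrix(NA_real_, n_groups, nb)
  set.seed(seed)
  for (g in seq_len(n_groups)) {
    coin <- stats::runif(1) < 0.5
    q1 <- half + as.integer(odd && coin)
    q2 <- n_draw - q1
    idx1 <- sample.int(n1, q1, replace = q1 > n1)
    idx2 <- sample.int(n2, q2, replace = q2 > n2)
    z <- matrix(0, length(peths1), nb)
    for (i in seq_along(peths1)) {
      m <- (colSums(peths1[[i]][idx1, , drop = FALSE]) +
              colSums(peths2[[i]][idx2, , drop = FALSE])) / n_draw
      z[i, ] <- if (sdv[i] > 0) (m - mu[i]) / sdv[i] else 0
    }
    out[g, ] <- colMeans(z)
  }
  out
}

# Brute-force cross-correlogram: full double loop over spike pairs.
oracle_ccg_counts <- function(pre, post, bin_width = 5e-4, span = 0.05) {
  n_bins <- 2L * round(span / bin_width) + 1L
  counts <- integer(n_bins)
  lo <- -span - bin_width / 2
  for (tp in pre) {
    for (tq in post) {
      d <- tq - tp
      if (d >= lo && d < span + bin_width / 2) {
        b <- floor((d - lo) / bin_width) + 1L
        counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# A short homogeneous Poisson spike train for unit tests.
poisson_train <- function(rate, span, seed, id = 1L) {
  simulate_rate_train(rate, NULL, span, seed = seed, neuron_id = id)
}
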