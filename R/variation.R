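#' Trial-resampling null band for a trial-type comparison
#'
#' Builds the null distribution for the movement-variation divergence test.
#' Given a neuron population with N trials of type 1 and M of type 2
#' (N <= M), each of `n_groups` random groups draws N trials split as evenly
#' as possible between the two types; for an odd N the extra trial's type is
#' decided by a seeded coin flip per group. For every group the
#' population-average z-scored rate is computed per bin, and the band is the
#' per-bin 0.05th and 99.95th percentile over groups (the 99.9% confidence
#' interval).
#'
#' Seed protocol (relied on by independent re-implementations): after
#' `set.seed(seed)`, each group consumes, in order, one uniform for the coin
#' flip, then `sample.int(n1, q1)`, then `sample.int(n2, q2)`. Sampling is
#' without replacement unless a type has fewer trials than its quota, in
#' which case that type is sampled with replacement and the result flagged.
#'
#' @param peths1,peths2 lists (one element per neuron, same order) of
#'   trials x bins rate matrices on a shared bin grid, for trial types 1
#'   and 2
#' @param zstats a [zscore_concatenated()] result holding the per-neuron
#'   normalization constants (from the concatenation of the per-type mean
#'   rates)
#' @param n_groups number of random groups (default 1000)
#' @param seed integer seed
#' @return list with `lower`, `upper` (per-bin band), `null_curves`
#'   (n_groups x bins), `n_draw` (N), `replacement` flag
#' @export
resampled_trial_null <- function(peths1, peths2, zstats, n_groups = 1000L,
                                 seed = 1L) {
  n_neurons <- length(peths1)
  stopifnot(n_neurons == length(peths2), n_neurons >= 1L)
  n1 <- nrow(peths1[[1]]); n2 <- nrow(peths2[[1]])
  n_draw <- min(n1, n2)
  if (n_draw < 5L) {
    warning("fewer than 5 trials in the smaller type; ",
            "the resampling null will be coarse")
  }
  nb <- ncol(peths1[[1]])
  # wide layout: trials x (bins * neurons), so a group's population curves
  # are column means over the selected rows
  w1 <- do.call(cbind, peths1)
  w2 <- do.call(cbind, peths2)
  mu <- rep(zstats$mean, each = nb)
  denom <- zstats$sd
  denom[denom == 0 | is.na(denom)] <- 1
  denom <- rep(denom, each = nb)
  zero <- rep(seq_len(n_neurons) %in% zstats$flagged, each = nb)

  set.seed(seed)
  replacement <- FALSE
  null_curves <- matrix(NA_real_, n_groups, nb)
  half <- n_draw %/% 2L
  odd <- n_draw %% 2L == 1L
  for (g in seq_len(n_groups)) {
    coin <- stats::runif(1) < 0.5
    q1 <- half + as.integer(odd && coin)
    q2 <- n_draw - q1
    r1 <- q1 > n1; r2 <- q2 > n2
    replacement <- replacement || r1 || r2
    idx1 <- sample.int(n1, q1, replace = r1)
    idx2 <- sample.int(n2, q2, replace = r2)
    s <- (colSums(w1[idx1, , drop = FALSE]) +
            colSums(w2[idx2, , drop = FALSE])) / n_draw
    z <- (s - mu) / denom
    z[zero] <- 0
    null_curves[g, ] <- rowMeans(matrix(z, nrow = nb))
  }
  qs <- apply(null_curves, 2, stats::quantile, probs = c(0.0005, 0.9995),
              type = 7, names = FALSE)
  list(lower = qs[1, ], upper = qs[2, ], null_curves = null_curves,
       n_draw = n_draw, replacement = replacement)
}

#' Detect divergent windows between two trial-type curves
#'
#' Flags bins at which one trial type's population curve lies below the
#' lower band percentile while the other lies above the upper one (either
#' orientation), and reports maximal runs of flagged bins spanning at least
#' `min_dur` seconds, with the direction of each run.
#'
#' @param curve1,curve2 per-bin population-average z-scored rates
#' @param lower,upper the null band from [resampled_trial_null()]
#' @param bin_starts bin start times, seconds (relative to alignment)
#' @param bin_width bin width, seconds
#' @param min_dur minimum window duration, seconds (default 0.05)
#' @return data.frame with columns `start`, `stop` (seconds, half-open) and
#'   `direction` (`"type1_below"` or `"type2_below"`); zero rows when the
#'   curves stay inside the band
#' @export
detect_divergent_windows <- function(curve1, curve2, lower, upper,
                                     bin_starts, bin_width,
                                     min_dur = 0.05) {
  f1 <- curve1 < lower & curve2 > upper
  f2 <- curve2 < lower & curve1 > upper
  state <- ifelse(f1, 1L, ifelse(f2, 2L, 0L))
  state[is.na(state)] <- 0L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths * bin_width >= min_dur
  data.frame(
    start = bin_starts[starts[keep]],
    stop = bin_starts[ends[keep]] + bin_width,
    direction = c("type1_below", "type2_below")[r$values[keep]]
  )[seq_len(sum(keep)), , drop = FALSE]
}

#' Trial-type divergence test for a neuron population
#'
#' End-to-end wrapper: computes event-aligned per-trial rates for every
#' neuron and both trial types, z-scores with constants from the
#' concatenated per-type averages, builds the trial-resampling null band and
#' reports divergent windows.
#'
#' @param trains list of [spike_train()]
#' @param events1,events2 alignment times (retraction starts) of trial types
#'   1 and 2
#' @param window analysis window, seconds (default `c(-2, 2)`)
#' @param bin_width bin width, seconds (default 0.005)
#' @param smoothing smoothing spec passed to [compute_peth()] (default the
#'   standard Gaussian)
#' @param n_groups,seed null parameters
#' @param min_dur minimum divergent-window duration, seconds
#' @return object of class `divergence_result`: list with `curve1`,
#'   `curve2`, `lower`, `upper`, `bin_starts`, `windows`, `null`
#' @export
variation_test <- function(trains, events1, events2, window = c(-2, 2),
                           bin_width = 0.005, smoothing = list(),
                           n_groups = 1000L, seed = 1L, min_dur = 0.05) {
  p1 <- lapply(trains, function(tr) {
    compute_peth(tr, events1, bin_width, window, smoothing)$rate
  })
  p2 <- lapply(trains, function(tr) {
    compute_peth(tr, events2, bin_width, window, smoothing)$rate
  })
  m1 <- do.call(rbind, lapply(p1, colMeans))
  m2 <- do.call(rbind, lapply(p2, colMeans))
  zs <- zscore_concatenated(list(m1, m2))
  null <- resampled_trial_null(p1, p2, zs, n_groups, seed)
  curve1 <- colMeans(zs$z[[1]])
  curve2 <- colMeans(zs$z[[2]])
  nb <- ncol(m1)
  bin_starts <- window[1] + (seq_len(nb) - 1L) * bin_width
  windows <- detect_divergent_windows(curve1, curve2, null$lower,
                                      null$upper, bin_starts, bin_width,
                                      min_dur)
  structure(list(curve1 = curve1, curve2 = curve2, lower = null$lower,
                 upper = null$upper, bin_starts = bin_starts,
                 bin_width = bin_width, windows = windows, null = null),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("Trial-type divergence:", nrow(x$windows),
      "significant window(s) >= 50 ms\n")
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}
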