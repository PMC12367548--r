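#' Permutation null of mean rates over random duration-matched windows
#'
#' Builds the null distribution for the task-window modulation test: 1,000
#' (by default) groups of N random windows placed uniformly over the whole
#' session span, the k-th window of each group matching the duration of the
#' k-th trial's window; the group statistic is the mean of the per-window
#' rates. Task periods are not excluded from the sampling domain, which is
#' conservative.
#'
#' Seed protocol (relied on by independent re-implementations): after
#' `set.seed(seed)`, a single stream of `n_groups * N` uniforms is consumed
#' group-major (all windows of group 1, then group 2, ...); the k-th window
#' of a group starts at `span_start + u * (span_length - duration_k)`.
#'
#' @param train a [spike_train()]
#' @param durations numeric vector of the N per-trial window durations,
#'   seconds
#' @param n_groups number of null groups (default 1000)
#' @param seed integer seed
#' @return object of class `null_distribution`: list with `group_rates`
#'   (n_groups mean rates, Hz), `median`, `durations`, `n_groups`, `seed`
#' @export
sample_null_windows <- function(train, durations, n_groups = 1000L,
                                seed = 1L) {
  stopifnot(inherits(train, "spike_train"), length(durations) >= 1L)
  span_len <- diff(train$span)
  if (any(durations > span_len)) {
    stop("null window duration exceeds the session span")
  }
  if (any(durations <= 0)) stop("window durations must be positive")
  n <- length(durations)
  set.seed(seed)
  u <- matrix(stats::runif(n_groups * n), nrow = n_groups, byrow = TRUE)
  starts <- train$span[1] + u * rep(span_len - durations, each = n_groups)
  stops <- starts + rep(durations, each = n_groups)
  counts <- count_in_windows(train$times, as.numeric(starts),
                             as.numeric(stops))
  rates <- matrix(counts, nrow = n_groups) /
    rep(durations, each = n_groups)
  group_rates <- rowMeans(rates)
  structure(list(group_rates = group_rates,
                 median = stats::median(group_rates),
                 durations = durations, n_groups = n_groups, seed = seed),
            class = "null_distribution")
}

#' Task-window modulation index against a permutation null
#'
#' The modulation index is the difference between the mean spike rate during
#' the task window (averaged over trials, each trial's rate = in-window count
#' / window duration) and the median of the null distribution, normalized to
#' the sum of the two — bounded in `[-1, 1]` and robust to baseline-rate
#' differences. Significance requires `|MI| > 0.025` together with a
#' mid-rank percentile of the observed rate within the null at or below the
#' 1st percentile (negative modulation) or at or above the 99th (positive).
#'
#' @param train a [spike_train()]
#' @param windows data.frame with columns `start`, `stop` (seconds), one row
#'   per trial; durations must match `null$durations`
#' @param null a [sample_null_windows()] result
#' @param mi_threshold absolute MI significance threshold (default 0.025)
#' @return one-row data.frame: `r_win_hz`, `null_median_hz`, `mi`,
#'   `rank_pct`, `significant`, `direction`, `degenerate`
#' @export
window_modulation <- function(train, windows, null, mi_threshold = 0.025) {
  durs <- windows$stop - windows$start
  if (length(durs) != length(null$durations) ||
        max(abs(durs - null$durations)) > 1e-9) {
    stop("window durations do not match the null distribution")
  }
  counts <- count_in_windows(train$times, windows$start, windows$stop)
  r_win <- mean(counts / durs)
  med <- null$median
  degenerate <- (r_win + med) == 0
  mi <- if (degenerate) 0 else (r_win - med) / (r_win + med)
  g <- null$group_rates
  rank_pct <- (sum(g < r_win) + 0.5 * sum(g == r_win)) / length(g) * 100
  sig_neg <- rank_pct <= 1 & mi < -mi_threshold
  sig_pos <- rank_pct >= 99 & mi > mi_threshold
  data.frame(r_win_hz = r_win, null_median_hz = med, mi = mi,
             rank_pct = rank_pct, significant = sig_neg | sig_pos,
             direction = if (sig_neg) "negative" else
               if (sig_pos) "positive" else "none",
             degenerate = degenerate)
}

#' Modulation table over neurons and task windows
#'
#' Runs the modulation test for every (neuron, task window) combination.
#' Trials lacking a window (NA bounds) are omitted from that window's test;
#' windows defined for fewer than `min_trials` trials are skipped. Each
#' (neuron, window) pair derives its own sub-seed from `seed` so any single
#' test can be reproduced in isolation.
#'
#' @param trains list of [spike_train()]
#' @param windows data.frame from [task_windows()]
#' @param n_groups null groups per test
#' @param seed top-level seed
#' @param min_trials minimum trials per window (default 5)
#' @param mi_threshold see [window_modulation()]
#' @return data.frame with one row per (neuron, window): `neuron_id`,
#'   `window_id`, `n_trials` plus the [window_modulation()] columns
#' @export
modulation_table <- function(trains, windows, n_groups = 1000L, seed = 1L,
                             min_trials = 5L, mi_threshold = 0.025) {
  res <- list()
  for (tr in trains) {
    for (w in sort(unique(windows$window_id))) {
      ww <- windows[windows$window_id == w & !is.na(windows$start), ,
                    drop = FALSE]
      if (nrow(ww) < min_trials) next
      sub <- derive_seed(seed, paste0("mod-", tr$neuron_id, "-", w))
      null <- sample_null_windows(tr, ww$stop - ww$start, n_groups, sub)
      row <- window_modulation(tr, ww, null, mi_threshold)
      res[[length(res) + 1L]] <-
        cbind(data.frame(neuron_id = tr$neuron_id, window_id = w,
                         n_trials = nrow(ww)), row)
    }
  }
  do.call(rbind, res)
}

#' Classify neurons by modulation direction across task windows
#'
#' A neuron is negatively modulated if it has at least one significant
#' negative window, positively modulated likewise, bidirectional if both,
#' and unmodulated otherwise.
#'
#' @param table a [modulation_table()] result
#' @return list with `per_neuron` (data.frame: `neuron_id`, `any_negative`,
#'   `any_positive`, `class`) and `fractions` (named proportions over
#'   neurons, including `negative_any` and `positive_any` marginals)
#' @export
classify_bidirectional <- function(table) {
  ids <- unique(table$neuron_id)
  neg <- vapply(ids, function(i) {
    any(table$direction[table$neuron_id == i] == "negative")
  }, logical(1))
  pos <- vapply(ids, function(i) {
    any(table$direction[table$neuron_id == i] == "positive")
  }, logical(1))
  cls <- ifelse(neg & pos, "bidirectional",
                ifelse(neg, "negative",
                       ifelse(pos, "positive", "unmodulated")))
  per_neuron <- data.frame(neuron_id = ids, any_negative = neg,
                           any_positive = pos, class = cls)
  fr <- c(modulated = mean(neg | pos),
          negative_any = mean(neg),
          positive_any = mean(pos),
          bidirectional = mean(neg & pos),
          unmodulated = mean(!neg & !pos))
  n_mod <- sum(neg | pos)
  fr["bidirectional_of_modulated"] <-
    if (n_mod > 0) sum(neg & pos) / n_mod else NA_real_
  list(per_neuron = per_neuron, fractions = fr)
}

#' Per-trial lever-press modulation classifier
#'
#' For each press trial, the modulation value is the firing rate in the
#' 200 ms window centred on the press minus the rate in the 200 ms baseline
#' window preceding the cue. The trial values are compared with a null set
#' built from at least 200 random timepoints over the session (or the number
#' of trials if larger) using a two-sided Mann-Whitney U test. For each
#' random timepoint the press-like window is centred on it and the baseline
#' window is placed at the median cue-to-press offset before it, mirroring
#' the trial construction. A neuron is classified when `p < 0.05`, with the
#' direction given by the sign of the mean trial modulation.
#'
#' @param train a [spike_train()]
#' @param press_times,cue_times numeric vectors, seconds, one per responded
#'   trial (equal length, press after cue)
#' @param seed integer seed for the random timepoints
#' @param n_random minimum number of random timepoints (default 200)
#' @param press_halfwidth half-width of the press window, s (default 0.1)
#' @param baseline_width baseline window width, s (default 0.2)
#' @return object of class `press_modulation`: list with `trial_mi` (Hz),
#'   `null_mi`, `mean_mi`, `p`, `classified`, `direction`
#' @export
press_trial_modulation <- function(train, press_times, cue_times, seed = 1L,
                                   n_random = 200L, press_halfwidth = 0.1,
                                   baseline_width = 0.2) {
  stopifnot(length(press_times) == length(cue_times))
  if (length(press_times) < 5L) stop("at least 5 press trials are required")
  rate_in <- function(starts, stops) {
    count_in_windows(train$times, starts, stops) / (stops - starts)
  }
  trial_mi <- rate_in(press_times - press_halfwidth,
                      press_times + press_halfwidth) -
    rate_in(cue_times - baseline_width, cue_times)
  offset <- stats::median(press_times - cue_times)
  m <- max(n_random, length(press_times))
  lo <- train$span[1] + offset + baseline_width
  hi <- train$span[2] - press_halfwidth
  if (hi <= lo) {
    stop("session too short to place ", m, " random-timepoint windows")
  }
  set.seed(seed)
  t0 <- stats::runif(m, lo, hi)
  null_mi <- rate_in(t0 - press_halfwidth, t0 + press_halfwidth) -
    rate_in(t0 - offset - baseline_width, t0 - offset)
  p <- stats::wilcox.test(trial_mi, null_mi, exact = FALSE)$p.value
  mean_mi <- mean(trial_mi)
  classified <- is.finite(p) && p < 0.05
  structure(list(trial_mi = trial_mi, null_mi = null_mi, mean_mi = mean_mi,
                 p = p, classified = classified,
                 direction = if (!classified) "none" else
                   if (mean_mi < 0) "negative" else "positive"),
            class = "press_modulation")
}
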