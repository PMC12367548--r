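#' Event-aligned neuron-to-neuron correlation matrix
#'
#' Correlates the trial-averaged, Gaussian-smoothed firing rates of all
#' neurons over a window around a set of timestamps (e.g. first retraction
#' starts, repeated-reach retractions, or random session timestamps as a
#' control). Returns the pairwise Pearson correlation across time bins.
#' Zero-variance neurons yield NA for their pairs; the diagonal is 1.
#'
#' @param trains list of [spike_train()] (>= 2)
#' @param timestamps alignment times, seconds (>= 5)
#' @param window analysis window, seconds (default `c(-2, 2)`)
#' @param bin_width bin width, seconds (default 0.005)
#' @param smoothing smoothing spec for [compute_peth()]; `list()` applies
#'   the standard Gaussian, NULL disables
#' @param condition optional label stored on the result
#' @return neurons x neurons correlation matrix with attribute `condition`
#' @export
event_aligned_correlation_matrix <- function(trains, timestamps,
                                             window = c(-2, 2),
                                             bin_width = 0.005,
                                             smoothing = list(),
                                             condition = NULL) {
  if (length(trains) < 2L) stop("at least 2 neurons are required")
  if (length(timestamps) < 5L) stop("at least 5 timestamps are required")
  curves <- vapply(trains, function(tr) {
    colMeans(compute_peth(tr, timestamps, bin_width, window, smoothing)$rate)
  }, numeric(round(diff(window) / bin_width)))
  sds <- apply(curves, 2, stats::sd)
  m <- suppressWarnings(stats::cor(curves))
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  ids <- vapply(trains, function(tr) as.character(tr$neuron_id), "")
  dimnames(m) <- list(ids, ids)
  attr(m, "condition") <- condition
  m
}

#' Regression between two pairwise correlation structures
#'
#' Ordinary least squares of matrix B's off-diagonal pairwise correlations
#' on matrix A's (upper triangle only, pairwise-complete), quantifying how
#' much of the correlational structure around one set of timestamps is
#' preserved around another.
#'
#' @param matrix_a,matrix_b correlation matrices over the same neuron set
#' @return list with `slope`, `intercept`, `r` (Pearson r of the fit) and
#'   `n_pairs`
#' @export
correlation_structure_regression <- function(matrix_a, matrix_b) {
  stopifnot(all(dim(matrix_a) == dim(matrix_b)))
  ut <- upper.tri(matrix_a)
  a <- matrix_a[ut]; b <- matrix_b[ut]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("fewer than 3 complete neuron pairs")
  fit <- stats::lm(b[ok] ~ a[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(a[ok], b[ok]),
       n_pairs = sum(ok))
}

#' Trial-to-trial noise correlation of a neuron pair
#'
#' Correlates the single-trial spike rates of a (putatively presynaptic,
#' postsynaptic) pair in 20 ms bins across a 400 ms window centred on a
#' behavioural timestamp, bin by bin across trials. Also reports the
#' correlation at the bin where the postsynaptic mean rate peaks.
#'
#' @param pre,post [spike_train()] objects
#' @param timestamps behavioural alignment times (>= 10)
#' @param bin_width bin width, seconds (default 0.02)
#' @param window centred window, seconds (default `c(-0.2, 0.2)`)
#' @return object of class `noise_correlation`: list with `r_per_bin`
#'   (NA where a bin has zero variance), `bin_starts`, `peak_bin`,
#'   `r_at_post_peak`, `n_trials`
#' @export
noise_correlation <- function(pre, post, timestamps, bin_width = 0.02,
                              window = c(-0.2, 0.2)) {
  if (length(timestamps) < 10L) stop("at least 10 trials are required")
  rp <- compute_peth(pre, timestamps, bin_width, window)$rate
  rq <- compute_peth(post, timestamps, bin_width, window)$rate
  nb <- ncol(rp)
  r <- vapply(seq_len(nb), function(b) {
    x <- rp[, b]; y <- rq[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  peak <- which.max(colMeans(rq))
  structure(list(r_per_bin = r,
                 bin_starts = window[1] + (seq_len(nb) - 1L) * bin_width,
                 peak_bin = peak, r_at_post_peak = r[peak],
                 n_trials = nrow(rp)),
            class = "noise_correlation")
}
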