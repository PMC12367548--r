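#' Cross-correlogram of a neuron pair
#'
#' Histogram of postsynaptic-minus-presynaptic spike-time differences in
#' 0.5 ms bins over a +/-50 ms lag span (both configurable). Positive lags
#' mean the post spike follows the pre spike; the central bin is centred on
#' lag zero. Duplicate timestamps across the two trains fall in the lag-0
#' bin.
#'
#' @param pre,post [spike_train()] objects with distinct ids
#' @param bin_width lag bin width, seconds (default 5e-4)
#' @param span maximum |lag|, seconds (default 0.05)
#' @return object of class `ccg`: list with `lags` (bin centres, s),
#'   `counts`, `bin_width`, `span`, `pre_id`, `post_id`, `n_pre`, `n_post`
#' @export
compute_ccg <- function(pre, post, bin_width = 5e-4, span = 0.05) {
  if (identical(pre$neuron_id, post$neuron_id)) {
    stop("pre and post must be different neurons (no autocorrelograms)")
  }
  if (!length(pre$times) || !length(post$times)) {
    stop("both spike trains must be non-empty")
  }
  half_bin <- bin_width / 2
  n_bins <- 2L * round(span / bin_width) + 1L
  lags <- (seq_len(n_bins) - (n_bins + 1L) / 2) * bin_width
  lo_edge <- -span - half_bin
  # indices of post spikes within [t_pre + lo_edge, t_pre + span + half_bin)
  i_lo <- findInterval(pre$times + lo_edge, post$times, left.open = TRUE)
  i_hi <- findInterval(pre$times + span + half_bin, post$times,
                       left.open = TRUE)
  n_each <- i_hi - i_lo
  keep <- n_each > 0L
  if (!any(keep)) {
    counts <- integer(n_bins)
  } else {
    post_idx <- sequence(n_each[keep], from = i_lo[keep] + 1L)
    diffs <- post$times[post_idx] - rep(pre$times[keep], n_each[keep])
    bin_idx <- floor((diffs - lo_edge) / bin_width) + 1L
    bin_idx <- bin_idx[bin_idx >= 1L & bin_idx <= n_bins]
    counts <- tabulate(bin_idx, n_bins)
  }
  structure(list(lags = lags, counts = counts, bin_width = bin_width,
                 span = span, pre_id = pre$neuron_id,
                 post_id = post$neuron_id,
                 n_pre = length(pre$times), n_post = length(post$times)),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("CCG %s -> %s: %d pairs in +/-%g ms (%g ms bins)\n",
              format(x$pre_id), format(x$post_id), sum(x$counts),
              x$span * 1000, x$bin_width * 1000))
  invisible(x)
}

#' @export
plot.ccg <- function(x, ...) {
  graphics::plot(x$lags * 1000, x$counts, type = "h",
                 xlab = "lag (ms)", ylab = "count", ...)
  if (!is.null(x$predictor)) {
    graphics::lines(x$lags * 1000, x$predictor, col = 2)
  }
  invisible(x)
}

#' Hollow-Gaussian Poisson deficit test on a cross-correlogram
#'
#' Computes the slow-comodulation predictor by convolving the observed
#' correlogram with a Gaussian kernel whose central bin weight is multiplied
#' by `1 - hollow_fraction` (partially hollowed window, renormalized;
#' reflect padding at the edges). For every lag, the deficit p-value is the
#' probability under Poisson(predictor) of a count at most the observed
#' one, with half weight on the observed count (continuity correction):
#' `P(X < k) + 0.5 P(X = k)`. The z-score standardizes the observed count
#' against the mean and s.d. of the flank bins (|lag| in `flank_ms`),
#' which is robust to slow comodulation of the pair.
#'
#' @param ccg a [compute_ccg()] result
#' @param kernel_sd_ms Gaussian kernel s.d., ms (default 10)
#' @param hollow_fraction central-bin hollowing in `[0, 1]` (default 0.6)
#' @param flank_ms |lag| range of the flank bins used for the z-score, ms
#'   (default `c(20, 50)`)
#' @return the ccg with added fields `predictor`, `p_deficit` (NA where the
#'   predictor is 0) and `z`
#' @export
stark_poisson_test <- function(ccg, kernel_sd_ms = 10, hollow_fraction = 0.6,
                               flank_ms = c(20, 50)) {
  stopifnot(inherits(ccg, "ccg"))
  sd_bins <- kernel_sd_ms / (ccg$bin_width * 1000)
  half <- min(ceiling(3 * sd_bins), length(ccg$counts) - 1L)
  w <- stats::dnorm(seq(-half, half), sd = sd_bins)
  w[half + 1L] <- w[half + 1L] * (1 - hollow_fraction)
  w <- w / sum(w)
  obs <- ccg$counts
  n <- length(obs)
  pad_idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - rev(seq_len(half)))
  padded <- obs[pad_idx]
  pred <- vapply(seq_len(n), function(b) {
    sum(padded[b:(b + 2L * half)] * w)
  }, 0)
  p <- stats::ppois(obs - 1, pred) + 0.5 * stats::dpois(obs, pred)
  p[pred == 0] <- NA_real_
  flank <- abs(ccg$lags) * 1000 >= flank_ms[1] &
    abs(ccg$lags) * 1000 <= flank_ms[2]
  fm <- mean(obs[flank])
  fs <- stats::sd(obs[flank])
  z <- (obs - fm) / fs
  ccg$predictor <- pred
  ccg$p_deficit <- p
  ccg$z <- z
  ccg
}

#' Screen neuron pairs for putative monosynaptic inhibition
#'
#' Applies the compound acceptance rule to tested cross-correlograms: a pair
#' is accepted as a putative inhibitory connection when the minimum deficit
#' p-value within the test lag band (1-2.5 ms) is below `p_threshold`, the
#' trough (most negative z over positive lags) lies within `trough_max_ms`,
#' and the trough z is below `z_threshold`.
#'
#' @param ccgs list of [stark_poisson_test()] results
#' @param p_threshold deficit p threshold (default 0.02)
#' @param band_ms test lag band, ms (default `c(1, 2.5)`)
#' @param trough_max_ms maximum trough lag, ms (default 2.5)
#' @param z_threshold maximum trough z (default -10)
#' @return data.frame with one row per pair: `pre_id`, `post_id`, `p_min`,
#'   `trough_lag_ms`, `trough_z`, `accepted`
#' @export
screen_connections <- function(ccgs, p_threshold = 0.02,
                               band_ms = c(1, 2.5), trough_max_ms = 2.5,
                               z_threshold = -10) {
  if (inherits(ccgs, "ccg")) ccgs <- list(ccgs)
  rows <- lapply(ccgs, function(cc) {
    if (is.null(cc$p_deficit)) {
      stop("run stark_poisson_test() before screening")
    }
    lag_ms <- cc$lags * 1000
    in_band <- lag_ms >= band_ms[1] & lag_ms <= band_ms[2]
    p_min <- suppressWarnings(min(cc$p_deficit[in_band], na.rm = TRUE))
    pos <- lag_ms > 0
    trough_i <- which(pos)[which.min(cc$z[pos])]
    trough_lag <- lag_ms[trough_i]
    trough_z <- cc$z[trough_i]
    data.frame(pre_id = cc$pre_id, post_id = cc$post_id, p_min = p_min,
               trough_lag_ms = trough_lag, trough_z = trough_z,
               accepted = is.finite(p_min) && p_min < p_threshold &&
                 trough_lag <= trough_max_ms && trough_z < z_threshold)
  })
  do.call(rbind, rows)
}
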