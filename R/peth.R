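#' Discrete Gaussian smoothing kernel
#'
#' Gaussian kernel evaluated on the bin grid, truncated to a total support of
#' `support_s` seconds and renormalized to unit mass. By default sigma is
#' given in bins (sigma 10 at 5 ms bins = 50 ms) with 100 ms support, i.e.
#' truncation at one sigma; `sigma_units = "s"` interprets sigma in seconds
#' instead.
#'
#' @param bin_width bin width, seconds
#' @param sigma kernel sigma, in bins or seconds per `sigma_units`
#' @param support_s total kernel support, seconds
#' @param sigma_units `"bins"` or `"s"`
#' @return numeric kernel of odd length summing to 1
#' @export
gaussian_kernel <- function(bin_width, sigma = 10, support_s = 0.1,
                            sigma_units = c("bins", "s")) {
  sigma_units <- match.arg(sigma_units)
  sd_bins <- if (sigma_units == "bins") sigma else sigma / bin_width
  half <- floor(support_s / bin_width / 2)
  w <- stats::dnorm(seq(-half, half), sd = sd_bins)
  w / sum(w)
}

# Convolve each row with a symmetric kernel. Kernel mass falling off either
# edge is folded back (reflecting boundary), so the per-row total — and hence
# the per-trial mean rate — is conserved exactly.
smooth_rows <- function(m, kernel) {
  half <- (length(kernel) - 1L) / 2L
  nb <- ncol(m)
  if (half == 0L || nb == 1L) return(m)
  if (half > nb) stop("kernel support exceeds the analysis window")
  s <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    targets <- j + seq(-half, half)
    w <- kernel
    # fold out-of-range mass back inside
    low <- targets < 1L
    targets[low] <- 1L - targets[low]
    high <- targets > nb
    targets[high] <- 2L * nb + 1L - targets[high]
    for (k in seq_along(targets)) {
      s[targets[k], j] <- s[targets[k], j] + w[k]
    }
  }
  m %*% t(s)
}

#' Peri-event time histogram (PETH)
#'
#' Bins a neuron's firing rate around a set of alignment events. Bin `b`
#' covers `[t_pre + b*bin_width, t_pre + (b+1)*bin_width)` relative to the
#' event; rates are counts divided by bin width, per trial. Optional Gaussian
#' smoothing (see [gaussian_kernel()]) is applied along time within each
#' trial. Events whose window extends beyond the session span are dropped
#' with a warning.
#'
#' @param train a [spike_train()]
#' @param events numeric vector of alignment times, seconds
#' @param bin_width bin width, seconds (default 0.05 for single-neuron
#'   displays; population analyses use 0.005 with smoothing)
#' @param window length-2 numeric `[t_pre, t_post]` relative to the event
#' @param smoothing NULL for none, or a list with elements `sigma`,
#'   `support_s`, `sigma_units` (defaults 10 bins, 0.1 s)
#' @return object of class `peth`: list with `rate` (trials x bins matrix,
#'   Hz), `bin_starts` (relative seconds), `bin_width`, `window`, `events`
#'   (the events used), `smoothing`
#' @export
compute_peth <- function(train, events, bin_width = 0.05, window = c(-2, 2),
                         smoothing = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  stopifnot(inherits(train, "spike_train"))
  ok <- events + window[1] >= train$span[1] &
    events + window[2] <= train$span[2]
  if (any(!ok)) {
    warning(sum(!ok), " event(s) clipped by the session edge were dropped")
    events <- events[ok]
  }
  n_bins <- round((window[2] - window[1]) / bin_width)
  bin_starts <- window[1] + (seq_len(n_bins) - 1L) * bin_width
  starts <- rep(events, each = n_bins) + bin_starts
  counts <- count_in_windows(train$times, starts, starts + bin_width)
  rate <- matrix(counts / bin_width, nrow = length(events),
                 ncol = n_bins, byrow = TRUE)
  if (!is.null(smoothing)) {
    sm <- utils::modifyList(list(sigma = 10, support_s = 0.1,
                                 sigma_units = "bins"),
                            if (is.list(smoothing)) smoothing else list())
    k <- gaussian_kernel(bin_width, sm$sigma, sm$support_s, sm$sigma_units)
    rate <- smooth_rows(rate, k)
    smoothing <- sm
  }
  structure(list(rate = rate, bin_starts = bin_starts, bin_width = bin_width,
                 window = window, events = events, smoothing = smoothing,
                 neuron_id = train$neuron_id),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("PETH (neuron %s): %d trials x %d bins of %.0f ms, window [%g, %g] s%s\n",
              format(x$neuron_id), nrow(x$rate), ncol(x$rate),
              x$bin_width * 1000, x$window[1], x$window[2],
              if (is.null(x$smoothing)) "" else ", Gaussian-smoothed"))
  invisible(x)
}

#' @export
plot.peth <- function(x, ...) {
  m <- colMeans(x$rate)
  plot(x$bin_starts + x$bin_width / 2, m, type = "l",
       xlab = "time from event (s)", ylab = "rate (Hz)", ...)
  invisible(x)
}

#' z-score condition-average rates with concatenated statistics
#'
#' Implements the concatenation convention used for population displays and
#' the trial-type divergence analysis: for each neuron, the mean and s.d.
#' are computed over the concatenation of its condition-average rate
#' vectors (all trial types considered, e.g. the 2 s windows surrounding
#' retraction start), and every condition is z-transformed with those shared
#' constants. The s.d. is the population (divide-by-n) s.d. Zero-variance
#' neurons get z = 0 everywhere and are flagged.
#'
#' @param cond_means list of neurons x bins matrices, one per condition, all
#'   on the same bin grid (a single matrix is accepted)
#' @return object of class `zscored_rate`: list with `z` (list of z-scored
#'   matrices), `mean`, `sd` (per neuron), `flagged` (zero-variance neurons),
#'   `n_conditions`
#' @export
zscore_concatenated <- function(cond_means) {
  if (is.matrix(cond_means)) cond_means <- list(cond_means)
  nb <- vapply(cond_means, ncol, 0L)
  nn <- vapply(cond_means, nrow, 0L)
  if (length(unique(nn)) != 1L) stop("all conditions must share the neuron set")
  cat_mat <- do.call(cbind, cond_means)
  mu <- rowMeans(cat_mat)
  sd_ <- apply(cat_mat, 1, pop_sd)
  flagged <- sd_ == 0 | is.na(sd_)
  denom <- ifelse(flagged, 1, sd_)
  z <- lapply(cond_means, function(m) {
    zz <- (m - mu) / denom
    zz[flagged, ] <- 0
    zz
  })
  structure(list(z = z, mean = mu, sd = sd_, flagged = which(flagged),
                 n_conditions = length(cond_means), n_bins = nb),
            class = "zscored_rate")
}

#' Invert a concatenated z-transform
#'
#' Reconstructs the original rates from a [zscore_concatenated()] result
#' using its stored constants; a round trip reproduces the input to
#' floating-point precision.
#'
#' @param zs a `zscored_rate`
#' @return list of back-transformed matrices
#' @export
unzscore <- function(zs) {
  denom <- zs$sd
  denom[zs$flagged] <- 1
  lapply(zs$z, function(m) m * denom + zs$mean)
}
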