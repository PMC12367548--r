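#' Laser-evoked population response, z-scored against control trials
#'
#' For each neuron, the cue-aligned average firing rate is computed
#' separately for laser and control trials; both traces are z-scored with
#' the mean and s.d. of the neuron's control trace, and the
#' control-subtracted trace (laser z minus control z) is averaged over
#' neurons. Zero-variance control neurons are flagged and excluded from the
#' averages. By construction the control average of the control-subtracted
#' trace is ~0 and all quantities are invariant to per-neuron affine rate
#' transforms.
#'
#' @param trains list of [spike_train()]
#' @param trials opto trial table (`cue_time_s`, `laser`)
#' @param bin_width bin width, s (default 0.02)
#' @param window cue-aligned window, s (default `c(-0.5, 1.5)`)
#' @return object of class `laser_response`: list with `bin_starts`,
#'   `pop_mean`, `pop_sem` (control-subtracted), `z_laser`, `z_control`
#'   (neurons x bins), `excluded` (neuron indices), `n_laser`, `n_control`
#' @export
laser_evoked_response <- function(trains, trials, bin_width = 0.02,
                                  window = c(-0.5, 1.5)) {
  cue_l <- trials$cue_time_s[trials$laser]
  cue_c <- trials$cue_time_s[!trials$laser]
  if (length(cue_l) < 10L || length(cue_c) < 10L) {
    stop("at least 10 laser and 10 control trials are required")
  }
  nb <- round(diff(window) / bin_width)
  curves <- lapply(trains, function(tr) {
    list(laser = colMeans(compute_peth(tr, cue_l, bin_width, window)$rate),
         control = colMeans(compute_peth(tr, cue_c, bin_width, window)$rate))
  })
  mu <- vapply(curves, function(cv) mean(cv$control), 0)
  sdv <- vapply(curves, function(cv) pop_sd(cv$control), 0)
  excluded <- which(sdv == 0 | !is.finite(sdv))
  keep <- setdiff(seq_along(trains), excluded)
  if (!length(keep)) stop("all neurons have zero-variance control traces")
  z_laser <- t(vapply(seq_along(trains), function(i) {
    if (i %in% excluded) rep(NA_real_, nb)
    else (curves[[i]]$laser - mu[i]) / sdv[i]
  }, numeric(nb)))
  z_control <- t(vapply(seq_along(trains), function(i) {
    if (i %in% excluded) rep(NA_real_, nb)
    else (curves[[i]]$control - mu[i]) / sdv[i]
  }, numeric(nb)))
  diff_mat <- z_laser[keep, , drop = FALSE] - z_control[keep, , drop = FALSE]
  structure(list(
    bin_starts = window[1] + (seq_len(nb) - 1L) * bin_width,
    bin_width = bin_width,
    pop_mean = colMeans(diff_mat),
    pop_sem = apply(diff_mat, 2, stats::sd) / sqrt(length(keep)),
    z_laser = z_laser, z_control = z_control, excluded = excluded,
    n_laser = length(cue_l), n_control = length(cue_c)),
    class = "laser_response")
}

#' Effective optogenetic activation duration
#'
#' Total time after cue offset during which the laser-evoked population
#' response exceeds the control by at least one control s.d. (the s.d. of
#' the population-average control trace over the same post-cue interval).
#' All supra-threshold bins are summed, whether contiguous or not; returns
#' 0 when the threshold is never exceeded.
#'
#' @param response a [laser_evoked_response()] result
#' @param cue_offset time of cue offset relative to cue onset, s (default
#'   0.1)
#' @return effective duration, seconds
#' @export
effective_activation_duration <- function(response, cue_offset = 0.1) {
  stopifnot(inherits(response, "laser_response"))
  post <- response$bin_starts >= cue_offset - 1e-9
  keep <- setdiff(seq_len(nrow(response$z_control)), response$excluded)
  pop_control <- colMeans(response$z_control[keep, , drop = FALSE])
  sd_c <- stats::sd(pop_control[post])
  supra <- response$pop_mean[post] >= sd_c
  sum(supra) * response$bin_width
}

#' Press-latency statistics for laser versus control trials
#'
#' Cumulative latency distributions per condition over responded trials, a
#' two-sample Kolmogorov-Smirnov test between them, the control-normalized
#' response rate (laser responded fraction over control responded
#' fraction), and the control-subtracted press rate in 200 ms bins after
#' the cue.
#'
#' @param trials opto trial table (`cue_time_s`, `laser`, `latency_s`,
#'   `responded`)
#' @param rate_bin press-rate bin width, s (default 0.2)
#' @param rate_window press-rate window after cue, s (default `c(0, 2)`)
#' @return list with `median_latency` (per condition), `median_diff`
#'   (laser - control), `ks` (statistic, p), `response_rate` (fractions and
#'   laser/control ratio; ratio NA when no control response), `cdf`
#'   (per-condition data.frames) and `press_rate` (per-bin, with
#'   control-subtracted column)
#' @export
press_latency_stats <- function(trials, rate_bin = 0.2,
                                rate_window = c(0, 2)) {
  lat_l <- trials$latency_s[trials$laser & trials$responded]
  lat_c <- trials$latency_s[!trials$laser & trials$responded]
  frac_l <- mean(trials$responded[trials$laser])
  frac_c <- mean(trials$responded[!trials$laser])
  ks <- if (length(lat_l) >= 1L && length(lat_c) >= 1L) {
    kt <- suppressWarnings(stats::ks.test(lat_l, lat_c))
    list(statistic = unname(kt$statistic), p = kt$p.value)
  } else list(statistic = NA_real_, p = NA_real_)
  cdf <- function(x) {
    x <- sort(x)
    data.frame(latency = x, cum_prob = seq_along(x) / length(x))
  }
  edges <- seq(rate_window[1], rate_window[2], by = rate_bin)
  rate_of <- function(cond) {
    lat <- trials$latency_s[trials$laser == cond & trials$responded]
    n_tr <- sum(trials$laser == cond)
    counts <- graphics::hist(lat[lat >= rate_window[1] & lat < rate_window[2]],
                             breaks = edges, plot = FALSE)$counts
    counts / n_tr / rate_bin
  }
  pr_l <- rate_of(TRUE); pr_c <- rate_of(FALSE)
  list(
    median_latency = c(laser = stats::median(lat_l),
                       control = stats::median(lat_c)),
    median_diff = stats::median(lat_l) - stats::median(lat_c),
    ks = ks,
    response_rate = c(laser = frac_l, control = frac_c,
                      ratio = if (frac_c > 0) frac_l / frac_c else NA_real_),
    cdf = list(laser = cdf(lat_l), control = cdf(lat_c)),
    press_rate = data.frame(bin_start = edges[-length(edges)],
                            laser_hz = pr_l, control_hz = pr_c,
                            control_subtracted = pr_l - pr_c)
  )
}

#' Regression of press-latency increase on effective activation duration
#'
#' Ordinary least squares of the per-mouse median latency increase (laser
#' minus control) on the per-mouse effective activation duration, with a
#' one-sided Wald test for a positive slope.
#'
#' @param durations per-mouse effective activation durations, s
#' @param latency_shifts per-mouse median latency differences, s
#' @return list with `slope`, `intercept`, `r_squared` (Pearson R^2),
#'   `p_one_sided`, `n`
#' @export
duration_latency_regression <- function(durations, latency_shifts) {
  if (length(durations) < 3L || length(latency_shifts) != length(durations)) {
    stop("at least 3 mice with matched durations and latency shifts needed")
  }
  fit <- stats::lm(latency_shifts ~ durations)
  sm <- summary(fit)
  tval <- sm$coefficients[2, "t value"]
  p1 <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(durations, latency_shifts)^2,
       p_one_sided = unname(p1),
       n = length(durations))
}
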