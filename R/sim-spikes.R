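# Piecewise-constant rate function: merge possibly overlapping gain
# intervals into disjoint segments; gain products multiply where intervals
# overlap. Returns breakpoints and the rate within each segment.
build_rate_segments <- function(baseline, intervals, span) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(list(breaks = span, rates = baseline))
  }
  if (any(intervals$gain < 0)) stop("rate gain must be >= 0")
  if (any(intervals$start < span[1]) || any(intervals$stop > span[2])) {
    stop("modulation window extends past the session span")
  }
  brk <- sort(unique(c(span, intervals$start, intervals$stop)))
  mids <- brk[-length(brk)] + diff(brk) / 2
  rates <- vapply(mids, function(m) {
    g <- intervals$gain[intervals$start <= m & intervals$stop > m]
    baseline * prod(g)
  }, 0)
  list(breaks = brk, rates = rates)
}

rate_at <- function(seg, t) {
  idx <- findInterval(t, seg$breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(seg$rates)] <- length(seg$rates)
  seg$rates[idx]
}

#' Simulate one spike train with a piecewise-constant rate
#'
#' Realizes an inhomogeneous point process whose rate is `baseline`
#' multiplied by the gain of every interval covering the current time
#' (gains of overlapping intervals multiply). Two ISI models are available:
#'
#' * `"poisson"`: Lewis-Shedler thinning of a dominating homogeneous Poisson
#'   process at `baseline * max(gain product)` — exact and fully seeded.
#' * `"gamma"`: a gamma-ISI renewal process (shape `gamma_shape`, unit mean)
#'   generated in operational time and mapped back through the inverse of the
#'   integrated rate (time rescaling), mimicking the regularity of tonic SNr
#'   firing. Thinning is not exact for renewal processes, which is why the
#'   rescaling construction is used here.
#'
#' @param baseline baseline rate, Hz (> 0)
#' @param intervals data.frame with columns `start`, `stop`, `gain`
#'   (seconds, unitless gain >= 0); may be NULL or empty
#' @param span session `[start, stop)` seconds
#' @param seed integer seed
#' @param isi_model `"poisson"` or `"gamma"`
#' @param gamma_shape gamma shape parameter
#' @param neuron_id id stored on the returned train
#' @return a [spike_train()]
#' @export
simulate_rate_train <- function(baseline, intervals = NULL, span = c(0, 300),
                                seed = 1L, isi_model = "poisson",
                                gamma_shape = 4, neuron_id = 1L) {
  stopifnot(baseline > 0)
  seg <- build_rate_segments(baseline, intervals, span)
  set.seed(seed)
  if (isi_model == "poisson") {
    lambda_max <- max(seg$rates, baseline)
    if (lambda_max <= 0) {
      return(spike_train(numeric(), span, neuron_id))
    }
    n_expect <- lambda_max * diff(span)
    times <- span[1] + cumsum(stats::rexp(ceiling(n_expect + 6 * sqrt(n_expect) + 20),
                                          lambda_max))
    while (length(times) && times[length(times)] < span[2]) {
      times <- c(times, times[length(times)] +
                   cumsum(stats::rexp(200, lambda_max)))
    }
    times <- times[times < span[2]]
    keep <- stats::runif(length(times)) < rate_at(seg, times) / lambda_max
    spikes <- times[keep]
  } else if (isi_model == "gamma") {
    durs <- diff(seg$breaks)
    cum <- c(0, cumsum(seg$rates * durs))
    total <- cum[length(cum)]
    n_expect <- total
    ops <- cumsum(stats::rgamma(ceiling(n_expect + 6 * sqrt(n_expect) + 20),
                                shape = gamma_shape, rate = gamma_shape))
    while (length(ops) && ops[length(ops)] < total) {
      ops <- c(ops, ops[length(ops)] +
                 cumsum(stats::rgamma(200, shape = gamma_shape,
                                      rate = gamma_shape)))
    }
    ops <- ops[ops < total]
    idx <- findInterval(ops, cum, rightmost.closed = TRUE)
    spikes <- seg$breaks[idx] + (ops - cum[idx]) / seg$rates[idx]
  } else {
    stop("unknown isi_model: ", isi_model)
  }
  spike_train(spikes, span, neuron_id)
}

#' Simulate a population of task-modulated neurons
#'
#' Each neuron fires tonically at a baseline rate drawn from the configured
#' range, multiplied by its profile's gain inside every trial's task window
#' (windows 1-9 built from the trial event times). The true interval of every
#' injected gain change is recorded as ground truth.
#'
#' @param config a [sim_config()]
#' @param profiles list of [modulation_profile()]; one per neuron, unique ids
#' @param trials trial table from [simulate_behavior_session()]
#' @return list with `trains` (list of [spike_train()]), `baselines` (Hz) and
#'   `truth` (per-neuron modulated intervals)
#' @export
simulate_population <- function(config, profiles, trials) {
  ids <- vapply(profiles, function(p) p$neuron_id, 0L)
  if (anyDuplicated(ids)) stop("profile neuron_ids must be unique")
  win <- task_windows(trials)
  span <- c(0, config$session_duration)
  set.seed(derive_seed(config$seed, "population-baselines"))
  baselines <- stats::runif(length(profiles),
                            config$baseline_rate_range[1],
                            config$baseline_rate_range[2])
  trains <- vector("list", length(profiles))
  truth <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    mod_w <- which(p$gains != 1)
    iv <- win[win$window_id %in% mod_w & !is.na(win$start), , drop = FALSE]
    if (nrow(iv)) {
      iv$gain <- p$gains[iv$window_id]
      iv <- iv[, c("start", "stop", "gain")]
    } else {
      iv <- NULL
    }
    trains[[i]] <- simulate_rate_train(
      baselines[i], iv, span,
      seed = derive_seed(config$seed, paste0("neuron-", p$neuron_id)),
      isi_model = config$isi_model, gamma_shape = config$gamma_shape,
      neuron_id = p$neuron_id)
    truth[[i]] <- list(neuron_id = p$neuron_id, gains = p$gains,
                       baseline = baselines[i], intervals = iv)
  }
  list(trains = trains, baselines = baselines, truth = truth)
}

#' Simulate an inhibitory-coupled neuron pair
#'
#' The presynaptic train is homogeneous Poisson. The postsynaptic rate is its
#' baseline multiplied by `1 - strength` during
#' `[delay, delay + duration]` after every presynaptic spike, realized by
#' thinning a homogeneous candidate train. With strength 0 the trains are
#' independent.
#'
#' @param spec a [coupling_spec()]
#' @param rates length-2 numeric, Hz: pre and post baseline rates
#' @param duration session length, seconds
#' @param seed integer seed
#' @return list of two [spike_train()] (`pre`, `post`)
#' @export
simulate_connected_pair <- function(spec, rates, duration, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (any(rates < 0)) stop("rates must be non-negative")
  if (rates[1] * duration < 10000) {
    warning("expected presynaptic spike count below 10,000; ",
            "cross-correlogram statistics will be noisy")
  }
  span <- c(0, duration)
  pre <- simulate_rate_train(rates[1], NULL, span,
                             seed = derive_seed(seed, "pre"),
                             neuron_id = spec$pre_id)
  set.seed(derive_seed(seed, "post"))
  n_expect <- rates[2] * duration
  cand <- cumsum(stats::rexp(ceiling(n_expect + 6 * sqrt(n_expect) + 20),
                             rates[2]))
  while (length(cand) && cand[length(cand)] < duration) {
    cand <- c(cand, cand[length(cand)] + cumsum(stats::rexp(200, rates[2])))
  }
  cand <- cand[cand < duration]
  # candidate is suppressed when any pre spike lies in
  # [t - delay - dur, t - delay]
  lo <- cand - (spec$delay_ms + spec$duration_ms) / 1000
  hi <- cand - spec$delay_ms / 1000
  suppressed <- (findInterval(hi, pre$times) -
                   findInterval(lo, pre$times, left.open = TRUE)) > 0
  u <- stats::runif(length(cand))
  keep <- !suppressed | u < (1 - spec$strength)
  post <- spike_train(cand[keep], span, spec$post_id)
  list(pre = pre, post = post)
}
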