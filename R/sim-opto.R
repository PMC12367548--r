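#' Simulate a cued lever-press session with optogenetic perturbation
#'
#' Generates the trial structure of the cued lever task — 2-5 s uniform
#' intertrial interval, 100 ms visual cue, 1.5 s response window — with the
#' laser on a configurable fraction of randomly chosen trials. Press
#' latencies (press minus cue onset) are gamma-distributed past the cue; on
#' laser trials they are shifted by `latency_shift`, and presses pushed past
#' the response window become no-response trials. Simulated neurons fire
#' tonically; on laser trials their rate is multiplied by `activation_gain`
#' for `activation_duration` starting at cue offset, and a configurable
#' subset of press-pausing neurons multiplies its rate by `press_pause_gain`
#' in the 200 ms around every press, on control and laser trials alike.
#'
#' @param spec an [opto_effect_spec()]
#' @param config a [sim_config()] (uses `seed`, `n_opto_trials`,
#'   `n_neurons`, `baseline_rate_range`, `isi_model`, `gamma_shape`)
#' @param press_pause_frac fraction of neurons that pause at the press
#' @param press_pause_gain rate gain of pausing neurons around the press
#' @param cue_gain_range range of the multiplicative cue-evoked gain drawn
#'   per neuron; SNr units respond to the visual cue on every trial, which
#'   gives the control traces the real structure the control-s.d. criterion
#'   of the activation-duration estimate relies on
#' @param cue_response_duration duration of the cue-evoked response, s
#' @param response_window response window, s (default 1.5)
#' @param cue_duration cue duration, s (default 0.1)
#' @param respond_prob baseline probability that a trial has any press
#' @return list with `trials` (the opto trial table), `trains` (list of
#'   [spike_train()]) and `truth` (spec, per-neuron baselines and pausing
#'   flags)
#' @export
simulate_opto_session <- function(spec, config, press_pause_frac = 0.3,
                                  press_pause_gain = 0.2,
                                  cue_gain_range = c(1.3, 2),
                                  cue_response_duration = 0.15,
                                  response_window = 1.5, cue_duration = 0.1,
                                  respond_prob = 0.95) {
  stopifnot(inherits(spec, "opto_effect_spec"), inherits(config, "sim_config"))
  if (spec$latency_shift < 0) stop("latency_shift must be >= 0")
  n <- config$n_opto_trials
  set.seed(derive_seed(config$seed, "opto-behavior"))
  iti <- stats::runif(n, 2, 5)
  block <- cue_duration + response_window + 0.5 # cue + response + consume
  cue <- 2 + cumsum(iti) - iti[1] + (seq_len(n) - 1L) * block
  laser <- rep(FALSE, n)
  laser[sample.int(n, round(spec$laser_fraction * n))] <- TRUE
  latency <- cue_duration + stats::rgamma(n, shape = 6, rate = 12)
  latency[laser] <- latency[laser] + spec$latency_shift
  responded <- stats::runif(n) < respond_prob & latency <= response_window
  latency[!responded] <- NA_real_
  press <- cue + latency
  trials <- data.frame(
    trial_id = seq_len(n), cue_time_s = cue, laser = laser,
    press_time_s = press,
    reward_time_s = ifelse(responded, press + 0.05, NA_real_),
    latency_s = latency, responded = responded)
  span <- c(0, max(cue) + 5)

  set.seed(derive_seed(config$seed, "opto-neurons"))
  baselines <- stats::runif(config$n_neurons,
                            config$baseline_rate_range[1],
                            config$baseline_rate_range[2])
  pauser <- stats::runif(config$n_neurons) < press_pause_frac
  cue_gain <- stats::runif(config$n_neurons, cue_gain_range[1],
                           cue_gain_range[2])
  act_iv <- if (spec$activation_duration > 0 && any(laser)) {
    data.frame(start = cue[laser] + cue_duration,
               stop = cue[laser] + cue_duration + spec$activation_duration,
               gain = spec$activation_gain)
  } else NULL
  press_iv <- if (any(responded)) {
    data.frame(start = press[responded] - 0.1,
               stop = press[responded] + 0.1,
               gain = press_pause_gain)
  } else NULL
  trains <- lapply(seq_len(config$n_neurons), function(i) {
    iv <- rbind(act_iv,
                if (cue_response_duration > 0) {
                  data.frame(start = cue, stop = cue + cue_response_duration,
                             gain = cue_gain[i])
                })
    if (pauser[i]) iv <- rbind(iv, press_iv)
    simulate_rate_train(baselines[i], iv, span,
                        seed = derive_seed(config$seed,
                                           paste0("opto-neuron-", i)),
                        isi_model = config$isi_model,
                        gamma_shape = config$gamma_shape, neuron_id = i)
  })
  truth <- list(spec = spec, baselines = baselines, pauser = pauser,
                cue_gain = cue_gain, trials = trials,
                press_pause_gain = press_pause_gain)
  list(trials = trials, trains = trains, truth = truth)
}
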