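#' Configuration for a synthetic reaching session
#'
#' Collects all parameters of the synthetic behaviour and spike generators in
#' one validated object. Defaults emulate a head-fixed mouse pellet-reaching
#' session recorded at 100 frames/s with tonically active SNr-like units:
#' reach and retraction durations of a few hundred milliseconds, food handling
#' lasting seconds, repeated reaches 0.3-0.6 s apart, and baseline firing
#' rates between 5 and 100 Hz.
#'
#' @param seed integer; fully determines every generated quantity.
#' @param session_duration session length in seconds.
#' @param frame_rate tracking frame rate, frames/s.
#' @param n_neurons number of units simulated by default.
#' @param baseline_rate_range length-2 numeric, Hz; per-unit baseline rates
#'   are drawn uniformly from this range.
#' @param n_isolated,n_repeated_pairs,n_abbreviated,n_handled trial counts per
#'   type. A repeated pair counts as one unit of two reaches; handled trials
#'   carry handle/manipulation events.
#' @param event_timing list of timing-distribution parameters (seconds):
#'   `reach_duration_meanlog`/`_sdlog` (log-normal), `retract_duration_meanlog`
#'   /`_sdlog`, `handle_latency` (range after retraction stop),
#'   `handle_duration` (range), `mean_gap` (mean of the exponential inter-trial
#'   gap added to the 0.75 s isolation floor).
#' @param isi_model `"poisson"` for an inhomogeneous Poisson process or
#'   `"gamma"` for a more regular renewal process (shape `gamma_shape`),
#'   mimicking the regularity of tonic SNr firing.
#' @param gamma_shape gamma ISI shape when `isi_model = "gamma"`.
#' @param scale_cm_per_px pixel-to-centimetre scale of the bottom-view camera.
#' @param tracking_noise_sd s.d. of Gaussian tracking noise added to the hand
#'   coordinates, pixels.
#' @param reach_amplitude_range extension past the slit of complete reaches
#'   along the major movement axis, pixels (range).
#' @param n_opto_trials number of cued lever-task trials for opto sessions.
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       session_duration = 300,
                       frame_rate = 100,
                       n_neurons = 10L,
                       baseline_rate_range = c(5, 100),
                       n_isolated = 20L,
                       n_repeated_pairs = 0L,
                       n_abbreviated = 0L,
                       n_handled = 0L,
                       event_timing = list(),
                       isi_model = c("poisson", "gamma"),
                       gamma_shape = 4,
                       scale_cm_per_px = 0.02,
                       tracking_noise_sd = 0.5,
                       reach_amplitude_range = c(40, 80),
                       n_opto_trials = 200L) {
  isi_model <- match.arg(isi_model)
  timing <- utils::modifyList(list(
    reach_duration_meanlog   = log(0.30),
    reach_duration_sdlog     = 0.25,
    retract_duration_meanlog = log(0.20),
    retract_duration_sdlog   = 0.25,
    handle_latency           = c(0.15, 0.40),
    handle_duration          = c(1.0, 3.0),
    mean_gap                 = 1.0
  ), event_timing)
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    session_duration > 0, frame_rate > 0,
    length(baseline_rate_range) == 2L,
    baseline_rate_range[1] > 0,
    diff(baseline_rate_range) >= 0,
    n_isolated >= 0, n_repeated_pairs >= 0,
    n_abbreviated >= 0, n_handled >= 0,
    gamma_shape > 0, scale_cm_per_px > 0, tracking_noise_sd >= 0
  )
  structure(list(
    seed = as.integer(seed),
    session_duration = session_duration,
    frame_rate = frame_rate,
    n_neurons = as.integer(n_neurons),
    baseline_rate_range = baseline_rate_range,
    n_isolated = as.integer(n_isolated),
    n_repeated_pairs = as.integer(n_repeated_pairs),
    n_abbreviated = as.integer(n_abbreviated),
    n_handled = as.integer(n_handled),
    event_timing = timing,
    isi_model = isi_model,
    gamma_shape = gamma_shape,
    scale_cm_per_px = scale_cm_per_px,
    tracking_noise_sd = tracking_noise_sd,
    reach_amplitude_range = reach_amplitude_range,
    n_opto_trials = as.integer(n_opto_trials)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_tr <- x$n_isolated + 2L * x$n_repeated_pairs + x$n_abbreviated +
    x$n_handled
  cat("Synthetic session config:", x$session_duration, "s,",
      n_tr, "reaches,", x$n_neurons, "neurons,",
      x$isi_model, "ISIs, seed", x$seed, "\n")
  invisible(x)
}

#' Per-neuron task-window modulation profile
#'
#' Specifies the multiplicative rate gain a simulated neuron applies inside
#' each of the nine task windows. Gain 1 leaves the baseline untouched, gain
#' below 1 injects a firing pause (0 = complete pause), gain above 1 a firing
#' increase. Windows not named keep gain 1.
#'
#' @param neuron_id integer id
#' @param gains named numeric vector; names are window ids `"1"`..`"9"`,
#'   values are gains >= 0
#' @return object of class `modulation_profile`: numeric vector of 9 gains
#' @export
#' @examples
#' modulation_profile(1, c("2" = 0.2, "6" = 2.5)) # pause in reach, burst at handle
modulation_profile <- function(neuron_id, gains = numeric()) {
  g <- rep(1, 9)
  if (length(gains)) {
    idx <- as.integer(names(gains))
    if (anyNA(idx) || any(idx < 1L | idx > 9L)) {
      stop("gain names must be window ids 1..9")
    }
    if (any(gains < 0)) stop("window gains must be >= 0")
    g[idx] <- unname(gains)
  }
  structure(list(neuron_id = as.integer(neuron_id), gains = g),
            class = "modulation_profile")
}

#' Inhibitory coupling specification for a simulated neuron pair
#'
#' Describes fast pre-to-post suppression: after every presynaptic spike the
#' postsynaptic rate is multiplied by `1 - strength` for `duration_ms`,
#' beginning `delay_ms` after the spike — the signature of a putative
#' monosynaptic inhibitory connection at 1-2.5 ms latency.
#'
#' @param pre_id,post_id neuron ids
#' @param delay_ms synaptic delay, ms (>= 0)
#' @param duration_ms suppression duration, ms (> 0)
#' @param strength suppression strength in `[0, 1]`; 1 silences completely
#' @return object of class `coupling_spec`
#' @export
coupling_spec <- function(pre_id, post_id, delay_ms = 1, duration_ms = 1.5,
                          strength = 0.8) {
  stopifnot(delay_ms >= 0, duration_ms > 0,
            strength >= 0, strength <= 1)
  structure(list(pre_id = pre_id, post_id = post_id,
                 delay_ms = delay_ms, duration_ms = duration_ms,
                 strength = strength),
            class = "coupling_spec")
}

#' Optogenetic perturbation specification for a cued lever-task session
#'
#' @param mouse_id identifier
#' @param activation_duration seconds of elevated firing starting at cue
#'   offset on laser trials
#' @param activation_gain multiplicative rate gain during activation (> 1)
#' @param latency_shift seconds added to press latency on laser trials;
#'   presses pushed past the 1.5 s response window become no-response trials
#' @param laser_fraction fraction of trials with laser on
#' @return object of class `opto_effect_spec`
#' @export
opto_effect_spec <- function(mouse_id = 1L, activation_duration = 0.3,
                             activation_gain = 3, latency_shift = 0.4,
                             laser_fraction = 0.475) {
  if (latency_shift < 0) stop("latency_shift must be >= 0")
  stopifnot(laser_fraction >= 0, laser_fraction <= 1,
            activation_gain > 0, activation_duration >= 0)
  structure(list(mouse_id = mouse_id,
                 activation_duration = activation_duration,
                 activation_gain = activation_gain,
                 latency_shift = latency_shift,
                 laser_fraction = laser_fraction),
            class = "opto_effect_spec")
}
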