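# Reach kinematic model
# ---------------------
# Each reach is rendered from a piecewise velocity profile along the main
# reach axis, built so that every detected event time is identifiable to one
# frame under realistic tracking noise and zero-phase filtering:
#
#   backswing ramp/plateau (-60 px/s) -> steep ramp through 0 at reach start
#   -> +60 px/s shoulder -> raised-cosine velocity bell (peak set by the
#   required displacement) -> +60 shoulder -> steep ramp through 0 at
#   maximum extension (retraction start) -> mirrored retraction -> steep
#   ramp through 0 at retraction stop -> +60 rebound plateau -> ramp to 0.
#
# The velocity is locally antisymmetric around each event (a steep ramp
# through zero flanked by +/-60 px/s plateaus), so symmetric zero-phase
# filtering leaves the threshold-crossing times unchanged, and the hand
# speed is bell-shaped within each movement phase. The brief backswing and
# rebound are the postural loading/settling that bracket real reaches; they
# also keep the +/-1 px/s detection thresholds out of noise-dominated flat
# regions.

SWING_V <- 150     # shoulder/backswing speed, px/s
RAMP_HW <- 0.015   # event ramp half-width, s
SHOULDER <- 0.04   # constant-speed shoulder duration, s
EDGE <- RAMP_HW + SHOULDER  # 55 ms: bell starts this long after the event
SWING_T <- 0.085   # backswing/rebound total duration, s
SWING_DIP <- SWING_V *
  ((SWING_T - SHOULDER - RAMP_HW) / 2 + SHOULDER + RAMP_HW / 2) # 9.375 px

# Displacement from reach start to apex given the out-phase duration and the
# bell peak velocity: two half-ramps, two shoulders, one raised-cosine bell.
phase_peak_velocity <- function(duration, displacement) {
  l_bell <- duration - 2 * EDGE
  fixed <- SWING_V * (RAMP_HW / 2) * 2 + SWING_V * SHOULDER * 2
  SWING_V + 2 * (displacement - fixed - SWING_V * l_bell) / l_bell
}

# Integral of the out-phase velocity from the event at t = 0 (reach start or,
# mirrored, retraction start) to t in [0, duration].
phase_displacement <- function(t, duration, vp) {
  l_bell <- duration - 2 * EDGE
  ramp_slope <- SWING_V / RAMP_HW
  f_ramp <- SWING_V * RAMP_HW / 2            # area of the half ramp
  f_shoulder <- SWING_V * SHOULDER
  bell_int <- function(tau) {                # from bell start, tau in [0, l]
    s <- tau / l_bell
    SWING_V * tau + (vp - SWING_V) * l_bell * (s / 2 - sin(2 * pi * s) /
                                                 (4 * pi))
  }
  ifelse(t <= RAMP_HW, ramp_slope * t^2 / 2,
  ifelse(t <= EDGE, f_ramp + SWING_V * (t - RAMP_HW),
  ifelse(t <= duration - EDGE, f_ramp + f_shoulder + bell_int(t - EDGE),
  ifelse(t <= duration - RAMP_HW,
         f_ramp + f_shoulder + bell_int(l_bell) + SWING_V * (t - duration +
                                                               EDGE),
         2 * f_shoulder + f_ramp + bell_int(l_bell) +
           (SWING_V * RAMP_HW / 2 -
              ramp_slope * (duration - t)^2 / 2)))))
}

# Backswing displacement at time t before the reach start (t in
# [-SWING_T, 0]); mirrored for the rebound after retraction stop.
swing_displacement <- function(t) {
  # ramp 0 -> -60 over 40 ms, plateau -60, half ramp back to 0 at t = 0
  t_ramp <- SWING_T - SHOULDER - RAMP_HW    # 0.03
  u <- t + SWING_T
  ramp_a <- SWING_V / t_ramp
  ifelse(u <= t_ramp, -ramp_a * u^2 / 2,
  ifelse(u <= SWING_T - RAMP_HW,
         -ramp_a * t_ramp^2 / 2 - SWING_V * (u - t_ramp),
         -SWING_DIP + (SWING_V / RAMP_HW) * (t)^2 / 2))
}

#' Simulate a pellet-reaching behaviour session with tracked kinematics
#'
#' Generates a bottom-view hand trajectory at the configured frame rate,
#' containing the requested numbers of isolated reaches, repeated-reach pairs
#' (second retraction start 0.3-0.6 s after the first), abbreviated reaches
#' (extension never exceeding the spatial abbreviation thresholds past the
#' slit) and handled reaches (followed by handle/manipulation events). Reach
#' kinematics follow a piecewise raised-cosine velocity model: bell-shaped
#' speed within each movement phase, a sharp grasp turnaround at maximum
#' extension, and a brief backswing/rebound bracketing each reach; white
#' Gaussian tracking noise is added to the hand coordinates. All true event
#' times are recorded as ground truth.
#'
#' Trials are packed sequentially with exponential gaps on top of a 0.75 s
#' isolation floor; packing that does not fit the session is re-drawn up to
#' 1,000 times before failing.
#'
#' @param config a [sim_config()]
#' @return an object of class `behavior_session`: list with `track` (the hand
#'   tracking data.frame), `trials` (true event times and labels) and `truth`
#'   (ground-truth bundle including the config)
#' @export
simulate_behavior_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "behavior"))
  fr <- config$frame_rate
  tm <- config$event_timing
  slit_x <- 100
  slit_y <- 100
  rest_dist <- stats::runif(1, 40, 55) # resting distance behind slit, px

  dur_min <- 2 * EDGE + 0.05           # shortest renderable phase (0.16 s)
  draw_dur <- function(meanlog, sdlog) {
    min(max(stats::rlnorm(1, meanlog, sdlog), dur_min + 0.01), 0.45)
  }

  types <- c(rep("isolated", config$n_isolated),
             rep("pair", config$n_repeated_pairs),
             rep("abbreviated", config$n_abbreviated),
             rep("handled", config$n_handled))
  if (length(types) == 0L) stop("no trials requested")
  types <- sample(types)

  draw_reach <- function(abbreviated = FALSE, reach_dur = NULL,
                         retract_dur = NULL) {
    rd <- reach_dur %||% draw_dur(tm$reach_duration_meanlog,
                                  tm$reach_duration_sdlog)
    td <- retract_dur %||% draw_dur(tm$retract_duration_meanlog,
                                    tm$retract_duration_sdlog)
    if (abbreviated) {
      # abbreviated pokes are brief; also keeps the bell peak above the
      # shoulder speed at their small amplitude
      rd <- min(rd, 0.3); td <- min(td, 0.3)
      a_past <- stats::runif(1, 5, 18)   # <= 0.45 cm at 0.02 cm/px
      minor <- stats::runif(1, -3, 3)    # <= 0.25 cm
    } else {
      a_past <- stats::runif(1, config$reach_amplitude_range[1],
                             config$reach_amplitude_range[2])
      minor <- stats::runif(1, -8, 8)
    }
    list(rd = rd, td = td, a_past = a_past, minor = minor)
  }

  # -- pack trial units sequentially; retry on session overflow ------------
  min_within_gap <- 2 * SWING_T + 0.02
  for (attempt in seq_len(1000L)) {
    cursor <- 1.0
    rows <- list()
    pair_id <- 0L
    for (ty in types) {
      gap <- 0.75 + stats::rexp(1, 1 / tm$mean_gap)
      if (ty == "pair") {
        pair_id <- pair_id + 1L
        for (retry in seq_len(1000L)) {
          k1 <- draw_reach(retract_dur = stats::runif(1, dur_min + 0.01,
                                                      0.18))
          k2 <- draw_reach(reach_dur = stats::runif(1, dur_min + 0.01, 0.2))
          delta <- stats::runif(1, 0.32, 0.58)
          within_gap <- delta - k1$td - k2$rd
          if (within_gap >= min_within_gap) break
          if (retry == 1000L) stop("cannot satisfy repeated-pair timing")
        }
        rs1 <- cursor + gap
        row1 <- c(k1, list(reach_start = rs1, type = "repeated",
                           pair = pair_id))
        rs2 <- rs1 + k1$rd + k1$td + within_gap
        row2 <- c(k2, list(reach_start = rs2, type = "repeated",
                           pair = pair_id))
        rows <- c(rows, list(row1, row2))
        cursor <- rs2 + k2$rd + k2$td
      } else {
        k <- draw_reach(abbreviated = ty == "abbreviated")
        rs <- cursor + gap
        row <- c(k, list(reach_start = rs, type = ty, pair = NA_integer_))
        if (ty == "handled") {
          row$handle_start <- rs + k$rd + k$td +
            stats::runif(1, tm$handle_latency[1], tm$handle_latency[2])
          row$manipulation_start <- row$handle_start + stats::runif(1, 0.1, 0.3)
          row$manipulation_stop <- row$manipulation_start +
            stats::runif(1, tm$handle_duration[1], tm$handle_duration[2])
          cursor <- row$manipulation_stop + 0.05
        } else {
          cursor <- rs + k$rd + k$td
        }
        rows <- c(rows, list(row))
      }
    }
    if (cursor + 1.0 <= config$session_duration) break
    if (attempt == 1000L) {
      stop("cannot pack ", length(types), " trial units into ",
           config$session_duration,
           " s with the 0.75 s isolation constraint; ",
           "increase session_duration or reduce trial counts")
    }
  }

  # -- assemble trial table -----------------------------------------------
  n_tr <- length(rows)
  trials <- data.frame(
    trial_id = seq_len(n_tr),
    trial_type = vapply(rows, function(r) r$type, ""),
    reach_start = vapply(rows, function(r) r$reach_start, 0),
    slit_cross = NA_real_, retract_start = NA_real_, retract_stop = NA_real_,
    handle_start = vapply(rows, function(r) r$handle_start %||% NA_real_, 0),
    manipulation_start =
      vapply(rows, function(r) r$manipulation_start %||% NA_real_, 0),
    manipulation_stop =
      vapply(rows, function(r) r$manipulation_stop %||% NA_real_, 0),
    repeated_pair_id = vapply(rows, function(r) r$pair %||% NA_integer_, 0L),
    ext_major_cm = NA_real_, ext_minor_cm = NA_real_,
    peak_speed_px_s = NA_real_
  )
  rd <- vapply(rows, function(r) r$rd, 0)
  td <- vapply(rows, function(r) r$td, 0)
  a_past <- vapply(rows, function(r) r$a_past, 0)
  minor <- vapply(rows, function(r) r$minor, 0)
  rest_x <- slit_x - rest_dist
  d_out <- rest_dist + SWING_DIP + a_past  # reach start (dipped) -> apex
  vp_out <- phase_peak_velocity(rd, d_out)
  vp_ret <- phase_peak_velocity(td, d_out)
  trials$retract_start <- trials$reach_start + rd
  trials$retract_stop <- trials$retract_start + td
  trials$ext_major_cm <- a_past * config$scale_cm_per_px
  trials$ext_minor_cm <- abs(minor) * config$scale_cm_per_px
  trials$peak_speed_px_s <- vp_out * sqrt(1 + (minor / d_out)^2)
  trials$handled <- trials$trial_type == "handled"
  # true slit crossing: out-phase displacement passes rest_dist + SWING_DIP
  trials$slit_cross <- vapply(seq_len(n_tr), function(i) {
    f <- function(t) {
      phase_displacement(t, rd[i], vp_out[i]) - (rest_dist + SWING_DIP)
    }
    trials$reach_start[i] +
      stats::uniroot(f, c(RAMP_HW, rd[i]), tol = 1e-10)$root
  }, 0)

  # -- render the trajectory ----------------------------------------------
  n_frames <- round(config$session_duration * fr)
  time_s <- (seq_len(n_frames) - 1) / fr
  hand_x <- rep(rest_x, n_frames)
  hand_y <- rep(slit_y, n_frames)
  for (i in seq_len(n_tr)) {
    t0 <- trials$reach_start[i]
    t1 <- trials$retract_start[i]
    t3 <- trials$retract_stop[i]
    x0 <- rest_x - SWING_DIP
    idx <- which(time_s >= t0 - SWING_T & time_s < t0)
    hand_x[idx] <- rest_x + swing_displacement(time_s[idx] - t0)
    idx <- which(time_s >= t0 & time_s < t1)
    dx <- phase_displacement(time_s[idx] - t0, rd[i], vp_out[i])
    hand_x[idx] <- x0 + dx
    hand_y[idx] <- slit_y + minor[i] * dx / d_out[i]
    idx <- which(time_s >= t1 & time_s < t3)
    dx <- phase_displacement(t3 - time_s[idx], td[i], vp_ret[i])
    hand_x[idx] <- x0 + dx
    hand_y[idx] <- slit_y + minor[i] * dx / d_out[i]
    idx <- which(time_s >= t3 & time_s < t3 + SWING_T)
    hand_x[idx] <- rest_x + swing_displacement(t3 - time_s[idx])
  }
  if (config$tracking_noise_sd > 0) {
    hand_x <- hand_x + stats::rnorm(n_frames, 0, config$tracking_noise_sd)
    hand_y <- hand_y + stats::rnorm(n_frames, 0, config$tracking_noise_sd)
  }
  track <- data.frame(
    frame = seq_len(n_frames) - 1L,
    time_s = time_s,
    hand_x_px = hand_x, hand_y_px = hand_y,
    slit_x_px = slit_x, slit_y_px = slit_y,
    likelihood = 1.0
  )
  class(track) <- c("hand_track", "data.frame")
  attr(track, "frame_rate") <- fr

  truth <- list(config = config, trials = trials, rest_dist_px = rest_dist,
                slit_px = c(slit_x, slit_y))
  structure(list(track = track, trials = trials, truth = truth),
            class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  cat("Synthetic behaviour session:", nrow(x$trials), "reaches over",
      round(max(x$track$time_s), 1), "s (",
      attr(x$track, "frame_rate"), "frames/s )\n")
  invisible(x)
}
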