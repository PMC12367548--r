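#' The nine task time windows of a reaching trial
#'
#' Builds, per trial, the labeled intervals tiling the movement sequence:
#' (1) reach start, -150 ms to +25 ms around the detected reach start;
#' (2) reach, reach start to retraction start; (3) reach distal, slit
#' crossing to retraction start; (4) retraction start, the 50 ms from
#' retraction start; (5) retraction, retraction start to stop; (6) handle
#' start, the 100 ms centred on handle start; (7) manipulation start, the
#' 50 ms after manipulation start; (8) manipulation, start to stop;
#' (9) manipulation stop, the 50 ms after manipulation stop. All intervals
#' are half-open `[start, stop)`. Windows whose defining events are absent
#' (e.g. handling on non-handled trials) get NA bounds.
#'
#' @param events trial table with columns `trial_id`, `reach_start`,
#'   `slit_cross`, `retract_start`, `retract_stop` and optionally
#'   `handle_start`, `manipulation_start`, `manipulation_stop` (seconds)
#' @return data.frame with columns `trial_id`, `window_id` (1-9), `start`,
#'   `stop`
#' @export
task_windows <- function(events) {
  e <- events
  opt <- function(col) if (col %in% names(e)) e[[col]] else NA_real_
  hs <- opt("handle_start"); ms <- opt("manipulation_start")
  me <- opt("manipulation_stop")
  defs <- list(
    list(1L, e$reach_start - 0.150, e$reach_start + 0.025),
    list(2L, e$reach_start, e$retract_start),
    list(3L, e$slit_cross, e$retract_start),
    list(4L, e$retract_start, e$retract_start + 0.050),
    list(5L, e$retract_start, e$retract_stop),
    list(6L, hs - 0.050, hs + 0.050),
    list(7L, ms, ms + 0.050),
    list(8L, ms, me),
    list(9L, me, me + 0.050)
  )
  out <- do.call(rbind, lapply(defs, function(d) {
    data.frame(trial_id = e$trial_id, window_id = d[[1]],
               start = d[[2]], stop = d[[3]])
  }))
  out[order(out$trial_id, out$window_id), , drop = FALSE]
}

#' Filter a tracked trajectory
#'
#' Either a running-median filter (size 5, default) or a zero-phase low-pass
#' Butterworth filter (order 4, cutoff 15 Hz) applied to the hand
#' coordinates, matching the two standard choices for cleaning markerless
#' pose-estimation output.
#'
#' @param track hand-track data.frame (`time_s`, `hand_x_px`, `hand_y_px`,
#'   `slit_x_px`, `slit_y_px`); attribute `frame_rate` or a `frame_rate`
#'   argument
#' @param method `"median"` or `"lowpass"`
#' @param size running-median window (odd)
#' @param order,cutoff Butterworth order and cutoff (Hz)
#' @param frame_rate frames/s; defaults to the track attribute
#' @return track with filtered hand coordinates
#' @export
filter_track <- function(track, method = c("median", "lowpass"), size = 5,
                         order = 4, cutoff = 15, frame_rate = NULL) {
  method <- match.arg(method)
  fr <- frame_rate %||% attr(track, "frame_rate") %||%
    (1 / stats::median(diff(track$time_s)))
  f <- if (method == "median") {
    function(x) as.numeric(stats::runmed(x, size, endrule = "median"))
  } else {
    bw <- signal::butter(order, cutoff / (fr / 2), type = "low")
    function(x) as.numeric(signal::filtfilt(bw, x))
  }
  track$hand_x_px <- f(track$hand_x_px)
  track$hand_y_px <- f(track$hand_y_px)
  track
}

# Local maxima with topographic prominence >= `prominence`. Equal-height
# summits are tie-broken leftward (the left scan treats equal heights as
# higher), so only one of a pair of tied summits carries the shared
# prominence — median filtering routinely produces exact ties.
find_peaks_prominence <- function(x, prominence) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]; h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher <- which(left >= h)
    left_base <- if (length(higher)) {
      if (max(higher) == i - 1L) h else min(left[(max(higher) + 1L):(i - 1L)])
    } else min(left)
    right <- x[(i + 1L):n]
    higher <- which(right > h)
    right_base <- if (length(higher)) {
      if (min(higher) == 1L) h else min(right[seq_len(min(higher) - 1L)])
    } else min(right)
    keep[j] <- (h - max(left_base, right_base)) >= prominence
  }
  cand[keep]
}

# Session-level main reach direction: unit vector from mean hand position at
# one set of frames to the mean at another; falls back to the first principal
# axis of hand position when no events are available yet.
main_direction <- function(xy, from_idx = NULL, to_idx = NULL) {
  if (!is.null(from_idx) && length(from_idx) && length(to_idx)) {
    d <- colMeans(xy[to_idx, , drop = FALSE]) -
      colMeans(xy[from_idx, , drop = FALSE])
  } else {
    pc <- stats::prcomp(xy)
    d <- pc$rotation[, 1]
  }
  nd <- sqrt(sum(d^2))
  if (nd == 0) c(1, 0) else d / nd
}

#' Detect reach events from a tracked hand trajectory
#'
#' Reaches are detected as prominence-thresholded peaks of hand displacement
#' past the slit along the main reach direction (slit crossings); the peak
#' frame of maximum extension is the retraction start (= reach stop). The
#' reach start is found by rolling back from the retraction start, within
#' 0.5 s, to the moment the hand velocity along the main reach direction
#' falls below +1 px/s; the retraction stop by rolling forward to where that
#' velocity rises above -1 px/s. Velocity is the central difference of the
#' filtered position. The main direction is estimated from the hand
#' trajectory (principal axis), then refined once from the detected events.
#'
#' @param track hand-track data.frame (see [filter_track()])
#' @param params list of detection parameters: `filter` ("median" or
#'   "lowpass"), `size`, `order`, `cutoff`, `prominence` (px, default 5),
#'   `velocity_threshold` (px/s, default 1), `rollback` (s, default 0.5)
#' @return data.frame of task events (`trial_id`, `reach_start`,
#'   `slit_cross`, `retract_start`, `retract_stop`, `start_fallback`,
#'   `stop_fallback`), with the main-direction vector as attribute
#'   `direction`. Zero detected crossings give a zero-row data.frame.
#' @export
detect_reaches <- function(track, params = list()) {
  p <- utils::modifyList(list(filter = "median", size = 5, order = 4,
                              cutoff = 15, prominence = 5,
                              velocity_threshold = 1, rollback = 0.5),
                         params)
  if (is.unsorted(track$time_s, strictly = TRUE)) {
    stop("track time must be strictly increasing")
  }
  fr <- attr(track, "frame_rate") %||% (1 / stats::median(diff(track$time_s)))
  ft <- filter_track(track, method = p$filter, size = p$size,
                     order = p$order, cutoff = p$cutoff, frame_rate = fr)
  xy <- cbind(ft$hand_x_px, ft$hand_y_px)
  slit <- cbind(ft$slit_x_px, ft$slit_y_px)
  rel <- xy - slit

  detect_pass <- function(dir) {
    d <- rel %*% dir
    # central difference over +/-2 frames: spans the short flat plateaus the
    # median filter leaves at velocity zero crossings
    nn <- length(d)
    v <- c(0, 0, (d[-(1:4)] - d[seq_len(nn - 4)]) * fr / 4, 0, 0)
    peaks <- find_peaks_prominence(as.numeric(d), p$prominence)
    peaks <- peaks[d[peaks] > 0]
    if (!length(peaks)) {
      return(data.frame(trial_id = integer(), reach_start = numeric(),
                        slit_cross = numeric(), retract_start = numeric(),
                        retract_stop = numeric(), start_fallback = logical(),
                        stop_fallback = logical()))
    }
    nb <- round(p$rollback * fr)
    thr <- p$velocity_threshold
    n <- length(d)
    dt <- 1 / fr
    # sub-frame crossing of `level` between frames j and j + 1
    interp <- function(j, level, y) {
      frac <- (level - y[j]) / (y[j + 1L] - y[j])
      ft$time_s[j] + max(0, min(1, frac)) * dt
    }
    out <- lapply(seq_along(peaks), function(k) {
      pk <- peaks[k]
      # maximum extension: the outward-to-inward velocity sign change
      # nearest the displacement peak (robust to peak clipping by the
      # median filter); sub-frame time by linear interpolation
      win <- max(pk - 6L, 2L):min(pk + 6L, n - 1L)
      sc <- win[v[win] >= 0 & v[win + 1L] < 0]
      if (length(sc)) {
        j <- sc[which.min(abs(sc - pk))]
        t_pk <- interp(j, 0, v)
        pk <- as.integer(round(j + v[j] / (v[j] - v[j + 1L])))
      } else {
        t_pk <- ft$time_s[pk]
      }
      # slit crossing: last upward zero crossing of displacement before the
      # peak, at sub-frame resolution
      before <- which(d[seq_len(pk)] < 0)
      t_cross <- if (length(before)) {
        interp(max(before), 0, d)
      } else ft$time_s[max(pk - nb, 1L)]
      # reach start: anchor at the fastest outward frame before the peak
      # (velocity at the peak itself is ~0), roll back to the first frame
      # below +1 px/s, then interpolate the threshold crossing
      lo <- max(pk - nb, 1L)
      j <- lo + which.max(v[lo:pk]) - 1L
      while (j > lo && v[j] >= thr) j <- j - 1L
      fb_start <- v[j] >= thr
      t_rs <- if (fb_start) ft$time_s[lo] else interp(j, thr, v)
      # retraction stop: anchor at the fastest inward frame after the peak,
      # roll forward to the first frame above -1 px/s, interpolate
      hi <- min(pk + nb, n)
      j <- pk + which.min(v[pk:hi]) - 1L
      while (j < hi && v[j] <= -thr) j <- j + 1L
      fb_stop <- v[j] <= -thr
      t_re <- if (fb_stop) ft$time_s[hi] else interp(j - 1L, -thr, v)
      c(t_rs, t_cross, t_pk, t_re, fb_start, fb_stop)
    })
    m <- do.call(rbind, out)
    data.frame(trial_id = seq_along(peaks),
               reach_start = m[, 1],
               slit_cross = m[, 2],
               retract_start = m[, 3],
               retract_stop = m[, 4],
               start_fallback = as.logical(m[, 5]),
               stop_fallback = as.logical(m[, 6]))
  }

  dir <- main_direction(xy)
  # orient towards the largest excursion from the resting (median) position
  d0 <- rel %*% dir
  med <- stats::median(d0)
  if (abs(min(d0) - med) > max(d0) - med) dir <- -dir
  ev <- detect_pass(dir)
  if (nrow(ev)) {
    idx_from <- findInterval(ev$reach_start, ft$time_s)
    idx_to <- findInterval(ev$retract_start, ft$time_s)
    dir <- main_direction(xy, idx_from, idx_to)
    ev <- detect_pass(dir)
  }
  attr(ev, "direction") <- as.numeric(dir)
  ev
}

#' Label trial types from detected reach events
#'
#' Applies the trial stratifications used throughout the analysis: isolated
#' reaches (>= 0.75 s from neighbouring reaches on both sides), repeated
#' pairs (retraction starts within 0.3-0.6 s of each other), reach-duration
#' strata (session percentiles: short = 1st-25th, long = 73rd-97th, linear
#' interpolation, inclusive band membership), abbreviated reaches (maximum
#' extension at most 0.45 cm past the slit on the major movement axis and
#' 0.25 cm on the minor axis) and handled trials (from an annotation table,
#' else from the presence of a handle-start event).
#'
#' @param events data.frame from [detect_reaches()] (or a ground-truth trial
#'   table with the same event columns)
#' @param track hand-track data.frame; required for abbreviation labels
#' @param params list: `scale_cm_per_px` (required for abbreviation),
#'   `abbrev_major_cm` (0.45), `abbrev_minor_cm` (0.25), `isolation_s`
#'   (0.75), `pair_band_s` (c(0.3, 0.6)), plus [filter_track()] options
#' @param annotations optional data.frame (`trial_id`, `handle_start_s`,
#'   `manipulation_start_s`, `manipulation_stop_s`) of manually annotated
#'   handling events, merged into the output
#' @return the events data.frame with added columns `isolated`,
#'   `repeated_pair_id`, `duration_stratum`, `abbreviated`, `handled`
#' @export
classify_trials <- function(events, track = NULL, params = list(),
                            annotations = NULL) {
  p <- utils::modifyList(list(scale_cm_per_px = NULL,
                              abbrev_major_cm = 0.45, abbrev_minor_cm = 0.25,
                              isolation_s = 0.75, pair_band_s = c(0.3, 0.6),
                              filter = "median", size = 5, order = 4,
                              cutoff = 15),
                         params)
  ev <- events[order(events$reach_start), , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L) return(ev)

  gap_before <- c(Inf, ev$reach_start[-1] - ev$retract_stop[-n])
  gap_after <- c(ev$reach_start[-1] - ev$retract_stop[-n], Inf)
  ev$isolated <- gap_before >= p$isolation_s & gap_after >= p$isolation_s

  # repeated pairs: consecutive retraction starts within the band, greedy
  ev$repeated_pair_id <- NA_integer_
  if (n > 1L) {
    dgap <- diff(ev$retract_start)
    pid <- 0L
    i <- 1L
    while (i < n) {
      if (!is.na(dgap[i]) && dgap[i] >= p$pair_band_s[1] &&
            dgap[i] <= p$pair_band_s[2]) {
        pid <- pid + 1L
        ev$repeated_pair_id[c(i, i + 1L)] <- pid
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }

  dur <- ev$retract_start - ev$reach_start
  q <- stats::quantile(dur, c(0.01, 0.25, 0.73, 0.97), type = 7, names = FALSE)
  ev$duration_stratum <- ifelse(dur >= q[1] & dur <= q[2], "short",
                                ifelse(dur >= q[3] & dur <= q[4], "long",
                                       "mid"))

  ev$abbreviated <- NA
  if (!is.null(track)) {
    if (is.null(p$scale_cm_per_px)) {
      stop("scale_cm_per_px is required to label abbreviated reaches")
    }
    ft <- filter_track(track, method = p$filter, size = p$size,
                       order = p$order, cutoff = p$cutoff)
    dirv <- attr(events, "direction") %||% c(1, 0)
    rel <- cbind(ft$hand_x_px - ft$slit_x_px, ft$hand_y_px - ft$slit_y_px)
    d_major <- as.numeric(rel %*% dirv)
    d_minor <- as.numeric(rel %*% c(-dirv[2], dirv[1]))
    ev$abbreviated <- vapply(seq_len(n), function(i) {
      idx <- which(ft$time_s >= ev$reach_start[i] &
                     ft$time_s <= ev$retract_stop[i] & d_major > 0)
      if (!length(idx)) return(FALSE)
      max(d_major[idx]) * p$scale_cm_per_px <= p$abbrev_major_cm &&
        max(abs(d_minor[idx])) * p$scale_cm_per_px <= p$abbrev_minor_cm
    }, logical(1))
  }

  if (!is.null(annotations)) {
    m <- match(ev$trial_id, annotations$trial_id)
    ev$handle_start <- annotations$handle_start_s[m]
    ev$manipulation_start <- annotations$manipulation_start_s[m]
    ev$manipulation_stop <- annotations$manipulation_stop_s[m]
  }
  ev$handled <- if ("handle_start" %in% names(ev)) {
    !is.na(ev$handle_start)
  } else FALSE
  ev
}

#' Event-aligned hand-speed profiles
#'
#' Mean hand-speed profiles aligned to reach start and to retraction start
#' over a +/-0.5 s window, computed per trial over isolated reaches and then
#' averaged, in px/s or cm/s.
#'
#' @param track hand-track data.frame
#' @param trials classified trial table; only rows with `isolated == TRUE`
#'   are used (all rows if the column is absent)
#' @param window alignment window, seconds
#' @param units `"px"` or `"cm"` (requires `scale_cm_per_px`)
#' @param scale_cm_per_px pixel size in cm
#' @param filter_params list passed to [filter_track()]
#' @return list with elements `reach_aligned` and `retract_aligned`, each a
#'   list of `time` (s relative to the event), `mean` and `per_trial` speed
#' @export
summarize_kinematics <- function(track, trials, window = c(-0.5, 0.5),
                                 units = c("px", "cm"),
                                 scale_cm_per_px = NULL,
                                 filter_params = list()) {
  units <- match.arg(units)
  tr <- if ("isolated" %in% names(trials)) {
    trials[trials$isolated, , drop = FALSE]
  } else trials
  if (nrow(tr) == 0L) stop("at least one isolated reach is required")
  fp <- utils::modifyList(list(method = "median"), filter_params)
  ft <- do.call(filter_track, c(list(track), fp))
  fr <- attr(track, "frame_rate") %||% (1 / stats::median(diff(track$time_s)))
  vx <- c(0, (ft$hand_x_px[-(1:2)] -
                ft$hand_x_px[seq_len(nrow(ft) - 2)]) * fr / 2, 0)
  vy <- c(0, (ft$hand_y_px[-(1:2)] -
                ft$hand_y_px[seq_len(nrow(ft) - 2)]) * fr / 2, 0)
  speed <- sqrt(vx^2 + vy^2)
  if (units == "cm") {
    if (is.null(scale_cm_per_px)) stop("scale_cm_per_px required for cm units")
    speed <- speed * scale_cm_per_px
  }
  rel_frames <- seq(round(window[1] * fr), round(window[2] * fr))
  align <- function(at) {
    idx0 <- round(at * fr) + 1L
    m <- vapply(idx0, function(i) {
      idx <- i + rel_frames
      out <- rep(NA_real_, length(rel_frames))
      ok <- idx >= 1L & idx <= length(speed)
      out[ok] <- speed[idx[ok]]
      out
    }, numeric(length(rel_frames)))
    m <- t(m)
    list(time = rel_frames / fr,
         mean = colMeans(m, na.rm = TRUE),
         per_trial = m)
  }
  list(reach_aligned = align(tr$reach_start),
       retract_aligned = align(tr$retract_start))
}
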