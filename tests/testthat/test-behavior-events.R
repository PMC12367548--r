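# Build a bare hand-track data.frame from coordinate vectors.
make_track <- function(x, y = NULL, fr = 100, slit = c(100, 100)) {
  n <- length(x)
  tr <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / fr,
                   hand_x_px = x, hand_y_px = y %||% rep(slit[2], n),
                   slit_x_px = slit[1], slit_y_px = slit[2],
                   likelihood = 1)
  class(tr) <- c("hand_track", "data.frame")
  attr(tr, "frame_rate") <- fr
  tr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a flat trajectory yields zero reaches and bad time errors out", {
  tr <- make_track(rep(55, 500))
  ev <- detect_reaches(tr)
  expect_equal(nrow(ev), 0)
  tr2 <- make_track(c(rep(55, 10), 120, rep(55, 10)))
  tr2$time_s[5] <- tr2$time_s[7]
  expect_error(detect_reaches(tr2), "strictly increasing")
})

test_that("a noiseless triangular bump is segmented at its exact frames", {
  # velocity crosses +1 px/s exactly at frame 200 and the peak sits at
  # frame 250; retraction ends at frame 300 (oracle by construction)
  fr <- 100
  x <- rep(50, 600)
  up <- 200:250; down <- 251:300
  x[up + 1] <- 50 + (up - 200) * 1.6       # 160 px/s out
  x[down + 1] <- 130 - (down - 250) * 1.6  # 160 px/s back
  ev <- detect_reaches(make_track(x, fr = fr),
                       params = list(prominence = 5))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$retract_start - 2.50), 0.011)
  expect_lt(abs(ev$reach_start - 2.00), 0.011)
  expect_lt(abs(ev$retract_stop - 3.00), 0.011)
  expect_true(ev$slit_cross > ev$reach_start &
                ev$slit_cross <= ev$retract_start)
})

test_that("generator events are recovered within one frame under noise", {
  cfg <- sim_config(seed = 17, session_duration = 180, n_isolated = 30,
                    tracking_noise_sd = 0.5)
  s <- simulate_behavior_session(cfg)
  ev <- detect_reaches(s$track)
  expect_equal(nrow(ev), nrow(s$trials))
  for (col in c("reach_start", "retract_start", "retract_stop")) {
    err <- vapply(s$trials[[col]], function(t) min(abs(ev[[col]] - t)), 0)
    expect_lt(max(err), 0.010 + 1e-9)
  }
})

test_that("detection is translation-equivariant", {
  cfg <- sim_config(seed = 23, session_duration = 90, n_isolated = 8)
  s <- simulate_behavior_session(cfg)
  ev1 <- detect_reaches(s$track)
  shifted <- s$track
  shifted$hand_x_px <- shifted$hand_x_px + 37
  shifted$hand_y_px <- shifted$hand_y_px - 12
  shifted$slit_x_px <- shifted$slit_x_px + 37
  shifted$slit_y_px <- shifted$slit_y_px - 12
  ev2 <- detect_reaches(shifted)
  expect_equal(ev1$reach_start, ev2$reach_start)
  expect_equal(ev1$retract_start, ev2$retract_start)
})

test_that("trial classification matches brute-force label oracles", {
  cfg <- sim_config(seed = 29, session_duration = 400, n_isolated = 40,
                    n_repeated_pairs = 8, n_abbreviated = 12)
  s <- simulate_behavior_session(cfg)
  ev <- detect_reaches(s$track)
  cl <- classify_trials(ev, s$track, params = list(scale_cm_per_px = 0.02))

  # repeated pairs recovered exactly
  expect_equal(sum(!is.na(cl$repeated_pair_id)) / 2, 8)
  truth_rep <- s$trials$trial_type == "repeated"
  m <- vapply(cl$retract_start, function(t) {
    which.min(abs(s$trials$retract_start - t))
  }, 0L)
  expect_equal(!is.na(cl$repeated_pair_id), unname(truth_rep[m]))

  # abbreviated flags match generator truth exactly
  expect_equal(cl$abbreviated,
               unname((s$trials$trial_type == "abbreviated")[m]))

  # isolated: every non-pair trial was packed with >= 0.75 s gaps
  expect_true(all(cl$isolated[is.na(cl$repeated_pair_id)]))
  expect_true(all(!cl$isolated[!is.na(cl$repeated_pair_id)]))

  # duration strata agree with an exhaustive percentile-band oracle
  dur <- cl$retract_start - cl$reach_start
  q <- stats::quantile(dur, c(0.01, 0.25, 0.73, 0.97), type = 7,
                       names = FALSE)
  oracle <- ifelse(dur >= q[1] & dur <= q[2], "short",
                   ifelse(dur >= q[3] & dur <= q[4], "long", "mid"))
  expect_equal(cl$duration_stratum, oracle)
  expect_equal(sum(oracle == "short"),
               sum(vapply(dur, function(d) d >= q[1] && d <= q[2],
                          logical(1))))
})

test_that("abbreviation thresholds and the missing-scale error behave as stated", {
  # single reach peaking 0.40 cm past the slit (major), 0.10 cm minor
  fr <- 100
  x <- rep(60, 400); y <- rep(100, 400)
  up <- 150:200; down <- 201:250
  x[up + 1] <- 60 + (up - 150) * 1.2   # apex 120 px = 0.40 cm past slit
  x[down + 1] <- 120 - (down - 200) * 1.2
  y[up + 1] <- 100 + (up - 150) * 0.1  # apex minor offset 5 px = 0.10 cm
  y[down + 1] <- 105 - (down - 200) * 0.1
  tr <- make_track(x, y, fr = fr)
  ev <- detect_reaches(tr)
  expect_equal(nrow(ev), 1)
  cl <- classify_trials(ev, tr, params = list(scale_cm_per_px = 0.02))
  expect_true(cl$abbreviated)
  expect_error(classify_trials(ev, tr), "scale_cm_per_px")
})

test_that("handling annotations are merged into the trial table", {
  cfg <- sim_config(seed = 31, session_duration = 90, n_isolated = 6)
  s <- simulate_behavior_session(cfg)
  ev <- detect_reaches(s$track)
  ann <- data.frame(trial_id = c(2, 4),
                    handle_start_s = ev$retract_stop[c(2, 4)] + 0.3,
                    manipulation_start_s = ev$retract_stop[c(2, 4)] + 0.5,
                    manipulation_stop_s = ev$retract_stop[c(2, 4)] + 2.0)
  cl <- classify_trials(ev, s$track, params = list(scale_cm_per_px = 0.02),
                        annotations = ann)
  expect_equal(which(cl$handled), c(2L, 4L))
  win <- task_windows(cl)
  w8 <- win[win$window_id == 8 & !is.na(win$start), ]
  expect_equal(nrow(w8), 2)
  expect_equal(w8$stop - w8$start, rep(1.5, 2))
})

test_that("speed profiles recover the programmed reach kinematics", {
  cfg <- sim_config(seed = 37, session_duration = 120, n_isolated = 10,
                    tracking_noise_sd = 0)
  s <- simulate_behavior_session(cfg)
  cl <- classify_trials(s$trials, params = list())
  ks <- summarize_kinematics(s$track, cl)
  # profile peaks near the mean programmed peak speed (median filter and
  # frame sampling shave the single-frame maximum slightly)
  expect_lt(abs(max(ks$reach_aligned$mean) -
                  mean(s$trials$peak_speed_px_s)) /
              mean(s$trials$peak_speed_px_s), 0.25)
  # identical windows: per-trial profiles have the right dimensions
  expect_equal(dim(ks$reach_aligned$per_trial),
               c(10L, length(ks$reach_aligned$time)))
  expect_error(summarize_kinematics(s$track, cl[0, ]), "isolated")
})
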