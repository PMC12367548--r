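test_that("the random-window null is stationary-centred and reproducible", {
  tr <- poisson_train(20, c(0, 500), seed = 6)
  durs <- rep(0.25, 60)
  null <- sample_null_windows(tr, durs, n_groups = 1000, seed = 3)
  expect_length(null$group_rates, 1000)
  se <- sqrt(20 / (0.25 * 60) / 1000) * sqrt(1000) # s.e. of one group mean
  expect_lt(abs(null$median - 20), 3 * se)
  null2 <- sample_null_windows(tr, durs, n_groups = 1000, seed = 3)
  expect_identical(null$group_rates, null2$group_rates)
  expect_error(sample_null_windows(tr, c(0.2, 600), seed = 1), "span")
})

test_that("the null distribution equals an independent brute-force resampler", {
  tr <- poisson_train(18, c(0, 60), seed = 12)
  durs <- c(0.18, 0.34, 0.07)
  null <- sample_null_windows(tr, durs, n_groups = 50, seed = 91)
  oracle <- oracle_null_windows(tr$times, tr$span, durs, 50, seed = 91)
  expect_equal(null$group_rates, oracle, tolerance = 1e-12)
})

test_that("the modulation index follows its formula and bounds", {
  tr <- poisson_train(20, c(0, 400), seed = 7)
  durs <- rep(0.3, 40)
  null <- sample_null_windows(tr, durs, n_groups = 500, seed = 5)
  win <- data.frame(start = seq(5, 395, by = 10)[1:40])
  win$stop <- win$start + 0.3
  row <- window_modulation(tr, win, null)
  expect_true(row$mi >= -1 && row$mi <= 1)
  # r_win = null median => MI = 0 (synthetic null object)
  fake_null <- structure(list(group_rates = rep(c(19, 20, 21), c(200, 100, 200)),
                              median = 20, durations = rep(0.3, 40),
                              n_groups = 500, seed = 1),
                         class = "null_distribution")
  empty <- spike_train(numeric(), c(0, 400), 2)
  row0 <- window_modulation(empty, win, fake_null)
  expect_equal(row0$mi, -1) # zero rate against positive null
  expect_equal(row0$rank_pct, 0)
  expect_true(row0$significant)
  expect_equal(row0$direction, "negative")

  # degenerate: zero rate and zero null
  zero_null <- structure(list(group_rates = rep(0, 100), median = 0,
                              durations = rep(0.3, 40), n_groups = 100,
                              seed = 1), class = "null_distribution")
  rowd <- window_modulation(empty, win, zero_null)
  expect_equal(rowd$mi, 0)
  expect_true(rowd$degenerate)

  # MI strictly monotone in r_win at fixed null median
  mi_of <- function(r) (r - 20) / (r + 20)
  rs <- c(0.5, 5, 19, 21, 60)
  expect_true(all(diff(mi_of(rs)) > 0))
  expect_error(window_modulation(tr, win[1:10, ], null), "durations")
})

test_that("an injected retraction gain is recovered at the analytic MI", {
  cfg <- sim_config(seed = 41, session_duration = 400, n_isolated = 100,
                    baseline_rate_range = c(20, 20))
  s <- simulate_behavior_session(cfg)
  win <- task_windows(s$trials)
  w5 <- win[win$window_id == 5, ]
  mis <- vapply(1:5, function(i) {
    pop <- simulate_population(
      sim_config(seed = 41 + i, session_duration = 400, n_isolated = 100,
                 baseline_rate_range = c(20, 20)),
      list(modulation_profile(1, c("5" = 2))), s$trials)
    null <- sample_null_windows(pop$trains[[1]], w5$stop - w5$start,
                                1000, seed = 100 + i)
    row <- window_modulation(pop$trains[[1]], w5, null)
    expect_true(row$significant)
    expect_equal(row$direction, "positive")
    row$mi
  }, 0)
  expect_lt(abs(mean(mis) - 1 / 3), 0.05)
})

test_that("neurons are classified by their significant window directions", {
  tab <- data.frame(
    neuron_id = c(1, 1, 2, 2, 3, 3, 4),
    window_id = c(2, 6, 2, 3, 1, 5, 4),
    direction = c("negative", "positive", "negative", "none", "none",
                  "none", "positive"))
  cls <- classify_bidirectional(tab)
  expect_equal(cls$per_neuron$class, c("bidirectional", "negative",
                                       "unmodulated", "positive"))
  expect_equal(unname(cls$fractions["modulated"]), 0.75)
  expect_equal(unname(cls$fractions["bidirectional_of_modulated"]), 1 / 3)
})

test_that("press-locked silencing is classified negative; null neurons are not", {
  span <- c(0, 600)
  n_tr <- 30
  cue <- seq(10, 590, length.out = n_tr)
  press <- cue + 0.6
  # complete press-locked silencing of a 30 Hz neuron
  iv <- data.frame(start = press - 0.1, stop = press + 0.1, gain = 0)
  tr <- simulate_rate_train(30, iv, span, seed = 14)
  pm <- press_trial_modulation(tr, press, cue, seed = 2)
  expect_true(pm$classified)
  expect_equal(pm$direction, "negative")
  expect_lt(abs(pm$mean_mi + 30), 3 * sqrt(30 / 0.2 / n_tr) + 1)
  expect_lt(pm$p, 0.05)

  # homogeneous neuron: not classified (single run; calibration is checked
  # population-wide in the acceptance suite)
  tr0 <- poisson_train(30, span, seed = 15)
  pm0 <- press_trial_modulation(tr0, press, cue, seed = 2)
  expect_lt(abs(pm0$mean_mi), 6)
  expect_length(pm0$null_mi, 200)
  expect_error(press_trial_modulation(tr0, press[1:3], cue[1:3]), "5 press")
})
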