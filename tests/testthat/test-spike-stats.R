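test_that("tonic-unit filtering applies a strict 5 Hz threshold", {
  span <- c(0, 100)
  mk <- function(rate, id) {
    spike_train(seq(0.5, 99.5, length.out = round(rate * 100)), span, id)
  }
  trains <- list(mk(4.9, 1), mk(5.1, 2), mk(20, 3))
  kept <- filter_tonic_units(trains)
  expect_equal(vapply(kept, function(t) t$neuron_id, 0), c(2, 3))
  expect_equal(attr(kept, "n_dropped"), 1L)
  expect_identical(filter_tonic_units(trains[3]), trains[3],
                   ignore_attr = TRUE)
  expect_warning(filter_tonic_units(list()), "no spike trains")

  # Poisson neurons at 2/4/6/8 Hz over 1,000 s: exactly the two above 5 Hz
  # survive, checked against a direct count/span computation
  tr4 <- lapply(1:4, function(i) {
    poisson_train(c(2, 4, 6, 8)[i], c(0, 1000), seed = 40 + i, id = i)
  })
  kept4 <- filter_tonic_units(tr4)
  direct <- vapply(tr4, function(t) length(t$times) / 1000 > 5, logical(1))
  expect_equal(vapply(kept4, function(t) t$neuron_id, 0L), which(direct))
  expect_equal(attr(kept4, "n_kept"), 2L)
})

test_that("PETH binning follows the half-open convention and conserves counts", {
  span <- c(0, 100)
  tr <- spike_train(c(50), span, 1)
  p <- compute_peth(tr, events = 50, bin_width = 0.05, window = c(-0.1, 0.1))
  expect_equal(ncol(p$rate), 4)
  # the spike at the event time falls in the first bin at/after zero
  expect_equal(as.numeric(p$rate), c(0, 0, 20, 0))

  # count conservation on a random train
  tr2 <- poisson_train(30, span, seed = 5)
  ev <- seq(10, 90, by = 5)
  p2 <- compute_peth(tr2, ev, bin_width = 0.05, window = c(-2, 2))
  direct <- sum(count_in_windows(tr2$times, ev - 2, ev + 2))
  expect_equal(sum(p2$rate) * 0.05, direct)

  # stationarity: grand mean ~ rate within 3 s.e.
  gm <- mean(p2$rate)
  se <- sqrt(30 / (length(ev) * 4))
  expect_lt(abs(gm - 30), 3 * se)

  expect_error(compute_peth(tr2, ev, bin_width = 0), "bin_width")
  expect_warning(compute_peth(tr2, c(1, 50), bin_width = 0.05,
                              window = c(-2, 2)), "clipped")
})

test_that("Gaussian smoothing matches the closed-form kernel and keeps mass", {
  # unit impulse smoothed = the renormalized truncated kernel
  span <- c(0, 1000)
  tr <- spike_train(500.0025, span, 1)
  p <- compute_peth(tr, events = 500, bin_width = 0.005, window = c(-0.5, 0.5),
                    smoothing = list())
  k_oracle <- stats::dnorm(-10:10, sd = 10)
  k_oracle <- k_oracle / sum(k_oracle)
  got <- as.numeric(p$rate[1, 91:111])
  expect_equal(got, 200 * k_oracle, tolerance = 1e-12)

  # per-trial mean rate preserved by smoothing (reflect padding)
  tr2 <- poisson_train(40, span, seed = 8)
  p_raw <- compute_peth(tr2, seq(100, 900, by = 40), 0.005, c(-2, 2))
  p_sm <- compute_peth(tr2, seq(100, 900, by = 40), 0.005, c(-2, 2),
                       smoothing = list())
  expect_equal(rowMeans(p_sm$rate), rowMeans(p_raw$rate), tolerance = 1e-6)

  # sigma interpretable in seconds as well
  k_s <- gaussian_kernel(0.005, sigma = 0.05, support_s = 0.1,
                         sigma_units = "s")
  expect_equal(k_s, gaussian_kernel(0.005, sigma = 10, support_s = 0.1))
})

test_that("concatenated z-scoring uses shared population statistics", {
  # two flat conditions at 10 and 30 Hz: z = -1 and +1 (population s.d.)
  m1 <- matrix(10, 3, 8)
  m2 <- matrix(30, 3, 8)
  zs <- zscore_concatenated(list(m1, m2))
  expect_true(all(zs$z[[1]] == -1))
  expect_true(all(zs$z[[2]] == 1))

  # zero-variance guard
  zc <- zscore_concatenated(list(matrix(30, 2, 4), matrix(30, 2, 4)))
  expect_true(all(zc$z[[1]] == 0))
  expect_equal(zc$flagged, 1:2)

  # exact round trip and idempotence
  set.seed(9)
  a <- matrix(rnorm(40, 20, 5), 4)
  b <- matrix(rnorm(40, 25, 5), 4)
  zs2 <- zscore_concatenated(list(a, b))
  back <- unzscore(zs2)
  expect_equal(back[[1]], a, tolerance = 1e-12)
  expect_equal(back[[2]], b, tolerance = 1e-12)
  rez <- zscore_concatenated(zs2$z)
  expect_equal(rez$z[[1]], zs2$z[[1]], tolerance = 1e-12)
  expect_error(zscore_concatenated(list(a, b[1:2, ])), "neuron set")
})

test_that("spike trains read back identically from csv and Phy-style arrays", {
  dir <- withr::local_tempdir()
  trains <- list(poisson_train(22, c(0, 60), seed = 1, id = 1L),
                 poisson_train(47, c(0, 60), seed = 2, id = 2L))
  write_session_bundle(trains = trains, dir = dir)
  back <- read_spikes_csv(file.path(dir, "spikes.csv"))
  expect_equal(back[[1]]$times, trains[[1]]$times)
  expect_equal(back[[2]]$span, c(0, 60))

  # Kilosort/Phy-style flat arrays: sample indices + cluster ids
  fs <- 30000
  all_t <- c(trains[[1]]$times, trains[[2]]$times)
  cl <- rep(c(5L, 9L), vapply(trains, function(t) length(t$times), 0L))
  ord <- order(all_t)
  snrreach:::write_npy_1d(round(all_t[ord] * fs), file.path(dir, "spike_times.npy"),
                          "i8")
  snrreach:::write_npy_1d(cl[ord], file.path(dir, "spike_clusters.npy"), "u4")
  writeLines(sprintf("sample_rate = %d.0", fs), file.path(dir, "params.py"))
  phy <- read_phy_dir(dir, span = c(0, 60))
  expect_equal(names(phy), c("5", "9"))
  expect_equal(phy[["5"]]$times, round(trains[[1]]$times * fs) / fs)
  expect_equal(length(phy[["9"]]$times), length(trains[[2]]$times))
  # float64 arrays round-trip exactly
  f <- file.path(dir, "f8.npy")
  snrreach:::write_npy_1d(all_t, f, "f8")
  expect_identical(snrreach:::read_npy_1d(f), all_t)
})
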