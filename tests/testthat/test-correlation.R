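test_that("event-aligned correlation matrices are symmetric with unit diagonal", {
  span <- c(0, 200)
  ev <- seq(10, 190, length.out = 12)
  # two neurons with identical spike times around events -> r = 1; a third
  # with duplicated spikes (affine x2 rate) keeps r = 1 with the first
  base <- sort(unlist(lapply(ev, function(t) t + stats::runif(30, -2, 2))))
  t1 <- spike_train(base, span, 1)
  t2 <- spike_train(base, span, 2)
  t3 <- spike_train(sort(c(base, base + 1e-6)), span, 3)
  m <- event_aligned_correlation_matrix(list(t1, t2, t3), ev,
                                        smoothing = list())
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(unname(m[1, 2]), 1)
  expect_gt(unname(m[1, 3]), 0.999) # affine rate scaling leaves r unchanged
  expect_error(event_aligned_correlation_matrix(list(t1), ev), "2 neurons")
  expect_error(event_aligned_correlation_matrix(list(t1, t2), ev[1:3]),
               "5 timestamps")
})

test_that("a silent neuron yields missing correlations but a unit diagonal", {
  span <- c(0, 200)
  ev <- seq(10, 190, length.out = 10)
  t1 <- poisson_train(20, span, seed = 3, id = 1)
  silent <- spike_train(numeric(), span, 2)
  m <- event_aligned_correlation_matrix(list(t1, silent), ev)
  expect_true(is.na(m[1, 2]))
  expect_equal(unname(diag(m)), c(1, 1))
})

test_that("the correlation matrix matches a closed-form Pearson oracle", {
  # three neurons, 4 x 1 s bins, counts chosen by hand
  span <- c(0, 100)
  ev <- c(10, 30, 50, 70, 90)
  counts <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 3, 2, 4))
  trains <- lapply(1:3, function(i) {
    tt <- unlist(lapply(ev, function(t) {
      unlist(lapply(1:4, function(b) {
        k <- counts[[i]][b]
        if (k > 0) t - 2 + (b - 1) + (seq_len(k) - 0.5) / k else numeric()
      }))
    }))
    spike_train(sort(tt), span, i)
  })
  m <- event_aligned_correlation_matrix(trains, ev, window = c(-2, 2),
                                        bin_width = 1, smoothing = NULL)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(unname(m[i, j]), pearson(counts[[i]], counts[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("structure regression recovers identity and abolished structure", {
  # long sparse session so random timestamps rarely overlap true events
  span <- c(0, 2000)
  ev <- seq(20, 1980, length.out = 20)
  # heterogeneously tuned population: per-neuron event latencies spread the
  # pairwise correlations over a broad range
  offs <- seq(-1, 1, length.out = 6)
  trains <- lapply(1:6, function(i) {
    iv <- data.frame(start = ev + offs[i] - 0.3, stop = ev + offs[i] + 0.3,
                     gain = 4)
    simulate_rate_train(15 + 5 * i, iv, span, seed = 80 + i, neuron_id = i)
  })
  m_ev <- event_aligned_correlation_matrix(trains, ev)
  self <- correlation_structure_regression(m_ev, m_ev)
  expect_equal(self$slope, 1, tolerance = 1e-9)
  expect_equal(self$r, 1, tolerance = 1e-9)
  # random timestamps abolish the structure: slope near 0
  set.seed(5)
  rnd <- sort(stats::runif(20, 5, 1995))
  m_rnd <- event_aligned_correlation_matrix(trains, rnd)
  reg <- correlation_structure_regression(m_ev, m_rnd)
  expect_lt(abs(reg$slope), 0.35)
  expect_error(correlation_structure_regression(m_ev[1:2, 1:2],
                                                m_rnd[1:2, 1:2]), "3")
})

test_that("noise correlations capture trial-coupled rate fluctuations", {
  span <- c(0, 400)
  ev <- seq(10, 390, length.out = 30)
  # anti-coupled pair by construction: on trial k the pre neuron fires k
  # spikes and the post neuron 31 - k in the centre bin
  pre_t <- unlist(lapply(seq_along(ev), function(k) {
    ev[k] + stats::runif(k, -0.01, 0.009)
  }))
  post_t <- unlist(lapply(seq_along(ev), function(k) {
    ev[k] + stats::runif(31 - k, -0.01, 0.009)
  }))
  pre <- spike_train(sort(pre_t), span, 1)
  post <- spike_train(sort(post_t), span, 2)
  nc <- noise_correlation(pre, post, ev)
  centre <- which(abs(nc$bin_starts + 0.02) < 1e-9) # bin [-0.02, 0)
  expect_lt(nc$r_per_bin[centre], -0.8)
  # independent Poisson pair: near-zero mean correlation
  p1 <- poisson_train(40, span, seed = 6, id = 1)
  p2 <- poisson_train(50, span, seed = 7, id = 2)
  nc0 <- noise_correlation(p1, p2, ev)
  expect_lt(abs(mean(nc0$r_per_bin, na.rm = TRUE)),
            3 / sqrt(length(ev) * sum(!is.na(nc0$r_per_bin))) * 3)
  # zero-variance bins are reported missing
  e1 <- spike_train(ev + 0.001, span, 3)
  nce <- noise_correlation(e1, e1, ev)
  expect_true(all(is.na(nce$r_per_bin[-nce$peak_bin])))
  expect_error(noise_correlation(p1, p2, ev[1:5]), "10 trials")
})
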