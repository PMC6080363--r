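test_that("autocorrelations match hand values and the scaling identity", {
  x <- c(1, 0, 1, 0)
  expect_equal(uacf_seq(x), c(0.5, 0, 0.5, 0))
  expect_equal(pacf_seq(x), c(0.5, 0, 0.25, 0))   # attenuated primary peak

  withr::with_seed(9, {
    for (rep in 1:10) {
      z <- abs(rnorm(sample(20:150, 1)))
      n <- length(z)
      u <- uacf_seq(z)
      p <- pacf_seq(z)
      expect_equal(p, u * (n - 0:(n - 1)) / n)
      expect_equal(u, brute_uacf(z))
      expect_equal(p, brute_pacf(z))
      expect_equal(which.max(p), 1L)   # biased form is lag-0 maximal
    }
  })
})

test_that("side-peak suppression squares then thresholds at 0.4 max", {
  out <- suppress_side_peaks(c(1, 0.2, 0.9))
  expect_equal(out, c(1, 0, 0.81))
  expect_equal(suppress_side_peaks(rep(0.5, 5)), rep(0.25, 5))
  # dominant lag: only lag 0 and that lag survive
  u <- c(1, 0.1, 0.05, 0.9, 0.1)
  expect_equal(which(suppress_side_peaks(u) > 0), c(1L, 4L))
})

test_that("last-peak removal works on runs and guards the single-run case", {
  expect_equal(remove_last_peak(c(1, 0, 0.8, 0, 0.5)), c(1, 0, 0.8, 0, 0))
  expect_warning(out <- remove_last_peak(c(1, 0, 0, 0, 0)), "one peak")
  expect_equal(out, c(1, 0, 0, 0, 0))
  # adjacent nonzero lags form one peak region
  expect_equal(remove_last_peak(c(1, 0.9, 0, 0.7, 0.6)), c(1, 0.9, 0, 0, 0))
  expect_error(remove_last_peak(rep(0, 5)), "all-zero")
})

test_that("cycle estimation recovers the period of a periodic envelope", {
  period <- 1600
  env <- numeric(3 * period)
  for (k in 0:2) {
    env[k * period + 1:150] <- 1                 # S1-like hump
    env[k * period + 601:720] <- 0.8             # S2-like hump
  }
  est <- estimate_cycle(env, 2000)
  expect_lt(abs(est$avg_cycle_samples - period) / period, 0.02)
  expect_equal(est$avg_cycle_s, est$avg_cycle_samples / 2000)

  # no repetition structure (single burst): failure of the documented class
  single <- numeric(4000)
  single[1000:1150] <- 1
  expect_error(expect_warning(estimate_cycle(single, 2000)),
               class = "pcg_cycle_error")
  expect_error(estimate_cycle(numeric(10), 2000), class = "pcg_cycle_error")
})

test_that("unbiased autocorrelation keeps primary peaks non-attenuating", {
  period <- 800
  env <- numeric(4 * period)
  for (k in 0:3) env[k * period + 1:100] <- 1
  u <- uacf_seq(env)
  p1 <- max(u[(period - 20):(period + 20) + 1])
  p2 <- max(u[(2 * period - 20):(2 * period + 20) + 1])
  expect_lt(abs(p1 - p2) / p1, 0.10)
  # while the biased form attenuates markedly
  pb <- pacf_seq(env)
  b1 <- max(pb[(period - 20):(period + 20) + 1])
  b2 <- max(pb[(2 * period - 20):(2 * period + 20) + 1])
  expect_gt((b1 - b2) / b1, 0.2)
})
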