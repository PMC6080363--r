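test_that("adaptive threshold reproduces the defining arithmetic", {
  res <- adaptive_threshold(c(0, 0.5, 1.0, 0.5, 0))
  expect_equal(res$mu, 0.4)
  expect_equal(res$theta_a, 0.8 * sqrt(0.14))
  expect_equal(res$theta, 0.025)
  expect_equal(res$env, c(0, 0.5, 1.0, 0.5, 0))   # nothing below 0.025

  # low plateau removed
  env <- c(0, rep(0.01, 5), 0.8, rep(0.01, 5), 0)
  res <- adaptive_threshold(env)
  expect_true(all(res$env[env == 0.01] == 0))

  # degenerate all-equal envelope: sd 0 -> theta 0 -> unchanged
  res <- adaptive_threshold(rep(1, 10))
  expect_equal(res$theta, 0)
  expect_equal(res$env, rep(1, 10))
  expect_error(adaptive_threshold(numeric(0)), "empty")
})

test_that("candidate extraction implements the zero-crossing rule with edges", {
  bs <- extract_candidate_boundaries(c(0, 0, 0.3, 0.4, 0, 0, 0.2, 0))
  expect_equal(bs$onset, c(1L, 5L))
  expect_equal(bs$offset, c(4L, 7L))

  expect_equal(extract_candidate_boundaries(rep(0, 10))$m, 0L)

  # run touching the start takes onset 0; touching the end takes the last index
  bs <- extract_candidate_boundaries(c(0.5, 0.5, 0, 0, 0.2, 0.2))
  expect_equal(bs$onset, c(0L, 3L))
  expect_equal(bs$offset, c(2L, 5L))

  # runs separated by a single zero merge into one pair (shared boundary)
  bs <- extract_candidate_boundaries(c(0, 0.5, 0, 0.4, 0))
  expect_equal(bs$m, 1L)
  expect_equal(bs$onset, 0L)
  expect_equal(bs$offset, 4L)
})

test_that("energy filtering removes weak pairs and zeroes their samples", {
  env <- c(0, 0, 0.3, 0.4, 0, 0, 0.2, 0)
  bs <- extract_candidate_boundaries(env)
  res <- energy_filter(env, bs, 0.25)
  expect_equal(res$bs$onset, 1L)      # E = 0.25 survives (not strictly below)
  expect_equal(res$bs$offset, 4L)
  expect_equal(res$bs$energy, 0.25)
  expect_true(all(res$env[6:8] == 0)) # removed pair zeroed

  # all pairs strong: unchanged
  env2 <- c(0, 0.9, 0.9, 0, 0, 0.8, 0.8, 0)
  bs2 <- extract_candidate_boundaries(env2)
  res2 <- energy_filter(env2, bs2, 0.25)
  expect_equal(res2$bs$m, 2L)
  expect_equal(res2$env, env2)

  # all pairs weak: empty set, zero envelope
  res3 <- energy_filter(env2, bs2, 10)
  expect_equal(res3$bs$m, 0L)
  expect_true(all(res3$env == 0))
})

test_that("boundary_set enforces strict interleaving", {
  expect_error(boundary_set(c(0, 5), c(6, 9)), "interleaved")
  expect_error(boundary_set(3, 3), "exceed")
  expect_equal(boundary_set()$m, 0L)
})

test_that("boundary detection recovers clean synthetic trains", {
  g <- generate_pcg(preset_catalog()[["normal"]])
  hs <- preprocess(g$signal)
  me <- eliminate_murmurs(hs)
  bd <- detect_boundaries(me$signal)
  expect_equal(bd$bs$m, 6L)
  truth <- g$truth$annotations
  expect_true(all(abs(bd$bs$onset - truth$onset_sample) <= 40))   # 20 ms at 2 kHz

  # click artifact removed by opening/energy filtering
  gc <- generate_pcg(preset_catalog()[["click"]])
  bdc <- detect_boundaries(eliminate_murmurs(preprocess(gc$signal))$signal)
  expect_equal(bdc$bs$m, 6L)

  # silence in, nothing out
  bd0 <- detect_boundaries(audio_signal(rep(0, 2000), 2000))
  expect_equal(bd0$bs$m, 0L)
})
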