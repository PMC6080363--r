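test_that("fft_modulus matches direct DFT expectations", {
  # constant signal: DC-only one-sided spectrum
  sp <- fft_modulus(audio_signal(rep(3, 4), 8))
  expect_equal(sp$fft_modulus, c(12, 0, 0))
  expect_equal(sp$freq_hz, c(0, 2, 4))

  # unit impulse: flat modulus
  sp <- fft_modulus(audio_signal(c(1, rep(0, 7)), 8))
  expect_equal(sp$fft_modulus, rep(1, 5))

  # pure sine exactly on bin 3 of N=32: single nonzero one-sided bin
  x <- sin(2 * pi * 3 * (0:31) / 32)
  sp <- fft_modulus(audio_signal(x, 32))
  nz <- which(sp$fft_modulus > 1e-9)
  expect_equal(nz, 4L)    # 1-based position of bin 3
})

test_that("moving-average envelope matches the three-branch formula", {
  expect_equal(moving_average_envelope(c(1, 2, 3, 4), 1, normalize = FALSE),
               c(1.5, 2, 3, 3.5))
  c5 <- rep(5, 20)
  expect_equal(moving_average_envelope(c5, 3, normalize = FALSE), c5)
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- abs(rnorm(sample(30:200, 1)))
      expect_equal(moving_average_envelope(x, 5, normalize = FALSE),
                   brute_moving_average(x, 5))
    }
  })
  expect_error(moving_average_envelope(1:4, 4), "smaller than")
})

test_that("cutoff search follows the first-valley-below-threshold rule", {
  mk_env <- function(freqs, values) {
    sp <- structure(list(fft_modulus = values, freq_hz = freqs,
                         env = values / max(values), l_f = 5, fs = 2000),
                    class = "spectral_envelope")
    sp
  }
  f <- seq(0, 500, by = 10)
  # peak at 60 Hz; minima at 110 (0.1) and 150 (0.05) -> first wins
  v <- approx(c(0, 60, 110, 130, 150, 170, 500),
              c(0.2, 1, 0.1, 0.5, 0.05, 0.4, 0.01), xout = f)$y
  res <- find_cutoff_frequency(mk_env(f, v))
  expect_true(res$found_valley)
  expect_equal(res$cutoff_hz, 110)
  expect_equal(res$primary_peak_hz, 60)

  # first minimum 0.25 fails the <0.2 test, next (0.15 at 140) is taken
  v <- approx(c(0, 60, 100, 120, 140, 160, 500),
              c(0.2, 1, 0.25, 0.5, 0.15, 0.4, 0.01), xout = f)$y
  res <- find_cutoff_frequency(mk_env(f, v))
  expect_equal(res$cutoff_hz, 140)

  # monotone decay: no valley in range -> fallback to 200
  v <- exp(-f / 100)
  res <- find_cutoff_frequency(mk_env(f, v))
  expect_false(res$found_valley)
  expect_equal(res$cutoff_hz, 200)
})

test_that("ALPF has the expected passband and stopband behavior", {
  t <- (0:3999) / 2000
  tone50 <- audio_signal(sin(2 * pi * 50 * t), 2000)
  out <- apply_alpf(tone50, 200)
  mid <- 500:3500
  expect_lt(abs(max(abs(out$samples[mid])) - 1), 0.01)

  # 400 Hz tone, cutoff 100 Hz: attenuated by >= 20 dB before renormalization
  tone400 <- sin(2 * pi * 400 * t)
  bf <- signal::butter(6, 100 / 1000, type = "low")
  att <- signal::filtfilt(bf, tone400)
  expect_lt(20 * log10(max(abs(att[mid])) / 1), -20)

  expect_error(apply_alpf(tone50, 1000), "Nyquist")
  expect_error(apply_alpf(audio_signal(rep(0, 100), 2000), 50), "all-zero")
})

test_that("murmur elimination preserves components and raises SMR", {
  cat <- preset_catalog()
  # murmur-free: output close to input inside component regions
  g <- generate_pcg(cat[["normal"]])
  hs <- preprocess(g$signal)
  me <- eliminate_murmurs(hs)
  expect_gte(me$cutoff$cutoff_hz, 20)
  expect_lte(me$cutoff$cutoff_hz, 200)
  # per component, the filtered waveform keeps the component's shape (relative
  # L2 error after optimal amplitude alignment). S1 sits well inside the
  # passband (< 5%); S2's upper band edge reaches the cutoff, so its
  # distortion is larger but bounded (< 15%, frozen from the method's
  # measured passband behavior on these conditions).
  u <- g$truth$region_mask$u
  truth_lab <- g$truth$annotations$label
  for (i in seq_len(nrow(u))) {
    idx <- (u[i, 1]:u[i, 2]) + 1L
    a <- hs$samples[idx]; b <- me$signal$samples[idx]
    scale <- sum(a * b) / sum(b^2)
    err <- sqrt(sum((a - scale * b)^2) / sum(a^2))
    expect_lt(err, if (truth_lab[i] == "S1") 0.05 else 0.15)
  }

  # murmur present: SMR must increase
  g2 <- generate_pcg(cat[["systolic-murmur"]])
  hs2 <- preprocess(g2$signal)
  me2 <- eliminate_murmurs(hs2)
  expect_gt(smr(me2$signal, g2$truth$region_mask),
            smr(hs2, g2$truth$region_mask))
})
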