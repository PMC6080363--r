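mk_bs <- function(onsets, width = 150) {
  boundary_set(onsets, onsets + width)
}

test_that("beat grouping windows components by onset", {
  cyc <- 1600
  on <- c(0, 0.3, 1, 1.3, 2, 2.3) * cyc
  beats <- group_into_beats(mk_bs(on), cyc)
  expect_length(beats, 3)
  expect_equal(lapply(beats, `[[`, "components"),
               list(1:2, 3:4, 5:6))
  expect_true(all(vapply(beats, `[[`, logical(1), "classifiable")))

  # one component in a window -> flagged
  b1 <- group_into_beats(mk_bs(c(0)), cyc)
  expect_false(b1[[1]]$classifiable)
  # five components crowded into one beat -> flagged
  b5 <- group_into_beats(mk_bs(seq(0, 600, by = 150), width = 100), 1600)
  expect_length(b5, 1)
  expect_false(b5[[1]]$classifiable)

  # drifting rhythm: re-anchoring follows the realized beat starts
  drift <- c(0, 480, 1520, 2000, 3120, 3600)   # cycles 1520 and 1600
  bd <- group_into_beats(mk_bs(drift), 1570)
  expect_equal(lapply(bd, `[[`, "components"), list(1:2, 3:4, 5:6))
})

test_that("two-component rule uses the systolic/diastolic gap comparison", {
  cyc <- 1600
  # T12 = 0.3 s (600 - offset 300), T21 = 0.5 s-ish: S1 first
  bs <- boundary_set(c(0, 600, 1600, 2200, 3200, 3800),
                     c(300, 800, 1900, 2400, 3500, 4000))
  beats <- group_into_beats(bs, cyc)
  lab <- recognize_components(beats, bs, rep(100, 6), cyc)
  expect_equal(lab, rep(c("S1", "S2"), 3))

  # reversed orientation: short gap second
  bs2 <- boundary_set(c(0, 1000, 1600, 2600, 3200, 4200),
                      c(200, 1300, 1800, 2900, 3400, 4500))
  lab2 <- recognize_components(group_into_beats(bs2, cyc), bs2,
                               rep(100, 6), cyc)
  expect_equal(lab2, rep(c("S2", "S1"), 3))
})

test_that("three-component rule resolves the gallop sound by timing priors", {
  cyc <- 1600
  # S1 0-200, S2 600-780, S3 1020-1120 per beat (gap S2->S3 < gap S3->S1)
  on <- c(outer(c(0, 600, 1020), c(0, 1600, 3200), "+"))
  off <- c(outer(c(200, 780, 1120), c(0, 1600, 3200), "+"))
  bs <- boundary_set(on, off)
  freqs <- rep(c(100, 110, 40), 3)
  beats <- group_into_beats(bs, cyc)
  lab <- recognize_components(beats, bs, freqs, cyc)
  expect_equal(lab, rep(c("S1", "S2", "S3"), 3))

  # S4 geometry: extra sound close to the *next* S1 (frequencies passed to
  # the grouper so the trailing gallop merges into the final beat)
  on4 <- c(outer(c(0, 600, 1360), c(0, 1600, 3200), "+"))
  off4 <- c(outer(c(200, 780, 1460), c(0, 1600, 3200), "+"))
  bs4 <- boundary_set(on4, off4)
  lab4 <- recognize_components(group_into_beats(bs4, cyc, freqs), bs4,
                               freqs, cyc)
  expect_equal(lab4, rep(c("S1", "S2", "S4"), 3))

  # verbatim rule flips the decision on the same geometry
  labv <- recognize_components(group_into_beats(bs, cyc), bs, freqs, cyc,
                               s3s4_rule = "verbatim")
  expect_equal(labv, rep(c("S1", "S2", "S4"), 3))
})

test_that("four-component rule orders the two low-frequency sounds as S3, S4", {
  cyc <- 1600
  on <- c(outer(c(0, 600, 1040, 1360), c(0, 1600, 3200), "+"))
  off <- c(outer(c(200, 780, 1140, 1460), c(0, 1600, 3200), "+"))
  bs <- boundary_set(on, off)
  freqs <- rep(c(100, 110, 40, 35), 3)
  lab <- recognize_components(group_into_beats(bs, cyc, freqs), bs, freqs, cyc)
  expect_equal(lab, rep(c("S1", "S2", "S3", "S4"), 3))
})

test_that("segmentation assembles named intervals and excludes unknowns", {
  bs <- boundary_set(c(0, 600, 1600, 2200), c(300, 800, 1900, 2400))
  beats <- group_into_beats(bs, 1600)
  lab <- recognize_components(beats, bs, rep(100, 4), 1600)
  seg <- build_segmentation(bs, lab, rep(100, 4), beats, NULL, 2000)
  expect_equal(seg$intervals$name, c("S1S2", "S2S1", "S1S2"))
  expect_true(all(seg$intervals$duration_s > 0))

  segu <- build_segmentation(bs, rep("unknown", 4), rep(100, 4), beats,
                             NULL, 2000)
  expect_equal(nrow(segu$intervals), 0L)
})
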