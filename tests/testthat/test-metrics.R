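test_that("SMR matches the energy-ratio definition and is scale invariant", {
  m <- region_mask(list(c(0, 0)), list(c(1, 1)))
  expect_equal(smr(c(1, 1), m), 0)
  expect_equal(smr(c(2, 1), m), 10 * log10(4))
  expect_equal(smr(c(2, 1) * 3.7, m), smr(c(2, 1), m))
  expect_error(smr(c(1, 0), m), "zero")
  expect_error(region_mask(list(c(0, 5)), list(c(3, 8))), "disjoint")
})

test_that("SMR gain arithmetic and antisymmetry", {
  expect_equal(smr_gain(26.95, 18.35), 8.6)
  expect_equal(smr_gain(18.35, 26.95), -8.6)
  expect_equal(percent_gain(8.66, 6.07), (8.66 - 6.07) / 6.07 * 100)
  expect_equal(percent_gain(5, 5), 0)
  expect_error(percent_gain(1, 0), "zero")
})

test_that("confusion metrics follow their definitions with guarded domains", {
  m <- confusion_metrics(confusion_counts(tp = 2850, fn = 0, fp = 2, tn = 0))
  expect_equal(m$se, 100)
  expect_equal(m$ppv, 2850 / 2852 * 100)
  expect_equal(m$acc, 2850 / 2852 * 100)

  m2 <- confusion_metrics(confusion_counts(tp = 102, fn = 36, fp = 0, tn = 0))
  expect_equal(m2$se, 102 / 138 * 100)
  expect_equal(m2$ppv, 100)

  expect_error(confusion_metrics(confusion_counts(tp = 0, fn = 0, fp = 5)),
               "Se undefined")
  expect_error(confusion_counts(tp = -1), "nonnegative")
})

test_that("detection matching is greedy, one-to-one and tolerance-bounded", {
  truth <- annotations(c("S1", "S2"), c(0, 600), c(200, 800), fs = 2000)
  cc <- match_detections(truth, truth, 0.05)
  expect_equal(cc$tp, 2L); expect_equal(cc$fp, 0L); expect_equal(cc$fn, 0L)

  extra <- annotations(c("S1", "S2", "S3"), c(0, 600, 1200),
                       c(200, 800, 1300), fs = 2000)
  cc <- match_detections(extra, truth, 0.05)
  expect_equal(cc$fp, 1L)

  # shifted by 2x tolerance: both a miss and a false alarm
  shifted <- annotations("S1", 200, 400, fs = 2000)
  one <- annotations("S1", 0, 200, fs = 2000)
  cc <- match_detections(shifted, one, 0.05)
  expect_equal(cc$fn, 1L); expect_equal(cc$fp, 1L)

  # with infinite tolerance equal-length lists always fully match
  cc <- match_detections(shifted, one, Inf)
  expect_equal(cc$fp + cc$fn, 0L)

  # label-aware: time match with wrong label counts as FP + FN
  wrong <- annotations("S2", 0, 200, fs = 2000)
  cc <- match_detections(wrong, one, 0.05, label_aware = TRUE)
  expect_equal(cc$tp, 0L); expect_equal(cc$fp, 1L); expect_equal(cc$fn, 1L)
  expect_equal(label_accuracy(wrong, one), 0)
  expect_error(match_detections(one, one, -1), "nonnegative")
})

test_that("paired t statistic matches hand computation and stats::t.test", {
  x <- c(2, 3, 4, 7); y <- c(1, 2, 3, 5)   # d = 1,1,1,2
  expect_equal(paired_t(x, y), 5.0)
  ref <- unname(stats::t.test(x, y, paired = TRUE)$statistic)
  expect_equal(paired_t(x, y), ref)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(t_critical(0, 5), "alpha")
})
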