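test_that("epe_curve matches hand-computed anchors", {
  # impulse: all energy in the first bin
  imp <- epe_curve(c(5, rep(0, 199)))
  expect_identical(imp$level_index, 0L)
  expect_true(all(imp$values == 1))
  # two entries: squared-envelope fractions 9/25, 1
  two <- epe_curve(c(3, 4), truncate_at = 150)
  expect_equal(two$values, c(0.36, 1.0))
  expect_identical(two$m, 2L)
  # uniform over 150: eps_i = (i+1)/150, first >= 0.9 at i = 134
  uni <- epe_curve(rep(1, 150))
  expect_equal(uni$values, (1:150) / 150)
  expect_identical(uni$level_index, 134L)
})

test_that("epe_curve is a nondecreasing cumulative fraction ending at 1", {
  withr::local_seed(31)
  for (i in 1:20) {
    e <- stats::rnorm(sample(150:400, 1))
    cur <- epe_curve(e)
    expect_identical(cur$m, min(length(e), 150L))
    expect_true(all(diff(cur$values) >= 0))
    expect_true(all(cur$values >= 0 & cur$values <= 1 + 1e-12))
    expect_equal(cur$values[cur$m], 1, tolerance = 1e-12)
  }
})

test_that("epe_curve is scale- and sign-invariant", {
  withr::local_seed(32)
  e <- stats::rnorm(200)
  base <- epe_curve(e)
  # power-of-two rescaling and sign flips are bit-exact
  expect_identical(epe_curve(4 * e)$values, base$values)
  expect_identical(epe_curve(-e)$values, base$values)
  flips <- e * sample(c(-1, 1), length(e), replace = TRUE)
  expect_identical(epe_curve(flips)$values, base$values)
  # arbitrary positive rescaling agrees to rounding
  expect_equal(epe_curve(2.5 * e)$values, base$values, tolerance = 1e-12)
})

test_that("truncation shortens the curve and degenerate input errors", {
  short <- epe_curve(rep(1, 120))          # N < 150 -> M = N, ends at 1
  expect_identical(short$m, 120L)
  expect_equal(short$values[120], 1)
  expect_error(epe_curve(rep(0, 200)), "degenerate")
  expect_error(epe_curve(c(rep(0, 150), rep(1, 50))), "degenerate")
  expect_error(epe_curve(numeric(0)), "empty")
})

test_that("decay_rate is monotone in the level and consistent with 90%", {
  withr::local_seed(33)
  cur <- epe_curve(abs(stats::rnorm(200)) + 0.01)
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)
  rates <- vapply(levels, function(l) decay_rate(cur, l), integer(1))
  expect_true(all(diff(rates) >= 0))
  expect_identical(decay_rate(cur, 0.9), cur$level_index)
  expect_error(decay_rate(cur, 0), "level")
  expect_error(decay_rate(list(), 0.9), "epe_curve")
})

test_that("classify_beat applies the threshold rule on the decay rate", {
  pvc <- classify_beat(generate_beat("pvc"), "teo")
  nor <- classify_beat(generate_beat("normal"), "teo")
  expect_identical(pvc$predicted_label, "pvc")
  expect_identical(nor$predicted_label, "normal")
  # rule boundary: pvc iff decay_rate <= threshold
  at <- classify_beat(generate_beat("normal"), "teo",
                      threshold = nor$decay_rate)
  expect_identical(at$predicted_label, "pvc")
  below <- classify_beat(generate_beat("normal"), "teo",
                         threshold = nor$decay_rate - 1L)
  expect_identical(below$predicted_label, "normal")
  expect_error(classify_beat(generate_beat("normal"), "teo", threshold = -1),
               "threshold")
})

test_that("default thresholds equal the documented calibration rule", {
  expect_identical(default_threshold("teo"), calibrate_threshold("teo"))
  expect_identical(default_threshold("cepstrum"),
                   calibrate_threshold("cepstrum"))
  # and they sit strictly inside the clean preset decay-rate gap
  dr <- function(name, m) classify_beat(generate_beat(name), m)$decay_rate
  for (m in c("teo", "cepstrum")) {
    expect_gt(default_threshold(m), dr("pvc", m))
    expect_lt(default_threshold(m), dr("normal", m))
  }
})

test_that("classify_beatset preserves order and is deterministic", {
  expect_identical(nrow(classify_beatset(beat_set(), "teo")), 0L)
  set <- generate_beatset(25, 25, seed = 3)
  a <- classify_beatset(set, "teo")
  b <- classify_beatset(set, "teo")
  expect_identical(a, b)
  expect_identical(a$beat_id, beat_ids(set))
  expect_identical(a$true_label, beat_labels(set))
  # degenerate beats are reported with their id
  zero <- beat_set(list(ecg_beat(rep(0, 256), 360, beat_id = "flatline")))
  expect_error(classify_beatset(zero, "teo"), "flatline")
})
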