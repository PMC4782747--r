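test_that("gaussian noise hits the target variance and realized SNR", {
  x <- sin(2 * pi * (0:99999) / 50)  # power 1/2
  p <- mean(x^2)
  for (snr in c(0, -5, 10)) {
    y <- add_gaussian_noise(x, fs = 400, snr_db = snr, seed = 5)
    realized <- 10 * log10(p / mean((y - x)^2))
    expect_lt(abs(realized - snr), 0.1)  # law of large numbers at n = 1e5
  }
  # sigma^2 closed form: snr 0 -> P, snr -5 -> P * 10^0.5
  y0 <- add_gaussian_noise(x, 400, 0, seed = 1) - x
  ym5 <- add_gaussian_noise(x, 400, -5, seed = 1) - x
  expect_equal(ym5 / y0, rep(10^0.25, length(x)))
  expect_error(add_gaussian_noise(rep(0, 100), 400, 0), "zero-power")
  expect_error(add_gaussian_noise(x, 400, Inf), "finite")
})

test_that("noise streams are reproducible bit-for-bit from the seed", {
  x <- generate_beat("normal")$samples
  expect_identical(add_gaussian_noise(x, 360, -5, seed = 9),
                   add_gaussian_noise(x, 360, -5, seed = 9))
  set <- generate_beatset(5, 5, seed = 2)
  spec <- noise_spec("gaussian", snr_db = 0, seed = 4)
  expect_identical(beat_matrix(apply_noise(set, spec)),
                   beat_matrix(apply_noise(set, spec)))
})

test_that("sinusoidal interference is exact and deterministic", {
  x <- rep(0, 400)
  expect_identical(add_pli(x, fs = 400, f0 = 50, amplitude = 0), x)
  y <- add_pli(x, fs = 400, f0 = 50, amplitude = 1)
  expect_equal(y, sin(2 * pi * (0:399) / 8))       # 8-sample period
  expect_lt(abs(mean(y)), 1e-12)                   # integer # of periods
  expect_error(add_pli(x, fs = 400, f0 = 200, amplitude = 1), "alias")
  expect_error(add_pli(x, fs = 400, f0 = 50, amplitude = -1), "amplitude")
})

test_that("baseline wander drifts near-monotonically within one window", {
  x <- rep(0, 256)
  y <- add_baseline_wander(x, fs = 360, f0 = 0.1, amplitude = 1, phase = 0)
  # 256 samples at 360 Hz span 7.1% of a 0.1 Hz cycle from phase 0
  expect_true(all(diff(y) > 0))
  expect_equal(y[1], sin(0))                        # DC shift at n=0
  y2 <- add_baseline_wander(x, 360, amplitude = 1, phase = pi / 3)
  expect_equal(y2[1], sin(pi / 3))
  expect_identical(add_baseline_wander(x, 360, amplitude = 0), x)
})

test_that("noise_spec validates and labels its conditions", {
  expect_error(noise_spec("gaussian"), "snr_db")
  expect_error(noise_spec("pli", amplitude = -2), "amplitude")
  s <- noise_spec("pli")
  expect_identical(s$f0, 50)
  expect_identical(s$amplitude_rel, 0.2)
  b <- noise_spec("baseline")
  expect_identical(b$f0, 0.1)
  expect_identical(b$amplitude_rel, 0.5)
  g <- noise_spec("gaussian", snr_db = -5, seed = 1)
  expect_match(g$label, "-5")
})

test_that("relative interference amplitude is common across a set", {
  set <- generate_beatset(4, 4, jitter_cv = 0, seed = 1)
  spec <- noise_spec("pli", amplitude_rel = 0.2)
  noisy <- apply_noise(set, spec)
  added <- beat_matrix(noisy) - beat_matrix(set)
  # every beat received the identical interference waveform
  expect_lt(max(abs(added - added[, 1])), 1e-12)
  # scaled by the set-median peak-to-peak, not each beat's own
  ref <- stats::median(apply(beat_matrix(set), 2, function(s) diff(range(s))))
  expect_equal(max(added[, 1]), 0.2 * ref, tolerance = 1e-3)
})

test_that("detection survives interference and noise inside the documented envelope", {
  set <- study_set(30)
  run <- function(spec) {
    evaluate_detection(classify_beatset(apply_noise(set, spec), "teo"))
  }
  # mains pickup below the envelope-domination knife edge (~0.25 mV)
  pli <- run(noise_spec("pli", amplitude = 0.2))
  expect_gte(pli$sensitivity, 95)
  expect_gte(pli$positive_predictivity, 95)
  # modest baseline wander (a quarter of the typical beat range)
  bw <- run(noise_spec("baseline", amplitude_rel = 0.25))
  expect_gte(bw$sensitivity, 95)
  expect_gte(bw$positive_predictivity, 95)
  # white noise at 0 dB: noise power equal to signal power
  g <- run(noise_spec("gaussian", snr_db = 0, seed = 7))
  expect_gte(g$sensitivity, 95)
  expect_gte(g$positive_predictivity, 95)
})
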