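test_that("beat constructor enforces the window invariants", {
  expect_error(ecg_beat(rep(0.5, 100), fs = 360), "150")
  expect_error(ecg_beat(rep(0.5, 256), fs = 0), "fs")
  expect_error(ecg_beat(rep(0.5, 256), fs = 360, r_index = 256), "r_index")
  expect_error(ecg_beat(rep(0.5, 256), fs = 360, r_index = -1), "r_index")
  b <- ecg_beat(rep(0.5, 256), fs = 360, label = "pvc")
  expect_s3_class(b, "ecg_beat")
  expect_identical(b$r_index, 128L)
})

test_that("beat sets require a common window length and sampling rate", {
  b1 <- ecg_beat(rep(0, 200), 360)
  b2 <- ecg_beat(rep(0, 256), 360)
  b3 <- ecg_beat(rep(0, 200), 250)
  expect_error(beat_set(list(b1, b2)), "window length")
  expect_error(beat_set(list(b1, b3)), "sampling frequency")
  expect_silent(s <- beat_set(list(b1, b1)))
  expect_length(s, 2L)
})

test_that("extract_beats windows symmetrically around the R sample", {
  sig <- as.numeric(0:999)  # value = 0-based index
  set <- extract_beats(sig, fs = 360, r_locations = 501L, window_w = 256)
  b <- set[[1]]
  # 128 samples before the R sample, 128 from it on; R at 0-based offset 128
  expect_identical(b$samples, sig[(501 - 128):(501 + 127)])
  expect_identical(b$r_index, 128L)
  expect_identical(b$samples[b$r_index + 1L], 500)
  expect_identical(attr(set, "skipped"), 0L)
})

test_that("extract_beats skips R peaks too close to the signal edges", {
  sig <- rep(1, 1000)
  set <- extract_beats(sig, fs = 360, r_locations = c(2L, 500L, 990L),
                       window_w = 256)
  expect_length(set, 1L)
  expect_identical(attr(set, "skipped"), 2L)
  expect_identical(attr(set, "skipped_at"), c(2L, 990L))
  # count conservation: beats + skipped = locations
  expect_identical(length(set) + attr(set, "skipped"), 3L)
  # constant signal yields a constant window
  expect_true(all(set[[1]]$samples == 1))
})

test_that("extract_beats validates the window and handles the empty case", {
  expect_error(extract_beats(rep(0, 500), 360, 250L, window_w = 255), "even")
  expect_error(extract_beats(rep(0, 500), 360, 250L, window_w = 100), "150")
  empty <- extract_beats(rep(0.0, 500), 360, integer(0), window_w = 256)
  expect_length(empty, 0L)
  expect_error(extract_beats(rep(0, 500), 360, c(300L, 200L), 256), "sorted")
})

test_that("beat CSV round-trips every field exactly", {
  set <- generate_beatset(2, 2, jitter_cv = 0.05, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_beats_csv(set, path)
  back <- read_beats_csv(path)
  expect_length(back, length(set))
  expect_identical(beat_labels(back), beat_labels(set))
  expect_identical(beat_ids(back), beat_ids(set))
  for (i in seq_len(length(set))) {
    expect_identical(back[[i]]$samples, set[[i]]$samples)  # %.17g is exact
    expect_identical(back[[i]]$fs, set[[i]]$fs)
    expect_identical(back[[i]]$r_index, set[[i]]$r_index)
  }
})

test_that("beat CSV parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_beats_csv(path), "empty")

  header <- paste(c("beat_id,label,fs,r_index",
                    paste0("s", 0:199)), collapse = ",")
  good_row <- paste(c("b1,normal,360,100", rep("0.5", 200)), collapse = ",")
  ragged <- paste(c("b2,pvc,360,100", rep("0.5", 150)), collapse = ",")
  writeLines(c(header, good_row, ragged), path)
  expect_error(read_beats_csv(path), "line 3")

  bad_num <- sub("0.5", "abc", good_row, fixed = TRUE)
  writeLines(c(header, bad_num), path)
  expect_error(read_beats_csv(path), "non-numeric")

  short_header <- paste(c("beat_id,label,fs,r_index",
                          paste0("s", 0:99)), collapse = ",")
  writeLines(c(short_header,
               paste(c("b1,normal,360,50", rep("0", 100)), collapse = ",")),
             path)
  expect_error(read_beats_csv(path), "W = 100")
})
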