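test_that("EEG recordings round-trip through the on-disk layout exactly", {
  set.seed(11)
  rec <- eeg_recording(matrix(rnorm(19 * 600, 0, 10), 19, 600), fs = 300,
                       subject_id = "S01",
                       trials = rbind(trial_annotation(0, 300, 1, "Pa"),
                                      trial_annotation(300, 600, 0, "Pb")))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  back <- read_recording(d, "eeg")
  expect_s3_class(back, "eeg_recording")
  expect_identical(ncol(back$data), 600L)
  expect_identical(back$data, rec$data)          # bit-exact numeric round-trip
  expect_identical(back$trials, rec$trials)
  expect_identical(back$subject_id, "S01")
  expect_equal(back$fs, 300)
  # writing again after reading is idempotent
  d2 <- withr::local_tempdir()
  write_recording(back, d2)
  expect_identical(read_recording(d2, "eeg")$data, rec$data)
})

test_that("ET recordings preserve validity flags, including blink gaps", {
  x <- c(10.5, 20.25, NA, NA, 50.125, 60)
  v <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  rec <- et_recording(x, rev(x), v, fs = 120, screen_size = c(800, 600),
                      trials = trial_annotation(0, 6, 1))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  back <- read_recording(d, "et")
  expect_identical(back$valid, v)
  expect_identical(back$gaze_x, rec$gaze_x)
  expect_identical(back$gaze_y, rec$gaze_y)

  # an all-invalid recording round-trips too
  rec2 <- et_recording(rep(NA_real_, 4), rep(NA_real_, 4), rep(FALSE, 4),
                       fs = 120, screen_size = c(800, 600))
  d2 <- withr::local_tempdir()
  write_recording(rec2, d2)
  expect_identical(read_recording(d2, "et")$valid, rep(FALSE, 4))
})

test_that("EEG and ET share one subject directory without clobbering", {
  cfg <- tiny_strong_cfg(seed = 3)
  recs <- generate_recordings(cfg)[[1]]
  d <- withr::local_tempdir()
  write_recording(recs$eeg, d)
  write_recording(recs$et, d)
  expect_identical(read_recording(d, "eeg")$data, recs$eeg$data)
  expect_identical(read_recording(d, "et")$gaze_x, recs$et$gaze_x)
  expect_identical(read_recording(d, "eeg")$trials, recs$eeg$trials)
  expect_identical(read_recording(d, "et")$trials, recs$et$trials)
})

test_that("malformed inputs are rejected with informative errors", {
  # declared channel names disagree with the data columns
  d <- withr::local_tempdir()
  rec <- eeg_recording(matrix(0, 3, 10), fs = 300)
  write_recording(rec, d)
  meta <- jsonlite::fromJSON(file.path(d, "meta.json"))
  meta$channel_names <- c("a", "b", "c", "d")
  jsonlite::write_json(meta, file.path(d, "meta.json"), auto_unbox = TRUE)
  expect_error(read_recording(d, "eeg"), "channel names")

  # non-positive sampling rate
  meta$channel_names <- NULL
  meta$eeg_fs <- 0
  jsonlite::write_json(meta, file.path(d, "meta.json"), auto_unbox = TRUE)
  expect_error(read_recording(d, "eeg"), "eeg_fs")

  # constructor invariants
  expect_error(eeg_recording(matrix(0, 2, 10), channel_names = "only_one"),
               "channel")
  expect_error(et_recording(1:5, 1:4), "equal length")
  expect_error(trial_annotation(10, 10, 1), "start < end")
  expect_error(trial_annotation(0, 10, 2), "label")
  expect_error(eeg_recording(matrix(0, 2, 10),
                             trials = trial_annotation(5, 20, 1)),
               "within")

  # writing onto a regular file path fails
  f <- withr::local_tempfile()
  writeLines("x", f)
  expect_error(write_recording(rec, f), "not a directory")
})

test_that("extract_trial slices exactly and propagates metadata", {
  set.seed(7)
  rec <- eeg_recording(matrix(rnorm(19 * 600), 19, 600), fs = 300,
                       subject_id = "S09",
                       trials = rbind(trial_annotation(0, 300, 1),
                                      trial_annotation(300, 600, 0)))
  s1 <- extract_trial(rec, rec$trials[1, ])
  s2 <- extract_trial(rec, rec$trials[2, ])
  expect_identical(ncol(s1$data), 300L)
  expect_identical(s1$subject_id, "S09")
  expect_identical(s1$trials$label, 1L)
  # slices are disjoint and concatenate back to the original
  expect_identical(cbind(s1$data, s2$data), rec$data)
  expect_error(extract_trial(rec, trial_annotation(500, 700, 1)),
               "out of bounds")

  et <- et_recording(seq_len(10), seq_len(10) + 100, fs = 120,
                     screen_size = c(800, 600),
                     trials = trial_annotation(2, 6, 0))
  se <- extract_trial(et, et$trials[1, ])
  expect_identical(se$gaze_x, c(3, 4, 5, 6))
})

test_that("read_dataset loads every subject of a generated dataset", {
  cfg <- synth_config_strong(seed = 5, n_subjects = 2, trials_per_subject = 4,
                             trial_duration = 1)
  d <- withr::local_tempdir()
  generate_dataset(cfg, d)
  recs <- read_dataset(d)
  expect_length(recs, 2)
  expect_s3_class(recs[[1]]$eeg, "eeg_recording")
  expect_s3_class(recs[[2]]$et, "et_recording")
  expect_identical(nrow(recs[[1]]$eeg$trials), 4L)
})
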