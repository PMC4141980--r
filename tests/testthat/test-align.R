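test_that("clock alignment recovers a known offset from aperiodic pulses", {
  a <- cumsum(c(10, 5, 8, 13, 6, 11, 17, 7, 12))
  off <- 123.4
  al <- align_clocks(a, a + off)
  expect_equal(al$offset_s, off, tolerance = 1e-12)
  expect_equal(al$n_matched, length(a))
  expect_lt(al$residual_s, 1e-9)
})

test_that("alignment works with partial overlap and jitter", {
  set.seed(11)
  a <- cumsum(c(10, 5, 8, 13, 6, 11, 17, 7, 12, 19, 9))
  off <- -42.25
  b <- a[4:11] + off + runif(8, -0.02, 0.02)
  al <- align_clocks(a, b)
  expect_equal(al$offset_s, off, tolerance = 0.05)
  expect_equal(al$n_matched, 8)
})

test_that("periodic pulses are flagged ambiguous, disjoint ones unmatched", {
  per <- seq(0, 90, by = 10)
  expect_error(align_clocks(per, per + 3), class = "neodot_ambiguity_error")
  a <- cumsum(c(10, 5, 8, 13))
  expect_error(align_clocks(a, a * 3 + 1000),
               class = "neodot_alignment_error")
  expect_error(align_clocks(c(1, 2), c(1, 2, 3)),
               class = "neodot_alignment_error")
})

test_that("annotation alignment moves onsets onto the DOT clock", {
  b <- simulate_recording(seed = 5, n_events = 2, duration_s = 900,
                          nuisance = silent_nuisance())
  expect_equal(b$annotation_clock, "eeg")
  ba <- align_annotations(b)
  expect_equal(ba$annotation_clock, "dot")
  al <- attr(ba, "alignment")
  expect_equal(al$offset_s, b$truth$clock_offset_s, tolerance = 1e-9)
  # shifted onsets match the scheduled DOT-clock onsets
  am <- ba$eeg_annotations[ba$eeg_annotations$annotator_id == "AM", ]
  expect_equal(sort(am$onset_s), sort(b$truth$schedule$am_onset_s),
               tolerance = 1e-9)
  # idempotent once on the DOT clock
  expect_identical(align_annotations(ba)$eeg_annotations, ba$eeg_annotations)
})

test_that("consensus onset averages annotators and falls back to one", {
  expect_equal(consensus_onset(136, 141), 138.5)
  expect_equal(consensus_onset(2539, NA), 2539)
  expect_equal(consensus_onset(c(10, 20, NA)), 15)
  expect_error(consensus_onset(NA, NA), class = "neodot_validation_error")
})

test_that("consensus_onsets adds the column and validates the schema", {
  ev <- tibble::tibble(event_id = 1:2, am_onset_s = c(10, NA),
                       dh_onset_s = c(20, 50))
  out <- consensus_onsets(ev)
  expect_equal(out$consensus_onset_s, c(15, 50))
  expect_error(consensus_onsets(tibble::tibble(event_id = 1)),
               class = "neodot_format_error")
})

test_that("annotation tables round-trip and are validated on read", {
  ev <- tibble::tibble(event_id = 1:2, am_onset_s = c(10, 30),
                       dh_onset_s = c(12, NA), eeg_duration_s = c(5, 8),
                       label = c("seizure", "possible-seizure"))
  path <- file.path(withr::local_tempdir(), "ann.csv")
  write_annotation_table(ev, path)
  back <- read_annotation_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))
  bad <- ev
  bad$eeg_duration_s[1] <- -1
  write_annotation_table(bad, path)
  expect_error(read_annotation_table(path),
               class = "neodot_validation_error")
  expect_error(read_annotation_table("no/such/file.csv"),
               class = "neodot_io_error")
})

test_that("bundled case timings table loads with the documented schema", {
  tab <- case_event_timings()
  expect_equal(nrow(tab), 7)
  expect_true(all(c("event_id", "am_onset_s", "dh_onset_s",
                    "consensus_onset_s", "eeg_duration_s",
                    "time_to_hbt_max_s", "time_max_to_min_s",
                    "time_min_to_recovery_s", "dot_event_duration_s")
                  %in% names(tab)))
})
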