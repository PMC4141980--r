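test_that("waveform extrema land exactly on the programmed knots", {
  p <- biphasic_response(onset_s = 300, t_rise_s = 12.5, t_fall_s = 116,
                         t_recover_s = 123, pre_onset_lead_s = 0)
  t <- seq(0, 900, by = 0.1)
  w <- make_response_waveform(p, t)
  expect_equal(t[which.max(w$hbt)], 312.5)
  expect_equal(t[which.min(w$hbt)], 312.5 + 116)
  # zero before onset and after full recovery
  expect_true(all(w$hbt[t <= 299.9] == 0))
  expect_true(all(abs(w$hbt[t > 300 + 12.5 + 116 + 123]) < 1e-12))
})

test_that("waveform amplitudes and undershoot scale as programmed", {
  p <- biphasic_response(onset_s = 200, amplitude_hbo_uM = 1.7,
                         amplitude_hbr_uM = 1.0, undershoot_scale = 1.3,
                         pre_onset_lead_s = 0)
  t <- seq(0, 700, by = 0.05)
  w <- make_response_waveform(p, t)
  expect_equal(max(w$hbo), 1.7, tolerance = 1e-6)
  expect_equal(max(w$hbr), 1.0, tolerance = 1e-6)
  expect_equal(max(w$hbt), 2.7, tolerance = 1e-6)
  expect_equal(min(w$hbt), -1.3 * 2.7, tolerance = 1e-6)
  # hbt is always the sum, never independent
  expect_equal(w$hbt, w$hbo + w$hbr)
})

test_that("waveform is C1: numerical derivative has no jumps at the knots", {
  p <- biphasic_response(onset_s = 200, pre_onset_lead_s = 5)
  t <- seq(0, 600, by = 0.01)
  w <- make_response_waveform(p, t)
  d <- diff(w$hbt) / 0.01
  # largest derivative jump between consecutive samples stays of the order
  # of the sampling resolution (a C0-only kink would give an O(1) jump)
  expect_lt(max(abs(diff(d))), 0.01)
})

test_that("pre-onset lead starts the rise early", {
  p <- biphasic_response(onset_s = 200, t_rise_s = 15, pre_onset_lead_s = 5)
  t <- seq(0, 600, by = 0.1)
  w <- make_response_waveform(p, t)
  expect_gt(w$hbt[which.min(abs(t - 199))], 0)  # rising before the onset
  expect_equal(t[which.max(w$hbt)], 210) # peak at onset - lead + t_rise
})

test_that("waveform parameter validation", {
  expect_error(biphasic_response(t_rise_s = 0),
               class = "neodot_validation_error")
  expect_error(biphasic_response(pre_onset_lead_s = -1),
               class = "neodot_validation_error")
  expect_error(biphasic_response(amplitude_hbo_uM = Inf),
               class = "neodot_validation_error")
  p <- biphasic_response(onset_s = 100)
  expect_error(make_response_waveform(p, seq(50, 200, by = 0.1)),
               class = "neodot_validation_error")   # axis too short
  expect_error(make_response_waveform(p, c(0, 1, 3, 700)),
               class = "neodot_validation_error")   # non-uniform
})

test_that("event schedule is reproducible and non-overlapping", {
  s1 <- make_event_schedule(7, 3600, seed = 42)
  s2 <- make_event_schedule(7, 3600, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 7)
  expect_true(all(diff(s1$consensus_onset_s) > 0))
  expect_true(all(s1$consensus_onset_s[-7] + s1$eeg_duration_s[-7]
                  <= s1$consensus_onset_s[-1]))
  # consensus equals the annotator mean (single-annotator rule included)
  expect_equal(s1$consensus_onset_s,
               consensus_onsets(s1[, 1:4])$consensus_onset_s)
})

test_that("schedule validation rejects impossible requests", {
  expect_error(make_event_schedule(0), class = "neodot_validation_error")
  expect_error(make_event_schedule(3, recording_duration_s = 100),
               class = "neodot_validation_error")
})
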