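test_that("event baseline is the pre-onset window mean", {
  fs <- 10
  t <- (0:1999) / fs
  trace <- 2 * t
  expect_equal(event_baseline(trace, fs, onset_s = 100),
               2 * mean(t[t >= 40 & t < 70]))
  expect_error(event_baseline(trace, fs, 100, window = c(-30, -60)),
               class = "neodot_validation_error")
  expect_error(event_baseline(trace, fs, onset_s = 30),
               class = "neodot_validation_error")  # window before t = 0
})

test_that("response metrics recover pure-waveform phases to 0.1 s", {
  w <- waveform_global(onset_s = 300, duration_s = 900)
  m <- response_metrics(w$hbt, 10, onset_s = 300)
  expect_lt(abs(m$time_to_hbt_max_s - 12.5), 0.1)
  expect_lt(abs(m$time_max_to_min_s - 116), 0.1)
  expect_lt(abs(m$time_min_to_recovery_s - 123), 0.1)
  expect_equal(m$dot_event_duration_s,
               m$time_to_hbt_max_s + m$time_max_to_min_s +
                 m$time_min_to_recovery_s)
  expect_false(m$unresponsive)
  expect_false(m$censored)
  expect_equal(m$peak_uM, 2.7, tolerance = 1e-3)
  expect_equal(m$trough_uM, -1.3 * 2.7, tolerance = 0.05)
})

test_that("response metrics are invariant to constant offsets and delays", {
  w <- waveform_global(onset_s = 300, duration_s = 900)
  m0 <- response_metrics(w$hbt, 10, 300)
  m_shift <- response_metrics(w$hbt + 57.3, 10, 300)
  expect_equal(m_shift, m0)
  w2 <- waveform_global(onset_s = 400, duration_s = 1000)
  m_delay <- response_metrics(w2$hbt, 10, 400)
  phases <- c("time_to_hbt_max_s", "time_max_to_min_s",
              "time_min_to_recovery_s")
  for (p in phases) {
    expect_lt(abs(m_delay[[p]] - m0[[p]]), 0.05)
  }
})

test_that("a flat trace is flagged unresponsive", {
  set.seed(4)
  trace <- rnorm(9000, 0, 0.01)
  m <- response_metrics(trace, 10, onset_s = 300)
  expect_true(m$unresponsive)
  expect_true(is.na(m$time_to_hbt_max_s))
})

test_that("phases running into the next event are censored, not guessed", {
  w <- waveform_global(onset_s = 300, duration_s = 900)
  # next onset before the trough is reached
  m <- response_metrics(w$hbt, 10, 300, next_onset_s = 330)
  expect_true(m$censored)
  expect_true(is.na(m$time_max_to_min_s))
  # next onset after the trough but before recovery
  m2 <- response_metrics(w$hbt, 10, 300, next_onset_s = 470)
  expect_true(m2$censored)
  expect_false(is.na(m2$time_max_to_min_s))
  expect_true(is.na(m2$time_min_to_recovery_s))
})

test_that("inter-ictal detrending recovers the drift exactly", {
  fs <- 10
  t <- (0:11999) / fs
  bump <- ifelse(t >= 300 & t <= 500, sin(pi * (t - 300) / 200), 0)
  trace <- 4 + 0.01 * t + bump
  d <- detrend_interictal(trace, t, onsets = 350)
  expect_equal(d$slope, 0.01, tolerance = 1e-9)
  expect_equal(d$intercept, 4, tolerance = 1e-7)
  expect_lt(max(abs(d$detrended[t > 600] - 0)), 1e-7)
  expect_error(detrend_interictal(trace, t, onsets = 350,
                                  pre_s = 1e4, post_s = 1e4),
               class = "neodot_validation_error")
})

test_that("seizure event table assembles per-event rows with peaks", {
  fs <- 10
  t <- seq(0, 1800, by = 1 / fs)
  p1 <- biphasic_response(onset_s = 300, t_rise_s = 12.5, t_fall_s = 116,
                          t_recover_s = 123, pre_onset_lead_s = 0)
  p2 <- biphasic_response(onset_s = 1100, t_rise_s = 12.5, t_fall_s = 116,
                          t_recover_s = 123, pre_onset_lead_s = 0)
  w <- make_response_waveform(p1, t)
  w2 <- make_response_waveform(p2, t)
  global <- tibble::tibble(time_s = t, hbo = w$hbo + w2$hbo,
                           hbr = w$hbr + w2$hbr, hbt = w$hbt + w2$hbt)
  events <- tibble::tibble(event_id = 1:2,
                           consensus_onset_s = c(300, 1100),
                           eeg_duration_s = c(100, 120))
  tab <- seizure_event_table(global, events, fs)
  expect_s3_class(tab, "seizure_event_table")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("event_id", "consensus_onset_s", "eeg_duration_s",
                    "time_to_hbt_max_s", "time_max_to_min_s",
                    "time_min_to_recovery_s", "dot_event_duration_s",
                    "peak_hbt_uM", "peak_hbo_uM", "peak_hbr_uM",
                    "unresponsive", "censored") %in% names(tab)))
  expect_lt(max(abs(tab$time_to_hbt_max_s - 12.5)), 0.1)
  expect_equal(tab$peak_hbt_uM, c(2.7, 2.7), tolerance = 1e-2)
  expect_equal(tab$peak_hbo_uM, c(1.7, 1.7), tolerance = 1e-2)
  expect_equal(tab$peak_hbr_uM, c(1.0, 1.0), tolerance = 1e-2)
  expect_false(any(tab$censored))
  expect_error(seizure_event_table(global, events[0, ], fs),
               class = "neodot_validation_error")
})

test_that("channel peak amplitudes reference 30 s pre-onset, per channel", {
  fs <- 10
  t <- (0:5999) / fs
  bump <- ifelse(t >= 300 & t <= 330, 0.8 * sin(pi * (t - 300) / 30)^2, 0)
  hbo <- cbind(0.2 + bump, rep(0.5, length(t)), 0.1 + 2 * bump)
  hs <- haemo_series(hbo, -hbo / 2, fs)
  amp <- channel_peak_amplitudes(hs, onset_s = 300)
  expect_equal(amp$channel, 1:3)
  expect_equal(amp$hbo, c(0.8, 0, 1.6), tolerance = 1e-6)
  # hbr = -hbo/2 here, so the per-chromophore peaks (each taken at its own
  # argmax) are 0 for HbR and half the HbO peak for HbT
  expect_equal(amp$hbr, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(amp$hbt, c(0.4, 0, 0.8), tolerance = 1e-6)
  masked <- channel_peak_amplitudes(hs, 300,
                                    channel_mask = c(TRUE, FALSE, TRUE))
  expect_equal(masked$channel, c(1L, 3L))
  expect_error(channel_peak_amplitudes(hs, onset_s = 5),
               class = "neodot_validation_error")
})

test_that("event summary statistics match closed forms", {
  events <- tibble::tibble(
    time_to_hbt_max_s = c(10, 14), time_max_to_min_s = c(100, 120),
    time_min_to_recovery_s = c(120, NA), dot_event_duration_s = c(230, 134),
    peak_hbo_uM = c(1, 3), peak_hbr_uM = c(0.5, 1.5),
    peak_hbt_uM = c(1.5, 4.5))
  s <- summarize_events(events)
  r <- s[s$metric == "time_to_hbt_max_s", ]
  expect_equal(r$mean, 12)
  expect_equal(r$sd, sd(c(10, 14)))
  expect_equal(r$max, 14)
  rec <- s[s$metric == "time_min_to_recovery_s", ]
  expect_equal(rec$n, 1)
  expect_equal(rec$sd, 0)   # single estimable value: sd defined as 0
  expect_true(all(s$max >= s$mean, na.rm = TRUE))
  expect_error(summarize_events(events[0, ]),
               class = "neodot_validation_error")
})

test_that("hemispheric paired t-test matches the hand-computed statistic", {
  left <- c(2, 4, 6)
  right <- c(1, 2, 3)     # differences 1, 2, 3
  res <- hemispheric_power_test(left, right)
  expect_equal(res$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$mean_difference, 2)
  expect_equal(res$n_pairs, 3)
})

test_that("hemispheric test rejects unusable inputs", {
  expect_error(hemispheric_power_test(1:3, 1:4),
               class = "neodot_validation_error")
  expect_error(hemispheric_power_test(5, 4),
               class = "neodot_validation_error")
  expect_error(hemispheric_power_test(c(1, 2, 3), c(1, 2, 3)),
               class = "neodot_degenerate_error")
})

test_that("channel power and null-power simulation behave", {
  x <- matrix(c(1, -1, 2, -2), 2, 2)
  expect_equal(channel_power(x), c(1, 4))
  expect_equal(channel_power(c(3, 4)), 12.5)
  p1 <- simulate_null_powers(50, seed = 11)
  p2 <- simulate_null_powers(50, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1$left > 0) && all(p1$right > 0))
  expect_length(p1$left, 50)
})
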