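fake_events <- function() {
  out <- tibble::tibble(
    event_id = 1:2, consensus_onset_s = c(300, 1100),
    eeg_duration_s = c(100, 120),
    time_to_hbt_max_s = c(12, 14), time_max_to_min_s = c(110, 120),
    time_min_to_recovery_s = c(120, NA),
    dot_event_duration_s = c(242, 134),
    peak_hbt_uM = c(2.5, 2.9), peak_hbo_uM = c(1.6, 1.8),
    peak_hbr_uM = c(0.9, 1.1),
    unresponsive = c(FALSE, FALSE), censored = c(FALSE, TRUE))
  class(out) <- c("seizure_event_table", class(out))
  out
}

fake_global <- function() {
  t <- seq(0, 1500, by = 1)
  tibble::tibble(time_s = t, hbo = sin(t / 100), hbr = cos(t / 100) / 2,
                 hbt = sin(t / 100) + cos(t / 100) / 2)
}

test_that("snapshot times chain the phases and drop missing ones", {
  ev <- fake_events()
  st <- event_snapshot_times(ev[1, ])
  expect_named(st, c("pre_onset", "onset", "hbt_max", "midpoint",
                     "hbt_min", "recovery"))
  expect_equal(unname(st["onset"]), 300)
  expect_equal(unname(st["hbt_max"]), 312)
  expect_equal(unname(st["hbt_min"]), 422)
  expect_equal(unname(st["recovery"]), 542)
  expect_equal(unname(st["midpoint"]), (312 + 422) / 2)
  st2 <- event_snapshot_times(ev[2, ])
  expect_false("recovery" %in% names(st2))
})

test_that("nearest frame matching warns beyond tolerance", {
  ft <- seq(0, 100, by = 1)
  expect_equal(nearest_frames(c(3.2, 50), ft), c(4L, 51L))
  expect_warning(nearest_frames(150, ft), "nearest frames substituted")
})

test_that("report renders tables, JSON and figures consistently", {
  out_dir <- withr::local_tempdir()
  ev <- fake_events()
  img <- haemo_image_series(matrix(rnorm(1501 * 5), 1501, 5),
                            matrix(rnorm(1501 * 5), 1501, 5),
                            seq(0, 1500, by = 1), 0.1)
  files <- build_report(ev, fake_global(), out_dir, images = img)
  expect_true(all(file.exists(unlist(files))))
  back <- tibble::as_tibble(data.table::fread(files$events_csv))
  expect_equal(back$dot_event_duration_s, ev$dot_event_duration_s)
  js <- jsonlite::read_json(files$summary_json, simplifyVector = TRUE)
  expect_equal(js$events$peak_hbt_uM, ev$peak_hbt_uM)
  expect_equal(js$summary$mean[js$summary$metric == "time_to_hbt_max_s"], 13)
  snaps <- data.table::fread(files$snapshots_csv)
  expect_true(all(snaps$snapshot %in% c("pre_onset", "onset", "hbt_max",
                                        "midpoint", "hbt_min", "recovery")))
  expect_true(all(snaps$hbt_spatial_max_uM >= snaps$hbt_spatial_min_uM))
  expect_message(build_report(ev, fake_global(), out_dir), "traces only")
  expect_error(build_report(ev[0, ], fake_global(), out_dir),
               class = "neodot_validation_error")
})

test_that("plot and broom-style methods return the right shapes", {
  ev <- fake_events()
  p <- plot_global_traces(fake_global(), onsets = ev$consensus_onset_s)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  td <- generics::tidy(ev)
  expect_false(inherits(td, "seizure_event_table"))
  expect_equal(nrow(td), 2)
  g <- generics::glance(ev)
  expect_equal(g$n_events, 2)
  expect_equal(g$n_censored, 1)
  expect_equal(g$mean_peak_hbt_uM, 2.7)
  hs <- haemo_series(matrix(rnorm(200), 100, 2), matrix(rnorm(200), 100, 2),
                     10)
  expect_s3_class(ggplot2::autoplot(hs, channels = 1), "ggplot")
})
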