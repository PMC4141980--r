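test_that("rendering is deterministic for a fixed seed", {
  b1 <- simulate_recording(seed = 3, n_events = 2, duration_s = 1200)
  b2 <- simulate_recording(seed = 3, n_events = 2, duration_s = 1200)
  expect_identical(b1$intensity, b2$intensity)
  expect_identical(b1$truth$schedule, b2$truth$schedule)
  b3 <- simulate_recording(seed = 4, n_events = 2, duration_s = 1200)
  expect_false(identical(b1$intensity, b3$intensity))
})

test_that("a silent zero-amplitude scene renders constant intensities", {
  b <- simulate_recording(seed = 1, n_events = 1, duration_s = 900,
                          nuisance = silent_nuisance(),
                          channel_peak_hbo_uM = 0, channel_peak_hbr_uM = 0)
  expect_equal(max(b$intensity) - min(b$intensity), 0, tolerance = 1e-12)
})

test_that("channel concentrations round-trip through render + MBLL", {
  b <- simulate_recording(seed = 2, n_events = 1, duration_s = 900,
                          nuisance = silent_nuisance())
  od <- to_optical_density(b)
  haemo <- mbll_convert(od, b$probe)
  # the OD reference is the channel mean, so each recovered channel trace
  # equals the truth up to one constant per channel
  delta_hbo <- haemo$hbo - b$truth$channel_hbo
  delta_hbr <- haemo$hbr - b$truth$channel_hbr
  expect_lt(max(apply(delta_hbo, 2, function(x) diff(range(x)))), 1e-9)
  expect_lt(max(apply(delta_hbr, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("nuisance components appear where programmed", {
  nu <- nuisance_model(step_time_s = 300, step_channels = 5L,
                       step_log_size = 0.5, dead_channels = 2L)
  b <- simulate_recording(seed = 6, n_events = 1, duration_s = 900,
                          nuisance = nu)
  t <- time_axis(b)
  # step: intensity drops by exp(-0.5) on channel 5 after 300 s; compare
  # windows clear of both the step and the first event response
  onset <- b$truth$schedule$consensus_onset_s[1]
  post <- t > 300.5 & t < onset - 10
  pre <- t > 280 & t < 299.5
  ratio <- mean(b$intensity[post, 5, 1]) / mean(b$intensity[pre, 5, 1])
  expect_equal(log(ratio), -0.5, tolerance = 0.01)
  # dead channel sits at the noise floor
  expect_lt(mean(b$intensity[, 2, 1]), 0.001)
  expect_gt(mean(b$intensity[, 1, 1]), 0.5)
})

test_that("default nuisance matches its documented composition", {
  nu <- default_nuisance()
  expect_equal(nu$dead_channels, c(7L, 19L, 33L, 50L))
  expect_equal(nu$step_channels, c(2L, 11L, 23L, 37L, 48L))
  expect_equal(nu$noise_sd, 0.001)
  # silent nuisance is the all-zero model
  s <- silent_nuisance()
  expect_equal(s$noise_sd, 0)
  expect_equal(s$drift_slope_uM_per_s, 0)
  expect_equal(s$cardiac_amplitude_uM, 0)
  expect_length(s$dead_channels, 0)
})

test_that("scene and nuisance validation", {
  expect_error(nuisance_model(noise_sd = -1),
               class = "neodot_validation_error")
  sched <- make_event_schedule(1, 900, seed = 1)
  expect_error(make_scene(sched, duration_s = -5),
               class = "neodot_validation_error")
  expect_error(
    make_scene(sched, duration_s = 900,
               nuisance = nuisance_model(step_time_s = 1e5,
                                         step_channels = 1L)),
    class = "neodot_validation_error")
})

test_that("spatial pattern normalises weights and reports its centroid", {
  mesh <- coarse_slab()
  pat <- spatial_pattern(mesh, center = c(30, 20, 5), focal_radius_mm = 8,
                         surround_weight = 0)
  expect_s3_class(pat, "spatial_pattern")
  expect_equal(max(pat$weights), 1)
  expect_true(all(pat$weights >= 0))
  expect_lt(sqrt(sum((pat$centroid - c(30, 20, 5))^2)), 4)
  expect_error(spatial_pattern(mesh, focal_radius_mm = -1),
               class = "neodot_validation_error")
  expect_error(spatial_pattern(mesh, center = c(1e4, 0, 0)),
               class = "neodot_validation_error")
})
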