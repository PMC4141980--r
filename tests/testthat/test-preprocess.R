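test_that("pruning drops the dead channels of the default nuisance", {
  b <- simulate_recording(seed = 1, n_events = 1, duration_s = 1200)
  pruned <- prune_channels(b)
  q <- pruned$channel_quality
  expect_equal(sum(q$retained), 54)
  expect_equal(which(!q$retained), c(7L, 19L, 33L, 50L))
  expect_true(all(q$reason[!q$retained] == "low mean intensity"))
  # data on retained channels untouched
  expect_identical(pruned$intensity, b$intensity)
})

test_that("pruning validates thresholds and refuses to drop everything", {
  b <- simulate_recording(seed = 1, n_events = 1, duration_s = 900,
                          nuisance = silent_nuisance())
  expect_error(prune_channels(b, min_mean_intensity = -1),
               class = "neodot_validation_error")
  expect_error(prune_channels(b, min_mean_intensity = 1e6),
               class = "neodot_pipeline_error")
  expect_equal(sum(prune_channels(b)$channel_quality$retained), 58)
})

test_that("qc report carries mean intensities per wavelength", {
  b <- simulate_recording(seed = 1, n_events = 1, duration_s = 1200)
  qc <- qc_report(prune_channels(b))
  expect_equal(nrow(qc), 58)
  expect_true(all(c("mean_intensity_780nm", "mean_intensity_850nm")
                  %in% names(qc)))
})

test_that("low-pass filter: passband flat, stopband attenuated, DC exact", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * t)
  fast <- sin(2 * pi * 2.5 * t)
  mid <- 400:5600   # interior, away from edges
  ys <- lowpass_dot(slow, fs, cutoff_hz = 1)
  yf <- lowpass_dot(fast, fs, cutoff_hz = 1)
  expect_equal(ys[mid], slow[mid], tolerance = 0.01)     # within 1%
  atten_db <- 20 * log10(sd(yf[mid]) / sd(fast[mid]))
  expect_lt(atten_db, -20)                               # >= 20 dB down
  cst <- rep(3.7, length(t))
  expect_equal(lowpass_dot(cst, fs, 1), cst, tolerance = 1e-9)
})

test_that("low-pass filter handles matrices/arrays and bad cut-offs", {
  fs <- 10
  x <- matrix(rnorm(2000), 1000, 2)
  y <- lowpass_dot(x, fs, 1)
  expect_equal(dim(y), dim(x))
  expect_equal(y[, 1], lowpass_dot(x[, 1], fs, 1))
  expect_error(lowpass_dot(x, fs, cutoff_hz = 6),
               class = "neodot_validation_error")  # above Nyquist
})

test_that("filtfilt padding suppresses edge transients on offset traces", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  x <- 5 + 0.2 * sin(2 * pi * 0.02 * t)   # large DC offset, slow content
  y <- lowpass_dot(x, fs, cutoff_hz = 1)
  expect_lt(max(abs(y - x)), 0.01)        # no multi-unit edge ringing
})

test_that("spline correction removes a step to well under its size", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  clean <- 0.02 * sin(2 * pi * 0.01 * t)
  step <- ifelse(t >= 300, 0.5, 0)
  corrected <- spline_correct(clean + step, c(295, 305), fs)
  expect_lt(max(abs(corrected - clean)), 0.025)
  # residual step across the window edges is tiny
  expect_lt(abs(mean(corrected[t > 306 & t < 316]) -
                  mean(corrected[t > 284 & t < 294])), 0.01)
})

test_that("spline correction validates windows", {
  fs <- 10
  x <- rnorm(1000)
  expect_warning(spline_correct(x, c(2000, 2010), fs), "no samples")
  expect_error(spline_correct(x, c(0, 1e4), fs),
               class = "neodot_validation_error")
})

test_that("artifact detector flags a variance burst and only that", {
  set.seed(9)
  fs <- 10
  x <- rnorm(6000, 0, 0.01)
  x[3000:3050] <- x[3000:3050] + rnorm(51, 0, 1)
  w <- detect_artifact_windows(x, fs)
  expect_equal(nrow(w), 1)
  expect_lt(abs(w$t0 - 299.9), 3)
  expect_lt(abs(w$t1 - 305), 3)
  expect_equal(nrow(detect_artifact_windows(rnorm(6000, 0, 0.01), fs)), 0)
})

test_that("optical density uses the mean-intensity reference", {
  b <- simulate_recording(seed = 2, n_events = 1, duration_s = 900,
                          nuisance = silent_nuisance())
  od <- to_optical_density(b)
  expect_s3_class(od, "od_series")
  expect_equal(od$reference[1, 1], mean(b$intensity[, 1, 1]))
  # -ln(I / mean(I)) has zero mean in the small-signal linearisation and
  # is exactly zero for a constant trace
  cst <- b
  cst$intensity[] <- 2.5
  odc <- to_optical_density(cst)
  expect_equal(max(abs(odc$delta_od)), 0)
})

test_that("full preprocessing returns consistent components", {
  b <- simulate_recording(seed = 3, n_events = 2, duration_s = 1200)
  pre <- preprocess_bundle(b)
  expect_named(pre, c("bundle", "od", "haemo", "global", "qc"))
  expect_equal(sum(pre$qc$retained), 54)
  expect_equal(pre$bundle$annotation_clock, "dot")
  expect_equal(nrow(pre$global), dim(b$intensity)[1])
  expect_equal(pre$global$hbt, pre$global$hbo + pre$global$hbr)
  # step-affected channels are excluded from nothing by default, but the
  # spline correction path runs when windows are supplied
  win <- tibble::tibble(t0 = 1075, t1 = 1085, channels = list(2L))
  expect_silent(preprocess_bundle(
    simulate_recording(seed = 3, n_events = 1, duration_s = 1200),
    artifact_windows = win))
})
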