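#' Optical density change series
#'
#' Dimensionless optical-density changes relative to each channel's mean
#' intensity over the whole acquisition, \eqn{\Delta OD = -\ln(I/\bar I)}.
#'
#' @param delta_od `time x channel x wavelength` array.
#' @param reference `channel x wavelength` matrix of mean intensities.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param wavelengths Wavelengths (nm).
#' @return An `od_series`.
#' @export
od_series <- function(delta_od, reference, sample_rate_hz, wavelengths) {
  if (any(!is.finite(delta_od))) {
    stop_neodot("delta_od must be finite", "neodot_validation_error")
  }
  if (mean(reference) <= 0) {
    stop_neodot("reference intensities must be positive on average",
                "neodot_validation_error")
  }
  structure(list(delta_od = delta_od, reference = reference,
                 sample_rate_hz = sample_rate_hz, wavelengths = wavelengths),
            class = "od_series")
}

#' @method print od_series
#' @export
print.od_series <- function(x, ...) {
  d <- dim(x$delta_od)
  cat(sprintf("<od_series> %d samples x %d channels x %d wavelengths @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate_hz))
  invisible(x)
}

#' Flag low-intensity channels
#'
#' Channels exhibiting very low optical intensity (poor optode coupling)
#' carry no usable signal and are excluded before analysis. A channel is
#' flagged when its mean intensity at either wavelength falls below
#' `min_mean_intensity`, which defaults to 1% of the median channel mean at
#' that wavelength. Pruning only updates the quality flags; retained
#' channels' data are untouched.
#'
#' @param bundle A [recording_bundle()].
#' @param min_mean_intensity Absolute intensity floor, or `NULL` for the
#'   relative default.
#' @param rel_floor Relative floor (fraction of the median channel mean) used
#'   when `min_mean_intensity` is `NULL`.
#' @return The bundle with updated `channel_quality`; errors if nothing
#'   would remain.
#' @export
prune_channels <- function(bundle, min_mean_intensity = NULL,
                           rel_floor = 0.01) {
  if (!is.null(min_mean_intensity) && min_mean_intensity <= 0) {
    stop_neodot("intensity threshold must be > 0", "neodot_validation_error")
  }
  if (is.null(min_mean_intensity) && rel_floor <= 0) {
    stop_neodot("rel_floor must be > 0", "neodot_validation_error")
  }
  d <- dim(bundle$intensity)
  mean_int <- apply(bundle$intensity, c(2, 3), mean)   # channel x wavelength
  thr <- if (!is.null(min_mean_intensity)) {
    matrix(min_mean_intensity, d[2], d[3], byrow = TRUE)
  } else {
    matrix(rel_floor * apply(mean_int, 2, median), d[2], d[3], byrow = TRUE)
  }
  low <- apply(mean_int < thr, 1, any)
  q <- bundle$channel_quality
  newly <- low & q$retained
  q$retained <- q$retained & !low
  q$reason[newly] <- "low mean intensity"
  if (!any(q$retained)) {
    stop_neodot(sprintf(
      "all %d channels fall below the intensity floor; check acquisition (median channel mean %.3g)",
      d[2], median(mean_int)), "neodot_pipeline_error")
  }
  bundle$channel_quality <- q
  bundle
}

#' Channel quality-control report
#' @param bundle A [recording_bundle()].
#' @return Tibble with per-channel mean intensities per wavelength, retained
#'   flag and exclusion reason.
#' @export
qc_report <- function(bundle) {
  mean_int <- apply(bundle$intensity, c(2, 3), mean)
  out <- tibble::as_tibble(mean_int, .name_repair = "minimal")
  names(out) <- paste0("mean_intensity_", bundle$probe$wavelengths, "nm")
  dplyr::bind_cols(bundle$channel_quality, out)
}

#' Spline correction of a flagged artifact segment
#'
#' Correction for step-like recording artifacts, following the
#' smoothing-spline motion-artifact approach: within the flagged window a
#' flexible smoothing spline is fitted to the trace and subtracted (treating
#' the windowed structure as artifact), the segment is re-levelled to join
#' the mean of the data just before the window, and - because a step is a
#' persistent level change - the data after the window are level-shifted so
#' the segments join continuously (`tail = "shift"`). Use `tail = "keep"`
#' to leave post-window data untouched.
#'
#' @param trace Numeric vector (one channel's intensity or OD trace).
#' @param window `c(t0, t1)` artifact window in seconds.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param p Spline flexibility in (0, 1]; 1 interpolates. Default 0.99
#'   (near-interpolating, so the windowed content is removed wholesale).
#' @param join_s Length (s) of the pre-/post-window segments whose means
#'   define the joining levels.
#' @param tail `"shift"` (default) or `"keep"`.
#' @return Corrected numeric vector of the same length.
#' @export
spline_correct <- function(trace, window, sample_rate_hz, p = 0.99,
                           join_s = 5, tail = c("shift", "keep")) {
  tail <- match.arg(tail)
  n <- length(trace)
  t <- (seq_len(n) - 1) / sample_rate_hz
  idx <- which(t >= window[1] & t <= window[2])
  if (!length(idx)) {
    rlang::warn("artifact window contains no samples; trace returned unchanged")
    return(trace)
  }
  if (length(idx) >= n) {
    stop_neodot("artifact window must be shorter than the recording",
                "neodot_validation_error")
  }
  if (window[2] <= window[1]) {
    stop_neodot("artifact window must have t1 > t0", "neodot_validation_error")
  }
  seg <- trace[idx]
  fit <- if (length(idx) >= 4) {
    # p close to 1 approaches interpolation. all.knots is required: the
    # default reduced knot set cannot follow a one-sample step at all, and
    # the penalty scale must be tiny on the seconds x-scale for the fit to
    # pass through the jump (p = 0.99 then reproduces it to ~1e-7 of its
    # size at the sample points)
    lambda <- max(1e-12 * (1 - p) / p, 1e-16)
    stats::smooth.spline(t[idx], seg, lambda = lambda, all.knots = TRUE)$y
  } else {
    seg
  }
  nj <- max(1, round(join_s * sample_rate_hz))
  pre <- idx[1] - 1
  level_pre <- if (pre >= 1) {
    mean(trace[max(1, pre - nj + 1):pre])
  } else {
    mean(seg[seq_len(min(nj, length(seg)))] - fit[seq_len(min(nj, length(seg)))])
  }
  corrected <- trace
  corrected[idx] <- seg - fit + level_pre
  last <- idx[length(idx)]
  if (tail == "shift" && last < n) {
    post <- trace[(last + 1):min(n, last + nj)]
    shift <- mean(corrected[idx][max(1, length(idx) - nj + 1):length(idx)]) -
      mean(post)
    corrected[(last + 1):n] <- trace[(last + 1):n] + shift
  }
  corrected
}

#' Optional moving-variance artifact flagger
#'
#' Conservative helper (off by default in the pipeline) that flags samples
#' whose local variance exceeds `k` times the median local variance;
#' contiguous runs are merged into candidate artifact windows.
#'
#' @param trace Numeric vector.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param window_s Variance window length (s).
#' @param k Threshold multiplier.
#' @return Tibble with columns `t0`, `t1` (s), possibly empty.
#' @export
detect_artifact_windows <- function(trace, sample_rate_hz, window_s = 2,
                                    k = 10) {
  w <- max(2, round(window_s * sample_rate_hz))
  n <- length(trace)
  cs <- cumsum(c(0, trace)); cs2 <- cumsum(c(0, trace^2))
  starts <- seq_len(n - w + 1)
  m <- (cs[starts + w] - cs[starts]) / w
  v <- (cs2[starts + w] - cs2[starts]) / w - m^2
  hot <- v > k * median(v)
  if (!any(hot)) {
    return(tibble::tibble(t0 = numeric(), t1 = numeric()))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(t0 = (begs[keep] - 1) / sample_rate_hz,
                 t1 = (ends[keep] + w - 2) / sample_rate_hz)
}

#' Zero-phase low-pass filter for DOT intensities
#'
#' 5th-order Butterworth applied forward and backward (zero group delay,
#' unit DC gain), removing the cardiac pulsation and high-frequency noise
#' while leaving the slow haemodynamics untouched.
#'
#' @param x Numeric vector or `time x channel` matrix or
#'   `time x channel x wavelength` array.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param cutoff_hz Cut-off frequency (Hz, default 1; must be below Nyquist).
#' @param order Filter order.
#' @return Filtered object of the same shape.
#' @export
lowpass_dot <- function(x, sample_rate_hz, cutoff_hz = 1.0, order = 5) {
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop_neodot("cutoff must be below the Nyquist frequency",
                "neodot_validation_error")
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2))
  np <- pad_length(sample_rate_hz, cutoff_hz)
  apply_columns(x, function(col) filtfilt_padded(bf, col, np))
}

# filtfilt with odd-reflection end padding: without it the IIR start-up
# transient (driven by any DC offset or trend at the trace ends) leaks tens
# of samples of large ringing into both ends of the output.
filtfilt_padded <- function(bf, col, np) {
  n <- length(col)
  np <- min(np, n - 1L)
  if (np < 1L) return(as.numeric(signal::filtfilt(bf, col)))
  head_pad <- 2 * col[1] - col[seq(np + 1L, 2L, by = -1L)]
  tail_pad <- 2 * col[n] - col[seq(n - 1L, n - np, by = -1L)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, col, tail_pad)))
  y[seq(np + 1L, np + n)]
}

# padding long enough for the transient of a filter with the given lowest
# pass frequency to settle; three characteristic periods still leaves an
# O(1e-3) relative end transient for a 5th-order Butterworth, ten periods
# settle it to rounding error, and the extra samples are cheap
pad_length <- function(sample_rate_hz, lowest_hz) {
  as.integer(ceiling(10 * sample_rate_hz / lowest_hz))
}

#' Zero-phase EEG band-pass and notch filtering
#'
#' Band-pass (default 0.3-70 Hz) followed by a mains notch (default 50 Hz),
#' both Butterworth and applied forward-backward.
#'
#' @param x Numeric vector or `time x channel` matrix of EEG samples.
#' @param sample_rate_hz EEG sampling rate (>= 256 Hz expected).
#' @param band Pass band `c(low, high)` in Hz.
#' @param notch_hz Mains frequency to suppress; `NULL` disables the notch.
#' @param notch_width_hz Full width of the stop band (Hz).
#' @return Filtered object of the same shape.
#' @export
filter_eeg <- function(x, sample_rate_hz, band = c(0.3, 70), notch_hz = 50,
                       notch_width_hz = 4) {
  if (band[1] >= band[2]) {
    stop_neodot("band must be increasing (low < high)",
                "neodot_validation_error")
  }
  nyq <- sample_rate_hz / 2
  if (band[2] >= nyq) {
    stop_neodot("band edge above Nyquist", "neodot_validation_error")
  }
  bp <- signal::butter(3, band / nyq, type = "pass")
  np <- pad_length(sample_rate_hz, band[1])
  flt <- function(col) {
    y <- filtfilt_padded(bp, col, np)
    if (!is.null(notch_hz)) {
      ns <- signal::butter(2, c(notch_hz - notch_width_hz / 2,
                                notch_hz + notch_width_hz / 2) / nyq,
                           type = "stop")
      y <- filtfilt_padded(ns, y, np)
    }
    y
  }
  apply_columns(x, flt)
}

apply_columns <- function(x, f) {
  if (is.null(dim(x))) return(f(x))
  d <- dim(x)
  if (length(d) == 2) {
    out <- x
    for (c in seq_len(d[2])) out[, c] <- f(x[, c])
    return(out)
  }
  out <- x
  for (w in seq_len(d[3])) for (c in seq_len(d[2])) {
    out[, c, w] <- f(x[, c, w])
  }
  out
}

#' Convert intensities to optical-density changes
#'
#' \eqn{\Delta OD(t,c,\lambda) = -\ln\big(I(t,c,\lambda)/\bar I(c,\lambda)\big)}
#' with \eqn{\bar I} the channel mean over the entire acquisition. Invariant
#' under per-channel rescaling of the intensities. Excluded channels are
#' carried through as zeros.
#'
#' @param bundle A [recording_bundle()] (typically pruned, artifact-corrected
#'   and low-pass filtered).
#' @return An [od_series()].
#' @export
to_optical_density <- function(bundle) {
  d <- dim(bundle$intensity)
  retained <- bundle$channel_quality$retained
  delta <- array(0, d)
  reference <- matrix(NA_real_, d[2], d[3])
  for (c in seq_len(d[2])) {
    for (w in seq_len(d[3])) {
      intens <- bundle$intensity[, c, w]
      reference[c, w] <- mean(intens)
      if (!retained[c]) next
      if (any(intens <= 0)) {
        stop_neodot(sprintf("non-positive intensity on retained channel %d", c),
                    "neodot_validation_error")
      }
      delta[, c, w] <- -log(intens / reference[c, w])
    }
  }
  od_series(delta, reference, bundle$sample_rate_hz,
            bundle$probe$wavelengths)
}

#' Standard DOT pre-processing pipeline
#'
#' Fixed order: channel pruning, spline correction of flagged artifact
#' windows (on intensity), zero-phase 1 Hz low-pass, optical-density
#' conversion, MBLL. Returns the intermediate objects so downstream stages
#' can pick what they need.
#'
#' @param bundle A [recording_bundle()] (annotations on either clock; they
#'   are aligned first when sync pulses are present).
#' @param artifact_windows Tibble/data frame with `t0`, `t1` columns (s) and
#'   optionally a `channels` list-column; `NULL` for none.
#' @param cutoff_hz Low-pass cut-off (Hz). The default (2 Hz) is
#'   deliberately gentle: a tight cut-off visibly shifts the sharp response
#'   peak toward its flatter side, whereas residual cardiac/broadband
#'   content is removed later by the coarse-scale smoothing inside the
#'   event analysis.
#' @param dpf Differential pathlength factor for the MBLL stage.
#' @param extinction Extinction table.
#' @param min_mean_intensity,rel_floor Pruning thresholds (see
#'   [prune_channels()]).
#' @return List with `bundle` (pruned/corrected/filtered), `od`, `haemo`,
#'   `global` (tibble from [global_mean()]), `qc` (from [qc_report()]).
#' @export
preprocess_bundle <- function(bundle, artifact_windows = NULL,
                              cutoff_hz = 2.0, dpf = 4.9,
                              extinction = extinction_table(),
                              min_mean_intensity = NULL, rel_floor = 0.01) {
  if (bundle$annotation_clock == "eeg" &&
      length(bundle$sync_pulses_dot) >= 3 &&
      length(bundle$sync_pulses_eeg) >= 3) {
    bundle <- align_annotations(bundle)
  }
  bundle <- prune_channels(bundle, min_mean_intensity, rel_floor)
  if (!is.null(artifact_windows) && nrow(artifact_windows)) {
    for (r in seq_len(nrow(artifact_windows))) {
      chans <- artifact_windows$channels[[r]] %||%
        which(bundle$channel_quality$retained)
      chans <- intersect(chans, which(bundle$channel_quality$retained))
      for (c in chans) for (w in seq_len(dim(bundle$intensity)[3])) {
        # correct in the log-intensity domain: step artifacts are
        # multiplicative in intensity (additive in optical density), so an
        # additive re-levelling is only exact on the log trace
        bundle$intensity[, c, w] <- exp(spline_correct(
          log(bundle$intensity[, c, w]),
          c(artifact_windows$t0[r], artifact_windows$t1[r]),
          bundle$sample_rate_hz))
      }
    }
  }
  bundle$intensity <- lowpass_dot(bundle$intensity, bundle$sample_rate_hz,
                                  cutoff_hz)
  od <- to_optical_density(bundle)
  haemo <- mbll_convert(od, bundle$probe, extinction, dpf)
  glob <- global_mean(haemo, bundle$channel_quality$retained)
  list(bundle = bundle, od = od, haemo = haemo, global = glob,
       qc = qc_report(bundle))
}
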