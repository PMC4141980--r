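#' Event-locked baseline value
#'
#' Baseline for event-locked measures: the mean of the trace over a window
#' relative to the electrographic onset, by default 60 to 30 s before it.
#'
#' @param trace Numeric vector.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param onset_s Electrographic onset (s from recording start).
#' @param window Window relative to onset (s), default `c(-60, -30)`;
#'   `window[1] < window[2]` required.
#' @return The baseline mean.
#' @export
event_baseline <- function(trace, sample_rate_hz, onset_s,
                           window = c(-60, -30)) {
  if (window[1] >= window[2]) {
    stop_neodot("baseline window inverted (need window[1] < window[2])",
                "neodot_validation_error")
  }
  t <- (seq_along(trace) - 1) / sample_rate_hz
  lo <- onset_s + window[1]
  hi <- onset_s + window[2]
  if (lo < 0 || hi > max(t)) {
    stop_neodot(sprintf(
      "baseline window [%g, %g] s for the event at %g s lies outside the recording",
      lo, hi, onset_s), "neodot_validation_error")
  }
  idx <- t >= lo & t < hi
  mean(trace[idx])
}

#' Event-locked response metrics for one event
#'
#' Quantifies the biphasic response on a (typically global HbT) trace:
#' time from electrographic onset to the HbT maximum, from maximum to
#' minimum, and from minimum to recovery, plus the event duration as the
#' sum of the estimable phases. The trace should already be detrended;
#' baseline referencing (mean of `baseline_window` before onset) is applied
#' internally.
#'
#' Timing is estimated at two scales. Extrema are first located on a
#' heavily smoothed copy of the trace (zero-phase low-pass at
#' `smooth_cutoff_hz`, robust to broadband noise); the sharp peak is then
#' re-located on the *unsmoothed* trace within `refine_halfwidth_s` of the
#' coarse position, because strong smoothing of an asymmetric extremum
#' shifts its apparent time toward the flatter side. The broad trough is
#' re-located on a medium-scale copy (cut-off `2.5 x smooth_cutoff_hz`) and
#' then refined by a two-branch quadratic fit sharing a common vertex: the
#' trough of a piecewise-smooth response is a curvature corner, and any
#' symmetric estimator (argmin, single parabola) is biased toward its
#' flatter side, while the two-branch vertex is not.
#'
#' Recovery is the return to the baseline level. A sustained-recovery
#' stretch is first identified on the smoothed trace: starting from a
#' sample at or above `-max(3.5 sigma_s, eps)`, at most 5% of the
#' following `recovery_hold_s` seconds may dip below that level (`sigma_s`
#' is the noise SD of the smoothed trace, estimated as the median of
#' autocorrelation-corrected detrended SDs over three pre-onset
#' sub-windows - a fraction-based hold is robust to the sampling
#' error of `sigma_s`, where an unbroken-run requirement is not). The
#' recovery point is then the earliest unsmoothed sample connected to that
#' stretch on which the trace has closed its deficit to within
#' `eps = max(2 sigma, 1e-6 (peak - trough))` (`sigma` from the unsmoothed
#' trace; the relative floor guards against numerically tiny thresholds on
#' noiseless data). The crossing time is interpolated between samples and
#' bias-corrected by `sqrt(eps / k)` with `k` the local curvature of the
#' approach: any smooth response closes its deficit quadratically, so
#' thresholding at `-eps` alone would fire early by exactly that amount.
#'
#' Phases whose search horizon crosses the next event's onset are censored
#' (`NA` with the corresponding flag), never extrapolated. A trace with no
#' maximum above the noise level is flagged unresponsive.
#'
#' @param trace Numeric vector (uM).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param onset_s Consensus electrographic onset (s).
#' @param next_onset_s Onset of the following event (censoring horizon);
#'   `Inf` when none.
#' @param max_rise_window_s Maximum onset-to-peak search window (s).
#' @param baseline_window Baseline window relative to onset (s).
#' @param recovery_hold_s Time the recovery criterion must hold (s).
#' @param smooth_cutoff_hz Cut-off of the coarse-scale smoothing (Hz);
#'   `NULL` disables it (the trace itself is then used at both scales).
#' @param refine_halfwidth_s Half-width of the window around the coarse
#'   peak within which the unsmoothed maximum is re-located (s).
#' @return One-row tibble with `time_to_hbt_max_s`, `time_max_to_min_s`,
#'   `time_min_to_recovery_s`, `dot_event_duration_s`, `peak_uM`,
#'   `trough_uM`, `unresponsive`, `censored`.
#' @export
response_metrics <- function(trace, sample_rate_hz, onset_s,
                             next_onset_s = Inf,
                             max_rise_window_s = 60,
                             baseline_window = c(-60, -30),
                             recovery_hold_s = 20,
                             smooth_cutoff_hz = 0.2,
                             refine_halfwidth_s = 2.5) {
  t <- (seq_along(trace) - 1) / sample_rate_hz
  base <- event_baseline(trace, sample_rate_hz, onset_s, baseline_window)
  y <- trace - base
  if (is.null(smooth_cutoff_hz)) {
    ys <- y
    ym <- y
  } else {
    ys <- lowpass_dot(y, sample_rate_hz, smooth_cutoff_hz)
    ym <- lowpass_dot(y, sample_rate_hz,
                      min(2.5 * smooth_cutoff_hz, 0.45 * sample_rate_hz))
  }
  bidx <- t >= onset_s + baseline_window[1] & t < onset_s + baseline_window[2]
  # noise SDs: median over three pre-onset sub-windows of the SD around a
  # local quadratic trend. The median discards a sub-window contaminated by
  # smooth structure (e.g. the tail of the previous event) without the
  # downward sampling bias of a minimum - the smoothed trace carries only
  # ~2 * span * cutoff independent samples per sub-window, so the smallest
  # of three SDs systematically underestimates the noise level.
  span <- baseline_window[2] - baseline_window[1]
  sub_lo <- onset_s + baseline_window[1] - (2:0) * span
  subs <- lapply(sub_lo[sub_lo >= 0], function(lo) {
    which(t >= lo & t < lo + span)
  })
  subs <- subs[lengths(subs) > 0]
  sigma_s <- stats::median(vapply(subs, function(ix) detrended_sd(ys, t, ix),
                                  numeric(1)))
  sigma <- stats::median(vapply(subs, function(ix) detrended_sd(y, t, ix),
                                numeric(1)))
  horizon <- min(next_onset_s, max(t))

  row <- tibble::tibble(
    time_to_hbt_max_s = NA_real_, time_max_to_min_s = NA_real_,
    time_min_to_recovery_s = NA_real_, dot_event_duration_s = NA_real_,
    peak_uM = NA_real_, trough_uM = NA_real_,
    unresponsive = FALSE, censored = FALSE)

  rise_end <- onset_s + max_rise_window_s
  ridx <- which(t >= onset_s & t <= min(rise_end, horizon))
  if (!length(ridx)) {
    row$censored <- TRUE
    return(row)
  }
  icoarse <- ridx[which.max(ys[ridx])]
  if (ys[icoarse] <= max(2 * sigma_s, 0)) {
    row$unresponsive <- TRUE
    return(row)
  }
  if (rise_end > horizon && icoarse == ridx[length(ridx)]) {
    # peak may lie beyond the censoring point
    row$censored <- TRUE
    return(row)
  }
  hw <- max(1L, as.integer(round(refine_halfwidth_s * sample_rate_hz)))
  widx <- intersect(ridx, (icoarse - hw):(icoarse + hw))
  imax <- widx[which.max(y[widx])]
  peak <- y[imax]
  row$peak_uM <- peak
  t_max <- t[imax] + interp3_offset(y, imax) / sample_rate_hz
  row$time_to_hbt_max_s <- t_max - onset_s

  fidx <- which(t >= t[imax] & t <= horizon)
  imin <- fidx[which.min(ys[fidx])]
  if (imin == fidx[length(fidx)] && is.finite(next_onset_s)) {
    row$censored <- TRUE               # trough not reached before next event
    row$dot_event_duration_s <- row$time_to_hbt_max_s
    return(row)
  }
  thw <- 4L * hw
  tidx <- intersect(fidx, (imin - thw):(imin + thw))
  imin <- tidx[which.min(ym[tidx])]
  trough <- ym[imin]
  row$trough_uM <- trough
  t_min <- t[imin] + interp3_offset(ym, imin) / sample_rate_hz
  t_min <- trough_knot_time(ym, t, t_min, lo = t[imax], hi = horizon) %||%
    t_min
  row$time_max_to_min_s <- t_min - t_max

  eps <- max(2 * sigma, 1e-6 * (peak - trough))
  # the run-qualifying tolerance on the smoothed trace is looser than the
  # crossing level so individual noise dips do not break a recovered run
  eps_hold <- max(3.5 * sigma_s, 1e-6 * (peak - trough))
  after <- which(t > t[imin] & t <= horizon)
  hold_n <- max(1L, as.integer(round(recovery_hold_s * sample_rate_hz)))
  n_after <- length(after)
  viol <- ys[after] < -eps_hold
  cs <- cumsum(c(0L, viol))
  pos <- seq_len(n_after)
  wend <- pmin(pos + hold_n - 1L, n_after)
  wlen <- wend - pos + 1L
  nviol <- cs[wend + 1L] - cs[pos]
  # a start qualifies if its hold window (a) fits before the censoring
  # horizon, or reaches the end of the recording when there is no next
  # event, and (b) contains at most 5% dips below the hold level
  qual <- !viol & nviol <= 0.05 * wlen &
    (wlen == hold_n | (wend == n_after & !is.finite(next_onset_s)))
  rec_i <- NA_integer_
  if (any(qual)) {
    j <- after[which(qual)[1]]
    hi_i <- after[n_after]
    # walk backward while the unsmoothed trace already satisfies the
    # crossing level (the smoothed stretch can start late: smoothing
    # smears the approach to baseline forward in time) ...
    while (j > after[1] && y[j - 1] >= -eps) j <- j - 1
    # ... then forward in case the stretch start itself sits below it
    while (j <= hi_i && y[j] < -eps) j <- j + 1
    if (j <= hi_i) rec_i <- j
  }
  if (is.na(rec_i)) {
    row$censored <- is.finite(next_onset_s)
  } else {
    t_rec <- recovery_time(y, t, rec_i, eps, sample_rate_hz, t[imin])
    row$time_min_to_recovery_s <- min(t_rec, horizon) - t_min
  }
  phases <- c(row$time_to_hbt_max_s, row$time_max_to_min_s,
              row$time_min_to_recovery_s)
  row$dot_event_duration_s <- sum(phases, na.rm = TRUE)
  row
}

# Trough refinement by a two-branch quadratic "knot" model. The trough of a
# piecewise-smooth response is a curvature corner: both neighbouring
# segments have zero slope there, so locally
#   y(t) = c + kl/2 (t - t0)^2 [t < t0] + kr/2 (t - t0)^2 [t >= t0]
# with generally unequal curvatures. A single symmetric fit (parabola or
# plain argmin) is biased toward the flatter side; profiling the
# least-squares vertex t0 of the two-branch model over a grid is not. The
# samples closest to the corner are excluded because smoothing rounds the
# corner itself. Returns NULL when there is not enough room on both sides.
trough_knot_time <- function(ym, t, t0c, lo, hi, exclude_s = 3,
                             span_s = 15, grid_halfwidth_s = 3,
                             grid_step_s = 0.05) {
  idx <- which(abs(t - t0c) > exclude_s & abs(t - t0c) <= span_s &
                 t > lo & t <= hi)
  left <- t[idx] < t0c
  if (sum(left) < 5 || sum(!left) < 5) return(NULL)
  tt <- t[idx]
  yy <- ym[idx]
  cand <- seq(t0c - grid_halfwidth_s, t0c + grid_halfwidth_s,
              by = grid_step_s)
  cand <- cand[cand > lo & cand < hi]
  if (length(cand) < 3) return(NULL)
  rss <- vapply(cand, function(t0) {
    d2 <- (tt - t0)^2
    fit <- stats::lm.fit(cbind(1, d2 * left, d2 * !left), yy)
    sum(fit$residuals^2)
  }, numeric(1))
  best <- which.min(rss)
  t0 <- cand[best]
  d2 <- (tt - t0)^2
  k <- stats::lm.fit(cbind(1, d2 * left, d2 * !left), yy)$coefficients[2:3]
  # reject fits that are not actually a trough or that ran into the grid edge
  if (any(!is.finite(k)) || any(k <= 0)) return(NULL)
  if (best == 1L || best == length(cand)) return(NULL)
  t0
}

# Noise SD of y over the given sample window, measured around a local
# quadratic trend so smooth structure does not inflate the estimate. The
# residual variance is corrected for the three fitted parameters using the
# effective (autocorrelation-adjusted) sample count: for lowpass-filtered
# noise the nominal n overstates the information content, and RSS/n would
# underestimate sigma^2 by roughly (1 - 3/n_eff).
detrended_sd <- function(y, t, idx) {
  if (length(idx) < 10) return(stats::sd(y[idx]))
  tc <- t[idx] - mean(t[idx])
  res <- stats::lm.fit(cbind(1, tc, tc^2), y[idx])$residuals
  n <- length(res)
  if (sum(res^2) == 0) return(0)   # exactly (locally) quadratic trace
  rho <- sum(res[-1] * res[-n]) / sum(res^2)
  rho <- max(0, min(rho, 0.995))
  n_eff <- n * (1 - rho) / (1 + rho)
  sqrt(sum(res^2) / (n * max(1 - 3 / n_eff, 0.25)))
}

# Sub-sample offset (in samples, clamped to +/- 1/2) of the extremum at
# grid index i, from the parabola through the three surrounding samples.
interp3_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(0)
  max(-0.5, min(0.5, (y[i - 1] - y[i + 1]) / (2 * denom)))
}

# Recovery time from the first threshold crossing: interpolate the -eps
# crossing between samples, then push it forward by sqrt(eps / k) with k
# the local curvature of the approach, because a trace that closes its
# deficit quadratically reaches -eps exactly that long before it reaches
# the baseline.
recovery_time <- function(ys, t, rec_i, eps, sample_rate_hz, t_min) {
  t_cross <- t[rec_i]
  if (rec_i > 1 && ys[rec_i - 1] < -eps && ys[rec_i] > ys[rec_i - 1]) {
    frac <- (-eps - ys[rec_i - 1]) / (ys[rec_i] - ys[rec_i - 1])
    t_cross <- t[rec_i - 1] + frac / sample_rate_hz
  }
  fit_lo <- max(t_min, t_cross - 30)
  idx <- which(t >= fit_lo & t <= t_cross)
  if (length(idx) >= 10) {
    tc <- t[idx] - t_cross
    fit <- stats::lm.fit(cbind(1, tc, tc^2), ys[idx])
    k <- -fit$coefficients[3]
    if (is.finite(k) && k > 0) t_cross <- t_cross + sqrt(eps / k)
  }
  t_cross
}

#' Inter-ictal linear detrending
#'
#' Removes a least-squares straight line fitted only on the samples away
#' from the events (outside `[onset - pre_s, onset + post_s]` for every
#' onset). Fitting on the full trace would bias the line - the biphasic
#' response has a nonzero integral - and shift the apparent steady levels
#' between events; the inter-ictal fit estimates the instrumental drift
#' unbiased by the responses.
#'
#' @param trace Numeric vector.
#' @param time_s Time axis (s).
#' @param onsets Event onset times (s).
#' @param pre_s,post_s Event window excluded from the fit, relative to each
#'   onset (s); `post_s` should cover the full response span.
#' @return List with `detrended`, `slope`, `intercept` (as
#'   [linear_detrend()]).
#' @export
detrend_interictal <- function(trace, time_s, onsets, pre_s = 60,
                               post_s = 320) {
  keep <- rep(TRUE, length(trace))
  for (o in onsets) keep <- keep & !(time_s >= o - pre_s & time_s <= o + post_s)
  if (sum(keep) < 2) {
    stop_neodot("no inter-ictal samples left to fit the trend",
                "neodot_validation_error")
  }
  fit <- linear_detrend(trace[keep], time_s[keep])
  list(detrended = trace - (fit$slope * time_s + fit$intercept),
       slope = fit$slope, intercept = fit$intercept)
}

#' Per-event seizure response table
#'
#' Applies [response_metrics()] to the global HbT trace for every scheduled
#' event (censoring each at the next consensus onset) and adds the
#' chromophore peak amplitudes from the global HbO/HbR traces, producing
#' the per-event summary table of the analysis.
#'
#' @param global Tibble from [global_mean()] (columns `time_s`, `hbo`,
#'   `hbr`, `hbt`), ideally detrended.
#' @param events Event table with `event_id`, `consensus_onset_s`,
#'   `eeg_duration_s` (see [consensus_onsets()]).
#' @param sample_rate_hz Sampling rate of `global`.
#' @param ... Passed to [response_metrics()] (e.g. `smooth_cutoff_hz`).
#' @return A `seizure_event_table` tibble: one row per event with consensus
#'   onset, EEG duration, the three phase durations, the DOT event duration
#'   and the HbO/HbR/HbT peak amplitudes.
#' @export
seizure_event_table <- function(global, events, sample_rate_hz, ...) {
  events <- tibble::as_tibble(events)
  if (!"consensus_onset_s" %in% names(events)) {
    events <- consensus_onsets(events)
  }
  events <- events[order(events$consensus_onset_s), ]
  if (!"eeg_duration_s" %in% names(events)) events$eeg_duration_s <- NA_real_
  n <- nrow(events)
  if (!n) stop_neodot("no events to analyse", "neodot_validation_error")
  next_onset <- c(events$consensus_onset_s[-1], Inf)
  rows <- purrr::map(seq_len(n), function(i) {
    onset <- events$consensus_onset_s[i]
    m <- response_metrics(global$hbt, sample_rate_hz, onset,
                          next_onset_s = next_onset[i], ...)
    m$peak_hbt_uM <- m$peak_uM
    for (chrom in c("hbo", "hbr")) {
      m[[paste0("peak_", chrom, "_uM")]] <- if (!m$unresponsive && !is.na(m$time_to_hbt_max_s)) {
        trace <- global[[chrom]]
        base <- event_baseline(trace, sample_rate_hz, onset)
        idx <- round((onset + m$time_to_hbt_max_s) * sample_rate_hz) + 1
        trace[idx] - base
      } else NA_real_
    }
    m$peak_uM <- NULL
    dplyr::bind_cols(
      tibble::tibble(event_id = events$event_id[i],
                     consensus_onset_s = onset,
                     eeg_duration_s = events$eeg_duration_s[i]),
      m)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("seizure_event_table", class(out))
  out
}

#' Per-channel event peak amplitudes
#'
#' Channel-wise peak concentration changes for one event: the maximum
#' within the rise window after onset, referenced to the value 30 s before
#' onset, per channel and chromophore.
#'
#' @param series A [haemo_series()].
#' @param onset_s Consensus onset (s).
#' @param max_rise_window_s Rise search window (s).
#' @param reference_offset_s Reference time relative to onset (s).
#' @param channel_mask Logical vector of channels to include.
#' @return Tibble with `channel`, `hbo`, `hbr`, `hbt` peak amplitudes (uM).
#' @export
channel_peak_amplitudes <- function(series, onset_s, max_rise_window_s = 60,
                                    reference_offset_s = -30,
                                    channel_mask = NULL) {
  fs <- series$sample_rate_hz
  nt <- nrow(series$hbo)
  t <- (seq_len(nt) - 1) / fs
  iref <- round((onset_s + reference_offset_s) * fs) + 1
  if (iref < 1 || onset_s + max_rise_window_s > max(t)) {
    stop_neodot("event window outside the recording", "neodot_validation_error")
  }
  idx <- which(t >= onset_s & t <= onset_s + max_rise_window_s)
  mask <- channel_mask %||% rep(TRUE, ncol(series$hbo))
  chans <- which(mask)
  peak_of <- function(m) {
    apply(m[idx, chans, drop = FALSE], 2, max) - m[iref, chans]
  }
  tibble::tibble(channel = chans,
                 hbo = peak_of(series$hbo),
                 hbr = peak_of(series$hbr),
                 hbt = peak_of(hbt(series)))
}

#' Summary statistics over events and channels
#'
#' Cross-event means and standard deviations of the phase durations and, if
#' per-channel amplitudes are given, cross-event/channel means, SDs and the
#' maximum single-channel amplitude per chromophore.
#'
#' @param events A [seizure_event_table()].
#' @param channel_amplitudes Optional long tibble of
#'   [channel_peak_amplitudes()] rows for all events (columns `channel`,
#'   `hbo`, `hbr`, `hbt`, optionally `event_id`).
#' @return Tibble with `metric`, `mean`, `sd`, `max`, `n`.
#' @export
summarize_events <- function(events, channel_amplitudes = NULL) {
  if (!nrow(events)) {
    stop_neodot("empty event table", "neodot_validation_error")
  }
  stat_row <- function(name, x) {
    x <- x[!is.na(x)]
    tibble::tibble(metric = name,
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) stats::sd(x) else
                     if (length(x) == 1) 0 else NA_real_,
                   max = if (length(x)) max(x) else NA_real_,
                   n = length(x))
  }
  out <- dplyr::bind_rows(
    stat_row("time_to_hbt_max_s", events$time_to_hbt_max_s),
    stat_row("time_max_to_min_s", events$time_max_to_min_s),
    stat_row("time_min_to_recovery_s", events$time_min_to_recovery_s),
    stat_row("dot_event_duration_s", events$dot_event_duration_s))
  if (!is.null(channel_amplitudes) && nrow(channel_amplitudes)) {
    out <- dplyr::bind_rows(
      out,
      stat_row("peak_hbo_uM", channel_amplitudes$hbo),
      stat_row("peak_hbr_uM", channel_amplitudes$hbr),
      stat_row("peak_hbt_uM", channel_amplitudes$hbt))
  } else {
    out <- dplyr::bind_rows(
      out,
      stat_row("peak_hbo_uM", events$peak_hbo_uM),
      stat_row("peak_hbr_uM", events$peak_hbr_uM),
      stat_row("peak_hbt_uM", events$peak_hbt_uM))
  }
  out
}

#' Paired hemispheric EEG power comparison
#'
#' Paired two-sided t-test of per-channel EEG band power over the left
#' versus right hemisphere (channels paired homotopically).
#'
#' @param power_left,power_right Equal-length numeric vectors of per-channel
#'   power, paired element-wise.
#' @return Tibble with `t_statistic`, `df`, `p_value`, `mean_difference`,
#'   `n_pairs`.
#' @export
hemispheric_power_test <- function(power_left, power_right) {
  if (length(power_left) != length(power_right)) {
    stop_neodot("left and right power vectors must pair up",
                "neodot_validation_error")
  }
  n <- length(power_left)
  if (n < 2) stop_neodot("need at least 2 channel pairs",
                         "neodot_validation_error")
  d <- power_left - power_right
  if (stats::sd(d) == 0) {
    stop_neodot(
      "zero-variance paired differences: t statistic undefined (perfect separation or identical data)",
      "neodot_degenerate_error")
  }
  ht <- stats::t.test(power_left, power_right, paired = TRUE)
  tibble::tibble(t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = unname(ht$estimate),
                 n_pairs = n)
}

#' Per-channel EEG band power
#'
#' Mean squared amplitude of a (filtered) EEG trace per channel over the
#' whole recording - the quantity compared across hemispheres.
#'
#' @param x Numeric vector or `time x channel` matrix of filtered EEG.
#' @return Scalar or per-channel numeric vector of power.
#' @export
channel_power <- function(x) {
  if (is.null(dim(x))) mean(x^2) else colMeans(x^2)
}

#' Simulate null hemispheric EEG powers
#'
#' Generates paired left/right per-channel powers under the null hypothesis
#' of no hemispheric difference: both hemispheres draw i.i.d. log-normal
#' powers. Used for type-I-error studies of [hemispheric_power_test()].
#'
#' @param n_pairs Number of channel pairs.
#' @param seed Optional seed.
#' @param sdlog Log-scale SD of the power distribution.
#' @return List with `left` and `right` numeric vectors.
#' @export
simulate_null_powers <- function(n_pairs = 100, seed = NULL, sdlog = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  list(left = stats::rlnorm(n_pairs, 0, sdlog),
       right = stats::rlnorm(n_pairs, 0, sdlog))
}
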