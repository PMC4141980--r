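#' Parameters of the biphasic seizure haemodynamic response
#'
#' The characteristic event-locked response seen in neonatal seizure
#' haemodynamics: concentrations rise to a peak shortly after (or slightly
#' before) the electrographic onset, fall over roughly two minutes to a
#' trough below baseline that is typically larger than the initial peak, and
#' then slowly recover to a steady state. The temporal knots are expressed as
#' phase durations; total haemoglobin is always derived as HbO + HbR and
#' never parameterised independently.
#'
#' Defaults follow the average morphology of the case recording this package
#' emulates: peak ~15 s after onset, decline ~130 s to the trough, recovery
#' ~120 s, trough 1.3 times the peak, channel-level peak amplitudes 1.7 uM
#' (HbO) and 1.0 uM (HbR), with the haemodynamic rise leading the
#' electrographic onset by a few seconds.
#'
#' @param onset_s Electrographic onset (s, DOT clock).
#' @param amplitude_hbo_uM,amplitude_hbr_uM Peak concentration increases (uM).
#' @param undershoot_scale Ratio of trough magnitude to peak (> 1 allowed).
#' @param t_rise_s Duration onset-to-peak (s).
#' @param t_fall_s Duration peak-to-trough (s).
#' @param t_recover_s Duration trough-to-steady-state (s).
#' @param pre_onset_lead_s Haemodynamic lead over the electrographic onset
#'   (s, >= 0); the rise starts at `onset_s - pre_onset_lead_s`.
#' @return A `biphasic_response` parameter object.
#' @export
biphasic_response <- function(onset_s = 0,
                              amplitude_hbo_uM = 1.7,
                              amplitude_hbr_uM = 1.0,
                              undershoot_scale = 1.3,
                              t_rise_s = 15,
                              t_fall_s = 130,
                              t_recover_s = 120,
                              pre_onset_lead_s = 5) {
  if (any(c(t_rise_s, t_fall_s, t_recover_s) <= 0)) {
    stop_neodot("phase durations must be > 0", "neodot_validation_error")
  }
  if (pre_onset_lead_s < 0) {
    stop_neodot("pre_onset_lead_s must be >= 0", "neodot_validation_error")
  }
  if (!all(is.finite(c(amplitude_hbo_uM, amplitude_hbr_uM, undershoot_scale)))) {
    stop_neodot("amplitudes must be finite", "neodot_validation_error")
  }
  structure(
    list(onset_s = onset_s,
         amplitude_hbo_uM = amplitude_hbo_uM,
         amplitude_hbr_uM = amplitude_hbr_uM,
         undershoot_scale = undershoot_scale,
         t_rise_s = t_rise_s, t_fall_s = t_fall_s, t_recover_s = t_recover_s,
         pre_onset_lead_s = pre_onset_lead_s),
    class = "biphasic_response")
}

# Unit-amplitude response shape: piecewise raised-cosine segments between the
# programmed knots. Each segment has zero slope at both ends, so the
# composite is C1 and its argmax/argmin land exactly on the knots.
response_shape <- function(t, params) {
  t0 <- params$onset_s - params$pre_onset_lead_s
  u <- t - t0
  r <- params$t_rise_s; f <- params$t_fall_s; rec <- params$t_recover_s
  k <- params$undershoot_scale
  s <- numeric(length(t))
  i <- u > 0 & u <= r
  s[i] <- (1 - cos(pi * u[i] / r)) / 2
  i <- u > r & u <= r + f
  s[i] <- 1 - (1 + k) * (1 - cos(pi * (u[i] - r) / f)) / 2
  i <- u > r + f & u <= r + f + rec
  s[i] <- -k * (1 + cos(pi * (u[i] - r - f) / rec)) / 2
  s
}

#' Evaluate the biphasic response waveform
#'
#' Evaluates the per-chromophore concentration time course on a uniform time
#' axis. The waveform is zero before `onset - lead`, rises to the programmed
#' peak over `t_rise_s`, falls to `-undershoot_scale` times the peak over
#' `t_fall_s`, and returns to zero over `t_recover_s`; it is C1 and its
#' extrema coincide with the programmed knots.
#'
#' @param params A [biphasic_response()] object.
#' @param time_axis Uniform numeric time axis (s) covering at least
#'   `onset - 120 s` to `onset + t_rise + t_fall + t_recover + 60 s`.
#' @return Tibble with columns `time_s`, `hbo`, `hbr`, `hbt` (uM).
#' @export
make_response_waveform <- function(params, time_axis) {
  stopifnot(inherits(params, "biphasic_response"))
  t <- as.numeric(time_axis)
  if (length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt))) {
      stop_neodot("time axis must be uniform", "neodot_validation_error")
    }
  }
  t_end <- params$onset_s + params$t_rise_s + params$t_fall_s +
    params$t_recover_s + 60
  if (min(t) > params$onset_s - 120 || max(t) < t_end) {
    stop_neodot(sprintf(
      "time axis too short: need [%g, %g] s around the event",
      params$onset_s - 120, t_end), "neodot_validation_error")
  }
  s <- response_shape(t, params)
  tibble::tibble(
    time_s = t,
    hbo = params$amplitude_hbo_uM * s,
    hbr = params$amplitude_hbr_uM * s,
    hbt = (params$amplitude_hbo_uM + params$amplitude_hbr_uM) * s
  )
}
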