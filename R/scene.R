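#' Focal centre-surround cortical activation pattern
#'
#' Spatial weight map over the volume nodes of a head mesh: a focal region
#' of positive weight (smooth cosine taper, peak normalised to 1) optionally
#' ringed by a disjoint surround of opposite sign, emulating the
#' centre-surround organisation of focal seizure haemodynamics.
#'
#' @param mesh A `head_mesh`.
#' @param center Length-3 centre of the focal region (mm); defaults to a
#'   mid-grey-depth point beneath the vertex of the scalp.
#' @param focal_radius_mm Radius of the focal (positive) region.
#' @param surround_radius_mm Outer radius of the surround annulus; set equal
#'   to `focal_radius_mm` to disable the surround.
#' @param surround_weight Peak weight of the surround, in `[-1, 0]`.
#' @return A `spatial_pattern`: `weights` (one per mesh node, in `[-1, 1]`,
#'   peak exactly 1), `focal_nodes`, `surround_nodes`, `center`, and
#'   `centroid` (volume-weighted centroid of the focal region).
#' @export
spatial_pattern <- function(mesh, center = NULL, focal_radius_mm = 10,
                            surround_radius_mm = 25, surround_weight = -0.5) {
  if (focal_radius_mm <= 0 || surround_radius_mm < focal_radius_mm) {
    stop_neodot("need 0 < focal_radius_mm <= surround_radius_mm",
                "neodot_validation_error")
  }
  if (surround_weight > 0 || surround_weight < -1) {
    stop_neodot("surround_weight must be in [-1, 0]", "neodot_validation_error")
  }
  center <- as.numeric(center %||% default_pattern_center(mesh))
  d <- sqrt((mesh$nodes[, 1] - center[1])^2 +
              (mesh$nodes[, 2] - center[2])^2 +
              (mesh$nodes[, 3] - center[3])^2)
  w <- numeric(nrow(mesh$nodes))
  focal <- which(d < focal_radius_mm)
  if (!length(focal)) {
    stop_neodot("no mesh node within the focal radius of the centre",
                "neodot_validation_error")
  }
  w[focal] <- cos(pi / 2 * d[focal] / focal_radius_mm)^2
  surround <- integer()
  if (surround_radius_mm > focal_radius_mm && surround_weight < 0) {
    surround <- which(d >= focal_radius_mm & d < surround_radius_mm)
    u <- (d[surround] - focal_radius_mm) /
      (surround_radius_mm - focal_radius_mm)
    w[surround] <- surround_weight * sin(pi * u)^2
  }
  w <- w / max(w)
  wv <- w[focal] * mesh$node_volume[focal]
  structure(
    list(weights = w, focal_nodes = focal, surround_nodes = surround,
         center = center,
         centroid = as.numeric(colSums(mesh$nodes[focal, , drop = FALSE] * wv) /
                                 sum(wv))),
    class = "spatial_pattern")
}

# Mid-grey-depth point beneath the vertex / top surface of the mesh.
default_pattern_center <- function(mesh, grey_depth_mm = 9) {
  if (mesh$geometry$type == "hemisphere") {
    c(0, 0, mesh$geometry$radius - grey_depth_mm)
  } else {
    c(mean(range(mesh$nodes[, 1])), mean(range(mesh$nodes[, 2])),
      grey_depth_mm)
  }
}

#' @method print spatial_pattern
#' @export
print.spatial_pattern <- function(x, ...) {
  cat(sprintf(
    "<spatial_pattern> %d focal + %d surround nodes; centroid (%.1f, %.1f, %.1f) mm\n",
    length(x$focal_nodes), length(x$surround_nodes),
    x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Nuisance components of a synthetic recording
#'
#' Physiological and instrumental confounds added on top of the programmed
#' cortical signal: a slow linear concentration drift, a cardiac pulsation
#' (neonatal heart rate ~2.5 Hz, removed by the 1 Hz low-pass), multiplicative
#' intensity noise, an optional step discontinuity in the measured log
#' intensities of selected channels, and dead channels forced to the noise
#' floor.
#'
#' @param drift_slope_uM_per_s Linear HbO drift slope (uM/s); HbR drifts at
#'   0.3 times this rate.
#' @param cardiac_freq_hz,cardiac_amplitude_uM Cardiac oscillation frequency
#'   and HbO amplitude.
#' @param noise_sd Multiplicative intensity noise SD (relative units, >= 0).
#' @param step_time_s Time of the log-intensity step, or `NULL` for none;
#'   must fall within the recording when rendered.
#' @param step_channels Channels receiving the step.
#' @param step_log_size Step size in log-intensity (OD) units.
#' @param dead_channels Channels forced to the noise floor.
#' @return A `nuisance_model`.
#' @export
nuisance_model <- function(drift_slope_uM_per_s = 0,
                           cardiac_freq_hz = 2.5,
                           cardiac_amplitude_uM = 0,
                           noise_sd = 0,
                           step_time_s = NULL,
                           step_channels = integer(),
                           step_log_size = 0.5,
                           dead_channels = integer()) {
  if (noise_sd < 0) stop_neodot("noise_sd must be >= 0",
                                "neodot_validation_error")
  if (cardiac_freq_hz <= 0) stop_neodot("cardiac_freq_hz must be > 0",
                                        "neodot_validation_error")
  structure(
    list(drift_slope_uM_per_s = drift_slope_uM_per_s,
         cardiac_freq_hz = cardiac_freq_hz,
         cardiac_amplitude_uM = cardiac_amplitude_uM,
         noise_sd = noise_sd,
         step_time_s = step_time_s,
         step_channels = as.integer(step_channels),
         step_log_size = step_log_size,
         dead_channels = as.integer(dead_channels)),
    class = "nuisance_model")
}

#' @rdname nuisance_model
#' @details `default_nuisance()` is the realistic default for a 58-channel
#'   hour-long recording: drift 0.001 uM/s, 2.5 Hz cardiac at 0.2 uM, 0.1%
#'   intensity noise, a 0.5 log-unit step on 5 channels at 1080 s and 4 dead
#'   channels. `silent_nuisance()` disables everything (noiseless scenes).
#' @export
default_nuisance <- function() {
  nuisance_model(drift_slope_uM_per_s = 0.001,
                 cardiac_freq_hz = 2.5, cardiac_amplitude_uM = 0.2,
                 noise_sd = 0.001,
                 step_time_s = 1080, step_channels = c(2L, 11L, 23L, 37L, 48L),
                 step_log_size = 0.5,
                 dead_channels = c(7L, 19L, 33L, 50L))
}

#' @rdname nuisance_model
#' @export
silent_nuisance <- function() nuisance_model()

#' Random seizure-event schedule with two annotators
#'
#' Draws a schedule of electrographic events over the recording: consensus
#' onsets spread across the span, two annotator onsets straddling each
#' consensus with a bounded random disagreement, and EEG durations drawn
#' uniformly. Optionally some events carry only one annotator onset.
#'
#' @param n_events Number of events (>= 1).
#' @param recording_duration_s Recording span (s).
#' @param seed Optional seed (`set.seed` is called when given).
#' @param first_onset_s Earliest possible consensus onset (s).
#' @param tail_margin_s Span kept free after the last onset (s).
#' @param disagreement_range_s Range of |am - dh| disagreement (s).
#' @param duration_range_s Range of EEG event durations (s).
#' @param missing_annotator_rate Probability an event lacks the second
#'   annotator's onset (labelled `possible-seizure`).
#' @param allow_overlap Permit EEG events to overlap the next onset; when
#'   `FALSE` (default) an overlapping draw raises an error instead.
#' @return Tibble with `event_id`, `am_onset_s`, `dh_onset_s`,
#'   `eeg_duration_s`, `label`, `consensus_onset_s`.
#' @export
make_event_schedule <- function(n_events = 7, recording_duration_s = 3600,
                                seed = NULL, first_onset_s = 150,
                                tail_margin_s = 450,
                                disagreement_range_s = c(0, 13),
                                duration_range_s = c(30, 90),
                                missing_annotator_rate = 0,
                                allow_overlap = FALSE) {
  if (n_events < 1) stop_neodot("n_events must be >= 1",
                                "neodot_validation_error")
  if (!is.null(seed)) set.seed(seed)
  span <- recording_duration_s - first_onset_s - tail_margin_s
  if (span <= 0) {
    stop_neodot("recording too short for the requested schedule",
                "neodot_validation_error")
  }
  gap <- if (n_events > 1) span / (n_events - 1) else 0
  jitter <- if (n_events > 1) stats::runif(n_events, -0.2 * gap, 0.2 * gap)
            else stats::runif(1, 0, span)
  consensus <- first_onset_s + (seq_len(n_events) - 1) * gap + jitter
  # the jitter may push the end events outside the documented bounds
  # [first_onset_s, duration - tail_margin_s]; clamp them back
  consensus <- pmin(pmax(consensus, first_onset_s),
                    recording_duration_s - tail_margin_s)
  consensus <- sort(consensus)
  disagreement <- stats::runif(n_events, disagreement_range_s[1],
                               disagreement_range_s[2])
  sign <- sample(c(-1, 1), n_events, replace = TRUE)
  am <- consensus - sign * disagreement / 2
  dh <- consensus + sign * disagreement / 2
  durations <- stats::runif(n_events, duration_range_s[1], duration_range_s[2])
  missing <- stats::runif(n_events) < missing_annotator_rate
  consensus[missing] <- am[missing]   # single-annotator consensus rule
  dh[missing] <- NA_real_
  if (!allow_overlap && n_events > 1) {
    if (any(consensus[-n_events] + durations[-n_events] > consensus[-1])) {
      stop_neodot("EEG events overlap; pass allow_overlap = TRUE or reduce durations",
                  "neodot_validation_error")
    }
  }
  tibble::tibble(
    event_id = seq_len(n_events),
    am_onset_s = am,
    dh_onset_s = dh,
    eeg_duration_s = durations,
    label = ifelse(missing, "possible-seizure", "seizure"),
    consensus_onset_s = consensus
  )
}

#' Synthetic scene description
#'
#' Collects everything [render_intensities()] needs: the event schedule, the
#' shared response morphology (per-event onsets come from the schedule), the
#' spatial pattern (used when rendering through a Jacobian), the nuisance
#' model, timing, and the channel-level amplitude targets the rendering is
#' calibrated to.
#'
#' @param schedule Event schedule from [make_event_schedule()] (or any table
#'   with `consensus_onset_s`, `am_onset_s`, `dh_onset_s`, `eeg_duration_s`).
#' @param response A [biphasic_response()] carrying the shared morphology
#'   (its `onset_s` is ignored; each event uses its scheduled onset).
#' @param pattern A [spatial_pattern()] or `NULL` (required for Jacobian
#'   rendering).
#' @param nuisance A [nuisance_model()].
#' @param duration_s,sample_rate_hz Recording length and rate.
#' @param baseline_intensity Baseline intensity level (arbitrary units).
#' @param channel_peak_hbo_uM,channel_peak_hbr_uM Channel-level peak
#'   concentration targets the rendering is calibrated to; the cortical
#'   amplitude achieving them is a computed calibration constant stored in
#'   the ground truth, not assumed.
#' @param clock_offset_s Constant offset of the EEG clock relative to the
#'   DOT clock (EEG time = DOT time + offset).
#' @return A `dot_scene`.
#' @export
make_scene <- function(schedule,
                       response = biphasic_response(),
                       pattern = NULL,
                       nuisance = silent_nuisance(),
                       duration_s = 3600, sample_rate_hz = 10,
                       baseline_intensity = 1,
                       channel_peak_hbo_uM = 1.7,
                       channel_peak_hbr_uM = 1.0,
                       clock_offset_s = 120) {
  stopifnot(inherits(response, "biphasic_response"),
            inherits(nuisance, "nuisance_model"))
  if (duration_s <= 0 || sample_rate_hz <= 0 || baseline_intensity <= 0) {
    stop_neodot("duration, rate and baseline intensity must be > 0",
                "neodot_validation_error")
  }
  schedule <- tibble::as_tibble(schedule)
  if (!"consensus_onset_s" %in% names(schedule)) {
    schedule <- consensus_onsets(schedule)
  }
  if (!is.null(nuisance$step_time_s) &&
      (nuisance$step_time_s < 0 || nuisance$step_time_s > duration_s)) {
    stop_neodot("step artifact time outside the recording",
                "neodot_validation_error")
  }
  structure(
    list(schedule = schedule, response = response, pattern = pattern,
         nuisance = nuisance, duration_s = duration_s,
         sample_rate_hz = sample_rate_hz,
         baseline_intensity = baseline_intensity,
         channel_peak_hbo_uM = channel_peak_hbo_uM,
         channel_peak_hbr_uM = channel_peak_hbr_uM,
         clock_offset_s = clock_offset_s),
    class = "dot_scene")
}

#' @method print dot_scene
#' @export
print.dot_scene <- function(x, ...) {
  cat(sprintf(
    "<dot_scene> %d events over %.0f s @ %g Hz; targets HbO %.2g / HbR %.2g uM%s\n",
    nrow(x$schedule), x$duration_s, x$sample_rate_hz,
    x$channel_peak_hbo_uM, x$channel_peak_hbr_uM,
    if (!is.null(x$pattern)) "; cortical pattern attached" else ""))
  invisible(x)
}

# Sum of unit response shapes across the scheduled events.
scene_shape <- function(scene, t) {
  s <- numeric(length(t))
  for (i in seq_len(nrow(scene$schedule))) {
    p <- scene$response
    p$onset_s <- scene$schedule$consensus_onset_s[i]
    s <- s + response_shape(t, p)
  }
  s
}

#' Render a synthetic scene into dual-wavelength intensities
#'
#' Forward synthesis inverting the measurement chain: programmed cortical
#' (or channel-level) concentration changes are mapped to per-wavelength
#' optical-density changes, nuisance components are added, and intensities
#' are formed as
#' \deqn{I(t) = I_0 \exp(-\Delta OD(t)) (1 + \epsilon(t)),}
#' with multiplicative Gaussian noise. Two rendering paths exist:
#'
#' * **Jacobian path** (`jac` supplied): the scene's [spatial_pattern()]
#'   weights times the summed event waveform give nodal HbO/HbR; nodal
#'   absorption changes per wavelength follow from the extinction
#'   coefficients and the per-wavelength Jacobians map them to channel
#'   \eqn{\Delta OD} - the same convention reconstruction assumes. The
#'   cortical amplitude is calibrated so the best-coupled channel's MBLL
#'   concentrations hit the scene's channel-level targets; the calibration
#'   constants are stored in the ground truth.
#' * **Channel path** (`jac = NULL`): every channel is programmed directly
#'   at the channel-level targets and converted to \eqn{\Delta OD} with the
#'   forward MBLL - exact for round-trip and timing-recovery studies.
#'
#' Ground truth (schedule, response parameters, calibration, clean
#' channel-level concentrations, pattern centroid) is stored in the bundle's
#' `truth` field. Identical seeds give identical bundles.
#'
#' @param scene A [make_scene()] object.
#' @param probe A [probe_geometry()].
#' @param jac A `jacobian_set` matching `probe` and `mesh`, or `NULL`.
#' @param mesh The `head_mesh` the Jacobian was built on (required with
#'   `jac`).
#' @param seed Integer seed driving all randomness.
#' @param extinction Extinction table.
#' @param dpf Differential pathlength factor used in both directions.
#' @return A [recording_bundle()] with annotations on the EEG clock, sync
#'   pulse trains on both clocks, and ground truth attached.
#' @export
render_intensities <- function(scene, probe, jac = NULL, mesh = NULL,
                               seed = 1, extinction = extinction_table(),
                               dpf = 4.9) {
  stopifnot(inherits(scene, "dot_scene"))
  set.seed(seed)
  nc <- n_channels(probe)
  wl <- probe$wavelengths
  nw <- length(wl)
  sep <- channel_separations(probe)
  eps <- extinction_at(extinction, wl)
  nt <- floor(scene$duration_s * scene$sample_rate_hz) + 1
  t <- (seq_len(nt) - 1) / scene$sample_rate_hz
  s <- scene_shape(scene, t)

  if (!is.null(jac)) {
    if (is.null(scene$pattern)) {
      stop_neodot("Jacobian rendering needs a spatial pattern in the scene",
                  "neodot_validation_error")
    }
    if (jac$n_channels != nc || jac$n_nodes != length(scene$pattern$weights)) {
      stop_neodot(sprintf(
        "jacobian (%d channels x %d nodes) does not match probe (%d channels) / pattern (%d nodes)",
        jac$n_channels, jac$n_nodes, nc, length(scene$pattern$weights)),
        "neodot_validation_error")
    }
    # channels x wavelengths sensitivity of OD to the unit pattern
    g <- vapply(as.character(wl),
                function(w) as.numeric(jac$jacobians[[w]] %*%
                                         scene$pattern$weights),
                numeric(nc))
    cal <- calibrate_cortical_amplitudes(
      g, eps, sep, dpf,
      c(scene$channel_peak_hbo_uM, scene$channel_peak_hbr_uM))
    # static per-channel OD weight per wavelength (time factor = s(t))
    od_static <- sweep(g, 2, cal["hbo"] * eps$eps_hbo, "*") +
      sweep(g, 2, cal["hbr"] * eps$eps_hbr, "*")       # nc x nw
    # clean channel-level concentrations via the MBLL inverse
    E <- as.matrix(eps[, c("eps_hbo", "eps_hbr")])
    hb_static <- od_static %*% t(solve(crossprod(E), t(E))) / (sep * dpf)
    hbo_clean <- outer(s, hb_static[, 1])
    hbr_clean <- outer(s, hb_static[, 2])
    od_clean <- array(0, c(nt, nc, nw))
    for (k in seq_len(nw)) od_clean[, , k] <- outer(s, od_static[, k])
    truth_extra <- list(
      cortical_amplitude_hbo_uM = unname(cal["hbo"]),
      cortical_amplitude_hbr_uM = unname(cal["hbr"]),
      pattern_centroid_mm = scene$pattern$centroid,
      calibration_channel = unname(attr(cal, "channel")))
  } else {
    hbo_clean <- outer(s, rep(scene$channel_peak_hbo_uM, nc))
    hbr_clean <- outer(s, rep(scene$channel_peak_hbr_uM, nc))
    od_clean <- mbll_forward(hbo_clean, hbr_clean, sep, extinction, wl, dpf)
    truth_extra <- list()
  }

  # nuisance concentrations (channel space), then OD
  nu <- scene$nuisance
  phases <- stats::runif(nc, 0, 2 * pi)
  drift <- nu$drift_slope_uM_per_s * t
  cardiac <- nu$cardiac_amplitude_uM *
    sin(outer(2 * pi * nu$cardiac_freq_hz * t, rep(1, nc)) +
          rep(phases, each = nt))
  hbo_nuis <- drift + cardiac
  hbr_nuis <- matrix(0.3 * drift, nt, nc)
  od <- od_clean + mbll_forward(hbo_nuis, hbr_nuis, sep, extinction, wl, dpf)

  if (!is.null(nu$step_time_s) && length(nu$step_channels)) {
    after <- t >= nu$step_time_s
    od[after, nu$step_channels, ] <- od[after, nu$step_channels, ] +
      nu$step_log_size
  }

  intensity <- scene$baseline_intensity * exp(-od)
  if (nu$noise_sd > 0) {
    intensity <- intensity *
      (1 + array(stats::rnorm(length(intensity), 0, nu$noise_sd),
                 dim(intensity)))
  }
  if (length(nu$dead_channels)) {
    nfloor <- scene$baseline_intensity * 1e-4
    nd <- length(nu$dead_channels)
    intensity[, nu$dead_channels, ] <-
      nfloor * abs(1 + array(stats::rnorm(nt * nd * nw, 0, 0.5),
                             c(nt, nd, nw)))
  }

  pulses_dot <- sync_pulse_pattern(scene$duration_s)
  sched <- scene$schedule
  ann <- dplyr::bind_rows(
    tibble::tibble(annotator_id = "AM", event_id = sched$event_id,
                   onset_s = sched$am_onset_s + scene$clock_offset_s,
                   duration_s = sched$eeg_duration_s),
    tibble::tibble(annotator_id = "DH", event_id = sched$event_id,
                   onset_s = sched$dh_onset_s + scene$clock_offset_s,
                   duration_s = sched$eeg_duration_s))
  ann <- ann[!is.na(ann$onset_s), ]

  truth <- c(list(
    seed = seed,
    schedule = sched,
    t_rise_s = scene$response$t_rise_s,
    t_fall_s = scene$response$t_fall_s,
    t_recover_s = scene$response$t_recover_s,
    undershoot_scale = scene$response$undershoot_scale,
    pre_onset_lead_s = scene$response$pre_onset_lead_s,
    channel_peak_hbo_uM = scene$channel_peak_hbo_uM,
    channel_peak_hbr_uM = scene$channel_peak_hbr_uM,
    clock_offset_s = scene$clock_offset_s,
    dpf = dpf,
    noise_sd = nu$noise_sd,
    drift_slope_uM_per_s = nu$drift_slope_uM_per_s,
    dead_channels = nu$dead_channels,
    step_channels = nu$step_channels,
    step_time_s = nu$step_time_s,
    channel_hbo = hbo_clean,
    channel_hbr = hbr_clean
  ), truth_extra)

  recording_bundle(
    intensity = intensity,
    sample_rate_hz = scene$sample_rate_hz,
    probe = probe,
    eeg_annotations = ann,
    sync_pulses_dot = pulses_dot,
    sync_pulses_eeg = pulses_dot + scene$clock_offset_s,
    annotation_clock = "eeg",
    truth = truth
  )
}

# Solve the 2x2 calibration: cortical amplitudes (for the unit pattern) that
# make the best-coupled channel's MBLL concentrations equal the targets.
calibrate_cortical_amplitudes <- function(g, eps, sep, dpf, targets) {
  E <- as.matrix(eps[, c("eps_hbo", "eps_hbr")])
  Einv <- solve(crossprod(E), t(E))                      # 2 x nw
  # calibrate on the channel with the largest sensitivity magnitude: a
  # centre-surround pattern can be net-negative on every channel, and the
  # least-negative channel would have near-zero sensitivity and blow the
  # amplitudes up
  cstar <- which.max(abs(rowSums(g)) / sep)
  # channel concentration response to unit cortical (a_hbo, a_hbr)
  M <- matrix(0, 2, 2)
  for (k in seq_len(nrow(eps))) {
    M[, 1] <- M[, 1] + Einv[, k] * eps$eps_hbo[k] * g[cstar, k]
    M[, 2] <- M[, 2] + Einv[, k] * eps$eps_hbr[k] * g[cstar, k]
  }
  M <- M / (sep[cstar] * dpf)
  if (abs(det(M)) < 1e-30) {
    stop_neodot("pattern has no sensitivity on any channel; cannot calibrate",
                "neodot_validation_error")
  }
  a <- solve(M, targets)
  structure(c(hbo = a[1], hbr = a[2]), channel = cstar)
}

# Deterministic aperiodic synchronisation pulse pattern (distinct
# inter-pulse intervals, repeated with a growing stretch so long recordings
# stay aperiodic).
sync_pulse_pattern <- function(duration_s, start_s = 10) {
  base <- c(5, 8, 13, 6, 11, 17, 7, 12, 19, 9, 14, 21, 16, 23, 18)
  times <- start_s
  k <- 0
  while (max(times) < duration_s - max(base)) {
    times <- c(times, max(times) + cumsum(base + 0.1 * k))
    k <- k + 1
  }
  times[times <= duration_s]
}

#' One-call synthetic recording
#'
#' Convenience wrapper drawing a schedule, building a scene and rendering it
#' through the channel path (fast, MBLL-exact). For Jacobian-path rendering
#' build the mesh/Jacobian once and call [render_intensities()] directly.
#'
#' @param seed Seed for schedule and rendering.
#' @param n_events Number of events.
#' @param duration_s Recording length (s).
#' @param probe Probe geometry (defaults to [default_probe()]).
#' @param response Response morphology.
#' @param nuisance Nuisance model (defaults to the realistic
#'   [default_nuisance()]).
#' @param ... Further arguments to [make_scene()].
#' @return A [recording_bundle()].
#' @export
simulate_recording <- function(seed = 1, n_events = 7, duration_s = 3600,
                               probe = default_probe(),
                               response = biphasic_response(),
                               nuisance = default_nuisance(), ...) {
  schedule <- make_event_schedule(n_events, duration_s, seed = seed)
  scene <- make_scene(schedule, response = response, nuisance = nuisance,
                      duration_s = duration_s, ...)
  render_intensities(scene, probe, seed = seed)
}
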