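#' Synchronised dual-wavelength DOT recording
#'
#' A `recording_bundle` holds everything one acquisition produces: the raw
#' dual-wavelength intensity array, the acquisition rate, the probe geometry,
#' the EEG-side event annotations, the shared synchronisation pulse trains
#' recorded on the two instrument clocks, and per-channel quality flags.
#' Intensities are in arbitrary units and must be strictly positive on every
#' retained channel (optical-density conversion takes a log).
#'
#' @param intensity Numeric array `time x channel x wavelength`.
#' @param sample_rate_hz Sampling rate in Hz (nominally 10).
#' @param probe A [probe_geometry()] describing the array; its channel count
#'   and wavelengths must match `intensity`.
#' @param eeg_annotations Data frame with columns `annotator_id`, `event_id`,
#'   `onset_s`, `duration_s` (may have zero rows). Onsets are on the clock
#'   named by `annotation_clock`.
#' @param sync_pulses_dot,sync_pulses_eeg Numeric vectors of pulse times (s)
#'   on the DOT and EEG clocks.
#' @param channel_quality Data frame with columns `channel`, `retained`,
#'   `reason`; defaults to all channels retained.
#' @param annotation_clock Either `"eeg"` (raw, pre-alignment) or `"dot"`
#'   (after [align_annotations()]); onsets are validated against the recording
#'   span only once on the DOT clock.
#' @param truth Optional list of generator ground truth (see
#'   [render_intensities()]); carried alongside so validation studies never
#'   re-derive it.
#'
#' @return A validated `recording_bundle`.
#' @export
recording_bundle <- function(intensity, sample_rate_hz, probe,
                             eeg_annotations = empty_annotations(),
                             sync_pulses_dot = numeric(),
                             sync_pulses_eeg = numeric(),
                             channel_quality = NULL,
                             annotation_clock = c("eeg", "dot"),
                             truth = NULL) {
  annotation_clock <- match.arg(annotation_clock)
  intensity <- as.array(intensity)
  if (length(dim(intensity)) != 3) {
    stop_neodot("intensity must be a time x channel x wavelength array",
                "neodot_format_error")
  }
  if (is.null(channel_quality)) {
    channel_quality <- tibble::tibble(
      channel = seq_len(dim(intensity)[2]),
      retained = TRUE, reason = ""
    )
  }
  bundle <- structure(
    list(
      intensity = intensity,
      sample_rate_hz = as.numeric(sample_rate_hz),
      probe = probe,
      eeg_annotations = tibble::as_tibble(eeg_annotations),
      sync_pulses_dot = as.numeric(sync_pulses_dot),
      sync_pulses_eeg = as.numeric(sync_pulses_eeg),
      channel_quality = tibble::as_tibble(channel_quality),
      annotation_clock = annotation_clock,
      truth = truth
    ),
    class = "recording_bundle"
  )
  validate_bundle(bundle)
}

empty_annotations <- function() {
  tibble::tibble(annotator_id = character(), event_id = integer(),
                 onset_s = numeric(), duration_s = numeric())
}

#' Validate a recording bundle
#'
#' Checks dimensional consistency with the probe, strict positivity of
#' intensities on retained channels, the sampling rate, and (once annotations
#' are on the DOT clock) that annotation onsets fall within the recording.
#'
#' @param bundle A [recording_bundle()].
#' @return The bundle, invisibly unchanged, or an error.
#' @export
validate_bundle <- function(bundle) {
  d <- dim(bundle$intensity)
  if (!is.null(bundle$probe)) {
    if (d[2] != n_channels(bundle$probe)) {
      stop_neodot(sprintf("intensity has %d channels but probe defines %d",
                          d[2], n_channels(bundle$probe)),
                  "neodot_validation_error")
    }
    if (d[3] != length(bundle$probe$wavelengths)) {
      stop_neodot("wavelength dimension does not match probe wavelengths",
                  "neodot_validation_error")
    }
  }
  if (!is.finite(bundle$sample_rate_hz) || bundle$sample_rate_hz <= 0) {
    stop_neodot("sample_rate_hz must be a positive scalar",
                "neodot_validation_error")
  }
  q <- bundle$channel_quality
  if (nrow(q) != d[2]) {
    stop_neodot("channel_quality must have one row per channel",
                "neodot_validation_error")
  }
  retained <- which(q$retained)
  if (length(retained)) {
    keep <- bundle$intensity[, retained, , drop = FALSE]
    if (any(!is.finite(keep)) || any(keep <= 0)) {
      bad <- retained[unique(which(apply(keep <= 0 | !is.finite(keep),
                                         2, any)))]
      stop_neodot(
        sprintf("non-positive intensity on retained channel(s) %s",
                paste(bad, collapse = ", ")),
        "neodot_validation_error")
    }
  }
  ann <- bundle$eeg_annotations
  need <- c("annotator_id", "event_id", "onset_s", "duration_s")
  if (!all(need %in% names(ann))) {
    stop_neodot("eeg_annotations must have annotator_id, event_id, onset_s, duration_s",
                "neodot_format_error")
  }
  if (nrow(ann) && any(ann$duration_s <= 0, na.rm = TRUE)) {
    stop_neodot("annotation durations must be > 0", "neodot_validation_error")
  }
  if (bundle$annotation_clock == "dot" && nrow(ann)) {
    span <- recording_duration(bundle)
    if (any(ann$onset_s < 0 | ann$onset_s > span, na.rm = TRUE)) {
      stop_neodot("aligned annotation onsets fall outside the recording span",
                  "neodot_validation_error")
    }
  }
  invisible(bundle)
}

#' Recording time axis
#' @param bundle A [recording_bundle()].
#' @return Numeric vector of sample times in seconds from recording start.
#' @export
time_axis <- function(bundle) {
  (seq_len(dim(bundle$intensity)[1]) - 1) / bundle$sample_rate_hz
}

#' Recording duration in seconds
#' @param bundle A [recording_bundle()].
#' @export
recording_duration <- function(bundle) {
  (dim(bundle$intensity)[1] - 1) / bundle$sample_rate_hz
}

#' @method print recording_bundle
#' @export
print.recording_bundle <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<recording_bundle> %d samples x %d channels x %d wavelengths @ %g Hz (%.1f s)\n",
    d[1], d[2], d[3], x$sample_rate_hz, recording_duration(x)))
  cat(sprintf("  %d/%d channels retained; %d annotation rows (%s clock); %d/%d sync pulses\n",
              sum(x$channel_quality$retained), d[2], nrow(x$eeg_annotations),
              x$annotation_clock,
              length(x$sync_pulses_dot), length(x$sync_pulses_eeg)))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' @export
glance.recording_bundle <- function(x, ...) {
  d <- dim(x$intensity)
  tibble::tibble(
    n_samples = d[1], n_channels = d[2], n_wavelengths = d[3],
    sample_rate_hz = x$sample_rate_hz,
    duration_s = recording_duration(x),
    n_retained = sum(x$channel_quality$retained),
    n_events = length(unique(x$eeg_annotations$event_id)),
    has_truth = !is.null(x$truth)
  )
}

# ---------------------------------------------------------------------------
# Plain-text container I/O.
#
# The on-disk layout mirrors SNIRF group naming (data/, probe/, stim/) but
# uses a directory of JSON + CSV files so the container stays human-readable
# and exactly round-trippable: data.table::fwrite writes doubles with their
# shortest exact decimal representation.

#' Write a recording bundle to a plain-text container
#'
#' Serialises the bundle into a directory whose layout mirrors SNIRF group
#' naming: `meta.json`, `probe/` (sources, detectors, channels, landmarks),
#' `data/intensity_<wavelength>.csv` (one `time x channel` matrix per
#' wavelength), `stim/annotations.csv`, `sync/` pulse trains,
#' `quality.csv`, and optionally `truth/` with the generator ground truth.
#'
#' @param bundle A [recording_bundle()].
#' @param path Directory to create.
#' @param overwrite Refuse to write into an existing container unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, overwrite = FALSE) {
  validate_bundle(bundle)
  if (dir.exists(path) && file.exists(file.path(path, "meta.json")) &&
      !overwrite) {
    stop_neodot(sprintf("container already exists at '%s' (set overwrite = TRUE)",
                        path), "neodot_io_error")
  }
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    stop_neodot(sprintf("cannot create container directory '%s'", path),
                "neodot_io_error")
  }
  for (sub in c("data", "probe", "stim", "sync")) {
    dir.create(file.path(path, sub), showWarnings = FALSE)
  }
  d <- dim(bundle$intensity)
  meta <- list(
    format = "neodot-bundle", version = 1L,
    sample_rate_hz = bundle$sample_rate_hz,
    n_samples = d[1], n_channels = d[2],
    wavelengths_nm = bundle$probe$wavelengths,
    annotation_clock = bundle$annotation_clock,
    has_truth = !is.null(bundle$truth)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (w in seq_len(d[3])) {
    fwrite_matrix(bundle$intensity[, , w, drop = TRUE],
                  file.path(path, "data",
                            sprintf("intensity_%g.csv",
                                    bundle$probe$wavelengths[w])))
  }
  p <- bundle$probe
  fwrite_positions(p$source_positions, file.path(path, "probe", "sources.csv"))
  fwrite_positions(p$detector_positions, file.path(path, "probe", "detectors.csv"))
  data.table::fwrite(p$channels, file.path(path, "probe", "channels.csv"))
  if (!is.null(p$landmarks)) {
    fwrite_positions(p$landmarks, file.path(path, "probe", "landmarks.csv"))
  }
  data.table::fwrite(bundle$eeg_annotations,
                     file.path(path, "stim", "annotations.csv"))
  data.table::fwrite(data.frame(time_s = bundle$sync_pulses_dot),
                     file.path(path, "sync", "pulses_dot.csv"))
  data.table::fwrite(data.frame(time_s = bundle$sync_pulses_eeg),
                     file.path(path, "sync", "pulses_eeg.csv"))
  data.table::fwrite(bundle$channel_quality, file.path(path, "quality.csv"))
  if (!is.null(bundle$truth)) write_truth(bundle$truth, file.path(path, "truth"))
  invisible(path)
}

fwrite_matrix <- function(m, file) {
  m <- as.matrix(m)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  data.table::fwrite(data.table::as.data.table(m), file)
}

fread_matrix <- function(file) {
  as.matrix(data.table::fread(file))
}

fwrite_positions <- function(m, file) {
  data.table::fwrite(data.frame(id = rownames(m), m), file)
}

fread_positions <- function(file) {
  d <- data.table::fread(file)
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$id
  m
}

write_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE)
  scalars <- truth[!names(truth) %in% c("schedule", "channel_hbo",
                                        "channel_hbr", "clean_od")]
  jsonlite::write_json(scalars, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth$schedule)) {
    data.table::fwrite(truth$schedule, file.path(path, "schedule.csv"))
  }
  for (nm in c("channel_hbo", "channel_hbr")) {
    if (!is.null(truth[[nm]])) {
      fwrite_matrix(truth[[nm]], file.path(path, paste0(nm, ".csv")))
    }
  }
}

read_truth <- function(path) {
  if (!dir.exists(path)) return(NULL)
  truth <- jsonlite::read_json(file.path(path, "params.json"),
                               simplifyVector = TRUE)
  sched <- file.path(path, "schedule.csv")
  if (file.exists(sched)) {
    truth$schedule <- tibble::as_tibble(data.table::fread(sched))
  }
  for (nm in c("channel_hbo", "channel_hbr")) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (file.exists(f)) truth[[nm]] <- unname(fread_matrix(f))
  }
  truth
}

#' Read a recording bundle from a plain-text container
#'
#' Inverse of [write_bundle()]. Missing mandatory files raise a format error
#' naming the absent component; the reconstructed bundle is re-validated, so
#' corrupt containers (e.g. a negative intensity on a retained channel) are
#' rejected.
#'
#' @param path Container directory written by [write_bundle()].
#' @return A [recording_bundle()].
#' @export
read_bundle <- function(path) {
  if (!dir.exists(path)) {
    stop_neodot(sprintf("no container at '%s'", path), "neodot_io_error")
  }
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) {
      stop_neodot(sprintf("container is missing '%s'", f),
                  "neodot_format_error")
    }
    fp
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  wl <- as.numeric(meta$wavelengths_nm)
  slices <- lapply(wl, function(w) {
    fread_matrix(need(file.path("data", sprintf("intensity_%g.csv", w))))
  })
  intensity <- array(0, dim = c(meta$n_samples, meta$n_channels, length(wl)))
  for (w in seq_along(wl)) intensity[, , w] <- slices[[w]]

  src <- fread_positions(need(file.path("probe", "sources.csv")))
  det <- fread_positions(need(file.path("probe", "detectors.csv")))
  ch <- data.table::fread(need(file.path("probe", "channels.csv")))
  lm_path <- file.path(path, "probe", "landmarks.csv")
  lm <- if (file.exists(lm_path)) fread_positions(lm_path) else NULL
  probe <- probe_geometry(src, det, ch, wl, lm)

  ann <- tibble::as_tibble(
    data.table::fread(need(file.path("stim", "annotations.csv")),
                      colClasses = list(character = "annotator_id")))
  if (nrow(ann) == 0) ann <- empty_annotations()
  qual <- tibble::as_tibble(data.table::fread(need("quality.csv")))
  qual$reason <- as.character(qual$reason)
  qual$reason[is.na(qual$reason)] <- ""
  recording_bundle(
    intensity = intensity,
    sample_rate_hz = meta$sample_rate_hz,
    probe = probe,
    eeg_annotations = ann,
    sync_pulses_dot = data.table::fread(
      need(file.path("sync", "pulses_dot.csv")))$time_s %||% numeric(),
    sync_pulses_eeg = data.table::fread(
      need(file.path("sync", "pulses_eeg.csv")))$time_s %||% numeric(),
    channel_quality = qual,
    annotation_clock = meta$annotation_clock,
    truth = read_truth(file.path(path, "truth"))
  )
}
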