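#' Frame times of the six canonical event snapshots
#'
#' For one event, the named time points at which image frames are reported:
#' 30 s before onset, the onset, the HbT maximum, the max-min midpoint, the
#' minimum, and the recovery point. Points whose phase was not estimable
#' are omitted.
#'
#' @param event One row of a [seizure_event_table()].
#' @return Named numeric vector of absolute times (s).
#' @export
event_snapshot_times <- function(event) {
  onset <- event$consensus_onset_s
  tmax <- onset + event$time_to_hbt_max_s
  tmin <- tmax + event$time_max_to_min_s
  trec <- tmin + event$time_min_to_recovery_s
  out <- c(pre_onset = onset - 30, onset = onset, hbt_max = tmax,
           midpoint = (tmax + tmin) / 2, hbt_min = tmin, recovery = trec)
  out[!is.na(out)]
}

#' Match requested times to available image frames
#'
#' @param times_s Requested times (s).
#' @param frame_times_s Available frame times (s).
#' @param tol_s Maximum exact-match tolerance before the nearest frame is
#'   substituted with a warning.
#' @return Integer frame indices.
#' @export
nearest_frames <- function(times_s, frame_times_s, tol_s = 0.5) {
  idx <- vapply(times_s, function(tt) which.min(abs(frame_times_s - tt)),
                integer(1))
  off <- abs(frame_times_s[idx] - times_s)
  if (any(off > tol_s)) {
    rlang::warn(sprintf(
      "no frame within %g s of %d requested time point(s); nearest frames substituted (max offset %.1f s)",
      tol_s, sum(off > tol_s), max(off)))
  }
  idx
}

#' Build a report bundle
#'
#' Renders the analysis outputs into a directory: the per-event table as
#' CSV (the standard per-event schema), a machine-readable JSON summary
#' (events + cross-event statistics), a PNG of the global haemodynamic
#' traces with event onsets marked, and - when an image series is supplied -
#' a CSV of the per-event snapshot frames (event, snapshot name, frame time,
#' spatial max/min of HbT).
#'
#' @param events A [seizure_event_table()].
#' @param global Tibble from [global_mean()].
#' @param out_dir Output directory (created if needed).
#' @param images Optional [haemo_image_series()].
#' @param channel_amplitudes Optional amplitudes for [summarize_events()].
#' @return Invisibly, a named list of the files written.
#' @export
build_report <- function(events, global, out_dir, images = NULL,
                         channel_amplitudes = NULL) {
  if (!nrow(events)) stop_neodot("empty event table",
                                 "neodot_validation_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  files$events_csv <- file.path(out_dir, "seizure_events.csv")
  data.table::fwrite(events, files$events_csv)

  summary_tbl <- summarize_events(events, channel_amplitudes)
  files$summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(events = events, summary = summary_tbl),
    files$summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")

  files$traces_png <- file.path(out_dir, "global_traces.png")
  p <- plot_global_traces(global, onsets = events$consensus_onset_s)
  grDevices::png(files$traces_png, width = 1400, height = 700, res = 130)
  print(p)
  grDevices::dev.off()

  if (!is.null(images)) {
    hbt_img <- image_hbt(images)
    snap <- purrr::map(seq_len(nrow(events)), function(i) {
      st <- event_snapshot_times(events[i, ])
      if (!length(st)) return(NULL)
      idx <- nearest_frames(st, images$frame_times_s)
      tibble::tibble(
        event_id = events$event_id[i], snapshot = names(st),
        requested_time_s = unname(st),
        frame_time_s = images$frame_times_s[idx],
        hbt_spatial_max_uM = apply(hbt_img[idx, , drop = FALSE], 1, max),
        hbt_spatial_min_uM = apply(hbt_img[idx, , drop = FALSE], 1, min))
    })
    files$snapshots_csv <- file.path(out_dir, "event_snapshots.csv")
    data.table::fwrite(dplyr::bind_rows(snap), files$snapshots_csv)
  } else {
    message("no image series supplied; report contains traces only")
  }
  invisible(files)
}

#' Plot global haemodynamic traces
#'
#' Line plot of the global HbO/HbR/HbT traces with optional event-onset
#' markers.
#'
#' @param global Tibble with `time_s`, `hbo`, `hbr`, `hbt`.
#' @param onsets Optional event onset times (s) drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_global_traces <- function(global, onsets = NULL) {
  long <- tidyr::pivot_longer(global, c("hbo", "hbr", "hbt"),
                              names_to = "chromophore",
                              values_to = "concentration_uM")
  long$chromophore <- toupper(long$chromophore)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_s, y = .data$concentration_uM,
    colour = .data$chromophore)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(HBO = "#d62728", HBR = "#1f77b4", HBT = "#2ca02c"),
      labels = c(HBO = "HbO", HBR = "HbR", HBT = "HbT")) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "c (" * mu * "M)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(onsets) && length(onsets)) {
    p <- p + ggplot2::geom_vline(xintercept = onsets, linetype = "dashed",
                                 colour = "grey40", linewidth = 0.3)
  }
  p
}

#' @export
autoplot.haemo_series <- function(object, channels = NULL, ...) {
  long <- tidy.haemo_series(object)
  if (!is.null(channels)) long <- long[long$channel %in% channels, ]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_s, y = .data$concentration_uM,
    group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~chromophore, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "c (" * mu * "M)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.seizure_event_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    c("time_to_hbt_max_s", "time_max_to_min_s", "time_min_to_recovery_s"),
    names_to = "phase", values_to = "duration_s")
  long$phase <- factor(long$phase,
                       levels = c("time_to_hbt_max_s", "time_max_to_min_s",
                                  "time_min_to_recovery_s"),
                       labels = c("onset to max", "max to min",
                                  "min to recovery"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$event_id), y = .data$duration_s, fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "event", y = "duration (s)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.seizure_event_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.seizure_event_table <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    n_unresponsive = sum(x$unresponsive),
    n_censored = sum(x$censored),
    mean_duration_s = mean(x$dot_event_duration_s, na.rm = TRUE),
    mean_peak_hbt_uM = mean(x$peak_hbt_uM, na.rm = TRUE))
}
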