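#' Probe geometry for a DOT-EEG head cap
#'
#' A `probe_geometry` object describes the optical array: source and detector
#' positions on the scalp (in mm, in a right-handed head frame with x to the
#' right, y anterior and z superior), the ordered list of source-detector
#' channels, the illumination wavelengths, and named anatomical fiducials.
#'
#' @param source_positions Numeric matrix (sources x 3) of scalp positions in
#'   mm; row names are used as source ids (defaults to `S1`, `S2`, ...).
#' @param detector_positions Numeric matrix (detectors x 3); row names are the
#'   detector ids (defaults to `D1`, `D2`, ...).
#' @param channels Data frame with columns `source` and `detector` giving the
#'   ordered channel list as id pairs.
#' @param wavelengths Numeric vector of distinct positive wavelengths in nm.
#' @param landmarks Numeric matrix of named fiducials (nasion, inion,
#'   preauricular points) in the same frame, or `NULL`.
#'
#' @return A `probe_geometry` object.
#' @seealso [default_probe()] for the standard whole-scalp neonatal array,
#'   [channel_separations()].
#' @export
probe_geometry <- function(source_positions, detector_positions, channels,
                           wavelengths, landmarks = NULL) {
  source_positions <- as_position_matrix(source_positions, "S")
  detector_positions <- as_position_matrix(detector_positions, "D")
  channels <- tibble::as_tibble(channels[, c("source", "detector")])
  channels$source <- as.character(channels$source)
  channels$detector <- as.character(channels$detector)

  if (!all(channels$source %in% rownames(source_positions))) {
    stop_neodot("channel list references unknown source ids",
                "neodot_validation_error")
  }
  if (!all(channels$detector %in% rownames(detector_positions))) {
    stop_neodot("channel list references unknown detector ids",
                "neodot_validation_error")
  }
  wavelengths <- as.numeric(wavelengths)
  if (any(wavelengths <= 0) || anyDuplicated(wavelengths) > 0) {
    stop_neodot("wavelengths must be distinct and positive",
                "neodot_validation_error")
  }
  if (!is.null(landmarks)) {
    landmarks <- as_position_matrix(landmarks, "L")
  }
  probe <- structure(
    list(
      source_positions = source_positions,
      detector_positions = detector_positions,
      channels = channels,
      wavelengths = sort(wavelengths),
      landmarks = landmarks
    ),
    class = "probe_geometry"
  )
  sep <- channel_separations(probe)
  if (any(!is.finite(sep)) || any(sep <= 0)) {
    stop_neodot("all source-detector separations must be finite and > 0",
                "neodot_validation_error")
  }
  probe
}

as_position_matrix <- function(x, prefix) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) {
    stop_neodot("positions must have 3 columns (x, y, z in mm)",
                "neodot_validation_error")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0(prefix, seq_len(nrow(x)))
  }
  colnames(x) <- c("x", "y", "z")
  x
}

#' Source-detector separations
#'
#' @param probe A [probe_geometry()] object.
#' @return Numeric vector of geometric source-detector distances (mm), one per
#'   channel, in channel order.
#' @export
channel_separations <- function(probe) {
  stopifnot(inherits(probe, "probe_geometry"))
  s <- probe$source_positions[probe$channels$source, , drop = FALSE]
  d <- probe$detector_positions[probe$channels$detector, , drop = FALSE]
  unname(sqrt(rowSums((s - d)^2)))
}

#' Number of channels of a probe
#' @param probe A [probe_geometry()] object.
#' @return Integer channel count.
#' @export
n_channels <- function(probe) nrow(probe$channels)

#' Default whole-scalp neonatal DOT array
#'
#' Builds the standard array emulated by this package: 16 dual-wavelength
#' sources (780 and 850 nm) and 16 detectors distributed over the upper scalp
#' of a head of given circumference at 10-5-style density, paired into
#' dual-wavelength channels with source-detector separations restricted to the
#' design range. When more pairs fall inside the range than requested, the
#' channels closest to the optimal 30 mm separation are retained, mirroring a
#' design that maximises channel density at optimal separations while covering
#' the whole scalp.
#'
#' Optodes are spread over the spherical cap (polar angle up to `cap_deg`)
#' with a deterministic golden-angle lattice and alternately assigned to the
#' source and detector sets so the two interleave spatially.
#'
#' @param circumference_mm Head circumference in mm (default 340, a term
#'   neonate).
#' @param n_sources,n_detectors Number of sources and detectors.
#' @param n_target_channels Desired channel count (default 58).
#' @param separation_range_mm Admissible separation range in mm.
#' @param wavelengths Illumination wavelengths in nm.
#' @param cap_deg Polar half-angle of the optode-covered cap, degrees.
#' @return A [probe_geometry()] object.
#' @export
default_probe <- function(circumference_mm = 340,
                          n_sources = 16, n_detectors = 16,
                          n_target_channels = 58,
                          separation_range_mm = c(20, 40),
                          wavelengths = c(780, 850),
                          cap_deg = 78) {
  R <- circumference_mm / (2 * pi)
  n <- n_sources + n_detectors
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 1
  # uniform-area lattice on the cap, avoiding the pole itself
  cmin <- cos(cap_deg * pi / 180)
  cz <- 1 - (i + 0.5) / n * (1 - cmin)
  sz <- sqrt(pmax(0, 1 - cz^2))
  az <- i * golden
  pts <- R * cbind(x = sz * cos(az), y = sz * sin(az), z = cz)
  src <- pts[i %% 2 == 0, , drop = FALSE]
  det <- pts[i %% 2 == 1, , drop = FALSE]
  rownames(src) <- paste0("S", seq_len(nrow(src)))
  rownames(det) <- paste0("D", seq_len(nrow(det)))

  sep <- sqrt(outer(rowSums(src^2), rep(1, nrow(det))) +
                outer(rep(1, nrow(src)), rowSums(det^2)) -
                2 * src %*% t(det))
  ok <- which(sep >= separation_range_mm[1] & sep <= separation_range_mm[2],
              arr.ind = TRUE)
  if (nrow(ok) < n_target_channels) {
    stop_neodot(sprintf(
      "only %d pairs within the separation range; cannot form %d channels",
      nrow(ok), n_target_channels), "neodot_validation_error")
  }
  d_ok <- sep[ok]
  keep <- order(abs(d_ok - 30))[seq_len(n_target_channels)]
  ok <- ok[keep, , drop = FALSE]
  ok <- ok[order(ok[, 1], ok[, 2]), , drop = FALSE]
  channels <- tibble::tibble(
    source = rownames(src)[ok[, 1]],
    detector = rownames(det)[ok[, 2]]
  )
  landmarks <- rbind(
    nasion = c(0, R, 0),
    inion = c(0, -R, 0),
    left_preauricular = c(-R, 0, 0),
    right_preauricular = c(R, 0, 0)
  )
  probe_geometry(src, det, channels, wavelengths, landmarks)
}

#' @method print probe_geometry
#' @export
print.probe_geometry <- function(x, ...) {
  sep <- channel_separations(x)
  cat(sprintf(
    "<probe_geometry> %d sources, %d detectors, %d channels, wavelengths %s nm\n",
    nrow(x$source_positions), nrow(x$detector_positions), n_channels(x),
    paste(x$wavelengths, collapse = "/")))
  cat(sprintf("  separations %.1f-%.1f mm (median %.1f)\n",
              min(sep), max(sep), median(sep)))
  invisible(x)
}

#' @describeIn probe_geometry Tidy the channel list into a tibble with
#'   positions and separations.
#' @param x A `probe_geometry` object.
#' @param ... Unused.
#' @export
tidy.probe_geometry <- function(x, ...) {
  s <- x$source_positions[x$channels$source, , drop = FALSE]
  d <- x$detector_positions[x$channels$detector, , drop = FALSE]
  tibble::tibble(
    channel = seq_len(n_channels(x)),
    source = x$channels$source,
    detector = x$channels$detector,
    separation_mm = channel_separations(x),
    mid_x = (s[, 1] + d[, 1]) / 2,
    mid_y = (s[, 2] + d[, 2]) / 2,
    mid_z = (s[, 3] + d[, 3]) / 2
  )
}
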