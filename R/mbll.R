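#' Haemoglobin extinction coefficients
#'
#' Loads the shipped specific extinction table (natural-log convention,
#' mm^-1 uM^-1) for oxy- and deoxy-haemoglobin, compiled from the standard
#' Gratzer/Kollias spectra. The two-wavelength spectral matrix must be
#' nonsingular for chromophore separation; its condition number is attached
#' as an attribute for reporting.
#'
#' @param path Optional CSV with columns `wavelength_nm`, `eps_hbo`,
#'   `eps_hbr` (natural-log mm^-1 uM^-1) to use instead of the shipped table.
#' @return Tibble of extinction coefficients with a `condition_number`
#'   attribute (for the shipped 780/850 nm pair).
#' @export
extinction_table <- function(path = NULL) {
  tab <- tibble::as_tibble(data.table::fread(
    path %||% neodot_extdata("extinction_coefficients.csv")))
  if (any(tab$eps_hbo <= 0) || any(tab$eps_hbr <= 0)) {
    stop_neodot("extinction coefficients must be positive",
                "neodot_validation_error")
  }
  if (nrow(tab) >= 2) {
    E <- as.matrix(tab[1:2, c("eps_hbo", "eps_hbr")])
    attr(tab, "condition_number") <- kappa(E, exact = TRUE)
  }
  tab
}

# Extinction rows for the requested wavelengths, erroring on gaps and
# singular spectral systems.
extinction_at <- function(extinction, wavelengths) {
  idx <- match(wavelengths, extinction$wavelength_nm)
  if (anyNA(idx)) {
    stop_neodot(sprintf("no extinction coefficients for wavelength(s) %s nm",
                        paste(wavelengths[is.na(idx)], collapse = ", ")),
                "neodot_validation_error")
  }
  out <- extinction[idx, ]
  if (length(wavelengths) >= 2) {
    E <- as.matrix(out[, c("eps_hbo", "eps_hbr")])
    if (abs(det(crossprod(E))) < 1e-30) {
      stop_neodot("spectral extinction matrix is singular",
                  "neodot_validation_error")
    }
  }
  out
}

#' Channel-wise haemoglobin time series
#'
#' Container for per-channel oxy-/deoxy-/total haemoglobin concentration
#' changes. `hbt` is always derived as `hbo + hbr` and re-derived by every
#' operation; it is never stored independently.
#'
#' @param hbo,hbr Numeric `time x channel` matrices (uM).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param dpf Differential pathlength factor used in the conversion.
#' @param separations Per-channel source-detector distances (mm).
#' @param channels Optional channel index labels.
#' @return A `haemo_series`.
#' @export
haemo_series <- function(hbo, hbr, sample_rate_hz, dpf = NA_real_,
                         separations = NULL, channels = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)))
  if (!is.na(dpf) && dpf <= 0) {
    stop_neodot("dpf must be > 0", "neodot_validation_error")
  }
  structure(
    list(hbo = hbo, hbr = hbr, sample_rate_hz = sample_rate_hz,
         dpf = dpf, separations = separations,
         channels = channels %||% seq_len(ncol(hbo))),
    class = "haemo_series")
}

#' Total haemoglobin of a series
#' @param series A [haemo_series()].
#' @return `time x channel` matrix of HbT = HbO + HbR (uM).
#' @export
hbt <- function(series) series$hbo + series$hbr

#' @method print haemo_series
#' @export
print.haemo_series <- function(x, ...) {
  cat(sprintf("<haemo_series> %d samples x %d channels @ %g Hz (DPF %s)\n",
              nrow(x$hbo), ncol(x$hbo), x$sample_rate_hz,
              format(x$dpf)))
  invisible(x)
}

#' @export
tidy.haemo_series <- function(x, ...) {
  t <- (seq_len(nrow(x$hbo)) - 1) / x$sample_rate_hz
  long <- function(m, chrom) {
    tibble::tibble(
      time_s = rep(t, times = ncol(m)),
      channel = rep(x$channels, each = nrow(m)),
      chromophore = chrom,
      concentration_uM = as.vector(m))
  }
  dplyr::bind_rows(long(x$hbo, "HbO"), long(x$hbr, "HbR"),
                   long(hbt(x), "HbT"))
}

#' @export
glance.haemo_series <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$hbo), n_channels = ncol(x$hbo),
                 sample_rate_hz = x$sample_rate_hz, dpf = x$dpf,
                 peak_abs_hbt_uM = max(abs(hbt(x))))
}

#' Modified Beer-Lambert conversion of optical density to haemoglobin
#'
#' Solves, channel by channel and sample by sample, the spectroscopic system
#' \deqn{\Delta OD(\lambda) = \big(\varepsilon_{HbO}(\lambda)\Delta HbO +
#'   \varepsilon_{HbR}(\lambda)\Delta HbR\big)\, d \cdot DPF,}
#' where `d` is the channel's true geometric source-detector separation and
#' `DPF` the differential pathlength factor (default 4.9, a term-neonate
#' estimate). Exact for two wavelengths; ordinary least squares for more.
#'
#' @param od An [od_series()] (from [to_optical_density()]).
#' @param probe The [probe_geometry()] the data were acquired with.
#' @param extinction Extinction table (see [extinction_table()]).
#' @param dpf Differential pathlength factor (> 0).
#' @return A [haemo_series()] of concentration changes in uM.
#' @export
mbll_convert <- function(od, probe, extinction = extinction_table(),
                         dpf = 4.9) {
  stopifnot(inherits(od, "od_series"))
  if (dpf <= 0) stop_neodot("dpf must be > 0", "neodot_validation_error")
  wl <- od$wavelengths
  if (length(wl) < 2) {
    stop_neodot("at least two wavelengths are required",
                "neodot_validation_error")
  }
  eps <- extinction_at(extinction, wl)
  E <- as.matrix(eps[, c("eps_hbo", "eps_hbr")])     # n_wl x 2
  d <- channel_separations(probe)
  if (length(d) != dim(od$delta_od)[2] || anyNA(d)) {
    stop_neodot("missing channel separations", "neodot_validation_error")
  }
  # pseudo-inverse of E (exact inverse when two wavelengths)
  Einv <- solve(crossprod(E), t(E))                  # 2 x n_wl
  nt <- dim(od$delta_od)[1]; nc <- dim(od$delta_od)[2]
  hbo <- matrix(0, nt, nc); hbr <- matrix(0, nt, nc)
  for (c in seq_len(nc)) {
    odc <- od$delta_od[, c, ] / (d[c] * dpf)         # time x n_wl
    hb <- odc %*% t(Einv)                            # time x 2
    hbo[, c] <- hb[, 1]
    hbr[, c] <- hb[, 2]
  }
  haemo_series(hbo, hbr, od$sample_rate_hz, dpf = dpf, separations = d)
}

#' Forward MBLL: haemoglobin to optical density
#'
#' Inverse companion of [mbll_convert()] used by the synthetic renderer and
#' in round-trip validation: maps channel concentration changes to
#' per-wavelength optical-density changes with the same extinction table,
#' separations and DPF convention.
#'
#' @param hbo,hbr `time x channel` matrices (uM).
#' @param separations Per-channel distances (mm).
#' @param extinction Extinction table.
#' @param wavelengths Wavelengths to synthesise (nm).
#' @param dpf Differential pathlength factor.
#' @return `time x channel x wavelength` array of \eqn{\Delta OD}.
#' @export
mbll_forward <- function(hbo, hbr, separations,
                         extinction = extinction_table(),
                         wavelengths = c(780, 850), dpf = 4.9) {
  eps <- extinction_at(extinction, wavelengths)
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  out <- array(0, c(nrow(hbo), ncol(hbo), length(wavelengths)))
  for (k in seq_along(wavelengths)) {
    od <- (hbo * eps$eps_hbo[k] + hbr * eps$eps_hbr[k]) *
      rep(separations * dpf, each = nrow(hbo))
    out[, , k] <- od
  }
  out
}

#' Global mean haemodynamic signal
#'
#' Unweighted mean across retained channels, per chromophore and time point;
#' the channel-wise average used to identify the dominant features of the
#' haemodynamic data.
#'
#' @param series A [haemo_series()].
#' @param channel_mask Logical vector of channels to include (default all).
#' @return Tibble with `time_s`, `hbo`, `hbr`, `hbt` (uM).
#' @export
global_mean <- function(series, channel_mask = NULL) {
  mask <- channel_mask %||% rep(TRUE, ncol(series$hbo))
  if (!any(mask)) {
    stop_neodot("no retained channels to average", "neodot_validation_error")
  }
  tibble::tibble(
    time_s = (seq_len(nrow(series$hbo)) - 1) / series$sample_rate_hz,
    hbo = rowMeans(series$hbo[, mask, drop = FALSE]),
    hbr = rowMeans(series$hbr[, mask, drop = FALSE]),
    hbt = rowMeans(series$hbo[, mask, drop = FALSE]) +
      rowMeans(series$hbr[, mask, drop = FALSE])
  )
}

#' Linear detrending
#'
#' Removes the least-squares straight line from a trace, returning the
#' residual together with the removed slope and intercept (so the trend can
#' be reconstructed exactly).
#'
#' @param trace Numeric vector (>= 2 samples).
#' @param time_s Optional time axis; defaults to 0-based sample index.
#' @return List with `detrended`, `slope`, `intercept`.
#' @export
linear_detrend <- function(trace, time_s = NULL) {
  n <- length(trace)
  if (n < 2) stop_neodot("need at least 2 samples", "neodot_validation_error")
  t <- time_s %||% (seq_len(n) - 1)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  slope <- if (denom > 0) sum(tc * (trace - mean(trace))) / denom else 0
  intercept <- mean(trace) - slope * mean(t)
  list(detrended = trace - (slope * t + intercept),
       slope = slope, intercept = intercept)
}
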