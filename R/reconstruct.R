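#' Regularisation parameter from the stacked system
#'
#' The linear regularisation parameter is set to 1% of the largest singular
#' value of the stacked multispectral Jacobian, computed from the dominant
#' eigenvalue of \eqn{AA^\top} (the measurement dimension is small even when
#' the node dimension is large).
#'
#' @param system A `multispectral_system` (or plain matrix).
#' @param fraction Fraction of \eqn{\sigma_{max}} (default 0.01).
#' @return The scalar regularisation parameter.
#' @export
choose_lambda <- function(system, fraction = 0.01) {
  A <- if (inherits(system, "multispectral_system")) system$A else as.matrix(system)
  if (!length(A) || all(A == 0)) {
    stop_neodot("cannot choose a regularisation parameter for a zero system",
                "neodot_validation_error")
  }
  G <- tcrossprod(A)
  sigma_max <- sqrt(max(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
  fraction * sigma_max
}

#' Reconstruct one measurement frame
#'
#' Minimum-norm Tikhonov solution of the underdetermined stacked system:
#' \deqn{x = A^\top (AA^\top + \lambda^2 I)^{-1} y,}
#' splitting the stacked solution into its HbO and HbR node vectors.
#' Deterministic for fixed inputs.
#'
#' @param system A `multispectral_system`.
#' @param delta_od Stacked measurement vector (length `channels * n_wl`,
#'   wavelength-major as produced by [stack_multispectral()]).
#' @param lambda_reg Regularisation parameter (> 0); default from
#'   [choose_lambda()].
#' @param operator Optional prefactorised operator from
#'   [reconstruction_operator()] (overrides `lambda_reg`).
#' @return List with `hbo`, `hbr` node vectors (uM) and `lambda_reg`.
#' @export
reconstruct_frame <- function(system, delta_od, lambda_reg = NULL,
                              operator = NULL) {
  op <- operator %||% reconstruction_operator(
    system, lambda_reg %||% choose_lambda(system))
  if (length(delta_od) != nrow(system$A)) {
    stop_neodot(sprintf("measurement length %d does not match system rows %d",
                        length(delta_od), nrow(system$A)),
                "neodot_validation_error")
  }
  x <- op$apply(as.numeric(delta_od))
  n <- system$n_nodes
  list(hbo = x[seq_len(n)], hbr = x[n + seq_len(n)], lambda_reg = op$lambda_reg)
}

#' Prefactorised reconstruction operator
#'
#' Cholesky-factorises \eqn{AA^\top + \lambda^2 I} once so that repeated
#' frame reconstructions cost one triangular solve each.
#'
#' @param system A `multispectral_system`.
#' @param lambda_reg Regularisation parameter (> 0).
#' @return List with `apply(y)` and `lambda_reg`.
#' @export
reconstruction_operator <- function(system, lambda_reg) {
  if (lambda_reg <= 0) {
    stop_neodot("lambda_reg must be > 0", "neodot_validation_error")
  }
  A <- system$A
  G <- tcrossprod(A)
  diag(G) <- diag(G) + lambda_reg^2
  R <- chol(G)
  list(
    apply = function(y) {
      as.numeric(crossprod(A, backsolve(R, forwardsolve(t(R), y))))
    },
    lambda_reg = lambda_reg)
}

#' Tomographic image time series
#'
#' Per-frame HbO/HbR node fields; HbT is always derived as the sum via
#' [image_hbt()] and never stored.
#'
#' @param node_hbo,node_hbr `frames x nodes` matrices (uM).
#' @param frame_times_s Frame times (s).
#' @param lambda_reg Regularisation parameter used.
#' @param space_tag `"volume"` or `"gm_surface"`.
#' @param missing Optional logical vector flagging nodes with no data
#'   (surface projection).
#' @return A `haemo_image_series`.
#' @export
haemo_image_series <- function(node_hbo, node_hbr, frame_times_s,
                               lambda_reg, space_tag = "volume",
                               missing = NULL) {
  node_hbo <- as.matrix(node_hbo); node_hbr <- as.matrix(node_hbr)
  stopifnot(all(dim(node_hbo) == dim(node_hbr)),
            nrow(node_hbo) == length(frame_times_s))
  if (!is.null(lambda_reg) && lambda_reg <= 0) {
    stop_neodot("lambda_reg must be > 0", "neodot_validation_error")
  }
  structure(
    list(node_hbo = node_hbo, node_hbr = node_hbr,
         frame_times_s = as.numeric(frame_times_s),
         lambda_reg = lambda_reg, space_tag = space_tag,
         missing = missing),
    class = "haemo_image_series")
}

#' Total haemoglobin image
#' @param images A [haemo_image_series()].
#' @return `frames x nodes` HbT matrix.
#' @export
image_hbt <- function(images) images$node_hbo + images$node_hbr

#' @method print haemo_image_series
#' @export
print.haemo_image_series <- function(x, ...) {
  cat(sprintf("<haemo_image_series> %d frames x %d %s nodes (lambda %.3g)\n",
              nrow(x$node_hbo), ncol(x$node_hbo), x$space_tag,
              x$lambda_reg %||% NA))
  invisible(x)
}

#' @export
glance.haemo_image_series <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$node_hbo), n_nodes = ncol(x$node_hbo),
    space_tag = x$space_tag, lambda_reg = x$lambda_reg %||% NA_real_,
    peak_abs_hbt_uM = max(abs(image_hbt(x))))
}

#' Reconstruct an optical-density series into volume images
#'
#' Frame-by-frame multispectral Tikhonov reconstruction. The baseline is
#' subtracted in measurement (channel) space before inversion: by default
#' the series' own reference (optical density is already relative to the
#' whole-recording channel mean), or an event-locked window whose mean
#' \eqn{\Delta OD} is removed. Frames are down-sampled (default to 1 Hz);
#' the factorisation of \eqn{AA^\top + \lambda^2 I} is shared by all frames.
#'
#' @param system A `multispectral_system` (rows must correspond to this
#'   probe's channels, wavelength-major).
#' @param od An [od_series()].
#' @param lambda_reg Regularisation parameter; default [choose_lambda()].
#' @param baseline_window `NULL` (whole-recording mean reference) or
#'   `c(t0, t1)` seconds whose mean OD is subtracted per channel.
#' @param channel_mask Logical vector of retained channels; excluded
#'   channels' rows are dropped from both the system and the data.
#' @param frame_rate_hz Output frame rate (default 1; `NULL` keeps all
#'   samples).
#' @return A volume-space [haemo_image_series()].
#' @export
reconstruct_series <- function(system, od, lambda_reg = NULL,
                               baseline_window = NULL, channel_mask = NULL,
                               frame_rate_hz = 1) {
  stopifnot(inherits(od, "od_series"))
  nc <- system$n_channels
  nw <- length(system$wavelengths)
  if (dim(od$delta_od)[2] != nc || dim(od$delta_od)[3] != nw) {
    stop_neodot("od dimensions do not match the stacked system",
                "neodot_validation_error")
  }
  nt <- dim(od$delta_od)[1]
  t_all <- (seq_len(nt) - 1) / od$sample_rate_hz

  # stacked measurements, wavelength-major rows
  Y <- do.call(cbind, lapply(seq_len(nw), function(k) od$delta_od[, , k]))
  if (!is.null(baseline_window)) {
    if (baseline_window[1] < 0 || baseline_window[2] > max(t_all) ||
        baseline_window[2] <= baseline_window[1]) {
      stop_neodot("baseline window outside the recording",
                  "neodot_validation_error")
    }
    idx <- t_all >= baseline_window[1] & t_all <= baseline_window[2]
    Y <- sweep(Y, 2, colMeans(Y[idx, , drop = FALSE]))
  }

  mask <- channel_mask %||% rep(TRUE, nc)
  row_keep <- rep(mask, times = nw)
  sys_used <- system
  if (!all(mask)) {
    sys_used <- structure(
      list(A = system$A[row_keep, , drop = FALSE],
           wavelengths = system$wavelengths,
           n_channels = sum(mask), n_nodes = system$n_nodes),
      class = "multispectral_system")
    Y <- Y[, row_keep, drop = FALSE]
  }

  frames <- if (is.null(frame_rate_hz)) seq_len(nt) else {
    unique(round(seq(1, nt, by = od$sample_rate_hz / frame_rate_hz)))
  }
  lambda_reg <- lambda_reg %||% choose_lambda(sys_used)
  op <- reconstruction_operator(sys_used, lambda_reg)
  n <- sys_used$n_nodes
  hbo <- matrix(0, length(frames), n)
  hbr <- matrix(0, length(frames), n)
  for (f in seq_along(frames)) {
    x <- op$apply(Y[frames[f], ])
    hbo[f, ] <- x[seq_len(n)]
    hbr[f, ] <- x[n + seq_len(n)]
  }
  haemo_image_series(hbo, hbr, t_all[frames], lambda_reg, "volume")
}

#' Project a volume field onto the grey-matter surface
#'
#' Each grey-matter surface node receives the unweighted mean of all volume
#' nodes within `radius_mm`; surface nodes with no volume node in range are
#' flagged missing (NA). Warns when more than half of the surface is empty.
#'
#' @param values Numeric vector (one frame, length = volume nodes) or
#'   `frames x nodes` matrix.
#' @param mesh A `head_mesh` with a non-`NULL` `gm_surface`.
#' @param radius_mm Averaging radius (default 3).
#' @return Vector or matrix over surface nodes with attribute `missing`
#'   (logical per surface node).
#' @export
project_to_surface <- function(values, mesh, radius_mm = 3.0) {
  if (is.null(mesh$gm_surface)) {
    stop_neodot("mesh has no grey-matter surface", "neodot_validation_error")
  }
  if (radius_mm <= 0) {
    stop_neodot("radius_mm must be > 0", "neodot_validation_error")
  }
  one_frame <- is.null(dim(values))
  V <- if (one_frame) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(V) != nrow(mesh$nodes)) {
    stop_neodot("field length does not match mesh node count",
                "neodot_validation_error")
  }
  surf <- mesh$gm_surface$nodes
  ns <- nrow(surf)
  out <- matrix(NA_real_, nrow(V), ns)
  missing <- logical(ns)
  r2 <- radius_mm^2
  for (s in seq_len(ns)) {
    d2 <- (mesh$nodes[, 1] - surf[s, 1])^2 +
      (mesh$nodes[, 2] - surf[s, 2])^2 +
      (mesh$nodes[, 3] - surf[s, 3])^2
    nb <- which(d2 <= r2)
    if (!length(nb)) {
      missing[s] <- TRUE
    } else {
      out[, s] <- rowMeans(V[, nb, drop = FALSE])
    }
  }
  if (mean(missing) > 0.5) {
    rlang::warn(sprintf(
      "%.0f%% of surface nodes have no volume node within %g mm",
      100 * mean(missing), radius_mm))
  }
  res <- if (one_frame) out[1, ] else out
  attr(res, "missing") <- missing
  res
}

#' @rdname project_to_surface
#' @param images A volume-space [haemo_image_series()].
#' @export
project_series_to_surface <- function(images, mesh, radius_mm = 3.0) {
  hbo <- project_to_surface(images$node_hbo, mesh, radius_mm)
  hbr <- project_to_surface(images$node_hbr, mesh, radius_mm)
  haemo_image_series(hbo, hbr, images$frame_times_s, images$lambda_reg,
                     "gm_surface", missing = attr(hbo, "missing"))
}

#' Centroid of the activated region of a node field
#'
#' Volume-weighted centroid of the nodes whose value exceeds a fraction of
#' the field maximum; used to quantify localisation error against a
#' generator's ground-truth pattern centroid.
#'
#' @param values Numeric node field (length = mesh nodes).
#' @param mesh The `head_mesh`.
#' @param threshold_fraction Fraction of the maximum (default 0.5).
#' @return Length-3 centroid (mm).
#' @export
field_centroid <- function(values, mesh, threshold_fraction = 0.5) {
  vmax <- max(values)
  if (vmax <= 0) {
    stop_neodot("field has no positive values; no activation to localise",
                "neodot_validation_error")
  }
  sel <- which(values >= threshold_fraction * vmax)
  w <- values[sel] * mesh$node_volume[sel]
  as.numeric(colSums(mesh$nodes[sel, , drop = FALSE] * w) / sum(w))
}
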