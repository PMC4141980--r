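#' Adjoint absorption Jacobian for one wavelength
#'
#' Builds the sensitivity matrix mapping nodal absorption changes to
#' channel optical-density changes using the adjoint (Rytov) construction:
#' \deqn{J_{ij} = \Phi_{s(i)}(x_j)\,\Phi_{d(i)}(x_j)\,V_j / m_i,}
#' with \eqn{\Phi_{s}} the forward fluence from the channel's source,
#' \eqn{\Phi_{d}} the adjoint fluence from its detector, \eqn{V_j} the node
#' volume, and \eqn{m_i} the baseline measurement. With the lumped nodal
#' absorption used in [fem_solve()]'s assembly this is the exact derivative
#' of the discrete \eqn{\Delta OD_i = -\ln(m_i'/m_i)} with respect to nodal
#' \eqn{\Delta\mu_a}, so entries are non-negative and an absorption increase
#' maps to a positive optical-density change.
#'
#' One factorisation per wavelength is shared by all source and detector
#' solves.
#'
#' @param mesh A `head_mesh`.
#' @param probe A [probe_geometry()]; optode positions are snapped to the
#'   mesh surface convention of [fem_solve()].
#' @param wavelength_nm Wavelength (nm).
#' @return List with `J` (channels x nodes matrix, ΔOD per mm^-1),
#'   `amplitude` (baseline measurement per channel) and `wavelength_nm`.
#' @export
build_jacobian <- function(mesh, probe, wavelength_nm) {
  sys <- fem_system(mesh, wavelength_nm)
  nn <- nrow(mesh$nodes)

  solve_at <- function(pos) {
    node <- source_node(mesh, pos, sys)
    q <- numeric(nn); q[node] <- 1
    list(phi = as.numeric(Matrix::solve(sys$chol, q)), node = node)
  }
  src <- apply(probe$source_positions, 1, solve_at, simplify = FALSE)
  det <- apply(probe$detector_positions, 1, solve_at, simplify = FALSE)

  nc <- n_channels(probe)
  J <- matrix(0, nc, nn)
  amplitude <- numeric(nc)
  for (c in seq_len(nc)) {
    s <- src[[probe$channels$source[c]]]
    d <- det[[probe$channels$detector[c]]]
    if (is.null(s) || is.null(d)) {
      message(sprintf("channel %d references a missing optode; skipped", c))
      next
    }
    amplitude[c] <- s$phi[d$node]
    J[c, ] <- s$phi * d$phi * mesh$node_volume / amplitude[c]
  }
  list(J = J, amplitude = amplitude, wavelength_nm = wavelength_nm)
}

#' Jacobian set across wavelengths
#'
#' Computes the per-wavelength adjoint Jacobians for every probe wavelength
#' and, given an extinction table, the stacked multispectral system.
#'
#' @param mesh A `head_mesh`.
#' @param probe A [probe_geometry()].
#' @param extinction Extinction table from [extinction_table()]; set to
#'   `NULL` to skip the stacked system.
#' @return A `jacobian_set`: per-wavelength matrices, baseline amplitudes,
#'   node volumes and (optionally) the stacked system of
#'   [stack_multispectral()].
#' @export
build_jacobian_set <- function(mesh, probe, extinction = extinction_table()) {
  per_wl <- lapply(probe$wavelengths, function(w) build_jacobian(mesh, probe, w))
  names(per_wl) <- as.character(probe$wavelengths)
  jset <- structure(
    list(
      jacobians = lapply(per_wl, `[[`, "J"),
      amplitudes = vapply(per_wl, `[[`, numeric(n_channels(probe)),
                          "amplitude"),
      wavelengths = probe$wavelengths,
      node_volume = mesh$node_volume,
      n_nodes = nrow(mesh$nodes),
      n_channels = n_channels(probe),
      stacked = NULL
    ),
    class = "jacobian_set")
  if (!is.null(extinction)) {
    jset$stacked <- stack_multispectral(jset, extinction)
  }
  jset
}

#' @method print jacobian_set
#' @export
print.jacobian_set <- function(x, ...) {
  cat(sprintf("<jacobian_set> %d channels x %d nodes at %s nm%s\n",
              x$n_channels, x$n_nodes,
              paste(x$wavelengths, collapse = "/"),
              if (!is.null(x$stacked)) " (stacked multispectral system attached)"
              else ""))
  invisible(x)
}

#' Stack per-wavelength Jacobians into the multispectral system
#'
#' Combines the absorption Jacobians with the chromophore extinction
#' coefficients into the block system that maps stacked
#' \eqn{(\Delta HbO, \Delta HbR)} node vectors (uM) directly to stacked
#' all-wavelength \eqn{\Delta OD}:
#' \deqn{\begin{pmatrix} J(\lambda_1)\varepsilon_{HbO}(\lambda_1) &
#'   J(\lambda_1)\varepsilon_{HbR}(\lambda_1)\\
#'   J(\lambda_2)\varepsilon_{HbO}(\lambda_2) &
#'   J(\lambda_2)\varepsilon_{HbR}(\lambda_2)\end{pmatrix}}
#' Rows are ordered wavelength-major (all channels at the first wavelength,
#' then the next); columns chromophore-major (all HbO nodes, then HbR).
#'
#' @param jset A `jacobian_set` (or a plain named list of per-wavelength
#'   matrices with a `wavelengths` entry).
#' @param extinction Extinction table from [extinction_table()] covering all
#'   wavelengths.
#' @return A `multispectral_system`: `A` ((channels*n_wl) x (nodes*2)),
#'   `wavelengths`, `n_channels`, `n_nodes`.
#' @export
stack_multispectral <- function(jset, extinction = extinction_table()) {
  wl <- jset$wavelengths
  if (length(wl) < 2) {
    stop_neodot("at least two wavelengths are needed to separate HbO and HbR",
                "neodot_validation_error")
  }
  eps <- extinction_at(extinction, wl)
  blocks <- lapply(seq_along(wl), function(k) {
    J <- jset$jacobians[[as.character(wl[k])]]
    cbind(J * eps$eps_hbo[k], J * eps$eps_hbr[k])
  })
  A <- do.call(rbind, blocks)
  structure(
    list(A = A, wavelengths = wl,
         n_channels = nrow(blocks[[1]]),
         n_nodes = ncol(blocks[[1]]) / 2L),
    class = "multispectral_system")
}

#' @method print multispectral_system
#' @export
print.multispectral_system <- function(x, ...) {
  cat(sprintf("<multispectral_system> %d x %d (%d channels x %d wavelengths -> %d nodes x 2 chromophores)\n",
              nrow(x$A), ncol(x$A), x$n_channels, length(x$wavelengths),
              x$n_nodes))
  invisible(x)
}

#' Finite-difference perturbation Jacobian (oracle)
#'
#' Brute-force check of the adjoint construction: perturbs the nodal
#' absorption at selected nodes by `delta_mua` and measures the resulting
#' \eqn{\Delta OD} by re-solving the forward problem. Intended for small
#' meshes and validation only.
#'
#' @param mesh A `head_mesh`.
#' @param probe A [probe_geometry()] (single channel used).
#' @param wavelength_nm Wavelength.
#' @param channel Channel index to probe.
#' @param nodes Node indices to perturb.
#' @param delta_mua Perturbation size (mm^-1).
#' @return Numeric vector of \eqn{\Delta OD/\Delta\mu_a} per node.
#' @export
fd_jacobian <- function(mesh, probe, wavelength_nm, channel, nodes,
                        delta_mua = 1e-4) {
  sys <- fem_system(mesh, wavelength_nm)
  spos <- probe$source_positions[probe$channels$source[channel], ]
  dpos <- probe$detector_positions[probe$channels$detector[channel], ]
  s_node <- source_node(mesh, spos, sys)
  d_node <- source_node(mesh, dpos, sys)
  q <- numeric(nrow(mesh$nodes)); q[s_node] <- 1
  m0 <- as.numeric(Matrix::solve(sys$chol, q))[d_node]
  vapply(nodes, function(j) {
    Kp <- sys$K + Matrix::sparseMatrix(i = j, j = j,
                                       x = delta_mua * mesh$node_volume[j],
                                       dims = dim(sys$K), symmetric = TRUE)
    m1 <- as.numeric(Matrix::solve(Kp, q))[d_node]
    -log(m1 / m0) / delta_mua
  }, numeric(1))
}
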