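#' Continuous-wave photon diffusion FEM solver
#'
#' Solves the steady-state photon diffusion equation
#' \deqn{-\nabla\cdot(\kappa\nabla\Phi) + \mu_a\Phi = q,\qquad
#'       \kappa = 1/(3(\mu_a+\mu_s')),}
#' on a labelled tetrahedral [make_layer_mesh()] with the Robin boundary
#' condition \eqn{\Phi + 2A\kappa\,\partial\Phi/\partial n = 0}, where the
#' internal-reflection parameter A follows from the Fresnel mismatch between
#' tissue (refractive index from the property table) and air. Sources are
#' modelled as isotropic point sources placed one transport mean free path
#' (\eqn{1/\mu_s'}) beneath the optode, the standard diffusion-theory
#' convention; measurements are the fluence at the detector's subsurface
#' point.
#'
#' Assembly uses P1 elements with per-element diffusion/absorption from the
#' tissue label; the absorption mass term is lumped onto the nodes, which
#' makes the adjoint sensitivity in [build_jacobian()] the exact derivative
#' of the discrete measurement with respect to nodal absorption. The sparse
#' symmetric positive-definite system is Cholesky-factorised once per
#' wavelength (cached on the mesh) and reused across sources.
#'
#' @param mesh A `head_mesh`.
#' @param source_pos Numeric length-3 optode position on the mesh surface (mm).
#' @param wavelength_nm Wavelength whose optical properties to use.
#' @return Numeric vector of nodal fluence values (strictly positive).
#' @export
fem_solve <- function(mesh, source_pos, wavelength_nm) {
  sys <- fem_system(mesh, wavelength_nm)
  node <- source_node(mesh, source_pos, sys)
  q <- numeric(nrow(mesh$nodes))
  q[node] <- 1
  phi <- as.numeric(Matrix::solve(sys$chol, q))
  res <- sqrt(sum((as.numeric(sys$K %*% phi) - q)^2)) / sqrt(sum(q^2))
  if (res > 1e-8) {
    stop_neodot(sprintf("FEM solve residual %.2e exceeds tolerance", res),
                "neodot_numeric_error")
  }
  phi
}

# Subsurface node implementing the point-source / detector convention.
source_node <- function(mesh, pos, sys) {
  pos <- as.numeric(pos)
  target <- pos + sys$z0 * inward_direction(mesh, pos)
  nearest_node(mesh, target)
}

# Assemble (and cache) the FEM system for one wavelength.
fem_system <- function(mesh, wavelength_nm) {
  key <- sprintf("sys_%g", wavelength_nm)
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])

  props <- mesh$properties[mesh$properties$wavelength_nm == wavelength_nm, ]
  if (!nrow(props)) {
    stop_neodot(sprintf("no optical properties at %g nm", wavelength_nm),
                "neodot_validation_error")
  }
  if (any(props$mua_mm <= 0) || any(props$musp_mm <= 0)) {
    stop_neodot("optical properties must be positive", "neodot_validation_error")
  }
  lut <- setNames(seq_len(nrow(props)), props$tissue)
  ti <- lut[mesh$tissue]
  mua_t <- props$mua_mm[ti]
  musp_t <- props$musp_mm[ti]
  kappa_t <- 1 / (3 * (mua_t + musp_t))

  nodes <- mesh$nodes
  tets <- mesh$tets
  nt <- nrow(tets)
  vol <- mesh$tet_volume

  # P1 gradients: grad(lambda_i) = n_i / (n_i . (p_i - p_a)) with n_i the
  # (unoriented) normal of the opposite face
  P <- lapply(1:4, function(i) nodes[tets[, i], , drop = FALSE])
  opp <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  grads <- vector("list", 4)
  for (i in 1:4) {
    f <- opp[[i]]
    a <- P[[f[2]]] - P[[f[1]]]
    b <- P[[f[3]]] - P[[f[1]]]
    n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    h <- rowSums(n * (P[[i]] - P[[f[1]]]))
    grads[[i]] <- n / h
  }

  # stiffness triplets (upper triangle incl. diagonal)
  ii <- jj <- xx <- vector("list", 10)
  m <- 1
  for (i in 1:4) for (j in i:4) {
    # canonicalise to the upper triangle: local ordering of a tet's vertex
    # indices says nothing about their global order
    ii[[m]] <- pmin(tets[, i], tets[, j])
    jj[[m]] <- pmax(tets[, i], tets[, j])
    xx[[m]] <- kappa_t * vol * rowSums(grads[[i]] * grads[[j]])
    m <- m + 1
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(nodes), 2), symmetric = TRUE)

  # lumped nodal absorption: mua averaged onto nodes weighted by volume share
  mua_node_num <- numeric(nrow(nodes))
  agg <- rowsum(rep(mua_t * vol / 4, 4), as.vector(tets))
  mua_node_num[as.integer(rownames(agg))] <- agg[, 1]
  mua_node <- ifelse(mesh$node_volume > 0,
                     mua_node_num / mesh$node_volume, 0)
  K <- K + Matrix::Diagonal(x = mua_node * mesh$node_volume)

  # Robin boundary term (lumped): (1/2A) * Area/3 on each boundary-face node
  n_outer <- props$refractive_index[match(outer_tissue(mesh), props$tissue)]
  A <- fresnel_A(n_outer)
  bf <- boundary_faces(tets)
  e1 <- nodes[bf[, 2], , drop = FALSE] - nodes[bf[, 1], , drop = FALSE]
  e2 <- nodes[bf[, 3], , drop = FALSE] - nodes[bf[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  bdiag <- numeric(nrow(nodes))
  agg <- rowsum(rep(area / 3, 3), as.vector(bf))
  bdiag[as.integer(rownames(agg))] <- agg[, 1]
  K <- K + Matrix::Diagonal(x = bdiag / (2 * A))

  ch <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop_neodot(
                     "FEM system is not positive definite (degenerate mesh?)",
                     "neodot_numeric_error")
                 })
  # source depth: one transport mean free path in the outermost tissue
  z0 <- 1 / props$musp_mm[match(outer_tissue(mesh), props$tissue)]
  sys <- list(K = K, chol = ch, mua_node = mua_node, z0 = z0, A = A,
              wavelength_nm = wavelength_nm)
  mesh$cache[[key]] <- sys
  sys
}

outer_tissue <- function(mesh) {
  if (mesh$geometry$type == "slab") {
    depth <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
                mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
    mesh$tissue[which.min(depth)]
  } else {
    ctr <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
              mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
    mesh$tissue[which.max(rowSums(ctr^2))]
  }
}

# Internal reflection parameter from the empirical polynomial fit to the
# Fresnel reflectance of a tissue/air interface.
fresnel_A <- function(n) {
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + r_eff) / (1 - r_eff)
}

# Faces appearing in exactly one tet = boundary triangulation.
boundary_faces <- function(tets) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c3
  o <- order(a, b, c3)
  sa <- a[o]; sb <- b[o]; sc <- c3[o]
  same_next <- c(sa[-1] == sa[-length(sa)] & sb[-1] == sb[-length(sb)] &
                   sc[-1] == sc[-length(sc)], FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  faces[o[!same_next & !same_prev], , drop = FALSE]
}

#' Boundary measurement between two optodes
#'
#' Fluence at the detector's subsurface point for a unit isotropic source
#' beneath the source optode. By symmetry of the diffusion operator this is
#' reciprocal in source and detector.
#'
#' @param mesh A `head_mesh`.
#' @param source_pos,detector_pos Optode positions on the surface (mm).
#' @param wavelength_nm Wavelength (nm).
#' @return Scalar measurement (fluence per unit source power).
#' @export
fem_measure <- function(mesh, source_pos, detector_pos, wavelength_nm) {
  sys <- fem_system(mesh, wavelength_nm)
  phi <- fem_solve(mesh, source_pos, wavelength_nm)
  phi[source_node(mesh, detector_pos, sys)]
}

#' Semi-infinite medium analytic boundary fluence
#'
#' Closed-form extrapolated-boundary (image source) solution of the
#' continuous-wave diffusion equation for a homogeneous semi-infinite medium:
#' an isotropic source at depth \eqn{z_0 = 1/\mu_s'} plus a negative image
#' source mirrored about the extrapolated boundary at \eqn{-z_b},
#' \eqn{z_b = 2AD}. Used as the independent oracle for [fem_solve()].
#'
#' @param rho_mm Source-detector separation(s) along the surface (mm).
#' @param mua_mm,musp_mm Absorption and reduced scattering (mm^-1).
#' @param n Tissue refractive index (air outside).
#' @param z_mm Depth of the evaluation point (defaults to the detector
#'   convention used by the FEM, \eqn{1/\mu_s'}).
#' @return Fluence value(s); warns outside the diffusion regime
#'   (\eqn{\rho \le 3/\mu_s'}).
#' @export
analytic_semi_infinite <- function(rho_mm, mua_mm, musp_mm, n = 1.4,
                                   z_mm = 1 / musp_mm) {
  if (any(rho_mm <= 3 / musp_mm)) {
    rlang::warn("separation inside ~3 transport mean free paths: diffusion theory unreliable")
  }
  D <- 1 / (3 * (mua_mm + musp_mm))
  mueff <- sqrt(mua_mm / D)
  z0 <- 1 / musp_mm
  zb <- 2 * fresnel_A(n) * D
  r1 <- sqrt(rho_mm^2 + (z_mm - z0)^2)
  r2 <- sqrt(rho_mm^2 + (z_mm + z0 + 2 * zb)^2)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Effective attenuation coefficient
#' @param mua_mm,musp_mm Optical coefficients (mm^-1).
#' @return \eqn{\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}} in mm^-1.
#' @export
mu_eff <- function(mua_mm, musp_mm) sqrt(3 * mua_mm * (mua_mm + musp_mm))
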