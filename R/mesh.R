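#' Per-tissue optical properties
#'
#' Reads the shipped table of per-tissue absorption and reduced scattering
#' coefficients and refractive indices at the package's default wavelengths.
#' The values are standard adult-head literature values (scalp/skull combined
#' as extra-cerebral tissue, cerebrospinal fluid with the customary raised
#' scattering so the diffusion approximation remains valid, grey and white
#' matter); infant-specific coefficients are not available in the literature
#' and adult values are the accepted stand-in. Fully overridable: any tibble
#' with columns `tissue`, `wavelength_nm`, `mua_mm`, `musp_mm`,
#' `refractive_index` may be passed wherever properties are accepted.
#'
#' @return Tibble of tissue optical properties.
#' @export
default_tissue_properties <- function() {
  tibble::as_tibble(data.table::fread(
    neodot_extdata("tissue_optical_properties.csv")))
}

#' Layered tetrahedral head mesh
#'
#' Generates a watertight, labelled tetrahedral mesh of a parametric layered
#' head geometry, together with a triangulated grey-matter surface. Two
#' geometries are provided: a rectangular `"slab"` (optode surface at z = 0,
#' depth increasing with z) used for validation against the semi-infinite
#' analytic solution, and a `"hemisphere"` (flat base at z = 0, scalp cap of
#' the given circumference) used as the stand-in for a whole-head model.
#'
#' Both are built from a structured hexahedral grid split into six
#' tetrahedra per cell (Kuhn subdivision, conforming across cells); the
#' hemisphere maps the grid cube onto the half-ball by the equal-max-norm
#' radial map, so mesh volume converges to the analytic hemisphere volume at
#' second order in the edge length. Tissue labels are assigned per element by
#' centroid depth (slab) or centroid radius (hemisphere), outermost layer
#' first; the remaining interior is labelled with `inner_tissue`.
#'
#' @param geometry `"slab"` or `"hemisphere"`.
#' @param layer_thicknesses Named numeric vector of layer thicknesses in mm,
#'   outermost first (default `c(extracerebral = 6, csf = 2, grey = 4)`); the
#'   interior fills with `inner_tissue`. Use a single `Inf` thickness for a
#'   homogeneous mesh.
#' @param target_edge_mm Nominal element edge length (mm).
#' @param slab_dims_mm Slab extents `c(Lx, Ly, Lz)` in mm (slab only).
#' @param x_breaks,y_breaks,z_breaks Optional explicit (possibly graded) grid
#'   planes for the slab, overriding uniform spacing.
#' @param circumference_mm Head circumference (hemisphere only; default 340).
#' @param inner_tissue Label of the innermost filling tissue.
#' @param properties Optical property table (see
#'   [default_tissue_properties()]).
#' @return A `head_mesh` with fields `nodes`, `tets`, `tissue`, `tet_volume`,
#'   `node_volume`, `gm_surface` (`nodes` + `faces`, or `NULL` when no grey
#'   layer exists), `properties`, `geometry`, and `quality` (the minimum
#'   dihedral angle in degrees).
#' @export
make_layer_mesh <- function(geometry = c("hemisphere", "slab"),
                            layer_thicknesses = c(extracerebral = 6,
                                                  csf = 2, grey = 4),
                            target_edge_mm = 4,
                            slab_dims_mm = c(60, 60, 40),
                            x_breaks = NULL, y_breaks = NULL, z_breaks = NULL,
                            circumference_mm = 340,
                            inner_tissue = "white",
                            properties = default_tissue_properties()) {
  geometry <- match.arg(geometry)
  if (any(layer_thicknesses <= 0)) {
    stop_neodot("layer thicknesses must be positive", "neodot_validation_error")
  }
  if (target_edge_mm <= 0) {
    stop_neodot("target_edge_mm must be positive", "neodot_validation_error")
  }
  thin <- min(layer_thicknesses)
  if (is.finite(thin) && target_edge_mm > 4 * thin) {
    stop_neodot(sprintf(
      "target edge %g mm cannot resolve the thinnest layer (%g mm)",
      target_edge_mm, thin), "neodot_validation_error")
  }

  if (geometry == "slab") {
    gx <- x_breaks %||% seq(0, slab_dims_mm[1],
                            length.out = max(2, ceiling(slab_dims_mm[1] / target_edge_mm) + 1))
    gy <- y_breaks %||% seq(0, slab_dims_mm[2],
                            length.out = max(2, ceiling(slab_dims_mm[2] / target_edge_mm) + 1))
    gz <- z_breaks %||% seq(0, slab_dims_mm[3],
                            length.out = max(2, ceiling(slab_dims_mm[3] / target_edge_mm) + 1))
    grid <- structured_tets(gx, gy, gz)
    nodes <- grid$nodes
    depth <- grid$centroid[, 3]
    geom <- list(type = "slab", dims = c(max(gx) - min(gx),
                                         max(gy) - min(gy),
                                         max(gz) - min(gz)))
  } else {
    R <- circumference_mm / (2 * pi)
    n_xy <- max(4, 2 * ceiling(R / target_edge_mm))
    n_z <- max(2, ceiling(R / target_edge_mm))
    grid <- structured_tets(seq(-1, 1, length.out = n_xy + 1),
                            seq(-1, 1, length.out = n_xy + 1),
                            seq(0, 1, length.out = n_z + 1))
    nodes <- cube_to_ball(grid$nodes) * R
    grid <- recompute_tets(nodes, grid$tets)
    depth <- R - sqrt(rowSums(grid$centroid^2))
    geom <- list(type = "hemisphere", radius = R,
                 circumference = circumference_mm)
  }

  tets <- grid$tets
  vol <- grid$volume
  if (any(vol <= 0)) {
    stop_neodot("mesh generation produced degenerate elements; refine target_edge_mm",
                "neodot_validation_error")
  }

  labels <- names(layer_thicknesses) %||%
    paste0("layer", seq_along(layer_thicknesses))
  if (length(layer_thicknesses) == 1 && !is.finite(layer_thicknesses[1])) {
    tissue <- rep(labels[1], nrow(tets))
  } else {
    edges <- cumsum(layer_thicknesses)
    lab_all <- c(labels, inner_tissue)
    idx <- findInterval(depth, c(0, edges), rightmost.closed = FALSE)
    tissue <- lab_all[pmin(pmax(idx, 1), length(lab_all))]
  }

  missing_props <- setdiff(unique(tissue), unique(properties$tissue))
  if (length(missing_props)) {
    stop_neodot(sprintf("no optical properties for tissue(s): %s",
                        paste(missing_props, collapse = ", ")),
                "neodot_validation_error")
  }

  node_volume <- numeric(nrow(nodes))
  agg <- rowsum(rep(vol / 4, 4), as.vector(tets))
  node_volume[as.integer(rownames(agg))] <- agg[, 1]

  mesh <- structure(
    list(nodes = nodes, tets = tets, tissue = tissue,
         tet_volume = vol, node_volume = node_volume,
         gm_surface = NULL, properties = tibble::as_tibble(properties),
         geometry = geom,
         quality = min_dihedral_deg(nodes, tets),
         cache = new.env(parent = emptyenv())),
    class = "head_mesh")

  if ("grey" %in% tissue && geometry == "hemisphere") {
    r_gm <- geom$radius - sum(layer_thicknesses[seq_len(
      which(names(layer_thicknesses) == "grey") - 1)])
    mesh$gm_surface <- uv_hemisphere_surface(r_gm, target_edge_mm)
  } else if ("grey" %in% tissue && geometry == "slab") {
    z_gm <- c(0, cumsum(layer_thicknesses))[which(names(layer_thicknesses) == "grey")]
    mesh$gm_surface <- plane_surface(range(nodes[, 1]), range(nodes[, 2]),
                                     z_gm, target_edge_mm)
  }
  mesh
}

# Structured grid -> conforming 6-tet (Kuhn) subdivision.
structured_tets <- function(gx, gy, gz) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  nodes <- cbind(x = rep(gx, times = ny * nz),
                 y = rep(rep(gy, each = nx), times = nz),
                 z = rep(gz, each = nx * ny))
  idx <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  ci <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  ck <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  v <- function(di, dj, dk) idx(ci + di, cj + dj, ck + dk)
  # six tets along the (1,1,1) diagonal: permutations of axis insertion order
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  steps <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tet_list <- lapply(perms, function(p) {
    s1 <- steps[[p[1]]]
    s2 <- s1 + steps[[p[2]]]
    cbind(v(0, 0, 0),
          v(s1[1], s1[2], s1[3]),
          v(s2[1], s2[2], s2[3]),
          v(1, 1, 1))
  })
  tets <- do.call(rbind, tet_list)
  out <- recompute_tets(nodes, tets)
  out$nodes <- nodes
  out
}

# Fix orientation, compute volumes and centroids for a node/tet pair.
recompute_tets <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  detv <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  flip <- detv < 0
  if (any(flip)) {
    tmp <- tets[flip, 3]
    tets[flip, 3] <- tets[flip, 4]
    tets[flip, 4] <- tmp
  }
  vol <- abs(detv) / 6
  centroid <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
                 nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  list(nodes = nodes, tets = tets, volume = vol, centroid = centroid)
}

# Equal-max-norm radial map: bijection from the unit cube (half) onto the
# (half) ball; L-infinity shells map onto spheres, so the cube surface maps
# exactly onto the sphere.
cube_to_ball <- function(p) {
  linf <- pmax(abs(p[, 1]), abs(p[, 2]), abs(p[, 3]))
  l2 <- sqrt(rowSums(p^2))
  f <- ifelse(l2 > 0, linf / l2, 0)
  p * f
}

min_dihedral_deg <- function(nodes, tets) {
  # outward unit normal of each tet face (face i omits vertex i)
  faces <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  normals <- lapply(seq_len(4), function(i) {
    f <- faces[[i]]
    a <- nodes[tets[, f[2]], , drop = FALSE] - nodes[tets[, f[1]], , drop = FALSE]
    b <- nodes[tets[, f[3]], , drop = FALSE] - nodes[tets[, f[1]], , drop = FALSE]
    n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    n <- n / sqrt(rowSums(n^2))
    # orient away from the omitted vertex
    toward <- rowSums(n * (nodes[tets[, i], , drop = FALSE] -
                             nodes[tets[, f[1]], , drop = FALSE]))
    n * ifelse(toward > 0, -1, 1)
  })
  worst <- 180
  pairs <- utils::combn(4, 2)
  for (q in seq_len(ncol(pairs))) {
    cosang <- rowSums(normals[[pairs[1, q]]] * normals[[pairs[2, q]]])
    dihedral <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    worst <- min(worst, dihedral)
  }
  worst
}

# Triangulated spherical cap at radius r (UV grid with pole fan).
uv_hemisphere_surface <- function(r, target_edge_mm) {
  n_th <- max(4, ceiling((pi / 2) * r / target_edge_mm))
  n_ph <- max(8, ceiling(2 * pi * r / target_edge_mm))
  th <- seq(pi / 2 / n_th, pi / 2, length.out = n_th)  # exclude pole row
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[-(n_ph + 1)]
  ring <- function(theta) {
    cbind(r * sin(theta) * cos(ph), r * sin(theta) * sin(ph),
          r * cos(theta))
  }
  nodes <- rbind(c(0, 0, r), do.call(rbind, lapply(th, ring)))
  faces <- list()
  # pole fan to first ring
  first <- 1 + seq_len(n_ph)
  faces[[1]] <- cbind(1, first, c(first[-1], first[1]))
  for (i in seq_len(n_th - 1)) {
    a <- 1 + (i - 1) * n_ph + seq_len(n_ph)
    b <- a + n_ph
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces[[length(faces) + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  list(nodes = nodes, faces = do.call(rbind, faces))
}

plane_surface <- function(xr, yr, z, target_edge_mm) {
  gx <- seq(xr[1], xr[2], length.out = max(2, ceiling(diff(xr) / target_edge_mm) + 1))
  gy <- seq(yr[1], yr[2], length.out = max(2, ceiling(diff(yr) / target_edge_mm) + 1))
  nx <- length(gx); ny <- length(gy)
  nodes <- cbind(rep(gx, times = ny), rep(gy, each = nx), z)
  ci <- rep(seq_len(nx - 1), times = ny - 1)
  cj <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- ci + (cj - 1) * nx
  faces <- rbind(cbind(v00, v00 + 1, v00 + nx + 1),
                 cbind(v00, v00 + nx + 1, v00 + nx))
  list(nodes = nodes, faces = faces)
}

#' Total mesh volume
#' @param mesh A `head_mesh`.
#' @return Summed element volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(mesh$tet_volume)

#' @method print head_mesh
#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("<head_mesh> %s: %d nodes, %d tets, %.0f mm^3, min dihedral %.1f deg\n",
              x$geometry$type, nrow(x$nodes), nrow(x$tets), mesh_volume(x),
              x$quality))
  tt <- table(x$tissue)
  cat("  tissues:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "),
      "\n")
  if (!is.null(x$gm_surface)) {
    cat(sprintf("  grey-matter surface: %d nodes, %d faces\n",
                nrow(x$gm_surface$nodes), nrow(x$gm_surface$faces)))
  }
  invisible(x)
}

# Inward (into-tissue) unit direction at a scalp position.
inward_direction <- function(mesh, pos) {
  if (mesh$geometry$type == "slab") {
    c(0, 0, 1)
  } else {
    -pos / sqrt(sum(pos^2))
  }
}

nearest_node <- function(mesh, pos) {
  d2 <- (mesh$nodes[, 1] - pos[1])^2 + (mesh$nodes[, 2] - pos[2])^2 +
    (mesh$nodes[, 3] - pos[3])^2
  which.min(d2)
}
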