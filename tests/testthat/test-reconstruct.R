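make_toy_system <- function(nm = 10, nn = 40, seed = 5) {
  set.seed(seed)
  A <- matrix(rexp(nm * 2 * nn), nm, 2 * nn)
  structure(list(A = A, wavelengths = c(780, 850),
                 n_channels = nm / 2, n_nodes = nn),
            class = "multispectral_system")
}

test_that("Tikhonov frame equals the dense SVD-filtered solution", {
  sys <- make_toy_system()
  set.seed(6)
  y <- rnorm(10)
  lam <- choose_lambda(sys)
  x <- reconstruct_frame(sys, y)
  sv <- svd(sys$A)
  f <- sv$d / (sv$d^2 + lam^2)
  x_svd <- sv$v %*% (f * crossprod(sv$u, y))
  expect_lt(max(abs(c(x$hbo, x$hbr) - x_svd)), 1e-8)
  expect_equal(x$lambda_reg, 0.01 * max(sv$d), tolerance = 1e-12)
})

test_that("choose_lambda is 1% of the top singular value", {
  sys <- make_toy_system(seed = 9)
  expect_equal(choose_lambda(sys), 0.01 * max(svd(sys$A)$d),
               tolerance = 1e-12)
  expect_equal(choose_lambda(sys, fraction = 0.1),
               10 * choose_lambda(sys), tolerance = 1e-12)
  zero <- sys; zero$A[] <- 0
  expect_error(choose_lambda(zero), class = "neodot_validation_error")
})

test_that("reconstruction is linear and the operator is reusable", {
  sys <- make_toy_system(seed = 7)
  op <- reconstruction_operator(sys, lambda_reg = 0.5)
  y1 <- rnorm(10); y2 <- rnorm(10)
  x1 <- reconstruct_frame(sys, y1, operator = op)
  x2 <- reconstruct_frame(sys, y2, operator = op)
  x12 <- reconstruct_frame(sys, 2 * y1 + 3 * y2, operator = op)
  expect_equal(x12$hbo, 2 * x1$hbo + 3 * x2$hbo, tolerance = 1e-10)
  expect_equal(x12$hbr, 2 * x1$hbr + 3 * x2$hbr, tolerance = 1e-10)
  expect_equal(reconstruct_frame(sys, y1, lambda_reg = 0.5), x1)
  expect_error(reconstruct_frame(sys, y1[1:4]),
               class = "neodot_validation_error")
  expect_error(reconstruction_operator(sys, 0),
               class = "neodot_validation_error")
})

test_that("series reconstruction downsamples, baselines and masks", {
  sys <- make_toy_system(nm = 8, nn = 20, seed = 8)
  nt <- 40; nc <- 4
  set.seed(10)
  arr <- array(rnorm(nt * nc * 2, 0, 0.01), c(nt, nc, 2))
  od <- od_series(arr, matrix(1, nc, 2), sample_rate_hz = 2, c(780, 850))
  img <- reconstruct_series(sys, od, lambda_reg = 0.3, frame_rate_hz = 1)
  expect_s3_class(img, "haemo_image_series")
  expect_equal(nrow(img$node_hbo), 20)          # 2 Hz -> 1 Hz over 40 samples
  expect_equal(img$frame_times_s[1:3], c(0, 1, 2))
  expect_equal(img$lambda_reg, 0.3)
  # frame f equals a standalone frame reconstruction of the same sample
  y5 <- c(arr[9, , 1], arr[9, , 2])
  x5 <- reconstruct_frame(sys, y5, lambda_reg = 0.3)
  expect_equal(img$node_hbo[5, ], x5$hbo, tolerance = 1e-10)
  # baseline subtraction removes a constant channel offset entirely
  arr_off <- sweep(arr, 2:3, array(5, c(nc, 2)), `+`)
  od_off <- od_series(arr_off, matrix(1, nc, 2), 2, c(780, 850))
  img_b <- reconstruct_series(sys, od_off, lambda_reg = 0.3,
                              baseline_window = c(0, 19.5))
  imgb0 <- reconstruct_series(sys, od, lambda_reg = 0.3,
                              baseline_window = c(0, 19.5))
  expect_equal(img_b$node_hbo, imgb0$node_hbo, tolerance = 1e-9)
  # channel mask drops rows of both data and system
  img_m <- reconstruct_series(sys, od, lambda_reg = 0.3,
                              channel_mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(dim(img_m$node_hbo), c(20, 20))
  expect_error(reconstruct_series(sys, od, baseline_window = c(-5, 2)),
               class = "neodot_validation_error")
})

test_that("image containers derive HbT and validate shapes", {
  img <- haemo_image_series(matrix(1, 2, 3), matrix(2, 2, 3), c(0, 1), 0.1)
  expect_equal(image_hbt(img), matrix(3, 2, 3))
  expect_error(haemo_image_series(matrix(1, 2, 3), matrix(1, 2, 3),
                                  c(0, 1), lambda_reg = -1),
               class = "neodot_validation_error")
  g <- generics::glance(img)
  expect_equal(g$n_frames, 2)
  expect_equal(g$peak_abs_hbt_uM, 3)
})

test_that("field centroid recovers simple geometry", {
  mesh <- coarse_slab()
  target <- c(30, 20, 5)
  d2 <- rowSums(sweep(mesh$nodes, 2, target)^2)
  values <- exp(-d2 / (2 * 8^2))
  cen <- field_centroid(values, mesh)
  expect_lt(sqrt(sum((cen - target)^2)), 3)
  expect_error(field_centroid(-values, mesh),
               class = "neodot_validation_error")
  # threshold 1 keeps only the maximum node
  imax <- which.max(values)
  expect_equal(field_centroid(values, mesh, threshold_fraction = 1),
               as.numeric(mesh$nodes[imax, ]))
})

test_that("surface projection averages within radius and flags gaps", {
  mesh <- make_layer_mesh("slab",
                          layer_thicknesses = c(extracerebral = 6, csf = 2,
                                                grey = 4),
                          slab_dims_mm = c(40, 40, 30), target_edge_mm = 2)
  vals <- mesh$nodes[, 3]          # field = depth: projection ~ gm depth
  surf <- project_to_surface(vals, mesh, radius_mm = 3)
  miss <- attr(surf, "missing")
  expect_length(surf, nrow(mesh$gm_surface$nodes))
  expect_true(all(abs(surf[!miss] - mesh$gm_surface$nodes[, 3]) <= 3))
  hmesh <- make_layer_mesh("hemisphere")
  expect_warning(project_to_surface(rep(1, nrow(hmesh$nodes)), hmesh,
                                    radius_mm = 0.05),
                 "no volume node")
  expect_error(project_to_surface(vals[-1], mesh),
               class = "neodot_validation_error")
  expect_error(project_to_surface(vals, coarse_slab()),
               class = "neodot_validation_error")  # no grey surface
  # series projection keeps frame structure and tags the space
  img <- haemo_image_series(rbind(vals, 2 * vals), rbind(vals, vals),
                            c(0, 1), 0.1)
  simg <- project_series_to_surface(img, mesh)
  expect_equal(simg$space_tag, "gm_surface")
  expect_equal(simg$node_hbo[2, !miss], 2 * simg$node_hbo[1, !miss])
})
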