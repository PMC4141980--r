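test_that("shipped extinction table is sane and well conditioned", {
  et <- extinction_table()
  expect_true(all(c(780, 850) %in% et$wavelength_nm))
  expect_true(all(et$eps_hbo > 0 & et$eps_hbr > 0))
  # HbR dominates at 780 nm, HbO at 850 nm (isosbestic point near 800 nm)
  e780 <- et[et$wavelength_nm == 780, ]
  e850 <- et[et$wavelength_nm == 850, ]
  expect_gt(e780$eps_hbr, e780$eps_hbo)
  expect_gt(e850$eps_hbo, e850$eps_hbr)
  expect_lt(attr(et, "condition_number"), 20)
})

test_that("MBLL round-trips concentrations exactly", {
  set.seed(31)
  nt <- 500; nc <- 8
  hbo <- matrix(rnorm(nt * nc, 0, 2), nt, nc)
  hbr <- matrix(rnorm(nt * nc, 0, 1), nt, nc)
  sep <- seq(20, 40, length.out = nc)
  od <- mbll_forward(hbo, hbr, sep)
  ods <- od_series(od, matrix(1, nc, 2), 10, c(780, 850))
  back <- mbll_convert(ods, line_probe(sep))
  expect_lt(max(abs(back$hbo - hbo)), 1e-9)
  expect_lt(max(abs(back$hbr - hbr)), 1e-9)
})

test_that("MBLL scales inversely with separation and DPF", {
  od <- mbll_forward(matrix(1), matrix(0), separations = 30, dpf = 4.9)
  od2 <- mbll_forward(matrix(1), matrix(0), separations = 60, dpf = 4.9)
  expect_equal(2 * od[1, 1, ], od2[1, 1, ])
  ods <- od_series(od, matrix(1, 1, 2), 10, c(780, 850))
  half_dpf <- mbll_convert(ods, line_probe(30), dpf = 2.45)
  expect_equal(half_dpf$hbo[1, 1], 2, tolerance = 1e-9)
})

test_that("MBLL input validation", {
  od <- mbll_forward(matrix(1), matrix(0), 30)
  ods <- od_series(od, matrix(1, 1, 2), 10, c(780, 850))
  expect_error(mbll_convert(ods, line_probe(30), dpf = 0),
               class = "neodot_validation_error")
  ods1 <- od_series(od[, , 1, drop = FALSE], matrix(1, 1, 1), 10, 780)
  expect_error(mbll_convert(ods1, line_probe(30)),
               class = "neodot_validation_error")  # one wavelength
  expect_error(od_series(array(NaN, c(2, 1, 2)), matrix(1, 1, 2), 10,
                         c(780, 850)),
               class = "neodot_validation_error")
})

test_that("haemo containers derive HbT and tidy to long format", {
  hs <- haemo_series(matrix(1:6, 3, 2), matrix(0.5, 3, 2), 10)
  expect_equal(hbt(hs), matrix(1:6, 3, 2) + 0.5)
  td <- generics::tidy(hs)
  expect_equal(nrow(td), 3 * 2 * 3)
  expect_setequal(unique(td$chromophore), c("HbO", "HbR", "HbT"))
  g <- generics::glance(hs)
  expect_equal(g$n_channels, 2)
})

test_that("global mean averages only retained channels", {
  hbo <- cbind(rep(1, 5), rep(3, 5), rep(100, 5))
  hs <- haemo_series(hbo, -hbo / 2, 10)
  g <- global_mean(hs, channel_mask = c(TRUE, TRUE, FALSE))
  expect_equal(unique(g$hbo), 2)
  expect_equal(unique(g$hbt), 1)
  expect_named(g, c("time_s", "hbo", "hbr", "hbt"))
})

test_that("linear detrend removes an exact line", {
  t <- seq(0, 100, by = 0.1)
  d <- linear_detrend(3 + 0.2 * t, t)
  expect_equal(d$slope, 0.2, tolerance = 1e-9)
  expect_equal(d$intercept, 3, tolerance = 1e-9)
  expect_lt(max(abs(d$detrended)), 1e-9)
  # least-squares residuals always have zero mean
  d2 <- linear_detrend(3 + 0.2 * t + sin(t), t)
  expect_lt(abs(mean(d2$detrended)), 1e-9)
})
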