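test_that("range estimation recovers a known uniform range", {
  set.seed(31)
  vox <- array(runif(8000, 0.40, 0.60), dim = c(20, 20, 20))
  lab <- array(1L, dim = c(20, 20, 20))
  r <- estimate_range(vox, lab, 1L, trim = c(0, 100))
  expect_equal(r[1], 0.40, tolerance = 5e-3)
  expect_equal(r[2], 0.60, tolerance = 5e-3)
})

test_that("percentile trimming suppresses injected outliers", {
  set.seed(32)
  vals <- c(runif(9990, 0.40, 0.60), rep(0.95, 10))
  vox <- array(vals, dim = c(10, 10, 100))
  lab <- array(1L, dim = c(10, 10, 100))
  r <- estimate_range(vox, lab, 1L)  # default trim (0.5, 99.5)
  expect_lt(r[2], 0.62)
  r_untrimmed <- estimate_range(vox, lab, 1L, trim = c(0, 100))
  expect_equal(r_untrimmed[2], 0.95)
})

test_that("degenerate organs are rejected downstream", {
  vox <- array(0.5, dim = c(4, 4, 4))
  lab <- array(1L, dim = c(4, 4, 4))
  r <- estimate_range(vox, lab, 1L)
  expect_equal(r, c(0.5, 0.5))
  expect_error(fit_rangeclip(r[1], r[2]), "zero-width")
  expect_error(estimate_range(vox, lab, 7L), "no voxels")
})

test_that("range estimation is invariant to volume order", {
  set.seed(33)
  v1 <- array(runif(512, 0.3, 0.5), dim = c(8, 8, 8))
  v2 <- array(runif(512, 0.35, 0.55), dim = c(8, 8, 8))
  l <- array(2L, dim = c(8, 8, 8))
  expect_identical(estimate_range(list(v1, v2), list(l, l), 2L),
                   estimate_range(list(v2, v1), list(l, l), 2L))
})

test_that("fitted constants span [0, 1] over the organ range", {
  p <- fit_rangeclip(0.400, 0.620, "liver")
  expect_equal(p$C, 0.400)
  expect_equal(p$B, 4.545, tolerance = 1e-3)
  expect_equal(apply_rangeclip(p$R_ll, p), 0, tolerance = 1e-9)
  expect_equal(apply_rangeclip(p$R_lh, p), 1, tolerance = 1e-9)
  p2 <- fit_rangeclip(0, 1)
  expect_equal(apply_rangeclip(c(0, 0.3, 1), p2), c(0, 0.3, 1))
  p3 <- fit_rangeclip(0.440, 0.600, "right_kidney")
  expect_equal(p3$B, 6.25)
})

test_that("the transform clamps below/above and is linear between", {
  p <- rangeclip_from_cb(0.400, 4.545, "liver")
  expect_equal(apply_rangeclip(0.30, p), 0)
  expect_equal(apply_rangeclip(0.50, p), 4.545 * 0.1, tolerance = 1e-9)
  x <- seq(0, 1, by = 0.01)
  y <- apply_rangeclip(x, p)
  expect_true(all(diff(y) >= 0))          # monotone on [0, 1]
  expect_true(all(y >= 0 & y <= 1))
})

test_that("inverse restores the organ range and exposes the clamp loss", {
  p <- fit_rangeclip(0.42, 0.58, "organ")
  expect_equal(apply_rangeclip_inverse(0, p), p$C)
  expect_equal(apply_rangeclip_inverse(1, p), p$R_lh, tolerance = 1e-12)
  set.seed(41)
  x <- runif(500, p$R_ll, p$R_lh)
  expect_equal(apply_rangeclip_inverse(apply_rangeclip(x, p), p), x,
               tolerance = 1e-9)
  # below-range values clamp to R_ll on the round trip
  expect_equal(apply_rangeclip_inverse(apply_rangeclip(0.30, p), p), p$R_ll)
})

test_that("air mask flags sub-threshold voxels and guards range estimates", {
  expect_true(air_mask(0))
  expect_false(air_mask(0.5))
  cfg <- tiny_phantom_cfg(seed = 8, n_slices = 9)
  ph <- generate_phantom(cfg)
  with_air <- estimate_range(ph$volume, ph$labels, 4L, trim = c(0, 100))
  no_air <- estimate_range(ph$volume, ph$labels, 4L, trim = c(0, 100),
                           exclude_air = TRUE)
  expect_lt(with_air[1], 0.25)            # pocket drags the bound down
  expect_gte(no_air[1], 0.25)
})

test_that("range-clip parameters survive a JSON round trip", {
  p <- fit_rangeclip(0.418, 0.418 + 1 / 4.762, "left_kidney")
  path <- tempfile(fileext = ".json")
  rangeclip_to_json(p, path)
  back <- rangeclip_from_json(path)[["left_kidney"]]
  expect_equal(back$C, p$C)
  expect_equal(back$B, p$B)
})
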