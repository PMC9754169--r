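make_bundle <- function(t = 2, seed = 17, organ = "liver",
                        params = fit_rangeclip(0.40, 0.62, "liver")) {
  spec <- tiny_spec()
  base <- build_parallel(spec, t, seed = seed)
  om <- build_parallel(spec, t, seed = seed + 100)
  organ_bundle(base, stats::setNames(
    list(list(model = om, params = params)), organ))
}

test_that("empty masks reproduce the base prediction exactly", {
  b <- make_bundle()
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  base_out <- predict_slices(b$base_model, l, r)
  expect_identical(reconstruct_organ_oriented(b, l, r), base_out)
  empty <- array(FALSE, dim = c(16, 16, 2))
  expect_identical(reconstruct_organ_oriented(b, l, r,
                                              list(liver = empty)),
                   base_out)
})

test_that("a full mask yields f-inverse of the organ model's prediction", {
  b <- make_bundle()
  p <- b$organ_models$liver$params
  l <- matrix(runif(256, 0.3, 0.7), 16, 16)
  r <- matrix(runif(256, 0.3, 0.7), 16, 16)
  full <- array(TRUE, dim = c(16, 16, 2))
  out <- reconstruct_organ_oriented(b, l, r, list(liver = full))
  tr <- transform_inputs(l, r, p)
  expected <- apply_rangeclip_inverse(
    predict_slices(b$organ_models$liver$model, tr$left, tr$right), p)
  expect_identical(out, expected)
})

test_that("replacement is local: outside masks the base output is bit-equal", {
  b <- make_bundle()
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  mk <- array(FALSE, dim = c(16, 16, 2))
  mk[5:9, 5:9, 1] <- TRUE
  base_out <- predict_slices(b$base_model, l, r)
  out <- reconstruct_organ_oriented(b, l, r, list(liver = mk))
  expect_identical(out[!mk], base_out[!mk])
  expect_false(identical(out[mk], base_out[mk]))
})

test_that("identity range-clip with the base model is a no-op", {
  spec <- tiny_spec()
  base <- build_parallel(spec, 2, seed = 23)
  ident <- fit_rangeclip(0, 1, "whole")
  b <- organ_bundle(base, list(whole = list(model = base, params = ident)))
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  mk <- array(runif(512) > 0.5, dim = c(16, 16, 2))
  out <- reconstruct_organ_oriented(b, l, r, list(whole = mk))
  expect_equal(out, predict_slices(base, l, r), tolerance = 1e-12)
})

test_that("overlapping organ masks are rejected", {
  spec <- tiny_spec()
  base <- build_parallel(spec, 1, seed = 3)
  om <- list(model = base, params = fit_rangeclip(0.3, 0.5, "a"))
  b <- organ_bundle(base, list(a = om, b = om))
  l <- matrix(0.5, 16, 16)
  mk <- array(TRUE, dim = c(16, 16, 1))
  expect_error(reconstruct_organ_oriented(b, l, l,
                                          list(a = mk, b = mk)),
               "overlap")
  expect_error(reconstruct_organ_oriented(b, l, l, list(zz = mk)),
               "without a model")
})

test_that("input transform maps sub-range voxels to exactly zero", {
  p <- fit_rangeclip(0.40, 0.62, "liver")
  l <- matrix(c(0.30, 0.45, 0.70, 0.40), 2, 2)
  tr <- transform_inputs(l, l, p)
  expect_identical(tr$left, tr$right)
  expect_equal(tr$left[1, 1], 0)
  expect_equal(tr$left[2, 2], 0)          # boundary maps to 0
  expect_equal(tr$left[1, 2], 1)          # above range saturates
  ident <- fit_rangeclip(0, 1)
  expect_equal(transform_inputs(l, l, ident)$left, l)
})

test_that("mask interpolation thresholds the blended membership", {
  lm <- matrix(FALSE, 4, 4); lm[1:2, ] <- TRUE
  rm_ <- matrix(FALSE, 4, 4); rm_[1:3, ] <- TRUE
  near_left <- interpolate_mask(lm, rm_, 0.25)
  expect_identical(near_left, lm)          # row 3: 0.25 < 0.5
  near_right <- interpolate_mask(lm, rm_, 0.75)
  expect_identical(near_right, rm_)        # row 3: 0.75 >= 0.5
})

test_that("bundle manifests round-trip models and parameters", {
  b <- make_bundle()
  dir <- tempfile()
  mp <- save_bundle(b, dir)
  b2 <- load_bundle(mp)
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  mk <- array(c(TRUE, FALSE), dim = c(16, 16, 2))
  # JSON stores parameters as decimal text: equal to double round-trip
  expect_equal(reconstruct_organ_oriented(b, l, r, list(liver = mk)),
               reconstruct_organ_oriented(b2, l, r, list(liver = mk)),
               tolerance = 1e-12)
})
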