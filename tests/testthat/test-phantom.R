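test_that("phantom generation is deterministic given the seed", {
  cfg <- tiny_phantom_cfg(seed = 44)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_identical(p1$labels$codes, p2$labels$codes)
  p3 <- generate_phantom(tiny_phantom_cfg(seed = 45))
  expect_false(identical(p1$volume$voxels, p3$volume$voxels))
})

test_that("organ voxels stay inside their configured intensity ranges", {
  cfg <- tiny_phantom_cfg(seed = 46)
  ph <- generate_phantom(cfg)
  air <- air_mask(ph$volume)
  for (o in cfg$organs) {
    sel <- ph$labels$codes == o$code & !air
    vals <- ph$volume$voxels[sel]
    expect_gte(min(vals), o$range[1])
    expect_lte(max(vals), o$range[2])
  }
})

test_that("the air pocket is dark but keeps its host organ's label", {
  cfg <- tiny_phantom_cfg(seed = 47)
  ph <- generate_phantom(cfg)
  pocket <- ph$labels$codes == 4L & air_mask(ph$volume)
  expect_gt(sum(pocket), 0)
  expect_lt(max(ph$volume$voxels[pocket]), 0.25)
})

test_that("config validation rejects impossible organs", {
  bad <- default_phantom_organs()
  bad$liver$center <- c(0.05, 0.05)
  expect_error(phantom_config(organs = bad), "outside the grid")
  bad2 <- default_phantom_organs()
  bad2$liver$range <- c(0.2, 0.9)
  expect_error(phantom_config(organs = bad2), "narrower")
})

test_that("linearity oracle: affine phantoms are exactly linear in z", {
  cfg0 <- tiny_phantom_cfg(seed = 48, noise_sd = 0, nonlinearity = 0)
  ph0 <- generate_phantom(cfg0)
  g <- slice_grouping(13, targets_per_gap = 2)
  sp <- split_volume(ph0$volume, g)
  lin <- slicerecon:::gap_list_to_stack(reconstruct_linear(sp$sparse, 2))
  expect_equal(mae(lin, sp$target), 0, tolerance = 1e-12)
  # the default nonlinear phantom defeats linear interpolation
  ph1 <- generate_phantom(tiny_phantom_cfg(seed = 48, noise_sd = 0))
  sp1 <- split_volume(ph1$volume, g)
  lin1 <- slicerecon:::gap_list_to_stack(reconstruct_linear(sp1$sparse, 2))
  expect_gt(mae(lin1, sp1$target, scale = 2000), 1)
})

test_that("dataset split is disjoint, seeded and sized 80/20", {
  cfg <- tiny_phantom_cfg(seed = 49, n_slices = 7, shape = c(16, 16))
  ds <- generate_dataset(cfg, n_volumes = 10, seed = 3)
  expect_length(ds$train, 8L)
  expect_length(ds$test, 2L)
  ds2 <- generate_dataset(cfg, n_volumes = 10, seed = 3)
  expect_identical(ds$test[[1]]$volume$voxels, ds2$test[[1]]$volume$voxels)
  # volumes are jittered: no two training volumes identical
  expect_false(identical(ds$train[[1]]$volume$voxels,
                         ds$train[[2]]$volume$voxels))
  expect_error(generate_dataset(cfg, n_volumes = 1), ">= 2")
})

test_that("range estimation recovers the configured organ ranges", {
  cfg <- tiny_phantom_cfg(seed = 50, n_slices = 9)
  ds <- generate_dataset(cfg, n_volumes = 6, seed = 50)
  vols <- lapply(ds$train, `[[`, "volume")
  labs <- lapply(ds$train, `[[`, "labels")
  liver_rng <- cfg$organs$liver$range
  est <- estimate_range(vols, labs, 1L)
  # jitter moves ranges by <= 0.008 and trimming shaves the tails
  expect_equal(est[1], liver_rng[1], tolerance = 0.03)
  expect_equal(est[2], liver_rng[2], tolerance = 0.03)
})

test_that("training examples carry one input pair and all targets per gap", {
  cfg <- tiny_phantom_cfg(seed = 51, n_slices = 7, shape = c(16, 16))
  ds <- generate_dataset(cfg, n_volumes = 3, seed = 51)
  g <- slice_grouping(7, targets_per_gap = 2)
  ex <- make_training_examples(ds$train, g)
  expect_length(ex, 2L * 2L)  # 2 train volumes x 2 gaps
  expect_identical(dim(ex[[1]]$input), c(16L, 16L, 2L))
  expect_identical(dim(ex[[1]]$target), c(16L, 16L, 2L))
  # input channels are the sparse neighbours of the first gap
  sp <- split_volume(ds$train[[1]]$volume, g)
  expect_identical(ex[[1]]$input[, , 1], sp$sparse[, , 1])
  expect_identical(ex[[1]]$input[, , 2], sp$sparse[, , 2])
})
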