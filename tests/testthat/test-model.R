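test_that("spec validates shape/depth and auto-reduces for small images", {
  s <- unet_spec(c(400, 320), base_channels = 64)
  expect_identical(s$encoder_blocks, 8L)
  expect_identical(s$decoder_blocks, 7L)
  expect_identical(s$levels, 5L)          # 400 = 2^4 * 25 caps the pools
  s2 <- unet_spec(c(64, 64), base_channels = 8, encoder_blocks = 3)
  expect_identical(s2$levels, 3L)
  expect_error(unet_spec(c(64, 64), decoder_blocks = 3, encoder_blocks = 3),
               "decoder_blocks")
  expect_error(unet_spec(c(5, 64)), "reconcilable|height")
})

test_that("output spatial shape equals input shape and clamps to [0, 1]", {
  spec <- tiny_spec()
  net <- build_parallel(spec, 2, seed = 3)
  l <- matrix(runif(256), 16, 16)
  r <- matrix(runif(256), 16, 16)
  out <- predict_slices(net, l, r)
  expect_identical(dim(out), c(16L, 16L, 2L))
  expect_true(all(out >= 0 & out <= 1))
  z <- matrix(0, 16, 16)
  out0 <- predict_slices(net, z, z)
  expect_true(all(is.finite(out0)) && all(out0 >= 0 & out0 <= 1))
  expect_error(predict_slices(net, matrix(0, 8, 8), z), "image_shape")
})

test_that("seeded builds are identical; different seeds differ", {
  spec <- tiny_spec()
  n1 <- build_unet(spec, seed = 7)
  n2 <- build_unet(spec, seed = 7)
  expect_identical(n1$layers, n2$layers)
  n3 <- build_unet(spec, seed = 8)
  expect_false(identical(n3$layers$enc1_a$W, n1$layers$enc1_a$W))
})

test_that("parallel branches are independently parameterized", {
  spec <- tiny_spec()
  m <- build_parallel(spec, 3, seed = 5)
  expect_length(m$branches, 3L)
  expect_false(identical(m$branches[[1]]$layers$enc1_a$W,
                         m$branches[[2]]$layers$enc1_a$W))
  # degenerate single-branch model is allowed (one middle slice)
  m1 <- build_parallel(spec, 1, seed = 5)
  expect_length(m1$branches, 1L)
  expect_error(build_parallel(spec, 0), ">= 1")
})

test_that("a branch's output ignores other branches entirely", {
  spec <- tiny_spec()
  m <- build_parallel(spec, 3, seed = 5)
  # give every head distinct nonzero weights so outputs are branch-specific
  set.seed(6)
  for (k in 1:3)
    m$branches[[k]]$layers$final$W[] <- rnorm(
      length(m$branches[[k]]$layers$final$W), sd = 0.1)
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  full <- predict_slices(m, l, r)
  m_cut <- m
  m_cut$branches[[2]]$layers$final$W[] <- 0.3  # perturb only branch 2
  cut <- predict_slices(m_cut, l, r)
  expect_identical(full[, , 1], cut[, , 1])
  expect_identical(full[, , 3], cut[, , 3])
  expect_false(identical(full[, , 2], cut[, , 2]))
})

test_that("training is seeded-deterministic and improves validation MAE", {
  spec <- tiny_spec(dropout_rate = 0.1)
  ex <- blend_examples(n = 12, t = 1)
  cfg <- train_config(lr = 2e-3, epochs = 4, batch_size = 4, seed = 21,
                      val_fraction = 0.25)
  m1 <- build_parallel(spec, 1, seed = 21)
  r1 <- train_parallel(m1, ex, cfg)
  m2 <- build_parallel(spec, 1, seed = 21)
  r2 <- train_parallel(m2, ex, cfg)
  expect_identical(r1$model$branches[[1]]$layers,
                   r2$model$branches[[1]]$layers)
  h <- r1$history
  expect_lt(h$val_mae[nrow(h)], h$val_mae[1])
})

test_that("a branch trained alone equals the same branch of a parallel run", {
  spec <- tiny_spec()
  ex <- blend_examples(n = 8, t = 2)
  cfg <- train_config(lr = 1e-3, epochs = 2, batch_size = 4, seed = 31,
                      val_fraction = 0)
  mp <- build_parallel(spec, 2, seed = 31)
  rp <- train_parallel(mp, ex, cfg)
  # train branch 2 alone: same init seed, same branch RNG stream
  alone_net <- build_unet(spec, seed = 31 + 2L)
  set.seed(cfg$seed + 7919L * 2L)
  alone <- slicerecon:::train_one_net(alone_net, ex, 2L, cfg, integer(0),
                                      2L, targets_per_gap = 2L)
  expect_identical(rp$model$branches[[2]]$layers, alone$net$layers)
})

test_that("missing target positions are rejected", {
  spec <- tiny_spec()
  ex <- blend_examples(n = 4, t = 1)
  m <- build_parallel(spec, 3, seed = 1)
  expect_error(train_parallel(m, ex, train_config(epochs = 1)),
               "target positions")
})

test_that("the single multi-output comparator trains and predicts all slices", {
  spec <- tiny_spec()
  m <- build_multiout(spec, 3, seed = 9)
  ex <- blend_examples(n = 6, t = 3)
  cfg <- train_config(lr = 1e-3, epochs = 2, batch_size = 4, seed = 9,
                      val_fraction = 0)
  r <- train_parallel(m, ex, cfg)
  out <- predict_slices(r$model, ex[[1]]$input[, , 1], ex[[1]]$input[, , 2])
  expect_identical(dim(out), c(16L, 16L, 3L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("checkpoints restore a model bit-exactly", {
  spec <- tiny_spec()
  m <- build_parallel(spec, 2, seed = 13)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  l <- matrix(runif(256), 16, 16); r <- matrix(runif(256), 16, 16)
  expect_identical(predict_slices(m, l, r), predict_slices(m2, l, r))
})
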