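test_that("MAE matches closed forms and a brute-force oracle", {
  a <- array(runif(64), dim = c(4, 4, 4))
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 0.0025, scale = 2000), 5)  # 5 HU offset
  set.seed(51)
  p <- matrix(runif(64), 8, 8); q <- matrix(runif(64), 8, 8)
  brute <- 0
  for (i in 1:8) for (j in 1:8) brute <- brute + abs(p[i, j] - q[i, j])
  expect_equal(mae(p, q), brute / 64)
  mk <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  brute_m <- mean(abs(p[mk] - q[mk]))
  expect_equal(mae(p, q, mask = mk), brute_m)
  expect_error(mae(p, q, mask = matrix(FALSE, 8, 8)), "empty")
})

test_that("maximum pixel-wise MAE picks the worst pixel", {
  p <- array(0, dim = c(2, 2, 3))
  q <- p
  q[1, 1, ] <- c(0.1, 0.2, 0.3)   # this pixel's MAE = 0.2
  q[2, 2, ] <- 0.05
  expect_equal(max_pixelwise_mae(p, q), 0.2)
  expect_equal(max_pixelwise_mae(p, q, scale = 2000), 400)
})

test_that("SSIM agrees with an independent reference implementation", {
  # frozen values from scikit-image structural_similarity
  # (gaussian_weights, sigma 1.5, population covariance, data_range 1)
  # on the identical seeded fixtures
  set.seed(421)
  a <- matrix(runif(256), 16, 16)
  b <- pmin(pmax(a + 0.1 * matrix(rnorm(256), 16, 16), 0), 1)
  expect_equal(ssim_slice(a, b, normalize = "none", data_range = 1),
               0.9355296555080709, tolerance = 1e-6)
  set.seed(777)
  c1 <- matrix(runif(576), 24, 24)
  c2 <- pmin(pmax(c1 + 0.05 * matrix(rnorm(576), 24, 24), 0), 1)
  expect_equal(ssim_slice(c1, c2, normalize = "none", data_range = 1),
               0.9859332866248262, tolerance = 1e-6)
})

test_that("SSIM identities, normalization and degenerate slices behave", {
  set.seed(52)
  a <- matrix(runif(256), 16, 16)
  expect_equal(ssim_slice(a, a), 1, tolerance = 1e-12)
  neg <- max(a) + min(a) - a
  expect_lt(ssim_slice(a, neg), 1)
  # min-max normalization makes SSIM invariant to affine intensity maps
  expect_equal(ssim_slice(a, 0.2 + 0.5 * a), 1, tolerance = 1e-9)
  flat <- matrix(0.5, 16, 16)
  expect_message(v <- ssim_slice(flat, flat), "dynamic range")
  expect_equal(v, 1)
  mk <- matrix(FALSE, 16, 16); mk[8:10, 8:10] <- TRUE
  expect_true(abs(ssim_slice(a, a, mask = mk) - 1) < 1e-12)
})

test_that("improvement percentages follow the error/similarity conventions", {
  expect_equal(round(improvement_pct(23.13, 18.03), 2), 22.05)
  expect_equal(improvement_pct(10, 10), 0)
  expect_equal(round(improvement_pct(14.25, 10.91), 2), 23.44)
  # similarity: higher is better
  expect_equal(round(improvement_pct(0.866, 0.885, "similarity"), 2), 2.19)
  expect_equal(round(improvement_pct(0.884, 0.883, "similarity"), 2), -0.11)
  # sign flips when roles swap
  expect_lt(improvement_pct(18.03, 23.13), 0)
  expect_error(improvement_pct(0, 5), "positive")
})

test_that("paired significance test detects shifts and flags degeneracy", {
  st0 <- significance_test(1:10, 1:10)
  expect_true(st0$degenerate)
  expect_equal(st0$p_value, 1)
  set.seed(53)
  a <- runif(100, 10, 20)
  b <- a + 1                     # B uniformly worse
  st <- significance_test(a, b)
  expect_lt(st$p_value, 0.01)
  expect_equal(st$direction, -1) # A has smaller errors
  b_noisy <- a + rnorm(100, mean = 1, sd = 0.3)
  st_t <- significance_test(a, b_noisy, method = "ttest")
  expect_lt(st_t$p_value, 0.01)
  expect_error(significance_test(1:5, 1:4), "length")
})

test_that("the null distribution of the test is not anti-conservative", {
  set.seed(54)
  p <- replicate(40, {
    a <- rnorm(30); b <- rnorm(30)
    significance_test(a, b)$p_value
  })
  expect_gt(mean(p < 0.05), 0)   # sanity: p-values vary
  expect_lt(mean(p < 0.05), 0.25)
})

test_that("m selection stops when the noise threshold is crossed", {
  tbl <- data.frame(m = c(1, 2, 3), max_mae = c(5, 12, 20))
  expect_equal(select_m(tbl, mu = 15), 2)
  expect_equal(select_m(data.frame(m = 1, max_mae = 5), mu = 5), 1)
  expect_warning(sel <- select_m(data.frame(m = c(2, 3),
                                            max_mae = c(20, 30)), mu = 15),
                 "smallest")
  expect_equal(sel, 2)
  # scan rule: a later dip below mu after a crossing is not revisited
  tbl2 <- data.frame(m = c(1, 2, 3), max_mae = c(5, 20, 10))
  expect_equal(select_m(tbl2, mu = 15), 1)
  expect_error(select_m(data.frame(), 10), "empty")
})

test_that("reports are internally consistent and zero for perfect input", {
  ph <- generate_phantom(tiny_phantom_cfg(seed = 12))
  g <- slice_grouping(13, targets_per_gap = 2)
  sp <- split_volume(ph$volume, g)
  spl <- split_volume(ph$labels$codes, g)
  lin <- slicerecon:::gap_list_to_stack(reconstruct_linear(sp$sparse, 2))
  rep1 <- build_report(list(linear = lin, perfect = sp$target), sp$target,
                       g, labels = spl$target,
                       organ_map = ph$labels$organ_map)
  avg <- rep1$averages
  pp <- rep1$per_position
  for (m in avg$method)
    expect_equal(avg$mae_hu[avg$method == m],
                 mean(pp$mae_hu[pp$method == m]), tolerance = 1e-9)
  expect_equal(avg$mae_hu[avg$method == "perfect"], 0)
  expect_equal(avg$ssim[avg$method == "perfect"], 1, tolerance = 1e-9)
  # improvement rows recompute from per-position cells
  imp <- rep1$improvements
  row <- imp[imp$position == 1 & !is.na(imp$position), ]
  lin1 <- pp$mae_hu[pp$method == "linear" & pp$position == 1]
  new1 <- pp$mae_hu[pp$method == "perfect" & pp$position == 1]
  expect_equal(row$mae_improvement_pct,
               round(improvement_pct(lin1, new1), 2))
  # perfect vs linear must be significantly better
  pv <- rep1$p_values
  expect_lt(pv$p_value[1], 0.05)
  d <- tempfile()
  write_report(rep1, d)
  expect_true(all(file.exists(file.path(d, c("per_position.csv",
                                             "averages.csv",
                                             "report.json")))))
})
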