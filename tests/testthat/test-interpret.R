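test_that("time-slice perturbation zeroes exactly the requested columns", {
  set.seed(1)
  x <- array(rnorm(2 * 4 * 1000), c(2, 4, 1000))
  xp <- perturb_time_slices(x, 0.3, seed = 0)
  zeroed <- which(apply(xp == 0, 3, all))
  expect_length(zeroed, 300)
  expect_identical(xp[, , -zeroed], x[, , -zeroed])
  # determinism under the seed
  expect_identical(xp, perturb_time_slices(x, 0.3, seed = 0))
  # ratio 1 kills the whole signal
  expect_true(all(perturb_time_slices(x, 1, seed = 0) == 0))
  expect_error(perturb_time_slices(x, 0), "ratio")
})

test_that("segment perturbation covers T/200 positions and zeroes one block", {
  set.seed(2)
  x <- array(rnorm(1 * 4 * 1000), c(1, 4, 1000))
  expect_error(perturb_time_segment(x, 6), "1..5")
  xp <- perturb_time_segment(x, 4)
  expect_true(all(xp[, , 601:800] == 0))
  expect_identical(xp[, , c(1:600, 801:1000)], x[, , c(1:600, 801:1000)])
})

test_that("channel perturbation zeroes floor(ratio * C) whole channels", {
  set.seed(3)
  x <- array(rnorm(2 * 22 * 500), c(2, 22, 500))
  xp <- perturb_channels(x, 0.5, seed = 1)
  dead <- which(apply(xp == 0, 2, all))
  expect_length(dead, 11)
  expect_identical(perturb_channels(x, 0.5, seed = 1), xp)
})

test_that("spatial regions partition the trial; 22 x 1000 gives a 5 x 5 grid", {
  grid <- spatial_regions(22, 1000)
  expect_equal(nrow(grid), 25)
  # last channel block holds only channels 21-22
  last_ch <- grid[grid$ch_from == 21, ]
  expect_true(all(last_ch$ch_to == 22))
  # the union of all regions covers every (channel, time) cell exactly once
  cover <- matrix(0, 22, 1000)
  for (i in seq_len(nrow(grid)))
    cover[grid$ch_from[i]:grid$ch_to[i], grid$t_from[i]:grid$t_to[i]] <-
      cover[grid$ch_from[i]:grid$ch_to[i], grid$t_from[i]:grid$t_to[i]] + 1
  expect_true(all(cover == 1))

  set.seed(4)
  x <- array(rnorm(1 * 22 * 1000), c(1, 22, 1000))
  xp <- perturb_spatial_region(x, 8)
  expect_equal(sum(xp == 0), 5 * 200)
  expect_error(perturb_spatial_region(x, 26), "1..25")
})

test_that("output difference is a metric-like score on logits", {
  m <- build_model(tiny_model_config(), seed = 2)
  set.seed(5)
  x <- array(rnorm(3 * 4 * 256), c(3, 4, 256))
  expect_equal(output_difference(m, x, x), 0)
  xa <- perturb_time_slices(x, 0.2, seed = 1)
  xb <- perturb_channels(x, 0.5, seed = 2)
  dab <- mean(sqrt(rowSums((model_forward(m, xa)$logits -
                              model_forward(m, xb)$logits)^2)))
  expect_lte(dab,
             output_difference(m, x, xa) + output_difference(m, x, xb) + 1e-9)
  # full zeroing equals the directly recomputed distance to f(0)
  x0 <- array(0, dim(x))
  d_direct <- mean(sqrt(rowSums((model_forward(m, x)$logits -
                                   model_forward(m, x0)$logits)^2)))
  expect_equal(output_difference(m, x, perturb_time_slices(x, 1)), d_direct)
  expect_error(output_difference(m, x, x[, , 1:100]), "mismatch")
})

test_that("perturbation sweep returns one row per setting", {
  m <- build_model(tiny_model_config(), seed = 3)
  set.seed(6)
  x <- array(rnorm(2 * 4 * 256), c(2, 4, 256))
  sw <- perturbation_sweep(m, x, "time_slice", settings = c(0.1, 0.3), seed = 0)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$output_difference >= 0))
})

test_that("grad_cam matches the closed-form weighted feature sum", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 4)
  set.seed(7)
  x <- matrix(rnorm(4 * 256), 4, 256)
  rm <- grad_cam(m, x, class_index = 1)
  expect_length(rm$temporal, cfg$seq_len)
  expect_length(rm$per_channel, cfg$C)
  # oracle: the classifier is affine in the flattened feature map, so the
  # temporal map must equal sum_f mean_t(W[class, f, t]) * feat[f, t]
  feat <- model_forward(m, x)$features[, , 1]
  W <- matrix(m$params$fc.w[2, ], cfg$F2, cfg$seq_len)
  expected <- as.vector(t(feat) %*% rowMeans(W))
  expect_equal(rm$temporal, expected)
  # per-channel relevance is the signed total projected on |spatial weights|
  spw <- apply(abs(m$params$cb.spatial.w), 3, sum)
  expect_equal(rm$per_channel, sum(expected) * spw / sum(spw))
  expect_error(grad_cam(m, x, 5), "class_index")
})

test_that("attention export averages to row-stochastic maps and reacts to time order", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 5)
  set.seed(8)
  x <- array(rnorm(2 * 4 * 256), c(2, 4, 256))
  a <- export_attention(m, x)
  expect_equal(dim(a), c(cfg$n_sa_layers, cfg$n_heads, cfg$seq_len, cfg$seq_len))
  expect_true(max(abs(apply(a, 1:3, sum) - 1)) < 1e-6)
  expect_identical(a, export_attention(m, x))
  # shuffling time changes the maps
  xs <- x[, , sample(256), drop = FALSE]
  expect_gt(max(abs(export_attention(m, xs) - a)), 1e-6)
  # persistence round trip
  path <- withr::local_tempfile(fileext = ".rds")
  export_attention(m, x, path)
  expect_equal(readRDS(path), a)
})
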