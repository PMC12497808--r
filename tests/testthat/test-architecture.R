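test_that("receptive field formula and its guards", {
  expect_identical(receptive_field(4, 2), 19L)
  expect_identical(receptive_field(1, 5), 1L)   # kernel 1 never grows
  expect_identical(receptive_field(3, 3), 29L)  # 1 + 2*2*(2^3-1)
  expect_error(receptive_field(0, 2), "positive")
  expect_warning(model_config(Kt = 2, L = 2),  # RFS 7 < 15
                 "receptive field")
})

test_that("canonical configuration reproduces every published block count", {
  cfg <- model_config()                        # C=22, T=1000, K=4
  rep <- count_parameters(cfg)
  expect_identical(rep$conv_block, 1312)
  expect_identical(rep$ms_conv, 44128)
  expect_identical(rep$sa_encoder, 4 * 12704)
  expect_identical(rep$channel_se, 672)
  expect_identical(rep$tdscfn, 11024)
  expect_identical(rep$classifier, 1924)
  expect_identical(rep$total, 109876)

  # single pieces: (1,75) branch, MHA per layer, block-1 pointwise conv
  expect_identical((cfg$F2 / 4) * cfg$F2 * 75 + cfg$F2 / 4, 19208)
  expect_identical(4 * (cfg$d_model^2 + cfg$d_model), 4224)
  m <- build_model(cfg, seed = 0)
  pw <- length(m$params$tcn.b1.pw.v) + length(m$params$tcn.b1.pw.g) +
    length(m$params$tcn.b1.pw.b)
  expect_identical(pw, 576L)
})

test_that("formula counts equal brute-force enumeration over random configs", {
  set.seed(99)
  for (i in 1:20) {
    repeat {
      F1 <- sample(c(4, 8, 12, 16), 1)
      D <- sample(1:3, 1)
      F2 <- F1 * D
      heads <- Filter(function(h) F2 %% h == 0, c(1, 2, 4, 8))
      r <- Filter(function(r) F1 %% r == 0, c(2, 4))
      if (F2 %% 4 == 0 && length(r) > 0) break
    }
    cfg <- suppressWarnings(model_config(
      C = sample(3:22, 1), T_samples = 64 * sample(2:8, 1),
      n_classes = sample(2:5, 1), F1 = F1, D = D,
      temporal_kernel = sample(c(16, 32), 1),
      ms_kernels = sort(sample(seq(3, 75, by = 2), 4)),
      n_heads = sample(heads, 1), n_sa_layers = sample(1:4, 1),
      ffn_hidden = sample(c(32, 64, 128), 1), r = sample(r, 1),
      Kt = sample(2:5, 1)))
    m <- build_model(cfg, seed = i)
    expect_identical(unclass(count_parameters(cfg)),
                     unclass(enumerate_parameters(m)))
  }
})

test_that("shape chain matches the published layer tables", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(2 * 22 * 1000), c(2, 22, 1000))
  st <- model_stages(m, x)
  expect_equal(dim(st$conv_block), c(32, 125, 2))
  expect_equal(dim(st$ms_conv), c(32, 15, 2))
  expect_equal(dim(st$sa_encoder), c(32, 15, 2))
  expect_equal(dim(st$channel_se), c(16, 15, 2))
  expect_equal(dim(st$tdscfn), c(32, 15, 2))
  fw <- model_forward(m, x, capture_attention = TRUE)
  expect_equal(dim(fw$logits), c(2, 4))
  expect_equal(dim(fw$attention), c(4, 8, 15, 15, 2))
})

test_that("attention rows are probability vectors; constant input is uniform", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  set.seed(4)
  x <- array(rnorm(3 * 4 * 256), c(3, 4, 256))
  fw <- model_forward(m, x, capture_attention = TRUE)
  sums <- apply(fw$attention, c(1, 2, 3, 5), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(fw$attention >= 0 & fw$attention <= 1))

  # identical tokens are temporally symmetric, so every query attends
  # uniformly: all rows equal 1/seq_len (checked at the encoder layer, where
  # the symmetry is exact; a constant raw input is broken by edge padding)
  S <- cfg$seq_len
  tok <- matrix(rep(rnorm(cfg$d_model), each = S), S, cfg$d_model)
  lay <- mieeg:::sa_layer_fwd(m$params, 1, tok, B = 1, S = S,
                              H = cfg$n_heads, drop = 0, training = FALSE)
  expect_true(all(abs(lay$A - 1 / S) < 1e-12))
})

test_that("SE gate lies strictly in (0,1) for any finite squeeze vector", {
  m <- build_model(tiny_model_config(), seed = 5)
  se_w <- function(z) {
    s1 <- pmax(m$params$se.w1 %*% z, 0)
    1 / (1 + exp(-(m$params$se.w2 %*% s1)))
  }
  set.seed(6)
  for (scale in c(1e-3, 1, 10)) {
    w <- se_w(matrix(rnorm(8, sd = scale), 8, 1))
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("temporal fusion network is strictly causal in evaluation mode", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 6)
  S <- cfg$seq_len
  set.seed(7)
  x <- array(rnorm(cfg$F1 * S * 1), c(cfg$F1, S, 1))
  base <- mieeg:::tcn_fwd(m$params, cfg, x, m$running, training = FALSE)$y
  for (t in seq_len(S)) {
    xp <- x
    xp[, t, ] <- xp[, t, ] + rnorm(cfg$F1)
    pert <- mieeg:::tcn_fwd(m$params, cfg, xp, m$running, training = FALSE)$y
    changed <- apply(abs(pert - base) > 1e-12, 2, any)
    if (t > 1) expect_false(any(changed[seq_len(t - 1)]))
    expect_true(changed[t])                    # kernel covers the current step
  }
})

test_that("all-zero input stays finite through the whole network", {
  m <- build_model(tiny_model_config(), seed = 8)
  fw <- model_forward(m, array(0, c(2, 4, 256)))
  expect_true(all(is.finite(fw$logits)))
})

test_that("build + forward are bit-deterministic under a fixed seed", {
  cfg <- tiny_model_config()
  set.seed(10)
  x <- array(rnorm(2 * 4 * 256), c(2, 4, 256))
  m1 <- build_model(cfg, seed = 0)
  m2 <- build_model(cfg, seed = 0)
  expect_identical(m1$params, m2$params)
  expect_identical(model_forward(m1, x)$logits, model_forward(m2, x)$logits)
})

test_that("configuration validation enforces divisibility constraints", {
  expect_error(model_config(F1 = 10, D = 1), "branches")
  expect_error(model_config(n_heads = 7), "n_heads")
  expect_error(model_config(r = 5), "reduction")
  expect_error(model_config(ms_kernels = c(14, 31, 51, 75)), "odd")
  expect_error(build_model(suppressWarnings(model_config(L = 3))), "L = 2")
  m <- build_model(tiny_model_config(), seed = 0)
  expect_error(model_forward(m, array(0, c(1, 5, 256))), "conv_block")
  # non-finite activations are surfaced before they reach the softmax
  bad <- array(0, c(1, 4, 256)); bad[1, 1, 1] <- NaN
  expect_error(model_forward(m, bad), "non-finite")
})
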