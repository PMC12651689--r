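# Encoder: attention blocks against hand oracles, shape contracts,
# determinism.

test_that("SE block: zero weights give uniform 0.5 scaling", {
  set.seed(31)
  f <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  w0 <- matrix(0, 2, 4)
  out <- se_block(f, r = 2, w1 = w0, w2 = t(w0))
  expect_equal(out, 0.5 * f, tolerance = 1e-12)
})

test_that("SE block: constant channels pool to their constants", {
  # GAP of a per-channel-constant map is the constant vector; with identity
  # sigmoid gates the scaling is sigmoid(W2 relu(W1 c))
  cvals <- c(-1, 0.5, 2, 3)
  f <- array(rep(cvals, each = 25), c(5, 5, 4))
  f <- aperm(f, c(3, 1, 2))
  w1 <- diag(4)[1:2, ]
  w2 <- matrix(0.3, 4, 2)
  out <- se_block(f, r = 2, w1 = w1, w2 = w2)
  z <- cvals                                  # the GAP descriptor
  u <- 1 / (1 + exp(-(w2 %*% pmax(w1 %*% z, 0))))
  for (c in 1:4) expect_equal(out[c, , ], f[c, , ] * u[c], tolerance = 1e-12)
})

test_that("SE block matches the step-by-step oracle on random input", {
  set.seed(32)
  f <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  w1 <- matrix(rnorm(2), 1, 2)
  w2 <- matrix(rnorm(2), 2, 1)
  expect_equal(se_block(f, r = 2, w1 = w1, w2 = w2), oracle_se(f, w1, w2),
               tolerance = 1e-12)
  expect_error(se_block(array(0, c(3, 4, 4)), r = 2),
               class = "promptseg_config_error")
})

test_that("spatial attention: zero kernel gives 0.5 scaling, map shape 1xHxW", {
  set.seed(33)
  f <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  k0 <- array(0, c(7, 7, 2, 1))
  expect_equal(cbam_spatial(f, kernel = k0, bias = 0), 0.5 * f,
               tolerance = 1e-12)
  ms <- cbam_attention_map(f, kernel = k0)
  expect_equal(dim(ms), c(1L, 8L, 8L))
  expect_true(all(ms > 0 & ms < 1))
})

test_that("spatial attention matches the direct convolution oracle", {
  set.seed(34)
  f <- array(rnorm(1 * 3 * 3), c(1, 3, 3))
  kern <- array(rnorm(7 * 7 * 2) * 0.3, c(7, 7, 2, 1))
  ms <- cbam_attention_map(f, kernel = kern, bias = 0.2)
  expect_equal(ms[1, , ], oracle_spatial_attention(f, kern, 0.2),
               tolerance = 1e-10)
  out <- cbam_spatial(f, kernel = kern, bias = 0.2)
  expect_equal(out[1, , ], f[1, , ] * oracle_spatial_attention(f, kern, 0.2),
               tolerance = 1e-10)
})

test_that("conv block preserves shape and is deterministic in eval mode", {
  set.seed(35)
  cfg <- encoder_config(se_reduction = 8L)
  x <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
  w <- conv_block_params(64L, 64L, cfg, seed = 5)
  y1 <- conv_block(x, 64L, cfg, weights = w)
  expect_equal(dim(y1), c(64L, 16L, 16L))
  y2 <- conv_block(x, 64L, cfg, weights = w)
  expect_identical(y1, y2)                  # bit-identical repeated calls
  expect_true(all(is.finite(y1)))
  # with attention disabled and dropout off the map is still deterministic
  cfg0 <- encoder_config(use_se = FALSE, use_cbam = FALSE, dropout_rate = 0)
  w0 <- conv_block_params(8L, 16L, cfg0, seed = 6)
  x0 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_identical(conv_block(x0, 16L, cfg0, weights = w0),
                   conv_block(x0, 16L, cfg0, weights = w0))
})

test_that("encoder stage shapes follow the printed contract", {
  set.seed(36)
  img <- matrix(rnorm(64 * 64), 64, 64)
  w <- encoder_params(base_width = 64L, seed = 2)
  pyr <- encode(img, weights = w, base_width = 64L)
  # stage l: 2^(l+5) channels at (H/2^l, W/2^l)
  for (l in 1:4) {
    e <- pyr[[paste0("E", l)]]
    expect_equal(dim(e), c(2L^(l + 5L), 64L %/% 2L^l, 64L %/% 2L^l))
    expect_true(all(is.finite(e)))
  }
})

test_that("non-divisible image sizes are rejected with the offending axis", {
  expect_error(encode(matrix(0, 40, 64), base_width = 16L),
               "height 40", class = "promptseg_dim_error")
  expect_error(encode(matrix(0, 64, 40), base_width = 16L),
               "width 40", class = "promptseg_dim_error")
  # 48 is divisible by 16, so it is accepted
  pyr <- encode(matrix(0, 48, 48), base_width = 16L)
  expect_equal(dim(pyr$E4)[2:3], c(3L, 3L))
})

test_that("encoder ablation toggles change the parameter set structurally", {
  all_on <- encoder_params(encoder_config(), base_width = 16L)
  no_se <- encoder_params(encoder_config(use_se = FALSE), base_width = 16L)
  no_cbam <- encoder_params(encoder_config(use_cbam = FALSE), base_width = 16L)
  nm_on <- names(all_on$params)
  expect_setequal(setdiff(nm_on, names(no_se$params)),
                  grep("\\.se\\.", nm_on, value = TRUE))
  expect_setequal(setdiff(nm_on, names(no_cbam$params)),
                  grep("\\.cbam\\.", nm_on, value = TRUE))
})
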