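# FiLM, CBN and the fused-bottleneck pipeline.

test_that("FiLM identity limits and the two-channel toy case", {
  e4 <- array(rnorm(512 * 2 * 2), c(512, 2, 2))
  expect_equal(film(e4, gamma = rep(0, 512), beta = rep(0, 512)), e4,
               tolerance = 1e-15)
  toy <- array(1, c(2, 1, 1))
  out <- film(toy, gamma = c(1, -1), beta = c(0.5, 0))
  expect_equal(out[, 1, 1], c(2.5, 0))
  # zero generating maps with zero biases behave as the identity
  maps <- list(Wg = matrix(0, 2, 768), bg = c(0, 0),
               Wb = matrix(0, 2, 768), bb = c(0, 0))
  vt <- rnorm(768)
  expect_equal(film(toy, v_t = vt, maps = maps), toy, tolerance = 1e-15)
  expect_error(film(toy, gamma = c(1, 2, 3), beta = c(0, 0, 0)),
               class = "promptseg_contract_error")
})

test_that("CBN: unit-scale on standardized input, zero-scale collapse, oracle", {
  set.seed(41)
  f <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  # standardize per channel first
  for (c in 1:2) f[c, , ] <- (f[c, , ] - mean(f[c, , ])) / sd(f[c, , ]) /
    sqrt(15 / 16)  # biased-variance scaling
  out <- cbn(f, gamma = c(1, 1), beta = c(0, 0), eps = 1e-8)
  expect_equal(out, f, tolerance = 1e-3)
  out0 <- cbn(f, gamma = c(0, 0), beta = c(3, -2))
  expect_equal(out0[1, , ], matrix(3, 4, 4))
  expect_equal(out0[2, , ], matrix(-2, 4, 4))
  # elementwise oracle with hand-set statistics
  g <- c(2, -1); b <- c(0.5, 1); mu <- c(0.3, -0.2); va <- c(1.5, 0.7)
  o <- cbn(f, g, b, mu = mu, var = va, eps = 1e-5)
  for (c in 1:2)
    expect_equal(o[c, , ], g[c] * (f[c, , ] - mu[c]) / sqrt(va[c] + 1e-5) + b[c],
                 tolerance = 1e-12)
})

test_that("fused bottleneck has unit channel norm at every location", {
  set.seed(42)
  e4 <- array(rnorm(32 * 4 * 4), c(32, 4, 4))
  vt <- rnorm(768)
  out <- fuse(e4, vt, fusion_config(), seed = 3)
  norms <- apply(out, c(2, 3), function(v) sqrt(sum(v^2)))
  expect_true(all(abs(norms - 1) < 1e-6))
})

test_that("with all stages disabled fuse is pure channel normalization", {
  set.seed(43)
  e4 <- array(rnorm(16 * 2 * 2), c(16, 2, 2))
  cfg <- fusion_config(use_film = FALSE, use_cbn = FALSE, use_se_fused = FALSE)
  out <- fuse(e4, rnorm(768), cfg)
  ref <- e4
  for (i in 1:2) for (j in 1:2)
    ref[, i, j] <- e4[, i, j] / sqrt(sum(e4[, i, j]^2) + cfg$l2_eps)
  expect_equal(out, ref, tolerance = 1e-8)  # residual doubling cancels in
  # the normalization up to the eps guard
  # an all-zero location is eps-guarded, not NaN
  e4[, 1, 1] <- 0
  out0 <- fuse(e4, rnorm(768), cfg)
  expect_true(all(is.finite(out0)))
})

test_that("toy bottleneck matches a straight-line hand evaluation", {
  # 2 channels, 1x1 spatial, FiLM + CBN enabled, SE disabled; all generating
  # maps set by hand so every intermediate is computable on paper
  cfg <- fusion_config(use_se_fused = FALSE, cbn_sites = "bottleneck")
  w <- fusion_params(2L, 4L, cfg, seed = 1)
  w$params[["fus.film.Wg"]] <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 2, 4)
  w$params[["fus.film.bg"]] <- c(0, 0.5)
  w$params[["fus.film.Wb"]] <- matrix(0, 2, 4)
  w$params[["fus.film.bb"]] <- c(0.1, -0.1)
  w$params[["fus.cbn.Wg"]] <- matrix(0, 2, 4)
  w$params[["fus.cbn.bg"]] <- c(1, 1)
  w$params[["fus.cbn.Wb"]] <- matrix(0, 2, 4)
  w$params[["fus.cbn.bb"]] <- c(0, 0)
  e4 <- array(c(2, -1), c(2, 1, 1))
  vt <- c(0.5, 0, 0, 0)
  out <- fuse(e4, vt, cfg, weights = w)
  # hand evaluation:
  gamma <- c(0.5, 0.5); beta <- c(0.1, -0.1)
  efused <- (1 + gamma) * c(2, -1) + beta          # 3.1, -1.6
  # batch stats over a single 1x1 sample: mu = value, var = 0
  ecbn <- 1 * (efused - efused) / sqrt(0 + cfg$cbn_eps) + 0   # 0, 0
  efinal <- c(2, -1) + ecbn
  enorm <- efinal / sqrt(sum(efinal^2) + cfg$l2_eps)
  expect_equal(out[, 1, 1], enorm, tolerance = 1e-9)
})

test_that("different prompts generically change the fused bottleneck", {
  set.seed(44)
  e4 <- array(rnorm(32 * 2 * 2), c(32, 2, 2))
  w <- fusion_params(32L, 768L, fusion_config(), seed = 9)
  a <- fuse(e4, rnorm(768), weights = w)
  b <- fuse(e4, rnorm(768), weights = w)
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("fusion ablation toggles add exactly their own parameters", {
  full <- fusion_params(32L, 768L, fusion_config())
  no_film <- fusion_params(32L, 768L, fusion_config(use_film = FALSE))
  no_cbn <- fusion_params(32L, 768L, fusion_config(use_cbn = FALSE))
  no_se <- fusion_params(32L, 768L, fusion_config(use_se_fused = FALSE))
  nm <- names(full$params)
  expect_setequal(setdiff(nm, names(no_film$params)),
                  grep("^fus\\.film\\.", nm, value = TRUE))
  expect_setequal(setdiff(nm, names(no_cbn$params)),
                  grep("^fus\\.cbn\\.", nm, value = TRUE))
  expect_setequal(setdiff(nm, names(no_se$params)),
                  grep("^fus\\.se\\.", nm, value = TRUE))
})
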