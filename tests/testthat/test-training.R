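# Preprocessing, splitting, schedule, optimizer determinism, harness
# statistics.

test_that("preprocess resizes, normalizes to [-1, 1], keeps masks binary", {
  set.seed(61)
  s <- generate_single_lesion(1, single_lesion_spec(64), seed = 3)[[1]]
  p128 <- preprocess(s, 128L)
  expect_equal(dim(p128$image), c(128L, 128L))
  expect_gte(min(p128$image), -1)
  expect_lte(max(p128$image), 1)
  expect_true(all(unlist(p128$masks) %in% c(0L, 1L)))
  expect_gt(sum(p128$masks[[1]]), 0)
  # an already-sized sample changes only by the linear intensity map
  p64 <- preprocess(s, 64L)
  a <- as.vector(s$image); b <- as.vector(p64$image)
  expect_gt(abs(cor(a, b)), 1 - 1e-12)   # affine relation preserved
  expect_equal(range(b), c(-1, 1))
  expect_identical(p64$masks, lapply(s$masks, binarize))
})

test_that("split is seeded, sized, and stratified by target", {
  ss <- attach_prompts(generate_multi_organ(20, multi_organ_spec(64), seed = 1),
                       organ_synonym_table(), seed = 2)
  sp <- split_samples(ss, 0.8, seed = 5)
  expect_length(sp$train, 16L)
  expect_length(sp$val, 4L)
  sp2 <- split_samples(ss, 0.8, seed = 5)
  expect_identical(vapply(sp$train, function(s) s$prompt, ""),
                   vapply(sp2$train, function(s) s$prompt, ""))
  # stratification: per-class train counts within one of fraction * total
  tgt_all <- table(vapply(ss, function(s) s$target, ""))
  tgt_tr <- table(factor(vapply(sp$train, function(s) s$target, ""),
                         levels = names(tgt_all)))
  expect_true(all(abs(tgt_tr - 0.8 * tgt_all) <= 1))
  expect_error(split_samples(ss[1], 0.8), "at least 2")
})

test_that("cosine schedule hits its endpoints", {
  expect_equal(cosine_lr(0, 500, 1e-4), 1e-4)
  expect_lte(cosine_lr(500, 500, 1e-4), 1e-7)
  expect_equal(cosine_lr(250, 500, 1e-4), 5e-5)
  lrs <- cosine_lr(0:60, 60, 1e-3)
  expect_true(all(diff(lrs) < 0))   # strictly decaying
})

tiny_setup <- function(seed = 0L, n = 6L) {
  ss <- attach_prompts(generate_multi_organ(n, multi_organ_spec(32), seed = seed),
                       organ_synonym_table(), seed = seed + 1L)
  lapply(ss, preprocess, size = 32L)
}

tiny_model <- function(seed = 1L) {
  promptseg_model(base_width = 4L,
                  encoder_cfg = encoder_config(se_reduction = 2L),
                  seed = seed)
}

test_that("a short training run reduces the training dice loss", {
  ss <- tiny_setup()
  m <- tiny_model()
  lcfg <- loss_config("dice")
  before <- mean(vapply(ss, function(s)
    dice_loss(model_predict(m, s$image, s$prompt),
              promptseg:::target_mask(s)), 1))
  cfg <- train_config(lr = 2e-3, epochs = 12L, batch_size = 4L, loss = lcfg,
                      seed = 3L)
  m <- train_model(m, ss, cfg)
  h <- attr(m, "history")
  expect_equal(nrow(h), 12L)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  after <- mean(vapply(ss, function(s)
    dice_loss(model_predict(m, s$image, s$prompt),
              promptseg:::target_mask(s)), 1))
  expect_lt(after, before)
})

test_that("identical seeds give bit-identical trained parameters and history", {
  ss <- tiny_setup()
  cfg <- train_config(lr = 1e-3, epochs = 3L, batch_size = 4L, seed = 11L)
  m1 <- train_model(tiny_model(5L), ss, cfg)
  m2 <- train_model(tiny_model(5L), ss, cfg)
  expect_identical(model_param_hash(m1), model_param_hash(m2))
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  m3 <- train_model(tiny_model(5L), ss,
                    train_config(lr = 1e-3, epochs = 3L, batch_size = 4L,
                                 seed = 12L))
  expect_false(identical(model_param_hash(m1), model_param_hash(m3)))
})

test_that("evaluation is deterministic and a perfect oracle scores 1", {
  ss <- tiny_setup()
  m <- tiny_model()
  e1 <- evaluate_model(m, ss)
  e2 <- evaluate_model(m, ss)
  expect_identical(e1$mean, e2$mean)
  # an untrained model cannot beat prevalence-level dice by much
  expect_lt(e1$mean$dice, 0.5)
  # stub a perfect model via the metric layer
  perfect <- lapply(ss, function(s) {
    tm <- promptseg:::target_mask(s)
    compute_metrics(tm + 0, tm)
  })
  agg <- aggregate_reports(perfect)
  expect_equal(agg$dice, 1)
  expect_equal(agg$hd, 0)
})

test_that("the text embedder is frozen through training", {
  ss <- tiny_setup()
  m <- tiny_model()
  v_before <- embed_prompt("Segment the Liver region", m$embedder)$v
  train_model(m, ss, train_config(lr = 1e-3, epochs = 2L, batch_size = 4L))
  v_after <- embed_prompt("Segment the Liver region", m$embedder)$v
  expect_identical(v_before, v_after)
})

test_that("non-finite losses abort with an epoch/batch diagnostic", {
  ss <- tiny_setup()
  m <- tiny_model()
  # a non-finite learning rate poisons the parameters after one step
  expect_error(
    suppressWarnings(train_model(m, ss,
      train_config(lr = NaN, epochs = 2L, batch_size = 4L, grad_clip = Inf))),
    "epoch", class = "promptseg_training_error")
})

test_that("t-interval matches the closed form on {1, 2, 3}", {
  ci <- t_ci(c(1, 2, 3))
  half <- stats::qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(unname(ci["mean"]), 2)
  expect_equal(unname(ci["lower"]), 2 - half, tolerance = 1e-12)
  expect_equal(unname(ci["upper"]), 2 + half, tolerance = 1e-12)
  expect_equal(unname(ci["lower"]), -0.4841377, tolerance = 1e-6)
  expect_equal(unname(ci["upper"]), 4.4841377, tolerance = 1e-6)
})

test_that("shapiro check returns p in [0,1] and rejects constant samples", {
  set.seed(62)
  for (i in 1:5) {
    r <- shapiro_check(rnorm(10))
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
  expect_error(shapiro_check(rep(2, 10)), class = "promptseg_degenerate_error")
})

test_that("multi_run: identical seeds give zero std; summaries are coherent", {
  ss <- tiny_setup()
  m <- tiny_model()
  run_fn <- function(seed) evaluate_model(m, ss)$mean  # deterministic cycle
  ex <- multi_run(run_fn, seeds = c(1, 1, 1))
  expect_true(all(ex$summary$sd == 0))
  expect_true(all(is.na(ex$summary$shapiro_p)))  # degenerate -> NA, not error
  # CI brackets the mean
  run2 <- function(seed) {
    r <- ex$reports[[1]]
    r$dice <- r$dice + seed / 100
    r
  }
  ex2 <- multi_run(run2, seeds = 1:4)
  sm <- ex2$summary[ex2$summary$metric == "dice", ]
  expect_lte(sm$ci_lower, sm$mean)
  expect_gte(sm$ci_upper, sm$mean)
})
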