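# Unit and oracle tests for the six training objectives.

test_that("dice loss matches hand-computed values and limits", {
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 1, 0, 0), eps = 0), 0)
  expect_equal(dice_loss(c(0, 0, 1, 1), c(1, 1, 0, 0), eps = 0), 1)
  expect_equal(dice_loss(c(1, 0, 0, 0), c(1, 1, 0, 0), eps = 0), 1 - 2 / 3)
  expect_error(dice_loss(c(1, 0), c(1, 0, 0)), class = "promptseg_contract_error")
})

test_that("focal loss hand values, gamma = 0 reduction to BCE", {
  expect_equal(focal_loss(0.5, 1, gamma = 2), 0.25 * log(2))
  # confident-correct limit approaches zero
  expect_lt(focal_loss(c(1, 0), c(1, 0), gamma = 2), 1e-5)
  set.seed(11)
  p <- runif(40); m <- rbinom(40, 1, 0.5)
  expect_equal(focal_loss(p, m, gamma = 0), oracle_bce(p, m), tolerance = 1e-12)
})

test_that("jaccard and tversky hand values and reductions", {
  expect_equal(jaccard_loss(c(1, 1, 0, 0), c(1, 1, 0, 0), eps = 0), 0)
  expect_equal(jaccard_loss(c(1, 0, 0, 0), c(1, 1, 0, 0), eps = 0), 0.5)
  expect_equal(tversky_loss(c(0, 1), c(1, 0), 0.7, 0.3, eps = 0), 1)
  expect_equal(tversky_loss(c(1, 1, 0), c(1, 1, 0), eps = 0), 0)
  # alpha = beta = 0.5 equals the non-squared Dice-form loss
  set.seed(12)
  for (i in 1:20) {
    p <- runif(16); m <- rbinom(16, 1, 0.5)
    tv <- tversky_loss(p, m, 0.5, 0.5, eps = 0)
    nd <- 1 - 2 * sum(p * m) / (sum(p) + sum(m))
    expect_equal(tv, nd, tolerance = 1e-12)
  }
})

test_that("dicebce equals dice plus mean BCE and dominates dice", {
  expect_equal(dicebce_loss(0.5, 1, eps = 0), (1 - 1 / 1.25) + log(2),
               tolerance = 1e-9)
  set.seed(13)
  for (i in 1:10) {
    p <- runif(25); m <- rbinom(25, 1, 0.4)
    expect_gte(dicebce_loss(p, m), dice_loss(p, m))
  }
})

test_that("all ratio losses match brute-force oracles over every 3x3 mask pair", {
  M <- all_masks_3x3()
  wd <- wj <- wt <- wf <- wb <- 0
  for (i in seq_len(nrow(M))) {
    p <- M[i, ]
    for (j in seq_len(nrow(M))) {
      m <- M[j, ]
      if (any(p + m > 0)) {   # 0/0 cases are eps-convention, checked below
        wd <- max(wd, abs(dice_loss(p, m, eps = 0) - oracle_dice(p, m)))
        wj <- max(wj, abs(jaccard_loss(p, m, eps = 0) - oracle_jaccard(p, m)))
        wt <- max(wt, abs(tversky_loss(p, m, 0.7, 0.3, eps = 0) -
                            oracle_tversky(p, m, 0.7, 0.3)))
        wb <- max(wb, abs(dicebce_loss(p, m, eps = 0) -
                            (oracle_dice(p, m) + oracle_bce(p, m))))
      }
      wf <- max(wf, abs(focal_loss(p, m, gamma = 2) - oracle_focal(p, m, 2)))
    }
  }
  expect_lt(max(wd, wj, wt, wf, wb), 1e-12)
})

test_that("degenerate 0/0 ratio losses are defined (0) at eps = 0", {
  z <- rep(0, 9)
  expect_true(is.nan(oracle_dice(z, z)))    # the raw formula is 0/0
  expect_equal(dice_loss(z, z, eps = 1e-6), 0, tolerance = 1e-6)
  expect_equal(jaccard_loss(z, z, eps = 1e-6), 0, tolerance = 1e-6)
})

test_that("losses vanish at perfect binary predictions and are nonnegative", {
  M <- all_masks_3x3()
  set.seed(14)
  for (i in sample(nrow(M), 40)) {
    m <- M[i, ]
    for (nm in loss_names()) {
      cfg <- loss_config(nm, smooth_eps = 1e-6)
      v <- segmentation_loss(matrix(m, 3, 3), matrix(m, 3, 3), cfg)
      expect_gte(v, 0)
      expect_lt(v, 1e-4)
    }
    p <- runif(9)
    for (nm in c("dice", "jaccard", "tversky", "focal", "dicebce"))
      expect_gte(segmentation_loss(matrix(p, 3, 3), matrix(m, 3, 3),
                                   loss_config(nm)), 0)
  }
})

test_that("hausdorff distance: hand cases, symmetry, empty-mask sentinels", {
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
  expect_equal(hausdorff_distance(m, m), 0)
  a <- matrix(0, 8, 8); a[2, 2] <- 1
  b <- matrix(0, 8, 8); b[5, 6] <- 1
  expect_equal(hausdorff_distance(a, b), 5)
  p1 <- matrix(0, 12, 12); p1[1, 1] <- 1; p1[11, 1] <- 1
  q1 <- matrix(0, 12, 12); q1[1, 1] <- 1
  expect_equal(hausdorff_distance(p1, q1), 10)
  expect_equal(hausdorff_distance(q1, p1), 10)   # symmetric
  e <- matrix(0, 8, 8)
  expect_equal(hausdorff_distance(e, e), 0)
  expect_equal(hausdorff_distance(e, m), sqrt(2 * 49))  # diagonal sentinel
})

test_that("hausdorff distance equals the all-pairs oracle on random masks", {
  set.seed(15)
  for (i in 1:100) {
    a <- rand_mask(16, 16, runif(1, 0.2, 0.6))
    b <- rand_mask(16, 16, runif(1, 0.2, 0.6))
    expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b),
                 tolerance = 1e-12)
  }
})

test_that("hausdorff surrogate: zero at perfect match, monotone, finite grad", {
  m <- matrix(0, 16, 16); m[6:10, 6:10] <- 1
  expect_equal(hausdorff_surrogate(m, m), 0)
  # an erroneous blob farther from the target costs more
  near <- m; near[6:8, 12] <- 1
  far <- m; far[14:16, 16] <- 1   # same error area, farther away
  expect_gt(hausdorff_surrogate(far, m), hausdorff_surrogate(near, m))
  g <- hausdorff_surrogate(matrix(runif(256), 16, 16), m, grad = TRUE)$grad
  expect_true(all(is.finite(g)))
})

test_that("jaccard loss dominates dice loss on binary masks", {
  M <- all_masks_3x3()
  set.seed(16)
  pairs <- cbind(sample(512, 300, replace = TRUE), sample(512, 300, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    p <- M[pairs[r, 1], ]; m <- M[pairs[r, 2], ]
    lj <- jaccard_loss(p, m, eps = 1e-9)
    ld <- dice_loss(p, m, eps = 1e-9)
    expect_gte(lj, ld - 1e-9)
  }
})

test_that("loss gradients agree with numerical differentiation", {
  set.seed(17)
  p <- runif(12, 0.05, 0.95)
  m <- rbinom(12, 1, 0.5)
  for (nm in c("dice", "focal", "jaccard", "tversky", "dicebce")) {
    cfg <- loss_config(nm)
    r <- promptseg:::loss_eval(p, m, cfg)
    ng <- vapply(seq_along(p), function(i) {
      eps <- 1e-6
      pp <- p; pp[i] <- pp[i] + eps
      pm <- p; pm[i] <- pm[i] - eps
      (promptseg:::loss_eval(pp, m, cfg)$value -
         promptseg:::loss_eval(pm, m, cfg)$value) / (2 * eps)
    }, 1)
    expect_equal(as.vector(r$grad), ng, tolerance = 1e-5)
  }
})

test_that("weighted loss combination is the weighted sum of parts", {
  set.seed(18)
  p <- runif(16); m <- rbinom(16, 1, 0.5)
  cfg <- loss_config(weights = c(dice = 1, focal = 0.5))
  expect_equal(segmentation_loss(p, m, cfg),
               dice_loss(p, m) + 0.5 * focal_loss(p, m),
               tolerance = 1e-12)
})
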