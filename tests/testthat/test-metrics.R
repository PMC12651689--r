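# The ten evaluation metrics against independent per-pixel oracles.

test_that("confusion counts match the per-pixel loop oracle", {
  p <- matrix(1, 2, 2)
  cc <- confusion_counts(p, p)
  expect_equal(cc, list(tp = 4L, fp = 0L, fn = 0L, tn = 0L))
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  cc2 <- confusion_counts(1 - g, g)
  expect_equal(cc2$tp, 0L); expect_equal(cc2$tn, 0L)
  set.seed(21)
  for (i in 1:20) {
    a <- rand_mask(4, 4); b <- rand_mask(4, 4)
    cc <- confusion_counts(a, b)
    oc <- oracle_confusion(a, b)
    expect_equal(unlist(cc)[c("tp", "fp", "fn", "tn")],
                 oc[c("tp", "fp", "fn", "tn")])
  }
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "promptseg_contract_error")
})

test_that("perfect prediction yields the all-ones report with hd 0", {
  gt <- matrix(0, 8, 8); gt[3:5, 2:6] <- 1
  r <- compute_metrics(gt, gt)
  for (nm in c("iou", "dice", "f1", "map", "kappa", "specificity",
               "recall", "precision", "pixel_accuracy"))
    expect_equal(r[[nm]], 1)
  expect_equal(r$hd, 0)
})

test_that("kappa follows the closed form on a constructed contingency", {
  # TP = 40, TN = 40, FP = 10, FN = 10 -> p_o = 0.8, p_e = 0.5, kappa = 0.6
  gt <- matrix(0, 10, 10); gt[1:50] <- 1           # 50 positives
  pred <- gt; pred[1:10] <- 0; pred[51:60] <- 1    # 10 FN, 10 FP
  cc <- confusion_counts(pred, gt)
  expect_equal(unlist(cc), c(tp = 40L, fp = 10L, fn = 10L, tn = 40L))
  r <- compute_metrics(pred, gt)
  expect_equal(r$kappa, 0.6)
  expect_equal(r$pixel_accuracy, 0.8)
})

test_that("metric identities: f1 == dice and dice = 2*iou/(1+iou)", {
  set.seed(22)
  for (i in 1:50) {
    r <- compute_metrics(rand_prob(8, 8), rand_mask(8, 8))
    expect_identical(r$f1, r$dice)
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
  }
})

test_that("full reports agree with the per-pixel loop oracle on 200 seeded pairs", {
  set.seed(23)
  for (i in 1:200) {
    prob <- rand_prob(8, 8)
    gt <- rand_mask(8, 8, runif(1, 0.2, 0.8))
    r <- compute_metrics(prob, gt)
    o <- oracle_metrics(prob, gt)
    for (nm in names(o)) expect_equal(r[[nm]], o[[nm]], tolerance = 1e-12)
  }
})

test_that("average precision: perfect ranking, constant scores, sweep oracle", {
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  perfect <- matrix(c(0.9, 0.8, 0.2, 0.1), 2, 2)
  expect_equal(average_precision(perfect, gt), 1)
  const <- matrix(0.5, 2, 2)
  expect_equal(average_precision(const, gt), 0.5)  # prevalence
  set.seed(24)
  for (i in 1:50) {
    prob <- rand_prob(4, 4)
    gt <- rand_mask(4, 4, 0.5)
    if (sum(gt) == 0) next
    expect_equal(average_precision(prob, gt), oracle_ap(prob, gt),
                 tolerance = 1e-12)
  }
  # ties: duplicate scores enter the sweep together
  prob <- matrix(c(0.7, 0.7, 0.3, 0.3), 2, 2)
  gt2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(average_precision(prob, gt2), oracle_ap(prob, gt2))
})

test_that("kappa never exceeds 1 on any mask pair", {
  set.seed(25)
  for (i in 1:300) {
    r <- compute_metrics(rand_prob(8, 8), rand_mask(8, 8, runif(1, 0.05, 0.95)))
    expect_lte(r$kappa, 1)
    expect_gte(r$kappa, -1)
  }
  # including degenerate all-one / all-zero masks
  one <- matrix(1, 4, 4); zero <- matrix(0, 4, 4)
  for (pair in list(list(one, one), list(zero, zero), list(one, zero)))
    expect_lte(compute_metrics(pair[[1]], pair[[2]])$kappa, 1)
})

test_that("ratio metrics are invariant to transposing both masks", {
  set.seed(26)
  for (i in 1:20) {
    prob <- rand_prob(6, 9); gt <- rand_mask(6, 9)
    a <- compute_metrics(prob, gt)
    b <- compute_metrics(t(prob), t(gt))
    for (nm in c("iou", "dice", "f1", "map", "kappa", "specificity",
                 "recall", "precision", "pixel_accuracy"))
      expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12)
  }
})

test_that("zero-denominator conventions are consistent", {
  e <- matrix(0, 4, 4)
  r <- compute_metrics(e, e)
  expect_equal(r$recall, 1)      # nothing to find, nothing found
  expect_equal(r$precision, 1)
  expect_equal(r$dice, 1)
  full <- matrix(1, 4, 4)
  r2 <- compute_metrics(full, e)
  expect_equal(r2$recall, 1)     # no positives to miss (FN = 0), so 1
  expect_equal(r2$specificity, 0)  # FP present, denominator nonzero
  expect_equal(r2$precision, 0)  # all 16 predictions are false positives
})

test_that("aggregation is the unweighted per-metric mean", {
  gt <- matrix(0, 8, 8); gt[2:4, 2:4] <- 1
  r1 <- compute_metrics(gt, gt)
  expect_equal(aggregate_reports(list(r1)), r1, ignore_attr = TRUE)
  expect_equal(aggregate_reports(list(r1, r1))$dice, r1$dice)
  ra <- r1; ra$dice <- 0.9
  rb <- r1; rb$dice <- 0.7
  expect_equal(aggregate_reports(list(ra, rb))$dice, 0.8)
  expect_error(aggregate_reports(list()))
})

test_that("metric report writer emits per-sample rows and a summary", {
  gt <- matrix(0, 8, 8); gt[2:4, 2:4] <- 1
  reps <- list(compute_metrics(gt, gt), compute_metrics(1 - gt, gt))
  dir <- withr::local_tempdir()
  out <- write_metric_report(reps, dir)
  expect_true(file.exists(file.path(dir, "metrics_per_sample.csv")))
  expect_true(file.exists(file.path(dir, "metrics_summary.csv")))
  expect_equal(nrow(out$per_sample), 2L)
  expect_equal(out$summary$mean[out$summary$metric == "dice"],
               mean(c(1, 0)))
})
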