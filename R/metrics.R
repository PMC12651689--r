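#' Pixelwise confusion counts
#'
#' @param pred Binary prediction mask.
#' @param gt Binary ground-truth mask of the same shape.
#' @return A list with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    ps_stop("mask shapes differ", class = "promptseg_contract_error")
  p <- pred >= 0.5
  g <- gt >= 0.5
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

# Zero-denominator convention, used consistently across all count-ratio
# metrics: a ratio whose denominator is 0 is 1 when the associated error
# count is also 0 (nothing to find and nothing found), else 0.
safe_ratio <- function(num, den, err) {
  if (den == 0) return(if (err == 0) 1 else 0)
  num / den
}

#' Pixelwise average precision
#'
#' Area under the precision-recall curve of the probability map against the
#' binary ground truth, swept over every distinct predicted score (step
#' interpolation). With constant scores this collapses to a single PR point
#' and equals the foreground prevalence.
#'
#' @param mhat Probability map.
#' @param gt Binary ground truth with at least one positive pixel (an empty
#'   ground truth yields 1 if the prediction is all-zero, 0 otherwise).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(mhat, gt) {
  g <- as.numeric(gt >= 0.5)
  npos <- sum(g)
  if (npos == 0) return(if (all(mhat == 0)) 1 else 0)
  o <- order(mhat, decreasing = TRUE)
  s <- mhat[o]
  gg <- g[o]
  # group ties: all pixels sharing a score enter together
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(gg)
  n_cum <- seq_along(gg)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp_cum[last]
  n <- n_cum[last]
  prec <- tp / n
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Compute the full metric report for one prediction
#'
#' Thresholds the probability map at `tau` and computes the ten evaluation
#' metrics: IoU, Dice, F1 (identical to Dice for binary masks), pixelwise
#' average precision (mAP), boundary Hausdorff distance, Cohen's kappa,
#' specificity, recall, precision, and pixel accuracy.
#'
#' @param mhat Probability map (`H x W`).
#' @param gt Binary ground truth (`H x W`).
#' @param tau Binarization threshold.
#' @return An object of class `promptseg_metrics`: a named list of the ten
#'   metric values.
#' @examples
#' gt <- matrix(0, 8, 8); gt[3:5, 3:5] <- 1
#' compute_metrics(gt, gt)$dice  # 1
#' @export
compute_metrics <- function(mhat, gt, tau = 0.5) {
  pred <- binarize(mhat, tau)
  cc <- confusion_counts(pred, gt)
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  dice <- safe_ratio(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn, cc$fp + cc$fn)
  iou <- safe_ratio(cc$tp, cc$tp + cc$fp + cc$fn, cc$fp + cc$fn)
  precision <- safe_ratio(cc$tp, cc$tp + cc$fp, cc$fp)
  recall <- safe_ratio(cc$tp, cc$tp + cc$fn, cc$fn)
  specificity <- safe_ratio(cc$tn, cc$tn + cc$fp, cc$fp)
  pixel_accuracy <- (cc$tp + cc$tn) / n
  po <- pixel_accuracy
  pe <- ((cc$tp + cc$fp) * (cc$tp + cc$fn) +
         (cc$tn + cc$fn) * (cc$tn + cc$fp)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  structure(list(
    iou = iou, dice = dice, f1 = dice,
    map = average_precision(mhat, gt),
    hd = hausdorff_distance(pred, gt),
    kappa = kappa, specificity = specificity, recall = recall,
    precision = precision, pixel_accuracy = pixel_accuracy),
    class = "promptseg_metrics")
}

metric_names <- function() c("iou", "dice", "f1", "map", "hd", "kappa",
                             "specificity", "recall", "precision",
                             "pixel_accuracy")

#' @export
print.promptseg_metrics <- function(x, ...) {
  v <- unlist(x[metric_names()])
  cat(paste(sprintf("%s=%.4f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' Aggregate metric reports over classes or samples
#'
#' Unweighted per-metric mean; with per-class reports the mean of the
#' per-class average precisions is the "m" in mAP.
#'
#' @param reports Non-empty list of [compute_metrics()] results.
#' @return A `promptseg_metrics` object of the means.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) ps_stop("no reports to aggregate")
  out <- lapply(metric_names(), function(nm)
    mean(vapply(reports, function(r) r[[nm]], 1)))
  names(out) <- metric_names()
  structure(out, class = "promptseg_metrics")
}

#' Write per-sample metric rows and an aggregate summary
#'
#' @param reports List of `promptseg_metrics` (one per sample).
#' @param dir Output directory (created if needed).
#' @param ids Optional sample identifiers.
#' @return Invisibly, a list with the per-sample data frame and the summary.
#' @export
write_metric_report <- function(reports, dir, ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(do.call(rbind, lapply(reports, function(r)
    unlist(r[metric_names()]))))
  df <- cbind(sample = ids %||% seq_len(nrow(df)), df)
  utils::write.csv(df, file.path(dir, "metrics_per_sample.csv"),
                   row.names = FALSE)
  summ <- data.frame(metric = metric_names(),
                     mean = vapply(metric_names(), function(nm) mean(df[[nm]]), 1),
                     sd = vapply(metric_names(), function(nm) stats::sd(df[[nm]]), 1))
  utils::write.csv(summ, file.path(dir, "metrics_summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(per_sample = df, summary = summ),
                       file.path(dir, "metrics.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(list(per_sample = df, summary = summ))
}
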