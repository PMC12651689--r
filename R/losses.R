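#' Loss configuration
#'
#' Selects and parameterizes one of the six training objectives, or a
#' weighted combination of them.
#'
#' @param name One of `"dice"`, `"focal"`, `"hausdorff"`, `"jaccard"`,
#'   `"tversky"`, `"dicebce"`.
#' @param focal_gamma Focusing exponent of the focal loss.
#' @param tversky_alpha,tversky_beta Tversky weights; `alpha` multiplies
#'   false positives, `beta` false negatives.
#' @param smooth_eps Smoothing constant added to the ratio losses so empty
#'   masks stay defined; set to 0 for exact closed-form checks.
#' @param weights Optional named numeric vector combining several losses
#'   into one objective (e.g. `c(dice = 1, focal = 0.5)`); overrides `name`.
#' @return An object of class `promptseg_loss_config`.
#' @export
loss_config <- function(name = c("dice", "focal", "hausdorff", "jaccard",
                                 "tversky", "dicebce"),
                        focal_gamma = 2, tversky_alpha = 0.7,
                        tversky_beta = 0.3, smooth_eps = 1e-6,
                        weights = NULL) {
  name <- match.arg(name)
  if (focal_gamma < 0) ps_stop("focal_gamma must be nonnegative")
  if (tversky_alpha + tversky_beta <= 0)
    ps_stop("tversky_alpha + tversky_beta must be positive")
  if (smooth_eps < 0) ps_stop("smooth_eps must be nonnegative")
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), loss_names())
    if (length(bad)) ps_stop("unknown loss in weights: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, focal_gamma = focal_gamma,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 smooth_eps = smooth_eps, weights = weights),
            class = "promptseg_loss_config")
}

#' Names of the available losses
#' @return Character vector of valid loss names.
#' @export
loss_names <- function() c("dice", "focal", "hausdorff", "jaccard",
                           "tversky", "dicebce")

check_pair <- function(mhat, m) {
  if (length(mhat) != length(m))
    ps_stop("prediction and mask lengths differ (", length(mhat), " vs ",
            length(m), ")", class = "promptseg_contract_error")
  invisible(NULL)
}

#' Dice loss
#'
#' `1 - (2 * sum(mhat * m) + eps) / (sum(mhat^2) + sum(m^2) + eps)`, the
#' soft Dice overlap between a probability map and a binary mask
#' (squared-denominator form; the shared smoothing constant keeps the loss
#' at 0 for a perfect prediction of an empty mask).
#'
#' @param mhat Predicted probabilities in `[0, 1]` (any shape).
#' @param m Binary ground-truth mask of equal length.
#' @param eps Smoothing constant.
#' @param grad If `TRUE`, also return the gradient w.r.t. `mhat`.
#' @return The loss value, or `list(value, grad)` when `grad = TRUE`.
#' @examples
#' dice_loss(c(1, 0, 0, 0), c(1, 1, 0, 0), eps = 0)  # 1 - 2/3
#' @export
dice_loss <- function(mhat, m, eps = 1e-6, grad = FALSE) {
  check_pair(mhat, m)
  inter <- sum(mhat * m)
  den <- sum(mhat * mhat) + sum(m * m) + eps
  val <- 1 - (2 * inter + eps) / den
  if (!grad) return(val)
  g <- -(2 * m * den - (2 * inter + eps) * 2 * mhat) / den^2
  list(value = val, grad = array(g, dim(mhat) %||% length(mhat)))
}

#' Focal loss
#'
#' Cross-entropy with a `(1 - p)^gamma` modulating factor that down-weights
#' easy pixels: `-(1/N) sum[(1-mhat)^g log(mhat) m + mhat^g log(1-mhat) (1-m)]`.
#' Predictions are clipped to `[clip, 1 - clip]` for log stability.
#'
#' @inheritParams dice_loss
#' @param gamma Focusing parameter (`gamma = 0` recovers mean BCE).
#' @param clip Clipping constant.
#' @export
focal_loss <- function(mhat, m, gamma = 2, clip = 1e-7, grad = FALSE) {
  check_pair(mhat, m)
  p <- pmin(pmax(mhat, clip), 1 - clip)
  n <- length(p)
  val <- -sum((1 - p)^gamma * log(p) * m + p^gamma * log(1 - p) * (1 - m)) / n
  if (!grad) return(val)
  gpos <- -((1 - p)^gamma / p - gamma * (1 - p)^(gamma - 1) * log(p))
  gneg <- -(gamma * p^(gamma - 1) * log(1 - p) - p^gamma / (1 - p))
  g <- (gpos * m + gneg * (1 - m)) / n
  g[mhat < clip | mhat > 1 - clip] <- 0
  list(value = val, grad = array(g, dim(mhat) %||% length(mhat)))
}

#' Jaccard (IoU) loss
#'
#' `1 - (sum(mhat m) + eps) / (sum(mhat) + sum(m) - sum(mhat m) + eps)`.
#' @inheritParams dice_loss
#' @export
jaccard_loss <- function(mhat, m, eps = 1e-6, grad = FALSE) {
  check_pair(mhat, m)
  inter <- sum(mhat * m)
  uni <- sum(mhat) + sum(m) - inter
  val <- 1 - (inter + eps) / (uni + eps)
  if (!grad) return(val)
  g <- -(m * (uni + eps) - (inter + eps) * (1 - m)) / (uni + eps)^2
  list(value = val, grad = array(g, dim(mhat) %||% length(mhat)))
}

#' Tversky loss
#'
#' `1 - (TP + eps) / (TP + alpha FP + beta FN + eps)` on soft counts, with
#' `alpha` weighting false positives and `beta` false negatives. The default
#' `alpha = 0.7, beta = 0.3` penalizes false positives more heavily;
#' `alpha = beta = 0.5` recovers the non-squared Dice-form loss.
#'
#' @inheritParams dice_loss
#' @param alpha,beta Asymmetry weights.
#' @export
tversky_loss <- function(mhat, m, alpha = 0.7, beta = 0.3, eps = 1e-6,
                         grad = FALSE) {
  check_pair(mhat, m)
  tp <- sum(mhat * m)
  fp <- sum(mhat * (1 - m))
  fn <- sum((1 - mhat) * m)
  den <- tp + alpha * fp + beta * fn + eps
  val <- 1 - (tp + eps) / den
  if (!grad) return(val)
  dtp <- m; dfp <- 1 - m; dfn <- -m
  dden <- dtp + alpha * dfp + beta * dfn
  g <- -(dtp * den - (tp + eps) * dden) / den^2
  list(value = val, grad = array(g, dim(mhat) %||% length(mhat)))
}

#' Dice + binary cross-entropy loss
#'
#' Sum of [dice_loss()] and the mean binary cross-entropy, unit weights.
#' @inheritParams dice_loss
#' @param clip Clipping constant for the BCE term.
#' @export
dicebce_loss <- function(mhat, m, eps = 1e-6, clip = 1e-7, grad = FALSE) {
  check_pair(mhat, m)
  p <- pmin(pmax(mhat, clip), 1 - clip)
  bce <- -mean(m * log(p) + (1 - m) * log(1 - p))
  if (!grad) return(dice_loss(mhat, m, eps) + bce)
  dl <- dice_loss(mhat, m, eps, grad = TRUE)
  gb <- (-m / p + (1 - m) / (1 - p)) / length(p)
  gb[mhat < clip | mhat > 1 - clip] <- 0
  list(value = dl$value + bce,
       grad = dl$grad + array(gb, dim(mhat) %||% length(mhat)))
}

## ---- Hausdorff distance and its training surrogate ----------------------

# Boundary pixels: foreground with at least one 4-connected background
# neighbour, counting pixels beyond the image border as background.
boundary_points <- function(mask) {
  mask <- (mask >= 0.5) + 0L
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(mask == 1L & !nb, arr.ind = TRUE)
}

#' Hausdorff distance between two binary masks
#'
#' The maximum over both directions of the largest nearest-neighbour
#' Euclidean distance between the masks' boundary point sets. Predictions
#' are binarized at 0.5 first. If exactly one mask is empty the image
#' diagonal is returned as a sentinel; if both are empty the distance is 0.
#'
#' @param a,b Binary masks (matrices); probability maps are thresholded at
#'   0.5.
#' @return Nonnegative distance in pixels.
#' @examples
#' m <- matrix(0, 8, 8); m[2, 2] <- 1
#' q <- matrix(0, 8, 8); q[5, 6] <- 1
#' hausdorff_distance(m, q)  # sqrt(3^2 + 4^2) = 5
#' @export
hausdorff_distance <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    ps_stop("mask shapes differ", class = "promptseg_contract_error")
  P <- boundary_points(a)
  Q <- boundary_points(b)
  if (nrow(P) == 0L && nrow(Q) == 0L) return(0)
  if (nrow(P) == 0L || nrow(Q) == 0L)
    return(sqrt(sum((dim(a) - 1)^2)))
  d2 <- outer(P[, 1L], Q[, 1L], "-")^2 + outer(P[, 2L], Q[, 2L], "-")^2
  dim(d2) <- c(nrow(P), nrow(Q))
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Differentiable Hausdorff training surrogate
#'
#' The exact boundary Hausdorff distance is not differentiable in the
#' predicted probabilities, so training uses a surrogate: the mean squared
#' error weighted by `1 +` the Euclidean distance transforms of each mask's
#' complement (distance of every pixel to the ground-truth foreground and to
#' the binarized predicted foreground, both treated as constants). Errors
#' far from the target boundary cost more; the surrogate is zero exactly on
#' a perfect binary match and has a finite gradient everywhere. This is a
#' documented stand-in, not the boundary metric itself.
#'
#' @param mhat Probability matrix.
#' @param m Binary ground-truth matrix.
#' @param grad If `TRUE`, also return the gradient w.r.t. `mhat`.
#' @return Loss value or `list(value, grad)`.
#' @export
hausdorff_surrogate <- function(mhat, m, grad = FALSE) {
  check_pair(mhat, m)
  w <- 1 + dist_to_fg(m) + dist_to_fg(mhat >= 0.5)
  err <- (mhat - m)^2
  val <- mean(err * w)
  if (!grad) return(val)
  list(value = val, grad = 2 * (mhat - m) * w / length(m))
}

# Distance of each pixel to the nearest foreground pixel of `mask`
# (0 on the foreground itself; large everywhere when the mask is empty).
dist_to_fg <- function(mask) {
  mask <- matrix(as.numeric(mask >= 0.5), nrow(mask), ncol(mask))
  if (!any(mask > 0)) return(matrix(sqrt(sum(dim(mask)^2)), nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(1 - mask, metric = "euclidean"))
}

## ---- dispatch ------------------------------------------------------------

# Evaluate the configured loss (or weighted combination) with gradient.
loss_eval <- function(mhat, m, cfg) {
  one <- function(nm) {
    switch(nm,
      dice = dice_loss(mhat, m, cfg$smooth_eps, grad = TRUE),
      focal = focal_loss(mhat, m, cfg$focal_gamma, grad = TRUE),
      jaccard = jaccard_loss(mhat, m, cfg$smooth_eps, grad = TRUE),
      tversky = tversky_loss(mhat, m, cfg$tversky_alpha, cfg$tversky_beta,
                             cfg$smooth_eps, grad = TRUE),
      dicebce = dicebce_loss(mhat, m, cfg$smooth_eps, grad = TRUE),
      hausdorff = hausdorff_surrogate(mhat, m, grad = TRUE),
      ps_stop("unknown loss: ", nm))
  }
  if (is.null(cfg$weights)) return(one(cfg$name))
  val <- 0
  g <- array(0, dim(mhat) %||% length(mhat))
  for (nm in names(cfg$weights)) {
    r <- one(nm)
    val <- val + cfg$weights[[nm]] * r$value
    g <- g + cfg$weights[[nm]] * r$grad
  }
  list(value = val, grad = g)
}

#' Evaluate a segmentation loss by name
#'
#' @param mhat Predicted probabilities.
#' @param m Binary ground truth.
#' @param cfg A [loss_config()].
#' @return The scalar loss value.
#' @export
segmentation_loss <- function(mhat, m, cfg = loss_config()) {
  loss_eval(mhat, m, cfg)$value
}
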