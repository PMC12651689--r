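# Independent brute-force oracles used across the suite. These are written
# from the formulas directly (explicit loops / elementary vector arithmetic)
# and share no code with the package implementation.

# All 2^9 binary 3x3 masks as a 512 x 9 matrix of 0/1.
all_masks_3x3 <- function() {
  m <- matrix(0L, 512L, 9L)
  for (i in 0:511) m[i + 1L, ] <- as.integer(intToBits(i)[1:9])
  m
}

# Loss oracles on flattened vectors (eps = 0 throughout).
oracle_dice <- function(p, m) 1 - 2 * sum(p * m) / (sum(p^2) + sum(m^2))
oracle_jaccard <- function(p, m) {
  1 - sum(p * m) / (sum(p) + sum(m) - sum(p * m))
}
oracle_tversky <- function(p, m, a, b) {
  tp <- sum(p * m); fp <- sum(p * (1 - m)); fn <- sum((1 - p) * m)
  1 - tp / (tp + a * fp + b * fn)
}
oracle_focal <- function(p, m, g, clip = 1e-7) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean((1 - p)^g * log(p) * m + p^g * log(1 - p) * (1 - m))
}
oracle_bce <- function(p, m, clip = 1e-7) {
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

# Boundary set: foreground pixels with a 4-neighbour background pixel or on
# the image border (independent double-loop implementation).
oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    edge <- i == 1 || i == H || j == 1 || j == W
    if (!edge) {
      nb <- c(mask[i - 1, j], mask[i + 1, j], mask[i, j - 1], mask[i, j + 1])
      edge <- any(nb == 0)
    }
    if (edge) pts <- rbind(pts, c(i, j))
  }
  pts
}

oracle_hausdorff <- function(a, b) {
  P <- oracle_boundary(a)
  Q <- oracle_boundary(b)
  if (is.null(P) && is.null(Q)) return(0)
  if (is.null(P) || is.null(Q)) return(sqrt(sum((dim(a) - 1)^2)))
  dmin_PQ <- apply(P, 1, function(p)
    min(apply(Q, 1, function(q) sqrt(sum((p - q)^2)))))
  dmin_QP <- apply(Q, 1, function(q)
    min(apply(P, 1, function(p) sqrt(sum((p - q)^2)))))
  max(max(dmin_PQ), max(dmin_QP))
}

# Per-pixel loop confusion counts and the metric set derived from them.
oracle_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] >= 0.5 && gt[i] >= 0.5) tp <- tp + 1L
    else if (pred[i] >= 0.5) fp <- fp + 1L
    else if (gt[i] >= 0.5) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_metrics <- function(prob, gt, tau = 0.5) {
  pred <- ifelse(prob >= tau, 1, 0)
  cc <- oracle_confusion(pred, gt)
  n <- sum(cc)
  sr <- function(num, den, err) if (den == 0) (if (err == 0) 1 else 0) else num / den
  dice <- sr(2 * cc["tp"], 2 * cc["tp"] + cc["fp"] + cc["fn"], cc["fp"] + cc["fn"])
  po <- (cc["tp"] + cc["tn"]) / n
  pe <- ((cc["tp"] + cc["fp"]) * (cc["tp"] + cc["fn"]) +
           (cc["tn"] + cc["fn"]) * (cc["tn"] + cc["fp"])) / n^2
  list(iou = unname(sr(cc["tp"], cc["tp"] + cc["fp"] + cc["fn"],
                       cc["fp"] + cc["fn"])),
       dice = unname(dice), f1 = unname(dice),
       kappa = unname(if (pe == 1) 1 else (po - pe) / (1 - pe)),
       specificity = unname(sr(cc["tn"], cc["tn"] + cc["fp"], cc["fp"])),
       recall = unname(sr(cc["tp"], cc["tp"] + cc["fn"], cc["fn"])),
       precision = unname(sr(cc["tp"], cc["tp"] + cc["fp"], cc["fp"])),
       pixel_accuracy = unname(po))
}

# Average precision by explicit sweep over every distinct score threshold.
oracle_ap <- function(prob, gt) {
  g <- as.numeric(gt >= 0.5)
  npos <- sum(g)
  if (npos == 0) return(if (all(prob == 0)) 1 else 0)
  ths <- sort(unique(as.vector(prob)), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in ths) {
    pred <- as.numeric(prob >= t)
    tp <- sum(pred * g)
    prec <- tp / sum(pred)
    rec <- tp / npos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# Direct-evaluation oracle for one SE block (global average pool, two
# affine maps, sigmoid gate, broadcast product).
oracle_se <- function(f, w1, w2) {
  C <- dim(f)[1]
  z <- vapply(seq_len(C), function(c) mean(f[c, , ]), 1)
  u <- 1 / (1 + exp(-(w2 %*% pmax(w1 %*% z, 0))))
  out <- f
  for (c in seq_len(C)) out[c, , ] <- u[c] * f[c, , ]
  out
}

# Direct convolution of the [avg; max] channel-pooled maps with a 7x7 (or
# k x k) kernel, zero padding, then sigmoid — the spatial attention map.
oracle_spatial_attention <- function(f, kernel, bias) {
  k <- dim(kernel)[1]
  p <- (k - 1) / 2
  H <- dim(f)[2]; W <- dim(f)[3]
  avg <- apply(f, c(2, 3), mean)
  mx <- apply(f, c(2, 3), max)
  pooled <- list(avg, mx)
  ms <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- bias
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - p; jj <- j + kj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + kernel[ki, kj, 1, 1] * pooled[[1]][ii, jj] +
          kernel[ki, kj, 2, 1] * pooled[[2]][ii, jj]
    }
    ms[i, j] <- 1 / (1 + exp(-s))
  }
  ms
}

# Small helpers shared by several test files.
rand_mask <- function(h, w, p = 0.4) matrix(rbinom(h * w, 1, p), h, w)
rand_prob <- function(h, w) matrix(runif(h * w), h, w)
`%||%` <- function(a, b) if (is.null(a)) b else a
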