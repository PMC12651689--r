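# Differentiable primitives on the internal [H, W, N, C] tensor layout.
# Every primitive comes as a *_fwd returning list(y, cache) and a *_bwd
# taking (dy, cache) and returning gradients. Convolutions are evaluated as
# cross-correlations via shifted-slice patch matrices and one BLAS GEMM,
# which is where essentially all compute time goes.

zero_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  xp
}

# Weight array [k, k, Cin, Cout] <-> GEMM matrix [Cin*k*k, Cout] with row
# order (cin fastest, then ki, then kj) — must match patch-matrix assembly.
conv_w_mat <- function(warr) {
  d <- dim(warr)
  matrix(aperm(warr, c(3L, 1L, 2L, 4L)), d[1L] * d[2L] * d[3L], d[4L])
}
conv_w_arr <- function(wm, k, cin, cout) {
  aperm(array(wm, c(cin, k, k, cout)), c(2L, 3L, 1L, 4L))
}

# Add per-column vector / multiply per-column vector without sweep()'s
# aperm overhead.
col_add <- function(M, v) M + rep(v, each = nrow(M))
col_mul <- function(M, v) M * rep(v, each = nrow(M))

# Flat-index gather for shifted slices: the slice at kernel offset
# (ki, kj) of the padded tensor is the base-offset slice plus a constant
# flat displacement, so one memoized index vector serves all k*k offsets of
# a given shape. The memo is tiny (one integer vector per distinct layer
# shape) and makes slice extraction a single C-level gather.
.conv_idx_memo <- new.env(parent = emptyenv())

conv_base_idx <- function(Hp, Wp, N, Ci, H, W) {
  key <- paste(Hp, Wp, N, Ci, H, W, sep = "x")
  idx <- .conv_idx_memo[[key]]
  if (is.null(idx)) {
    idx <- rep.int(seq_len(H), W * N * Ci) +
      rep(rep.int((seq_len(W) - 1L) * Hp, rep.int(H, W)), N * Ci) +
      rep(rep.int((seq_len(N) - 1L) * (Hp * Wp), rep.int(H * W, N)), Ci) +
      rep.int((seq_len(Ci) - 1L) * (Hp * Wp * N), rep.int(H * W * N, Ci))
    .conv_idx_memo[[key]] <- idx
  }
  idx
}

conv_slice <- function(xp, ki, kj, H, W) {
  d <- dim(xp)
  idx <- conv_base_idx(d[1L], d[2L], d[3L], d[4L], H, W)
  s <- xp[idx + ((ki - 1L) + d[1L] * (kj - 1L))]
  dim(s) <- c(H * W * d[3L], d[4L])
  s
}

# 2-D convolution, stride 1, square kernel k, zero padding p (spatial size
# preserved when p = (k-1)/2). wm: GEMM weight matrix [Cin*k*k, Cout], row
# blocks ordered (cin fastest, then ki, then kj) to match conv_w_mat().
# Evaluated as k*k accumulated GEMMs over shifted slices, which keeps peak
# memory at one slice instead of a full patch matrix.
conv2d_fwd <- function(x, wm, b, k, p) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  xp <- zero_pad(x, p)
  ym <- NULL
  idx <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    s <- conv_slice(xp, ki, kj, H, W)
    blk <- s %*% wm[(idx * Ci + 1L):((idx + 1L) * Ci), , drop = FALSE]
    ym <- if (is.null(ym)) blk else ym + blk
    idx <- idx + 1L
  }
  ym <- col_add(ym, b)
  dim(ym) <- c(H, W, N, length(b))
  list(y = ym, cache = list(xp = xp, dims = d, k = k, p = p, wm = wm))
}

# Weight gradient: per-offset crossprod of the cached padded slices with dy.
# Input gradient: the same-padded stride-1 cross-correlation of dy with the
# rotated, channel-transposed kernel, also evaluated slice-by-slice.
conv2d_bwd <- function(dy, cache) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  k <- cache$k; p <- cache$p
  cout <- dim(dy)[4L]
  dym <- dy
  dim(dym) <- c(H * W * N, cout)
  db <- colSums(dym)
  dW <- matrix(0, k * k * Ci, cout)
  idx <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    s <- conv_slice(cache$xp, ki, kj, H, W)
    dW[(idx * Ci + 1L):((idx + 1L) * Ci), ] <- crossprod(s, dym)
    idx <- idx + 1L
  }
  dyp <- zero_pad(dy, k - 1L - p)
  warr <- array(cache$wm, c(Ci, k, k, cout))
  dxm <- NULL
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    s <- conv_slice(dyp, ki, kj, H, W)
    wb <- matrix(warr[, k + 1L - ki, k + 1L - kj, ], Ci, cout)
    blk <- tcrossprod(s, wb)
    dxm <- if (is.null(dxm)) blk else dxm + blk
  }
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

# Transposed convolution, 2x2 kernel, stride 2: exact inverse geometry of the
# 2x2 pooling grid, so output blocks do not overlap. w: [2,2,Cin,Cout] stored
# as four [Cin, Cout] matrices (list index (di, dj) in row-major order).
tconv2_fwd <- function(x, ws, b) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  cout <- length(b)
  xm <- x
  dim(xm) <- c(H * W * N, Ci)
  y <- array(0, c(2L * H, 2L * W, N, cout))
  o <- 0L
  for (dj in 0:1) for (di in 0:1) {
    o <- o + 1L
    blk <- xm %*% ws[[o]]
    dim(blk) <- c(H, W, N, cout)
    y[seq.int(1L + di, 2L * H, 2L), seq.int(1L + dj, 2L * W, 2L), , ] <- blk
  }
  y <- y + array(rep(b, each = 4L * H * W * N), dim(y))
  list(y = y, cache = list(xm = xm, dims = d, ws = ws))
}

tconv2_bwd <- function(dy, cache) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  cout <- dim(dy)[4L]
  dxm <- matrix(0, H * W * N, Ci)
  dWs <- vector("list", 4L)
  db <- numeric(cout)
  o <- 0L
  for (dj in 0:1) for (di in 0:1) {
    o <- o + 1L
    blk <- dy[seq.int(1L + di, 2L * H, 2L), seq.int(1L + dj, 2L * W, 2L), , , drop = FALSE]
    dim(blk) <- c(H * W * N, cout)
    dWs[[o]] <- crossprod(cache$xm, blk)
    db <- db + colSums(blk)
    dxm <- dxm + tcrossprod(blk, cache$ws[[o]])
  }
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, dWs = dWs, db = db)
}

# 2x2 stride-2 max pooling; ties broken towards the earliest window position
# (row-major), which keeps eval-mode forward passes bit-reproducible.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  io <- seq.int(1L, H, 2L); ie <- seq.int(2L, H, 2L)
  jo <- seq.int(1L, W, 2L); je <- seq.int(2L, W, 2L)
  a <- list(x[io, jo, , , drop = FALSE], x[ie, jo, , , drop = FALSE],
            x[io, je, , , drop = FALSE], x[ie, je, , , drop = FALSE])
  y <- pmax(a[[1L]], a[[2L]], a[[3L]], a[[4L]])
  taken <- !logical(length(y))
  masks <- vector("list", 4L)
  for (o in 1:4) {
    m <- (a[[o]] == y) & taken
    taken <- taken & !m
    masks[[o]] <- m
  }
  list(y = y, cache = list(masks = masks, dims = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]
  io <- seq.int(1L, H, 2L); ie <- seq.int(2L, H, 2L)
  jo <- seq.int(1L, W, 2L); je <- seq.int(2L, W, 2L)
  dx <- array(0, d)
  sel <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  for (o in 1:4) {
    g <- dy * cache$masks[[o]]
    dx[sel[[o]][[1L]], sel[[o]][[2L]], , ] <- g
  }
  dx
}

leaky_relu_fwd <- function(x, slope = 0.1) {
  fac <- 1 + (slope - 1) * (x < 0)
  list(y = x * fac, cache = fac)
}

leaky_relu_bwd <- function(dy, cache) dy * cache

# Batch normalization over (H, W, N) per channel. `bufs` is an environment
# holding running_mean/running_var under `prefix`; biased batch variance is
# used both in-batch and for the running estimate (one consistent convention).
batchnorm_fwd <- function(x, gamma, beta, bufs, prefix, train,
                          eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  M <- d[1L] * d[2L] * d[3L]; C <- d[4L]
  xm <- x
  dim(xm) <- c(M, C)
  rm_key <- paste0(prefix, ".running_mean")
  rv_key <- paste0(prefix, ".running_var")
  if (train) {
    mu <- colMeans(xm)
    xc <- col_add(xm, -mu)
    v <- colMeans(xc * xc)
    bufs[[rm_key]] <- (1 - momentum) * bufs[[rm_key]] + momentum * mu
    bufs[[rv_key]] <- (1 - momentum) * bufs[[rv_key]] + momentum * v
  } else {
    mu <- bufs[[rm_key]]
    v <- bufs[[rv_key]]
    xc <- col_add(xm, -mu)
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- col_mul(xc, ivar)
  ym <- col_add(col_mul(xhat, gamma), beta)
  y <- array(ym, d)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma,
                           dims = d, train = train))
}

batchnorm_bwd <- function(dy, cache) {
  d <- cache$dims
  M <- d[1L] * d[2L] * d[3L]; C <- d[4L]
  dym <- dy
  dim(dym) <- c(M, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- col_mul(dym, cache$gamma)
  if (cache$train) {
    dxm <- col_add(dxhat, -colMeans(dxhat)) -
      col_mul(cache$xhat, colMeans(dxhat * cache$xhat))
    dxm <- col_mul(dxm, cache$ivar)
  } else {
    dxm <- col_mul(dxhat, cache$ivar)
  }
  dx <- array(dxm, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; identity in eval mode.
dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * keep, cache = keep)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# Dense layer on row-vectors: y = x %*% t(W) + b with W [dout, din] kept in
# the "maps rows are outputs" orientation used for the SE / FiLM / CBN maps.
linear_fwd <- function(x, W, b) {
  y <- col_add(tcrossprod(x, W), b)
  list(y = y, cache = list(x = x, W = W))
}

linear_bwd <- function(dy, cache) {
  list(dx = dy %*% cache$W,
       dW = crossprod(dy, cache$x),
       db = colSums(dy))
}
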