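# Composite blocks: squeeze-and-excitation (SE) channel attention, spatial
# convolutional attention (single 7x7-conv spatial branch), and the residual
# double-convolution block used by every encoder and decoder stage.
#
# Parameters live in a flat named list (model$params); gradients are
# accumulated into an environment keyed by the same names via grad_acc().

grad_acc <- function(genv, name, g) {
  cur <- genv[[name]]
  genv[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

relu <- function(x) pmax(x, 0)

## ---- squeeze-and-excitation -------------------------------------------

# u = sigmoid(W2 %*% relu(W1 %*% GAP(F))); y = u (.) F  (per sample/channel).
# W1: [C/r, C], W2: [C, C/r]; no bias terms.
se_fwd <- function(x, W1, W2) {
  d <- dim(x)
  z <- reduce_hw(x, mean = TRUE)              # [N, C]
  a <- tcrossprod(z, W1)                      # [N, C/r]
  h <- relu(a)
  s <- tcrossprod(h, W2)                      # [N, C]
  u <- sigmoid(s)
  y <- x * bcast_nc(u, d[1L], d[2L])
  list(y = y, cache = list(x = x, z = z, a = a, h = h, u = u,
                           W1 = W1, W2 = W2, dims = d))
}

se_bwd <- function(dy, cache, genv = NULL, prefix = NULL) {
  d <- cache$dims
  u <- cache$u
  du <- reduce_hw(dy * cache$x)               # [N, C]
  dx <- dy * bcast_nc(u, d[1L], d[2L])
  ds <- du * u * (1 - u)
  dW2 <- crossprod(ds, cache$h)
  dh <- ds %*% cache$W2
  da <- dh * (cache$a > 0)
  dW1 <- crossprod(da, cache$z)
  dz <- da %*% cache$W1
  dx <- dx + bcast_nc(dz / (d[1L] * d[2L]), d[1L], d[2L])
  if (!is.null(genv)) {
    grad_acc(genv, paste0(prefix, ".W1"), dW1)
    grad_acc(genv, paste0(prefix, ".W2"), dW2)
  }
  list(dx = dx, dW1 = dW1, dW2 = dW2)
}

## ---- spatial attention (7x7 conv over [avg;max] channel pools) ---------

cbam_fwd <- function(x, wm, b, k = 7L) {
  d <- dim(x)
  M <- d[1L] * d[2L] * d[3L]; C <- d[4L]
  xm <- x
  dim(xm) <- c(M, C)
  avg <- rowMeans(xm)
  mxi <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(M), mxi)]
  pooled <- array(c(avg, mx), c(d[1L], d[2L], d[3L], 2L))
  cv <- conv2d_fwd(pooled, wm, b, k = k, p = (k - 1L) %/% 2L)
  ms <- sigmoid(cv$y)                          # [H, W, N, 1]
  msl <- array(ms, d[1:3])
  y <- x * bcast_hwn(msl, C)
  list(y = y, cache = list(x = x, msl = msl, mxi = mxi, cv = cv$cache,
                           dims = d))
}

cbam_bwd <- function(dy, cache, genv = NULL, prefix = NULL) {
  d <- cache$dims
  M <- d[1L] * d[2L] * d[3L]; C <- d[4L]
  msl <- cache$msl
  dms <- reduce_c(dy * cache$x)                # [H, W, N]
  dx <- dy * bcast_hwn(msl, C)
  dsig <- dms * msl * (1 - msl)
  cb <- conv2d_bwd(array(dsig, c(d[1:3], 1L)), cache$cv)
  dpool <- cb$dx                               # [H, W, N, 2]
  davg <- array(dpool[, , , 1L], d[1:3])
  dmax <- as.vector(dpool[, , , 2L])
  dx <- dx + bcast_hwn(davg / C, C)
  dxm <- matrix(0, M, C)
  dxm[cbind(seq_len(M), cache$mxi)] <- dmax
  dx <- dx + array(dxm, d)
  if (!is.null(genv)) {
    grad_acc(genv, paste0(prefix, ".W"), cb$dW)
    grad_acc(genv, paste0(prefix, ".b"), cb$db)
  }
  list(dx = dx, dW = cb$dW, db = cb$db)
}

## ---- residual double-convolution block ---------------------------------

# Initialise parameters for one conv block under `prefix`. Uses the current
# RNG stream (the model constructor seeds it once).
init_conv_block <- function(params, bufs, prefix, cin, cout, cfg) {
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  params[[paste0(prefix, ".conv1.W")]] <- he(9L * cin, cout, 9L * cin)
  params[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  params[[paste0(prefix, ".conv2.W")]] <- he(9L * cout, cout, 9L * cout)
  params[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  for (bn in c(".bn1", ".bn2")) {
    params[[paste0(prefix, bn, ".gamma")]] <- rep(1, cout)
    params[[paste0(prefix, bn, ".beta")]] <- numeric(cout)
    bufs[[paste0(prefix, bn, ".running_mean")]] <- numeric(cout)
    bufs[[paste0(prefix, bn, ".running_var")]] <- rep(1, cout)
  }
  if (cin != cout) {
    params[[paste0(prefix, ".proj.W")]] <- he(cin, cout, cin)
    params[[paste0(prefix, ".proj.b")]] <- numeric(cout)
  }
  if (cfg$use_se) {
    r <- cfg$se_reduction
    if (cout %% r != 0L)
      ps_stop("SE reduction ratio ", r, " does not divide channel count ",
              cout, class = "promptseg_config_error")
    params[[paste0(prefix, ".se.W1")]] <- he(cout %/% r, cout, cout)
    params[[paste0(prefix, ".se.W2")]] <- he(cout, cout %/% r, cout %/% r)
  }
  if (cfg$use_cbam) {
    k <- cfg$cbam_kernel
    params[[paste0(prefix, ".cbam.W")]] <- he(k * k * 2L, 1L, k * k * 2L)
    params[[paste0(prefix, ".cbam.b")]] <- numeric(1L)
  }
  params
}

# Forward pass through one block:
#   LeakyReLU(BN1(conv1)) -> BN2(conv2) -> + shortcut -> LeakyReLU
#   -> SE (optional) -> spatial attention (optional) -> dropout.
conv_block_fwd <- function(params, bufs, prefix, x, cfg, train) {
  d <- dim(x)
  cin <- d[4L]
  p <- function(s) params[[paste0(prefix, s)]]
  cout <- length(p(".conv1.b"))
  caches <- list()

  c1 <- conv2d_fwd(x, p(".conv1.W"), p(".conv1.b"), 3L, 1L)
  b1 <- batchnorm_fwd(c1$y, p(".bn1.gamma"), p(".bn1.beta"), bufs,
                      paste0(prefix, ".bn1"), train, eps = cfg$bn_eps)
  r1 <- leaky_relu_fwd(b1$y, cfg$leaky_slope)
  c2 <- conv2d_fwd(r1$y, p(".conv2.W"), p(".conv2.b"), 3L, 1L)
  b2 <- batchnorm_fwd(c2$y, p(".bn2.gamma"), p(".bn2.beta"), bufs,
                      paste0(prefix, ".bn2"), train, eps = cfg$bn_eps)
  if (cin != cout) {
    xm <- x
    dim(xm) <- c(prod(d[1:3]), cin)
    sm <- sweep(xm %*% p(".proj.W"), 2L, p(".proj.b"), "+")
    short <- array(sm, c(d[1:3], cout))
    caches$proj_x <- xm
  } else short <- x
  r2 <- leaky_relu_fwd(b2$y + short, cfg$leaky_slope)
  y <- r2$y
  if (cfg$use_se) {
    se <- se_fwd(y, p(".se.W1"), p(".se.W2"))
    y <- se$y
    caches$se <- se$cache
  }
  if (cfg$use_cbam) {
    cb <- cbam_fwd(y, p(".cbam.W"), p(".cbam.b"), cfg$cbam_kernel)
    y <- cb$y
    caches$cbam <- cb$cache
  }
  dr <- dropout_fwd(y, cfg$dropout_rate, train)
  caches <- c(caches, list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                           c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                           dr = dr$cache, cin = cin, cout = cout, dims = d))
  list(y = dr$y, cache = caches)
}

conv_block_bwd <- function(dy, cache, params, prefix, cfg, genv) {
  p <- function(s) params[[paste0(prefix, s)]]
  g <- function(s, val) grad_acc(genv, paste0(prefix, s), val)

  dy <- dropout_bwd(dy, cache$dr)
  if (cfg$use_cbam) {
    cb <- cbam_bwd(dy, cache$cbam, genv, paste0(prefix, ".cbam"))
    dy <- cb$dx
  }
  if (cfg$use_se) {
    se <- se_bwd(dy, cache$se, genv, paste0(prefix, ".se"))
    dy <- se$dx
  }
  dsum <- leaky_relu_bwd(dy, cache$r2)
  # branch 1: BN2 <- conv2 <- LeakyReLU1 <- BN1 <- conv1
  b2 <- batchnorm_bwd(dsum, cache$b2)
  g(".bn2.gamma", b2$dgamma); g(".bn2.beta", b2$dbeta)
  c2 <- conv2d_bwd(b2$dx, cache$c2)
  g(".conv2.W", c2$dW); g(".conv2.b", c2$db)
  dr1 <- leaky_relu_bwd(c2$dx, cache$r1)
  b1 <- batchnorm_bwd(dr1, cache$b1)
  g(".bn1.gamma", b1$dgamma); g(".bn1.beta", b1$dbeta)
  c1 <- conv2d_bwd(b1$dx, cache$c1)
  g(".conv1.W", c1$dW); g(".conv1.b", c1$db)
  dx <- c1$dx
  # branch 2: shortcut
  if (cache$cin != cache$cout) {
    d <- cache$dims
    dsm <- dsum
    dim(dsm) <- c(prod(d[1:3]), cache$cout)
    g(".proj.W", crossprod(cache$proj_x, dsm))
    g(".proj.b", colSums(dsm))
    dxs <- tcrossprod(dsm, p(".proj.W"))
    dim(dxs) <- c(d[1:3], cache$cin)
    dx <- dx + dxs
  } else {
    dx <- dx + dsum
  }
  dx
}
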