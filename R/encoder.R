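#' Encoder configuration
#'
#' Settings for the four-stage attention-augmented encoder and for every
#' residual double-convolution block in the network (the decoder reuses the
#' same block type).
#'
#' @param se_reduction Bottleneck reduction ratio `r` of the
#'   squeeze-and-excitation block. Must divide every stage channel count.
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param dropout_rate Dropout rate applied at the end of each block
#'   (active in training mode only).
#' @param cbam_kernel Odd kernel size of the spatial-attention convolution.
#' @param use_se,use_cbam Ablation toggles for the two attention mechanisms.
#' @param bn_eps Batch-normalization variance floor.
#' @return An object of class `promptseg_encoder_config`.
#' @examples
#' cfg <- encoder_config(use_cbam = FALSE)
#' @export
encoder_config <- function(se_reduction = 16L, leaky_slope = 0.1,
                           dropout_rate = 0.1, cbam_kernel = 7L,
                           use_se = TRUE, use_cbam = TRUE, bn_eps = 1e-5) {
  if (se_reduction < 1L) ps_stop("se_reduction must be a positive integer")
  if (cbam_kernel %% 2L != 1L) ps_stop("cbam_kernel must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1)
    ps_stop("dropout_rate must lie in [0, 1)")
  structure(list(se_reduction = as.integer(se_reduction),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 cbam_kernel = as.integer(cbam_kernel),
                 use_se = isTRUE(use_se), use_cbam = isTRUE(use_cbam),
                 bn_eps = bn_eps),
            class = "promptseg_encoder_config")
}

validate_image <- function(image) {
  if (is.matrix(image)) image <- array(image, c(1L, dim(image)))
  if (length(dim(image)) != 3L)
    ps_stop("image must be a C x H x W array or an H x W matrix")
  check_finite(image, "image")
  d <- dim(image)
  if (d[2L] < 16L || d[3L] < 16L) ps_stop("image sides must be at least 16")
  if (d[2L] %% 16L != 0L)
    ps_stop("image height ", d[2L], " is not divisible by 16",
            class = "promptseg_dim_error")
  if (d[3L] %% 16L != 0L)
    ps_stop("image width ", d[3L], " is not divisible by 16",
            class = "promptseg_dim_error")
  image
}

#' Squeeze-and-excitation channel attention
#'
#' Recalibrates a feature map channel-wise:
#' `u = sigmoid(W2 %*% relu(W1 %*% z))` with `z` the global average pool of
#' each channel, and the output is `u * F` broadcast over space.
#'
#' @param f Feature map, a `C x H x W` array.
#' @param r Reduction ratio; `C` must be divisible by `r`.
#' @param w1 Optional `C/r x C` squeeze matrix (drawn from the current RNG
#'   when `NULL`).
#' @param w2 Optional `C x C/r` excitation matrix.
#' @return A `C x H x W` array of the same shape as `f`.
#' @examples
#' f <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
#' out <- se_block(f, r = 2)
#' stopifnot(dim(out) == dim(f))
#' @export
se_block <- function(f, r = 16L, w1 = NULL, w2 = NULL) {
  C <- dim(f)[1L]
  if (C %% r != 0L)
    ps_stop("channel count ", C, " is not divisible by the SE reduction ",
            "ratio ", r, class = "promptseg_config_error")
  if (is.null(w1)) w1 <- matrix(stats::rnorm(C %/% r * C, 0, sqrt(2 / C)), C %/% r, C)
  if (is.null(w2)) w2 <- matrix(stats::rnorm(C * C %/% r, 0, sqrt(2 / C)), C, C %/% r)
  x <- as_hwnc(f)
  as_chw(se_fwd(x, w1, w2)$y)
}

#' Spatial attention (single 7x7 convolutional branch)
#'
#' Computes a spatial attention map by convolving the concatenation of the
#' channel-wise average- and max-pooled maps with a single `k x k` filter,
#' passing it through a sigmoid, and rescaling the feature map per pixel.
#' Only this spatial branch is implemented (no channel branch); see the
#' methods vignette for the rationale.
#'
#' @param f Feature map, a `C x H x W` array.
#' @param kernel Optional `k x k x 2 x 1` filter array (random when `NULL`).
#' @param bias Scalar bias of the attention convolution.
#' @param k Kernel size (odd).
#' @return A `C x H x W` array.
#' @export
cbam_spatial <- function(f, kernel = NULL, bias = 0, k = 7L) {
  if (k %% 2L != 1L) ps_stop("spatial-attention kernel size must be odd")
  if (is.null(kernel))
    kernel <- array(stats::rnorm(k * k * 2L, 0, sqrt(2 / (k * k * 2L))),
                    c(k, k, 2L, 1L))
  x <- as_hwnc(f)
  as_chw(cbam_fwd(x, conv_w_mat(kernel), bias, k = k)$y)
}

#' Attention map of the spatial branch
#'
#' Returns the `1 x H x W` sigmoid attention map itself (before it multiplies
#' the feature map), mainly useful for inspection and testing.
#' @inheritParams cbam_spatial
#' @return A `1 x H x W` array with entries in (0, 1).
#' @export
cbam_attention_map <- function(f, kernel = NULL, bias = 0, k = 7L) {
  if (is.null(kernel))
    kernel <- array(stats::rnorm(k * k * 2L, 0, sqrt(2 / (k * k * 2L))),
                    c(k, k, 2L, 1L))
  x <- as_hwnc(f)
  d <- dim(x)
  xm <- x
  dim(xm) <- c(prod(d[1:3]), d[4L])
  avg <- rowMeans(xm)
  mx <- xm[cbind(seq_len(nrow(xm)), max.col(xm, ties.method = "first"))]
  pooled <- array(c(avg, mx), c(d[1:3], 2L))
  ms <- sigmoid(conv2d_fwd(pooled, conv_w_mat(kernel), bias, k = k,
                           p = (k - 1L) %/% 2L)$y)
  as_chw(ms)
}

#' Create weights for a standalone residual convolution block
#'
#' @param in_channels,out_channels Channel counts of input and output.
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list with elements `params` (named weight list) and `bufs`
#'   (batch-norm running statistics), usable with [conv_block()].
#' @export
conv_block_params <- function(in_channels, out_channels, cfg = encoder_config(),
                              seed = 1L) {
  bufs <- new.env(parent = emptyenv())
  plist <- with_seed(seed,
    init_conv_block(list(), bufs, "blk", in_channels, out_channels, cfg))
  list(params = plist, bufs = bufs)
}

#' Apply a residual double-convolution block
#'
#' Two 3x3 convolution + batch-norm + LeakyReLU layers with a residual
#' shortcut (identity when channel counts match, a learned 1x1 projection
#' otherwise), followed by optional SE and spatial attention and dropout.
#' Spatial size is preserved.
#'
#' @param x Input feature map, `C x H x W`.
#' @param out_channels Number of output channels.
#' @param cfg An [encoder_config()].
#' @param weights Optional result of [conv_block_params()]; created from
#'   `seed` when `NULL`.
#' @param train Logical; training mode activates dropout and batch statistics.
#' @param seed Seed used when `weights` is `NULL`.
#' @return A `out_channels x H x W` array.
#' @export
conv_block <- function(x, out_channels, cfg = encoder_config(),
                       weights = NULL, train = FALSE, seed = 1L) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  cin <- dim(x)[1L]
  if (is.null(weights)) weights <- conv_block_params(cin, out_channels, cfg, seed)
  xb <- as_hwnc(x)
  out <- conv_block_fwd(weights$params, weights$bufs, "blk", xb, cfg, train)
  as_chw(out$y)
}

## ---- full encoder -------------------------------------------------------

encoder_channels <- function(base_width) as.integer(base_width * 2^(0:3))

init_encoder <- function(params, bufs, cfg, in_channels, base_width) {
  ch <- encoder_channels(base_width)
  cin <- in_channels
  for (l in 1:4) {
    params <- init_conv_block(params, bufs, paste0("enc", l), cin, ch[l], cfg)
    cin <- ch[l]
  }
  params
}

# Batch forward: Eq. order is Downsample THEN ConvBlock at every stage, so
# stage l lives at spatial extent (H/2^l, W/2^l).
encoder_fwd <- function(params, bufs, x, cfg, train) {
  E <- vector("list", 4L)
  caches <- vector("list", 4L)
  h <- x
  for (l in 1:4) {
    mp <- maxpool2_fwd(h)
    cb <- conv_block_fwd(params, bufs, paste0("enc", l), mp$y, cfg, train)
    h <- cb$y
    E[[l]] <- h
    caches[[l]] <- list(mp = mp$cache, cb = cb$cache)
  }
  list(E = E, caches = caches)
}

encoder_bwd <- function(dE, caches, params, cfg, genv) {
  # dE: list of gradients w.r.t. E1..E4 (NULL entries allowed)
  dh <- NULL
  for (l in 4:1) {
    dl <- dE[[l]]
    if (!is.null(dh)) dl <- if (is.null(dl)) dh else dl + dh
    dcb <- conv_block_bwd(dl, caches[[l]]$cb, params, paste0("enc", l), cfg, genv)
    dh <- maxpool2_bwd(dcb, caches[[l]]$mp)
  }
  dh
}

#' Encode an image into a four-stage feature pyramid
#'
#' Each stage applies 2x2 stride-2 max pooling followed by a residual
#' convolution block with SE and spatial attention, doubling the channel
#' count and halving the spatial extent, so stage `l` has
#' `base_width * 2^(l-1)` channels at `(H/2^l, W/2^l)` pixels. Stages 1-3
#' are retained as skip connections for the decoder.
#'
#' @param image A `C x H x W` array (or `H x W` matrix) with `H`, `W`
#'   divisible by 16; values are expected on the `[-1, 1]` scale.
#' @param cfg An [encoder_config()].
#' @param weights Optional result of [encoder_params()].
#' @param base_width Channels of the first stage (64 reproduces the printed
#'   architecture: 64/128/256/512).
#' @param train Logical training-mode flag.
#' @param seed Seed used when `weights` is `NULL`.
#' @return An object of class `promptseg_pyramid`: a list with elements
#'   `E1`..`E4`, each a `C x H' x W'` array.
#' @examples
#' pyr <- encode(matrix(rnorm(32 * 32), 32, 32), base_width = 8)
#' dim(pyr$E4)  # 64 x 2 x 2
#' @export
encode <- function(image, cfg = encoder_config(), weights = NULL,
                   base_width = 64L, train = FALSE, seed = 1L) {
  image <- validate_image(image)
  if (is.null(weights)) weights <- encoder_params(cfg, dim(image)[1L],
                                                  base_width, seed)
  x <- as_hwnc(image)
  out <- encoder_fwd(weights$params, weights$bufs, x, cfg, train)
  pyr <- lapply(out$E, as_chw)
  names(pyr) <- paste0("E", 1:4)
  structure(pyr, class = "promptseg_pyramid")
}

#' Create weights for a standalone encoder
#'
#' @inheritParams encode
#' @param in_channels Number of input image channels.
#' @return A list with `params` and `bufs` for use with [encode()].
#' @export
encoder_params <- function(cfg = encoder_config(), in_channels = 1L,
                           base_width = 64L, seed = 1L) {
  bufs <- new.env(parent = emptyenv())
  plist <- with_seed(seed,
    init_encoder(list(), bufs, cfg, in_channels, base_width))
  list(params = plist, bufs = bufs)
}
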