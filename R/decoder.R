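# Decoder: three transposed-convolution upsampling stages with skip
# concatenation and attention blocks, an optional prompt-conditioned batch
# normalization at the 2*base_width stage, a final (skip-free) upsampling
# back to full resolution, and a 1x1 sigmoid head.
#
# Channel bookkeeping at base width b (printed architecture: b = 64):
#   up1: 8b -> 8b, cat E3 (4b) -> 12b, block -> 4b    (768 -> 256 at b = 64)
#   up2: 4b -> 4b, cat E2 (2b) ->  6b, block -> 2b    (384 -> 128)
#   [CBN site: 2b channels]
#   up3: 2b -> 2b, cat E1 (b)  ->  3b, block ->  b    (192 ->  64)
#   up4:  b ->  b (restores H x W), 1x1 conv + sigmoid.

init_tconv <- function(params, prefix, cin, cout) {
  for (o in 1:4)
    params[[paste0(prefix, ".w", o)]] <-
      matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
  params[[paste0(prefix, ".b")]] <- numeric(cout)
  params
}

tconv_w <- function(params, prefix) {
  list(params[[paste0(prefix, ".w1")]], params[[paste0(prefix, ".w2")]],
       params[[paste0(prefix, ".w3")]], params[[paste0(prefix, ".w4")]])
}

init_decoder <- function(params, bufs, ecfg, fcfg, base_width, embed_dim) {
  b <- base_width
  widths_in <- c(8L, 4L, 2L) * b     # upsampled channel counts per stage
  widths_skip <- c(4L, 2L, 1L) * b
  widths_out <- c(4L, 2L, 1L) * b
  for (l in 1:3) {
    params <- init_tconv(params, paste0("dec", l, ".up"),
                         widths_in[l], widths_in[l])
    params <- init_conv_block(params, bufs, paste0("dec", l),
                              widths_in[l] + widths_skip[l], widths_out[l],
                              ecfg)
  }
  if (fcfg$use_cbn && "decoder" %in% fcfg$cbn_sites) {
    C <- 2L * b
    params[["dcbn.Wg"]] <- matrix(stats::rnorm(C * embed_dim, 0, 0.02), C, embed_dim)
    params[["dcbn.bg"]] <- rep(1, C)
    params[["dcbn.Wb"]] <- matrix(stats::rnorm(C * embed_dim, 0, 0.02), C, embed_dim)
    params[["dcbn.bb"]] <- numeric(C)
    bufs[["dcbn.running_mean"]] <- numeric(C)
    bufs[["dcbn.running_var"]] <- rep(1, C)
  }
  params <- init_tconv(params, "up4", b, b)
  params[["head.W"]] <- matrix(stats::rnorm(b, 0, sqrt(1 / b)), b, 1L)
  params[["head.b"]] <- 0
  params
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4L] + db[4L]))
}

decoder_fwd <- function(params, bufs, enorm, skips, vt, ecfg, fcfg, train) {
  caches <- list()
  h <- enorm
  use_dcbn <- fcfg$use_cbn && "decoder" %in% fcfg$cbn_sites && !is.null(vt)
  for (l in 1:3) {
    skip <- skips[[4L - l]]           # E3, E2, E1
    up <- tconv2_fwd(h, tconv_w(params, paste0("dec", l, ".up")),
                     params[[paste0("dec", l, ".up.b")]])
    if (!all(dim(up$y)[1:2] == dim(skip)[1:2]))
      ps_stop("decoder stage ", l, ": upsampled map ",
              paste(dim(up$y)[1:2], collapse = "x"),
              " does not match skip connection ",
              paste(dim(skip)[1:2], collapse = "x"),
              class = "promptseg_contract_error")
    cat_ <- concat_c(up$y, skip)
    blk <- conv_block_fwd(params, bufs, paste0("dec", l), cat_, ecfg, train)
    h <- blk$y
    caches[[paste0("up", l)]] <- up$cache
    caches[[paste0("blk", l)]] <- blk$cache
    caches[[paste0("split", l)]] <- dim(up$y)[4L]
    if (l == 2L && use_dcbn) {
      cb <- cbn_fwd(h, vt, params, "dcbn", bufs, train, fcfg$cbn_eps)
      h <- h + cb$y                   # residual link after CBN
      caches$dcbn <- cb$cache
    }
  }
  up4 <- tconv2_fwd(h, tconv_w(params, "up4"), params[["up4.b"]])
  d <- dim(up4$y)
  hm <- up4$y
  dim(hm) <- c(prod(d[1:3]), d[4L])
  logits <- drop(hm %*% params[["head.W"]]) + params[["head.b"]]
  prob <- array(sigmoid(logits), d[1:3])    # [H, W, N]
  caches$up4 <- up4$cache
  caches$head_x <- hm
  caches$prob <- prob
  caches$use_dcbn <- use_dcbn
  list(prob = prob, cache = caches)
}

decoder_bwd <- function(dprob, cache, params, ecfg, fcfg, genv) {
  prob <- cache$prob
  dlogit <- dprob * prob * (1 - prob)
  dl <- as.vector(dlogit)
  grad_acc(genv, "head.W", crossprod(cache$head_x, dl))
  grad_acc(genv, "head.b", sum(dl))
  dhm <- tcrossprod(matrix(dl, ncol = 1L), params[["head.W"]])
  d4 <- cache$up4$dims
  dup4 <- array(dhm, c(2L * d4[1L], 2L * d4[2L], d4[3L], d4[4L]))
  tb <- tconv2_bwd(dup4, cache$up4)
  for (o in 1:4) grad_acc(genv, paste0("up4.w", o), tb$dWs[[o]])
  grad_acc(genv, "up4.b", tb$db)
  dh <- tb$dx
  dskips <- vector("list", 3L)
  for (l in 3:1) {
    if (l == 2L && isTRUE(cache$use_dcbn)) {
      # h_out = h + cbn(h): gradient flows through both branches
      dcb <- cbn_bwd(dh, cache$dcbn, genv, "dcbn")
      dh <- dh + dcb
    }
    dcat <- conv_block_bwd(dh, cache[[paste0("blk", l)]], params,
                           paste0("dec", l), ecfg, genv)
    nup <- cache[[paste0("split", l)]]
    d <- dim(dcat)
    dup <- dcat[, , , seq_len(nup), drop = FALSE]
    dskips[[4L - l]] <- dcat[, , , (nup + 1L):d[4L], drop = FALSE]
    tb <- tconv2_bwd(dup, cache[[paste0("up", l)]])
    for (o in 1:4) grad_acc(genv, paste0("dec", l, ".up.w", o), tb$dWs[[o]])
    grad_acc(genv, paste0("dec", l, ".up.b"), tb$db)
    dh <- tb$dx
  }
  list(denorm = dh, dskips = dskips)
}

#' Create standalone decoder weights
#'
#' @param base_width First-stage encoder width `b`; the decoder consumes a
#'   `8b`-channel bottleneck and `4b/2b/b` skip connections.
#' @param cfg An [encoder_config()] (the decoder reuses the same residual
#'   blocks and attention).
#' @param fusion_cfg A [fusion_config()]; controls the decoder CBN site.
#' @param embed_dim Prompt-embedding dimension for the decoder CBN.
#' @param seed Integer seed.
#' @return A list with `params` and `bufs` for [decode()].
#' @export
decoder_params <- function(base_width = 64L, cfg = encoder_config(),
                           fusion_cfg = fusion_config(), embed_dim = 768L,
                           seed = 1L) {
  bufs <- new.env(parent = emptyenv())
  plist <- with_seed(seed,
    init_decoder(list(), bufs, cfg, fusion_cfg, base_width, embed_dim))
  list(params = plist, bufs = bufs)
}

#' Decode a fused bottleneck into a probability mask
#'
#' Three upsampling stages (2x2 stride-2 transposed convolution, skip
#' concatenation, residual attention block), an optional prompt-conditioned
#' batch normalization at the second stage, a final skip-free upsampling to
#' full resolution, and a 1x1 convolution with sigmoid.
#'
#' @param e_norm Fused bottleneck, `8b x H/16 x W/16`.
#' @param skips List of the encoder skip maps `E1`, `E2`, `E3` (or a
#'   `promptseg_pyramid`).
#' @param cfg An [encoder_config()].
#' @param weights Optional [decoder_params()] result.
#' @param v_t Optional prompt embedding; enables the decoder CBN site.
#' @param fusion_cfg A [fusion_config()].
#' @param train Logical training-mode flag.
#' @param seed Seed used when `weights` is `NULL`.
#' @return An `H x W` matrix of probabilities in `[0, 1]`.
#' @export
decode <- function(e_norm, skips, cfg = encoder_config(), weights = NULL,
                   v_t = NULL, fusion_cfg = fusion_config(), train = FALSE,
                   seed = 1L) {
  b <- dim(e_norm)[1L] %/% 8L
  if (is.null(weights))
    weights <- decoder_params(b, cfg, fusion_cfg,
                              embed_dim = if (is.null(v_t)) 768L else
                                length(if (inherits(v_t, "promptseg_embedding"))
                                  v_t$v else v_t),
                              seed = seed)
  v <- if (inherits(v_t, "promptseg_embedding")) matrix(v_t$v, 1L)
       else if (!is.null(v_t)) matrix(v_t, 1L) else NULL
  sk <- lapply(list(skips$E1, skips$E2, skips$E3), as_hwnc)
  out <- decoder_fwd(weights$params, weights$bufs, as_hwnc(e_norm), sk, v,
                     cfg, fusion_cfg, train)
  out$prob[, , 1L]
}

#' Threshold a probability mask
#'
#' Pixelwise indicator `m >= tau` (ties go to foreground).
#'
#' @param m Probability mask (values in `[0, 1]`), any array shape.
#' @param tau Threshold in the open interval (0, 1).
#' @return An integer 0/1 array of the same shape.
#' @examples
#' binarize(matrix(c(0.4, 0.6), 1), 0.5)
#' @export
binarize <- function(m, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    ps_stop("tau must lie strictly between 0 and 1",
            class = "promptseg_validation_error")
  out <- (m >= tau) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask >= 0.5), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path PNG file path.
#' @return An integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  binarize(img, 0.5)
}
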