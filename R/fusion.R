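#' Fusion configuration
#'
#' Toggles and constants for the cross-modal fusion pipeline that conditions
#' the visual bottleneck on the prompt embedding:
#' FiLM -> SE on the fused map -> conditional batch normalization (CBN) ->
#' residual with the raw bottleneck -> channel-wise L2 normalization.
#'
#' @param use_film,use_cbn,use_se_fused Ablation toggles; a disabled stage is
#'   the identity.
#' @param l2_eps Small constant added under the square root of the channel
#'   norm so all-zero channel vectors do not divide by zero.
#' @param cbn_sites Character subset of `c("bottleneck", "decoder")`: where
#'   CBN layers are inserted. The running text places CBN at the decoder's
#'   128-channel stage while the bottleneck equations apply it to the fused
#'   map; both are implemented and enabled by default.
#' @param cbn_eps Variance floor of the CBN normalization.
#' @return An object of class `promptseg_fusion_config`.
#' @export
fusion_config <- function(use_film = TRUE, use_cbn = TRUE,
                          use_se_fused = TRUE, l2_eps = 1e-8,
                          cbn_sites = c("bottleneck", "decoder"),
                          cbn_eps = 1e-5) {
  if (l2_eps <= 0) ps_stop("l2_eps must be positive")
  bad <- setdiff(cbn_sites, c("bottleneck", "decoder"))
  if (length(bad)) ps_stop("unknown cbn site(s): ", paste(bad, collapse = ", "))
  structure(list(use_film = isTRUE(use_film), use_cbn = isTRUE(use_cbn),
                 use_se_fused = isTRUE(use_se_fused), l2_eps = l2_eps,
                 cbn_sites = cbn_sites, cbn_eps = cbn_eps),
            class = "promptseg_fusion_config")
}

## ---- FiLM ---------------------------------------------------------------

film_fwd <- function(x, gamma, beta) {
  d <- dim(x)
  gb <- bcast_nc(1 + gamma, d[1L], d[2L])
  y <- gb * x + bcast_nc(beta, d[1L], d[2L])
  list(y = y, cache = list(x = x, gb = gb))
}

film_bwd <- function(dy, cache) {
  list(dx = dy * cache$gb,
       dgamma = reduce_hw(dy * cache$x),
       dbeta = reduce_hw(dy))
}

#' Feature-wise linear modulation of a bottleneck
#'
#' Applies `E_fused = (1 + gamma) * E4 + beta` with per-channel scale and
#' shift broadcast over space. `gamma` and `beta` are either supplied
#' directly or generated from the prompt embedding by two affine maps
#' `gamma = Wg v_t + bg`, `beta = Wb v_t + bb`.
#'
#' @param e4 Bottleneck feature map, `C x h x w` array.
#' @param v_t Prompt embedding ([embed_prompt()] result or numeric vector);
#'   required when `gamma`/`beta` are not given.
#' @param gamma,beta Optional explicit length-`C` vectors.
#' @param maps Optional list with `Wg` (`C x 768`), `bg`, `Wb`, `bb`.
#' @return A `C x h x w` array.
#' @examples
#' e4 <- array(1, c(2, 1, 1))
#' film(e4, gamma = c(1, -1), beta = c(0.5, 0))[, 1, 1]  # 2.5, 0
#' @export
film <- function(e4, v_t = NULL, gamma = NULL, beta = NULL, maps = NULL) {
  C <- dim(e4)[1L]
  if (is.null(gamma) || is.null(beta)) {
    v <- if (inherits(v_t, "promptseg_embedding")) v_t$v else v_t
    if (is.null(v)) ps_stop("either gamma/beta or v_t must be supplied")
    if (is.null(maps)) ps_stop("generating maps are required with v_t")
    if (ncol(maps$Wg) != length(v) || nrow(maps$Wg) != C)
      ps_stop("FiLM map dimensions do not match",
              class = "promptseg_contract_error")
    gamma <- drop(maps$Wg %*% v) + maps$bg
    beta <- drop(maps$Wb %*% v) + maps$bb
  }
  if (length(gamma) != C || length(beta) != C)
    ps_stop("gamma/beta length must equal the channel count ", C,
            class = "promptseg_contract_error")
  x <- as_hwnc(e4)
  as_chw(film_fwd(x, matrix(gamma, 1L), matrix(beta, 1L))$y)
}

## ---- conditional batch normalization -----------------------------------

# gamma_n, beta_n: [N, C] per-sample parameters generated from v_t.
cbn_core_fwd <- function(x, gamma_n, beta_n, mu, v, eps) {
  d <- dim(x)
  M <- prod(d[1:3]); C <- d[4L]
  xm <- x
  dim(xm) <- c(M, C)
  ivar <- 1 / sqrt(v + eps)
  xhat <- col_mul(col_add(xm, -mu), ivar)
  xhat_a <- array(xhat, d)
  y <- bcast_nc(gamma_n, d[1L], d[2L]) * xhat_a + bcast_nc(beta_n, d[1L], d[2L])
  list(y = y, cache = list(xhat = xhat_a, ivar = ivar, gamma_n = gamma_n,
                           dims = d))
}

cbn_core_bwd <- function(dy, cache, train) {
  d <- cache$dims
  M <- prod(d[1:3]); C <- d[4L]
  xhat <- cache$xhat
  dgamma_n <- reduce_hw(dy * xhat)
  dbeta_n <- reduce_hw(dy)
  dxhat <- dy * bcast_nc(cache$gamma_n, d[1L], d[2L])
  dxm <- dxhat
  dim(dxm) <- c(M, C)
  if (train) {
    xhm <- xhat
    dim(xhm) <- c(M, C)
    dxm <- col_add(dxm, -colMeans(dxm)) -
      col_mul(xhm, colMeans(dxm * xhm))
  }
  dxm <- col_mul(dxm, cache$ivar)
  list(dx = array(dxm, d), dgamma_n = dgamma_n, dbeta_n = dbeta_n)
}

cbn_fwd <- function(x, vt, params, prefix, bufs, train, eps) {
  p <- function(s) params[[paste0(prefix, s)]]
  gamma_n <- col_add(tcrossprod(vt, p(".Wg")), p(".bg"))
  beta_n <- col_add(tcrossprod(vt, p(".Wb")), p(".bb"))
  d <- dim(x)
  M <- prod(d[1:3])
  xm <- x
  dim(xm) <- c(M, d[4L])
  rm_key <- paste0(prefix, ".running_mean")
  rv_key <- paste0(prefix, ".running_var")
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(col_add(xm, -mu)^2)
    bufs[[rm_key]] <- 0.9 * bufs[[rm_key]] + 0.1 * mu
    bufs[[rv_key]] <- 0.9 * bufs[[rv_key]] + 0.1 * v
  } else {
    mu <- bufs[[rm_key]]
    v <- bufs[[rv_key]]
  }
  out <- cbn_core_fwd(x, gamma_n, beta_n, mu, v, eps)
  out$cache$vt <- vt
  out$cache$train <- train
  out
}

cbn_bwd <- function(dy, cache, genv, prefix) {
  core <- cbn_core_bwd(dy, cache, cache$train)
  grad_acc(genv, paste0(prefix, ".Wg"), crossprod(core$dgamma_n, cache$vt))
  grad_acc(genv, paste0(prefix, ".bg"), colSums(core$dgamma_n))
  grad_acc(genv, paste0(prefix, ".Wb"), crossprod(core$dbeta_n, cache$vt))
  grad_acc(genv, paste0(prefix, ".bb"), colSums(core$dbeta_n))
  core$dx
}

#' Conditional batch normalization
#'
#' Normalizes a feature map per channel with batch (or supplied) statistics
#' and rescales it with `gamma`/`beta` parameters generated from the prompt
#' embedding rather than learned as constants:
#' `y = gamma * (F - mu) / sqrt(var + eps) + beta`.
#'
#' @param f Feature map, `C x H x W`.
#' @param gamma,beta Length-`C` conditioning parameters.
#' @param mu,var Optional per-channel statistics; computed from `f` when
#'   `NULL` (single-sample "batch" statistics).
#' @param eps Variance floor.
#' @return A `C x H x W` array.
#' @export
cbn <- function(f, gamma, beta, mu = NULL, var = NULL, eps = 1e-5) {
  x <- as_hwnc(f)
  d <- dim(x)
  xm <- x
  dim(xm) <- c(prod(d[1:3]), d[4L])
  if (is.null(mu)) mu <- colMeans(xm)
  if (is.null(var)) var <- colMeans(col_add(xm, -mu)^2)
  as_chw(cbn_core_fwd(x, matrix(gamma, 1L), matrix(beta, 1L), mu, var, eps)$y)
}

## ---- channel-wise L2 normalization --------------------------------------

l2norm_fwd <- function(x, eps) {
  q <- reduce_c(x * x)
  s <- sqrt(q + eps)
  d <- dim(x)
  sb <- bcast_hwn(s, d[4L])
  y <- x / sb
  list(y = y, cache = list(x = x, s = s, sb = sb))
}

l2norm_bwd <- function(dy, cache) {
  d <- dim(cache$x)
  dot <- reduce_c(dy * cache$x)
  dy / cache$sb - cache$x * bcast_hwn(dot / cache$s^3, d[4L])
}

## ---- full fusion pipeline -----------------------------------------------

init_fusion <- function(params, bufs, channels, embed_dim, cfg) {
  sm <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  if (cfg$use_film) {
    params[["fus.film.Wg"]] <- sm(channels, embed_dim)
    params[["fus.film.bg"]] <- numeric(channels)
    params[["fus.film.Wb"]] <- sm(channels, embed_dim)
    params[["fus.film.bb"]] <- numeric(channels)
  }
  if (cfg$use_se_fused) {
    r <- 16L
    if (channels %% r != 0L) r <- max(1L, channels %/% 4L)
    params[["fus.se.W1"]] <- matrix(stats::rnorm(channels %/% r * channels, 0,
                                                 sqrt(2 / channels)),
                                    channels %/% r, channels)
    params[["fus.se.W2"]] <- matrix(stats::rnorm(channels * channels %/% r, 0,
                                                 sqrt(2 / (channels %/% r))),
                                    channels, channels %/% r)
  }
  if (cfg$use_cbn && "bottleneck" %in% cfg$cbn_sites) {
    params[["fus.cbn.Wg"]] <- sm(channels, embed_dim)
    params[["fus.cbn.bg"]] <- rep(1, channels)
    params[["fus.cbn.Wb"]] <- sm(channels, embed_dim)
    params[["fus.cbn.bb"]] <- numeric(channels)
    bufs[["fus.cbn.running_mean"]] <- numeric(channels)
    bufs[["fus.cbn.running_var"]] <- rep(1, channels)
  }
  params
}

fusion_fwd <- function(params, bufs, e4, vt, cfg, train) {
  caches <- list()
  h <- e4
  if (cfg$use_film) {
    gamma <- col_add(tcrossprod(vt, params[["fus.film.Wg"]]),
                     params[["fus.film.bg"]])
    beta <- col_add(tcrossprod(vt, params[["fus.film.Wb"]]),
                    params[["fus.film.bb"]])
    fl <- film_fwd(h, gamma, beta)
    h <- fl$y
    caches$film <- fl$cache
    caches$vt <- vt
  }
  if (cfg$use_se_fused) {
    se <- se_fwd(h, params[["fus.se.W1"]], params[["fus.se.W2"]])
    h <- se$y
    caches$se <- se$cache
  }
  if (cfg$use_cbn && "bottleneck" %in% cfg$cbn_sites) {
    cb <- cbn_fwd(h, vt, params, "fus.cbn", bufs, train, cfg$cbn_eps)
    h <- cb$y
    caches$cbn <- cb$cache
  }
  efinal <- e4 + h
  nm <- l2norm_fwd(efinal, cfg$l2_eps)
  caches$l2 <- nm$cache
  list(y = nm$y, cache = caches)
}

fusion_bwd <- function(dy, cache, params, cfg, genv) {
  dfinal <- l2norm_bwd(dy, cache$l2)
  de4 <- dfinal          # residual branch
  dh <- dfinal
  if (cfg$use_cbn && "bottleneck" %in% cfg$cbn_sites)
    dh <- cbn_bwd(dh, cache$cbn, genv, "fus.cbn")
  if (cfg$use_se_fused) {
    se <- se_bwd(dh, cache$se, genv, "fus.se")
    dh <- se$dx
  }
  if (cfg$use_film) {
    fl <- film_bwd(dh, cache$film)
    grad_acc(genv, "fus.film.Wg", crossprod(fl$dgamma, cache$vt))
    grad_acc(genv, "fus.film.bg", colSums(fl$dgamma))
    grad_acc(genv, "fus.film.Wb", crossprod(fl$dbeta, cache$vt))
    grad_acc(genv, "fus.film.bb", colSums(fl$dbeta))
    dh <- fl$dx
  }
  de4 + dh
}

#' Create standalone fusion weights
#'
#' @param channels Bottleneck channel count (512 at the printed full scale).
#' @param embed_dim Prompt-embedding dimension.
#' @param cfg A [fusion_config()].
#' @param seed Integer seed.
#' @return A list with `params` and `bufs` for [fuse()].
#' @export
fusion_params <- function(channels = 512L, embed_dim = 768L,
                          cfg = fusion_config(), seed = 1L) {
  bufs <- new.env(parent = emptyenv())
  plist <- with_seed(seed, init_fusion(list(), bufs, channels, embed_dim, cfg))
  list(params = plist, bufs = bufs)
}

#' Fuse the visual bottleneck with a prompt embedding
#'
#' Runs the full conditioning pipeline
#' FiLM -> SE on the fused map -> CBN -> residual with the raw bottleneck ->
#' channel-wise L2 normalization, honoring the ablation toggles in `cfg`
#' (a disabled stage is the identity). After normalization every spatial
#' location's channel vector has unit L2 norm (up to `l2_eps`).
#'
#' @param e4 Bottleneck feature map, `C x h x w`.
#' @param v_t Prompt embedding (a `promptseg_embedding` or numeric vector).
#' @param cfg A [fusion_config()].
#' @param weights Optional [fusion_params()] result.
#' @param stats `"batch"` (default; CBN statistics computed from the given
#'   map, appropriate for a standalone call) or `"running"` (use stored
#'   running statistics, as in eval-mode inference).
#' @param seed Seed used when `weights` is `NULL`.
#' @return A `C x h x w` array with unit channel norms.
#' @export
fuse <- function(e4, v_t, cfg = fusion_config(), weights = NULL,
                 stats = c("batch", "running"), seed = 1L) {
  stats <- match.arg(stats)
  v <- if (inherits(v_t, "promptseg_embedding")) v_t$v else v_t
  C <- dim(e4)[1L]
  if (is.null(weights)) weights <- fusion_params(C, length(v), cfg, seed)
  x <- as_hwnc(e4)
  out <- fusion_fwd(weights$params, weights$bufs, x, matrix(v, 1L), cfg,
                    train = identical(stats, "batch"))
  as_chw(out$y)
}
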