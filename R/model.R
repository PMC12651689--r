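#' Assemble a prompt-conditioned segmentation model
#'
#' Builds the full network: four-stage attention U-Net encoder, FiLM/CBN
#' cross-modal fusion of the bottleneck with a frozen prompt embedding, and
#' an attention-guided transposed-convolution decoder with a sigmoid head.
#' All weights are initialized from `seed`; the text embedder is frozen by
#' construction and owns no trainable parameters.
#'
#' @param base_width First-stage channel count; 64 gives the printed
#'   64/128/256/512 architecture, 16 the quarter-width desk-scale variant.
#' @param in_channels Number of input image channels.
#' @param encoder_cfg An [encoder_config()].
#' @param fusion_cfg A [fusion_config()].
#' @param embedder Token embedder (frozen); default [hash_embedder()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `promptseg_model`.
#' @examples
#' m <- promptseg_model(base_width = 8)
#' pr <- model_predict(m, matrix(0, 32, 32), "Segment the Liver region")
#' range(pr)
#' @export
promptseg_model <- function(base_width = 64L, in_channels = 1L,
                            encoder_cfg = encoder_config(),
                            fusion_cfg = fusion_config(),
                            embedder = hash_embedder(), seed = 1L) {
  base_width <- as.integer(base_width)
  embed_dim <- attr(embedder, "embed_dim") %||% 768L
  bufs <- new.env(parent = emptyenv())
  plist <- with_seed(seed, {
    p <- init_encoder(list(), bufs, encoder_cfg, in_channels, base_width)
    p <- init_fusion(p, bufs, 8L * base_width, embed_dim, fusion_cfg)
    init_decoder(p, bufs, encoder_cfg, fusion_cfg, base_width, embed_dim)
  })
  params <- new.env(parent = emptyenv())
  for (nm in names(plist)) params[[nm]] <- plist[[nm]]
  structure(list(params = params, bufs = bufs,
                 encoder_cfg = encoder_cfg, fusion_cfg = fusion_cfg,
                 base_width = base_width, in_channels = as.integer(in_channels),
                 embed_dim = embed_dim, embedder = embedder,
                 vt_cache = new.env(parent = emptyenv()),
                 seed = as.integer(seed)),
            class = "promptseg_model")
}

#' @export
print.promptseg_model <- function(x, ...) {
  np <- sum(vapply(ls(x$params), function(n) length(x$params[[n]]), 1))
  cat("promptseg model: base width", x$base_width, "| input channels",
      x$in_channels, "|", format(np, big.mark = ","), "trainable parameters\n")
  cat("  fusion:", if (x$fusion_cfg$use_film) "FiLM" else "-",
      if (x$fusion_cfg$use_cbn) paste0("CBN(",
        paste(x$fusion_cfg$cbn_sites, collapse = "+"), ")") else "-",
      if (x$fusion_cfg$use_se_fused) "SE" else "-", "\n")
  invisible(x)
}

# Embed a prompt through the model's frozen embedder, with caching.
model_embed <- function(model, prompt) {
  v <- model$vt_cache[[prompt]]
  if (is.null(v)) {
    v <- embed_prompt(prompt, model$embedder)$v
    model$vt_cache[[prompt]] <- v
  }
  v
}

# Batch forward pass. x: [H, W, N, C]; vt: [N, embed_dim].
model_fwd <- function(model, x, vt, train = FALSE) {
  enc <- encoder_fwd(model$params, model$bufs, x, model$encoder_cfg, train)
  fus <- fusion_fwd(model$params, model$bufs, enc$E[[4L]], vt,
                    model$fusion_cfg, train)
  dec <- decoder_fwd(model$params, model$bufs, fus$y, enc$E[1:3], vt,
                     model$encoder_cfg, model$fusion_cfg, train)
  list(prob = dec$prob,
       cache = list(enc = enc$caches, fus = fus$cache, dec = dec$cache))
}

# Backprop dL/dprob through the whole network, accumulating parameter
# gradients into the environment `genv`.
model_bwd <- function(model, cache, dprob, genv) {
  db <- decoder_bwd(dprob, cache$dec, model$params, model$encoder_cfg,
                    model$fusion_cfg, genv)
  de4 <- fusion_bwd(db$denorm, cache$fus, model$params, model$fusion_cfg, genv)
  dE <- list(db$dskips[[1L]], db$dskips[[2L]], db$dskips[[3L]], de4)
  encoder_bwd(dE, cache$enc, model$params, model$encoder_cfg, genv)
}

#' Predict a probability mask for one image and prompt
#'
#' Runs the model in eval mode (running batch statistics, no dropout).
#'
#' @param model A [promptseg_model()].
#' @param image `H x W` matrix or `C x H x W` array on the `[-1, 1]` scale.
#' @param prompt Prompt string, or a precomputed embedding
#'   (`promptseg_embedding` or numeric vector).
#' @return An `H x W` probability matrix.
#' @export
model_predict <- function(model, image, prompt) {
  image <- validate_image(image)
  v <- if (is.character(prompt)) model_embed(model, prompt)
       else if (inherits(prompt, "promptseg_embedding")) prompt$v
       else prompt
  out <- model_fwd(model, as_hwnc(image), matrix(v, 1L), train = FALSE)
  out$prob[, , 1L]
}

# Snapshot / restore trainable parameters (used by determinism checks and
# checkpointing). Sorted names give a canonical order.
model_param_vector <- function(model) {
  nms <- sort(ls(model$params))
  unlist(lapply(nms, function(n) as.vector(model$params[[n]])), use.names = FALSE)
}

#' Fingerprint of the model's trainable parameters
#' @param model A [promptseg_model()].
#' @return Character md5 hash of the canonical parameter vector.
#' @export
model_param_hash <- function(model) content_hash(model_param_vector(model))

# Serialize a model to a plain list (for checkpoints).
model_state <- function(model) {
  list(params = mget(ls(model$params), envir = model$params),
       bufs = mget(ls(model$bufs), envir = model$bufs),
       base_width = model$base_width, in_channels = model$in_channels,
       embed_dim = model$embed_dim,
       encoder_cfg = unclass(model$encoder_cfg),
       fusion_cfg = unclass(model$fusion_cfg))
}

model_load_state <- function(state, embedder = hash_embedder()) {
  model <- promptseg_model(base_width = state$base_width,
                           in_channels = state$in_channels,
                           encoder_cfg = do.call(encoder_config, state$encoder_cfg),
                           fusion_cfg = do.call(fusion_config, state$fusion_cfg),
                           embedder = embedder, seed = 0L)
  for (nm in names(state$params)) model$params[[nm]] <- state$params[[nm]]
  for (nm in names(state$bufs)) model$bufs[[nm]] <- state$bufs[[nm]]
  model
}
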