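#' Training configuration
#'
#' The training protocol: AdamW (decoupled weight decay) with a cosine
#' annealing learning-rate schedule, dropout active, frozen text embedder.
#'
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param epochs Number of epochs (the reference protocol uses 500; the
#'   desk-scale experiments far fewer).
#' @param batch_size Mini-batch size.
#' @param loss A [loss_config()].
#' @param seed Integer seed controlling shuffling, dropout and dynamic
#'   prompt assignment.
#' @param prompt_mode `"dynamic"` re-draws each sample's prompt wording from
#'   the synonym table every epoch (the target class never changes), which
#'   mirrors dynamic prompt assignment during training; `"static"` keeps the
#'   prompts attached to the samples.
#' @param table Synonym table used by dynamic prompt mode.
#' @param tau Binarization threshold used by evaluation.
#' @param grad_clip Global gradient-norm clip (`Inf` disables).
#' @return An object of class `promptseg_train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, epochs = 500L,
                         batch_size = 8L, loss = loss_config(), seed = 0L,
                         prompt_mode = c("dynamic", "static"),
                         table = organ_synonym_table(), tau = 0.5,
                         grad_clip = 5) {
  prompt_mode <- match.arg(prompt_mode)
  if (epochs < 1L) ps_stop("epochs must be at least 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), prompt_mode = prompt_mode,
                 table = table, tau = tau, grad_clip = grad_clip),
            class = "promptseg_train_config")
}

#' Cosine annealing learning-rate schedule
#'
#' `lr(t) = lr0 * (1 + cos(pi * t / total)) / 2`, decaying from `lr0` at
#' `t = 0` to exactly 0 at `t = total`.
#'
#' @param t Step (0-based epoch index).
#' @param total Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return The learning rate at step `t`.
#' @export
cosine_lr <- function(t, total, lr0) lr0 * (1 + cos(pi * t / total)) / 2

#' Preprocess a sample to the network's input contract
#'
#' Resizes the image bilinearly to `size x size` and linearly rescales its
#' intensities to `[-1, 1]`; masks are resized with nearest-neighbour
#' interpolation and stay strictly binary.
#'
#' @param sample A `promptseg_sample`.
#' @param size Target side length (divisible by 16).
#' @return The preprocessed sample.
#' @export
preprocess <- function(sample, size = 128L) {
  img <- sample$image
  if (nrow(img) != size || ncol(img) != size)
    img <- as.matrix(EBImage::resize(EBImage::Image(img), w = size, h = size))
  rng <- range(img)
  img <- if (rng[2L] > rng[1L]) 2 * (img - rng[1L]) / (rng[2L] - rng[1L]) - 1
         else img * 0
  sample$image <- img
  sample$masks <- lapply(sample$masks, function(m) {
    if (nrow(m) != size || ncol(m) != size)
      m <- as.matrix(EBImage::resize(EBImage::Image(m), w = size, h = size,
                                     filter = "none"))
    binarize(m, 0.5)
  })
  sample
}

#' Split samples into training and validation sets
#'
#' Seeded shuffle then partition, stratified by target class when targets
#' are present so class proportions carry over.
#'
#' @param samples List of `promptseg_sample`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `val`.
#' @export
split_samples <- function(samples, fraction = 0.8, seed = 0L) {
  n <- length(samples)
  if (n < 2L) ps_stop("need at least 2 samples to split")
  if (fraction <= 0 || fraction >= 1) ps_stop("fraction must be in (0, 1)")
  strata <- vapply(samples, function(s) s$target %||% (s$labels[1L] %||% "none"), "")
  idx_tr <- with_seed(seed, {
    out <- integer(0)
    for (g in unique(strata)) {
      ig <- which(strata == g)
      k <- round(length(ig) * fraction)
      out <- c(out, sample(ig, k))
    }
    # guarantee both partitions are non-empty even with tiny strata
    if (length(out) == n) out <- out[-sample.int(length(out), 1L)]
    if (!length(out)) out <- sample.int(n, 1L)
    sort(out)
  })
  if (!length(idx_tr) || length(idx_tr) == n)
    ps_stop("split fraction ", fraction, " yields an empty partition")
  list(train = samples[idx_tr], val = samples[-idx_tr])
}

## ---- AdamW ---------------------------------------------------------------

adamw_step <- function(params, genv, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       grad_clip = Inf) {
  nms <- sort(ls(genv))
  if (is.finite(grad_clip)) {
    gn <- sqrt(sum(vapply(nms, function(n) sum(genv[[n]]^2), 1)))
    if (gn > grad_clip) for (n in nms) genv[[n]] <- genv[[n]] * (grad_clip / gn)
  }
  state$t <- (state$t %||% 0) + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (n in nms) {
    g <- genv[[n]]
    m <- state[[paste0("m.", n)]] %||% (g * 0)
    v <- state[[paste0("v.", n)]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[paste0("m.", n)]] <- m
    state[[paste0("v.", n)]] <- v
    params[[n]] <- params[[n]] -
      lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * params[[n]])
  }
  invisible(NULL)
}

## ---- training loop -------------------------------------------------------

#' Train a model
#'
#' End-to-end gradient training of every network parameter (the text
#' embedder is frozen by construction) with AdamW, cosine-annealed learning
#' rate, dropout active and per-epoch reshuffling. Fully deterministic under
#' a fixed `cfg$seed`.
#'
#' @param model A [promptseg_model()].
#' @param samples Preprocessed training samples with targets attached
#'   ([attach_prompts()]).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The model (parameters updated in place), invisibly augmented with
#'   a `history` attribute: data frame of epoch, lr and mean training loss.
#' @export
train_model <- function(model, samples, cfg = train_config(), verbose = FALSE) {
  if (!length(samples)) ps_stop("no training samples")
  n <- length(samples)
  state <- new.env(parent = emptyenv())
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg$epochs, cfg$lr)
    ord <- sample.int(n)
    prompts <- vapply(samples, function(s) {
      if (cfg$prompt_mode == "dynamic" && !is.null(s$target))
        draw_prompt(s$target, cfg$table)
      else s$prompt %||% ""
    }, "")
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      B <- length(idx)
      x <- stack_hwnc(lapply(idx, function(i) samples[[i]]$image))
      vt <- do.call(rbind, lapply(idx, function(i)
        model_embed(model, prompts[i])))
      out <- model_fwd(model, x, vt, train = TRUE)
      dprob <- array(0, dim(out$prob))
      bl <- 0
      for (b in seq_len(B)) {
        m <- target_mask(samples[[idx[b]]])
        r <- loss_eval(out$prob[, , b], m, cfg$loss)
        bl <- bl + r$value / B
        dprob[, , b] <- r$grad / B
      }
      if (!is.finite(bl))
        ps_stop("non-finite loss at epoch ", epoch, ", batch starting at ",
                start, class = "promptseg_training_error")
      genv <- new.env(parent = emptyenv())
      model_bwd(model, out$cache, dprob, genv)
      adamw_step(model$params, genv, state, lr, cfg$weight_decay,
                 grad_clip = cfg$grad_clip)
      losses <- c(losses, bl)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(losses)))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr, mean(losses)))
  }
  attr(model, "history") <- history
  invisible(model)
}

#' Evaluate a model on a sample set
#'
#' Eval-mode forward pass per sample with its prompt, metrics per sample,
#' unweighted mean over the set.
#'
#' @param model A trained [promptseg_model()].
#' @param samples Samples with prompts and targets.
#' @param tau Binarization threshold.
#' @return List with `mean` (a `promptseg_metrics`) and `per_sample`.
#' @export
evaluate_model <- function(model, samples, tau = 0.5) {
  reports <- lapply(samples, function(s) {
    prob <- model_predict(model, s$image, s$prompt)
    compute_metrics(prob, target_mask(s), tau)
  })
  list(mean = aggregate_reports(reports), per_sample = reports)
}
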