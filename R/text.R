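#' Synonym table for prompt construction
#'
#' Maps each class label to a list of synonym phrases and holds the prompt
#' templates (each with a single `{}` placeholder). Prompts are built by
#' substituting a randomly chosen synonym into a randomly chosen template,
#' which injects lexical variability into training.
#'
#' @param synonyms Named list: class label -> character vector of synonyms.
#' @param templates Character vector of templates containing one `{}`.
#' @return An object of class `promptseg_synonym_table`.
#' @examples
#' tab <- synonym_table(list(glioma = c("Glioma", "Brain tumor")))
#' build_prompt("glioma", tab, seed = 1)
#' @export
synonym_table <- function(synonyms,
                          templates = default_prompt_templates()) {
  if (!length(synonyms) || is.null(names(synonyms)))
    ps_stop("synonyms must be a non-empty named list")
  if (any(!vapply(synonyms, length, 1L)))
    ps_stop("every class needs at least one synonym")
  if (!length(templates) || any(!nzchar(templates)))
    ps_stop("templates must be non-empty strings")
  if (any(!grepl("{}", templates, fixed = TRUE)))
    ps_stop("every template needs one {} placeholder")
  structure(list(synonyms = lapply(synonyms, as.character),
                 templates = as.character(templates)),
            class = "promptseg_synonym_table")
}

#' Default prompt templates
#' @return Character vector of instruction templates.
#' @export
default_prompt_templates <- function() {
  c("Segment the {} region",
    "Identify the {}",
    "Your goal is to Spot the {}",
    "Isolate the {}",
    "Find the {} margins")
}

#' Bundled synonym table for the brain-lesion classes
#' @return A [synonym_table()] covering glioma, meningioma and pituitary
#'   tumor with their clinical synonyms.
#' @export
brain_synonym_table <- function() {
  synonym_table(list(
    glioma = c("Glioma", "Brain tumor", "Tumor", "Neoplasm",
               "Cerebral tumor", "Intracranial tumor"),
    meningioma = c("Meningioma", "Meningeal tumor", "Meningeal neoplasm",
                   "Cerebral meningioma"),
    pituitary = c("Pituitary tumor", "Pituitary adenoma",
                  "Pituitary neoplasm", "Pituitary gland tumor")))
}

#' Bundled synonym table for the abdominal-organ classes
#' @return A [synonym_table()] covering liver, spleen and both kidneys.
#' @export
organ_synonym_table <- function() {
  synonym_table(list(
    liver = c("Liver", "Hepatic organ"),
    spleen = c("Spleen", "Splenic organ"),
    right_kidney = c("Right kidney", "Right renal organ"),
    left_kidney = c("Left kidney", "Left renal organ")))
}

#' Read a synonym table from a YAML config file
#'
#' The file must contain a `classes` mapping (label -> list of synonyms) and
#' optionally a `templates` list.
#' @param path Path to the YAML file.
#' @return A [synonym_table()].
#' @examples
#' f <- system.file("extdata", "example_synonyms.yaml", package = "promptseg")
#' read_synonym_table(f)
#' @export
read_synonym_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$classes)) ps_stop("config has no `classes` mapping")
  templates <- if (is.null(cfg$templates)) default_prompt_templates()
               else unlist(cfg$templates)
  synonym_table(lapply(cfg$classes, unlist), templates)
}

#' Build a natural-language prompt for a class label
#'
#' Substitutes a uniformly chosen synonym of `label` into a uniformly chosen
#' template, e.g. `"Segment the Glioma region"`.
#'
#' @param label Class label present in `table`.
#' @param table A [synonym_table()].
#' @param rng A function `(n) -> n` uniform variates in (0, 1), or `NULL` to
#'   derive one from `seed`.
#' @param seed Integer seed used when `rng` is `NULL`.
#' @return A single prompt string; reproducible for identical seeds.
#' @export
build_prompt <- function(label, table, rng = NULL, seed = 1L) {
  if (!label %in% names(table$synonyms))
    ps_stop("unknown class label: ", label, class = "promptseg_lookup_error")
  if (is.null(rng)) {
    u <- with_seed(seed, stats::runif(2L))
  } else u <- rng(2L)
  syns <- table$synonyms[[label]]
  tmpl <- table$templates[[1L + floor(u[1L] * length(table$templates))]]
  syn <- syns[[1L + floor(u[2L] * length(syns))]]
  sub("{}", syn, tmpl, fixed = TRUE)
}

# Internal variant drawing from the current RNG stream (used by the
# generators and the training loop, which manage seeding themselves).
draw_prompt <- function(label, table) {
  tmpl <- table$templates[[sample.int(length(table$templates), 1L)]]
  syn <- table$synonyms[[label]][[sample.int(length(table$synonyms[[label]]), 1L)]]
  sub("{}", syn, tmpl, fixed = TRUE)
}

#' Tokenize a prompt
#'
#' Lowercases the prompt, splits it on non-alphanumeric characters, wraps it
#' in `[CLS]`/`[SEP]` markers and truncates or pads the result to the
#' 16-position cap. Token ids are stable 31-bit hashes of the token strings,
#' so tokenization is deterministic and vocabulary-free.
#'
#' @param prompt Non-empty prompt string.
#' @param max_len Sequence cap including the two markers.
#' @return An object of class `promptseg_tokens`: list with `ids` (integer
#'   vector of length `max_len`), `tokens` (character), and `mask` (logical;
#'   `FALSE` marks padding).
#' @examples
#' tok <- tokenize("Segment the Glioma region")
#' sum(tok$mask)  # 6 non-padding positions
#' @export
tokenize <- function(prompt, max_len = 16L) {
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(trimws(prompt)))
    ps_stop("prompt must be a non-empty string",
            class = "promptseg_validation_error")
  words <- strsplit(tolower(trimws(prompt)), "[^a-z0-9]+")[[1L]]
  words <- words[nzchar(words)]
  body_cap <- max_len - 2L
  if (length(words) > body_cap) words <- words[seq_len(body_cap)]
  toks <- c("[cls]", words, "[sep]")
  n <- length(toks)
  pad <- max_len - n
  structure(list(
    ids = c(vapply(toks, fnv1a32, 1L, USE.NAMES = FALSE), rep(0L, pad)),
    tokens = c(toks, rep("[pad]", pad)),
    mask = c(rep(TRUE, n), rep(FALSE, pad))),
    class = "promptseg_tokens")
}

#' Deterministic fallback text embedder
#'
#' Maps each token string to a fixed 768-dimensional vector drawn from an RNG
#' seeded by the token's hash. The embedder is frozen by construction: the
#' same token always yields the same vector, in any session, with no model
#' download. It carries no linguistic structure beyond token identity; the
#' downstream fusion only requires a fixed, distinct vector per prompt.
#'
#' @param dim Embedding dimension.
#' @return A function `(tokens: character) -> matrix [length(tokens), dim]`
#'   with attributes `embedder_id` and `dim`.
#' @export
hash_embedder <- function(dim = 768L) {
  f <- function(tokens) {
    out <- matrix(0, length(tokens), dim)
    for (i in seq_along(tokens)) {
      out[i, ] <- with_seed(fnv1a32(paste0("emb:", tokens[i])),
                            stats::rnorm(dim))
    }
    out
  }
  attr(f, "embedder_id") <- sprintf("hash-%d", dim)
  attr(f, "embed_dim") <- dim
  f
}

#' Embed a token sequence into a prompt vector
#'
#' Mean-pools the embedder's per-token vectors over all non-padding
#' positions (markers included) into a single semantic vector `v_t`.
#'
#' @param tokens A [tokenize()] result.
#' @param embedder A per-token embedder such as [hash_embedder()]; any
#'   function mapping a character vector of tokens to a numeric matrix with
#'   one row per token works, so a pretrained contextual encoder can be
#'   plugged in.
#' @return An object of class `promptseg_embedding`: list with `v` (numeric
#'   length-768 vector by default), `prompt_text`, `embedder_id`.
#' @export
embed_tokens <- function(tokens, embedder = hash_embedder()) {
  if (!inherits(tokens, "promptseg_tokens")) ps_stop("tokens must come from tokenize()")
  live <- tokens$tokens[tokens$mask]
  H <- embedder(live)
  want <- attr(embedder, "embed_dim")
  if (!is.matrix(H) || nrow(H) != length(live) ||
      (!is.null(want) && ncol(H) != want))
    ps_stop("embedder returned wrong dimensions",
            class = "promptseg_contract_error")
  check_finite(H, "token embeddings")
  structure(list(v = colMeans(H),
                 prompt_text = paste(live, collapse = " "),
                 embedder_id = attr(embedder, "embedder_id") %||% "custom"),
            class = "promptseg_embedding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed a prompt string end to end
#'
#' Convenience wrapper: [tokenize()] then [embed_tokens()].
#' @param prompt Prompt string.
#' @param embedder Token embedder.
#' @return A `promptseg_embedding`.
#' @export
embed_prompt <- function(prompt, embedder = hash_embedder()) {
  embed_tokens(tokenize(prompt), embedder)
}
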