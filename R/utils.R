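#' @keywords internal
"_PACKAGE"

# Internal tensor layout: 4-D array [H, W, N, C] (spatial fastest, channel
# slowest) so that `dim(x) <- c(H*W*N, C)` exposes a per-channel matrix view
# and spatial slices are contiguous. Public single-sample containers follow
# the C x H x W convention instead; see as_hwnc()/as_chw().

ps_stop <- function(..., class = "promptseg_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) ps_stop(what, " contains non-finite values")
  invisible(x)
}

# Convert a single C x H x W array (or H x W matrix) to internal [H,W,1,C].
as_hwnc <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  array(aperm(x, c(2L, 3L, 1L)), c(d[2L], d[3L], 1L, d[1L]))
}

# Convert internal [H,W,N,C] back to C x H x W for sample n.
as_chw <- function(x, n = 1L) {
  d <- dim(x)
  aperm(array(x[, , n, , drop = FALSE], c(d[1L], d[2L], d[4L])), c(3L, 1L, 2L))
}

# Stack a list of C x H x W arrays (or H x W matrices) into [H,W,N,C].
stack_hwnc <- function(xs) {
  xs <- lapply(xs, function(x) if (is.matrix(x)) array(x, c(1L, dim(x))) else x)
  d <- dim(xs[[1L]])
  out <- array(0, c(d[2L], d[3L], length(xs), d[1L]))
  for (n in seq_along(xs)) out[, , n, ] <- aperm(xs[[n]], c(2L, 3L, 1L))
  out
}

# Multiply x[H,W,N,C] by a per-(sample, channel) gain g[N,C], broadcast over
# space. Flattened [H,W,N,C] order repeats each (n,c) cell H*W times.
bcast_nc <- function(g, H, W) {
  array(rep(as.vector(g), each = H * W), c(H, W, nrow(g), ncol(g)))
}

# Multiply x[H,W,N,C] by a per-location map m[H,W,N], broadcast over channels.
bcast_hwn <- function(m, C) array(rep(as.vector(m), times = C), c(dim(m), C))

# Sum x[H,W,N,C] over space -> matrix [N, C].
reduce_hw <- function(x, mean = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L] * d[2L], d[3L] * d[4L])
  v <- if (mean) colMeans(xm) else colSums(xm)
  matrix(v, d[3L], d[4L])
}

# Sum x[H,W,N,C] over channels -> array [H, W, N].
reduce_c <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L] * d[2L] * d[3L], d[4L])
  array(rowSums(xm), d[1:3])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 32-bit FNV-1a hash of a string, kept in [0, 2^31 - 1] so it can seed R's
# RNG. Used by the fallback text embedder; must stay platform-stable.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # multiply mod 2^32 without exceeding double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2^31)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2^31))
  expr
}

# Stable content hash (hex string) of an R object, via serialization bytes.
# Used for dataset / parameter fingerprints in run manifests and tests.
content_hash <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
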