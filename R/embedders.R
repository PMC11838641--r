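# Embedding providers. Pretrained word/sentence embedding models plug in via
# this interface; the package ships deterministic hash-based providers so the
# clustering pipeline runs end-to-end with no external model files.

new_embedder <- function(dim, contextual, embed_fn, label) {
  structure(
    list(dim = as.integer(dim), contextual = contextual,
         embed = embed_fn, label = label),
    class = "noteps_embedder"
  )
}

#' @method print noteps_embedder
#' @export
print.noteps_embedder <- function(x, ...) {
  cat("<noteps_embedder>", x$label, "dim =", x$dim,
      if (x$contextual) "(contextual)" else "(non-contextual)", "\n")
  invisible(x)
}

# One fixed pseudo-random unit vector per (key, seed); cached.
hash_vector_factory <- function(dim, seed) {
  cache <- new.env(parent = emptyenv())
  function(key) {
    v <- cache[[key]]
    if (is.null(v)) {
      v <- with_seed(hash_string(key, seed), rnorm(dim))
      v <- v / sqrt(sum(v^2))
      cache[[key]] <- v
    }
    v
  }
}

#' Deterministic hash-based word embedder
#'
#' Maps each token to a fixed pseudo-random unit-norm vector keyed by
#' `(token, seed)`. Identical tokens always receive identical vectors, and in
#' moderate dimension distinct tokens are nearly orthogonal with overwhelming
#' probability, so cluster structure in the data (which tokens co-occur in
#' which patients) is preserved even though no semantics are encoded. Serves
#' as the built-in non-contextual provider in place of pretrained
#' word-embedding weights.
#'
#' @param dim Embedding dimension (>= 1).
#' @param seed Integer seed keying the hash.
#' @return A `noteps_embedder` whose `$embed(tokens)` returns a
#'   `length(tokens) x dim` matrix.
#' @export
hash_embedder <- function(dim = 16, seed = 1L) {
  stopifnot(dim >= 1)
  hv <- hash_vector_factory(dim, seed)
  embed_fn <- function(tokens) {
    if (length(tokens) == 0) return(matrix(numeric(0), 0, dim))
    t(vapply(tokens, hv, numeric(dim), USE.NAMES = FALSE))
  }
  new_embedder(dim, FALSE, embed_fn, sprintf("hash(seed=%d)", seed))
}

#' Deterministic contextual hash embedder
#'
#' Context-dependent stand-in for contextual word-embedding models: the
#' embedding of a token occurrence is its hash vector perturbed by a hash
#' vector of its two flanking tokens, then renormalized. The same token in
#' different contexts therefore receives genuinely different vectors, while
#' remaining deterministic. Real contextual models plug in via the same
#' interface.
#'
#' @inheritParams hash_embedder
#' @param context_weight Relative weight of the flanking-context vector.
#' @return A `noteps_embedder` whose `$embed(tokens)` returns per-occurrence
#'   embeddings using each token's neighbours within the supplied sequence.
#' @export
contextual_hash_embedder <- function(dim = 16, seed = 1L, context_weight = 0.5) {
  stopifnot(dim >= 1)
  hv <- hash_vector_factory(dim, seed)
  embed_fn <- function(tokens) {
    m <- length(tokens)
    if (m == 0) return(matrix(numeric(0), 0, dim))
    prev <- c("", tokens[-m])
    nxt <- c(tokens[-1], "")
    ctx <- paste0("ctx|", prev, "|", nxt)
    # hash only the distinct keys (cached across calls), then index
    ut <- unique(tokens)
    Et <- t(vapply(ut, hv, numeric(dim), USE.NAMES = FALSE))
    uc <- unique(ctx)
    Ec <- t(vapply(uc, hv, numeric(dim), USE.NAMES = FALSE))
    out <- Et[match(tokens, ut), , drop = FALSE] +
      context_weight * Ec[match(ctx, uc), , drop = FALSE]
    out / sqrt(rowSums(out^2))
  }
  new_embedder(dim, TRUE, embed_fn, sprintf("contextual-hash(seed=%d)", seed))
}
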