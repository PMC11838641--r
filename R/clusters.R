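# Embedding-cluster features: embed note units (words, words-in-context, or
# sentences/documents), cluster all embeddings, and give each patient a
# binary feature per cluster (1 iff any of the patient's units falls in it).

#' Binary embedding-cluster features from notes
#'
#' Embeds every unit in the cohort's pre-index notes with the supplied
#' provider, pools the embeddings across patients, clusters them with
#' mini-batch k-means, and emits `k` binary patient features: feature `c` is
#' 1 iff any of the patient's units is assigned to cluster `c`. Units are
#' token occurrences (`"word"`), token occurrences embedded with their
#' flanking context (`"contextual_word"`), or whole note documents
#' (`"sentence"`; the document embedding of a non-contextual provider is the
#' mean of its token vectors).
#'
#' @inheritParams extract_ngrams
#' @param provider A `noteps_embedder` (e.g. [hash_embedder()],
#'   [contextual_hash_embedder()], or a wrapper around a pretrained model).
#' @param unit One of `"word"`, `"contextual_word"`, `"sentence"`.
#' @param k Number of clusters (= number of features emitted).
#' @param seed Clustering seed.
#' @param batch_size,iters,nstart Passed to [minibatch_kmeans()].
#' @return List with `model` (a `cluster_model`) and `features` (sparse
#'   binary patients x k matrix). Patients with no notes have all-zero rows.
#' @export
cluster_features <- function(notes, patients, provider,
                             unit = c("word", "contextual_word", "sentence"),
                             k = 500, seed = 1L,
                             batch_size = 1024, iters = 100, nstart = 1) {
  unit <- match.arg(unit)
  stopifnot(inherits(provider, "noteps_embedder"))
  prefix <- switch(unit, word = "wclus", contextual_word = "cclus",
                   sentence = "sclus")
  feat_names <- sprintf("%s_%04d", prefix, seq_len(k))

  if (nrow(notes) == 0) {
    abort("Cohort has no embeddable units (no notes).")
  }
  toks <- tokenize(notes$text)
  if (is.character(toks)) toks <- list(toks)
  keep <- lengths(toks) > 0
  toks <- toks[keep]
  doc_pid <- notes$patient_id[keep]
  if (length(toks) == 0) abort("Cohort has no embeddable units (empty notes).")

  if (unit == "word" && !provider$contextual) {
    # identical tokens embed identically: embed distinct tokens once, then
    # replicate rows by occurrence
    occ_tok <- unlist(toks, use.names = FALSE)
    occ_pid <- rep(doc_pid, lengths(toks))
    distinct <- sort(unique(occ_tok))
    E <- provider$embed(distinct)
    idx <- match(occ_tok, distinct)
    X <- E[idx, , drop = FALSE]
    unit_pid <- occ_pid
  } else if (unit %in% c("word", "contextual_word")) {
    X <- do.call(rbind, lapply(toks, provider$embed))
    unit_pid <- rep(doc_pid, lengths(toks))
  } else if (!provider$contextual) {
    # document embedding = mean of token vectors; for a non-contextual
    # provider this is a row-group mean over distinct-token embeddings
    occ_tok <- unlist(toks, use.names = FALSE)
    distinct <- sort(unique(occ_tok))
    E <- provider$embed(distinct)
    occ_doc <- rep.int(seq_along(toks), lengths(toks))
    sums <- rowsum(E[match(occ_tok, distinct), , drop = FALSE], occ_doc)
    X <- sums / as.vector(table(occ_doc))
    unit_pid <- doc_pid
  } else {
    X <- do.call(rbind, lapply(toks, function(t) colMeans(provider$embed(t))))
    unit_pid <- doc_pid
  }
  if (!all(is.finite(X))) abort("Embedding provider returned non-finite values.")

  model <- minibatch_kmeans(X, k, seed = seed, batch_size = batch_size,
                            iters = iters, nstart = nstart)
  a <- assign_clusters(model, X)
  feats <- incidence_matrix(unit_pid, feat_names[a], patients)
  # guarantee all k columns, in cluster order, even if some cluster is empty
  missing <- setdiff(feat_names, colnames(feats))
  if (length(missing) > 0) {
    pad <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(patients), length(missing)),
      dimnames = list(patients, missing)
    )
    feats <- cbind(feats, pad)
  }
  feats <- feats[, feat_names, drop = FALSE]
  list(model = model, features = feats)
}
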