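# FeatureMatrix: sparse patients x features container with per-feature
# metadata (name, source block, prevalence, binary flag). The pipeline's
# lingua franca: all screening and propensity stages consume it.

valid_sources <- c("researcher", "claims", "ehr_code", "ngram", "lexicon",
                   "cluster_word", "cluster_contextual", "cluster_sentence")

#' Construct a feature matrix
#'
#' @param values Matrix (dense or sparse) of patients x features; coerced to
#'   a sparse `dgCMatrix`. Binary columns must contain only 0/1; continuous
#'   columns (e.g. age) are permitted and flagged in the metadata.
#' @param source Character vector (length 1 or `ncol`) of source tags, each
#'   one of `r paste(valid_sources, collapse = ", ")`.
#' @return A `feature_matrix`: list with `values` (dgCMatrix) and `meta`
#'   (tibble: feature, source, prevalence, binary). Prevalence is the exact
#'   column mean.
#' @export
feature_matrix <- function(values, source) {
  if (!inherits(values, "Matrix")) {
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  }
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(colnames(values))) {
    abort("Feature matrix columns must be named.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Feature names must be unique.")
  }
  source <- rep_len(source, ncol(values))
  bad <- setdiff(unique(source), valid_sources)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown source tag(s): ", paste(bad, collapse = ", "),
      ". Valid tags: ", paste(valid_sources, collapse = ", "), "."
    ))
  }
  # per-column 0/1 check on the sparse slots (implicit zeros are binary)
  nonbinary_entry <- values@x != 0 & values@x != 1
  col_of <- rep.int(seq_len(ncol(values)), diff(values@p))
  binary <- !as.logical(tabulate(col_of[nonbinary_entry], nbins = ncol(values)))
  meta <- tibble(
    feature = colnames(values),
    source = source,
    prevalence = Matrix::colMeans(values),
    binary = binary
  )
  structure(list(values = values, meta = meta), class = "feature_matrix")
}

#' @method print feature_matrix
#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "patients x", ncol(x$values), "features\n")
  print(count(x$meta, .data$source))
  invisible(x)
}

#' @method dim feature_matrix
#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Column-subset a feature matrix, keeping metadata aligned.
fm_subset <- function(fm, cols) {
  keep <- if (is.character(cols)) fm$meta$feature %in% cols else cols
  out <- fm
  out$values <- fm$values[, keep, drop = FALSE]
  out$meta <- fm$meta[keep, ]
  out
}

fm_bind <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  values <- do.call(cbind, lapply(parts, function(p) p$values))
  feature_matrix(values, unlist(lapply(parts, function(p) p$meta$source)))
}

researcher_block <- function(cohort) {
  p <- cohort$patients
  cols <- setdiff(names(p), c("patient_id", "A", "time_days", "event"))
  if (length(cols) == 0) return(NULL)
  m <- as.matrix(p[cols])
  rownames(m) <- p$patient_id
  feature_matrix(m, "researcher")
}

code_block <- function(cohort, domain, tag) {
  codes <- filter(cohort$codes, .data$domain == !!domain)
  incidence <- incidence_matrix(codes$patient_id, codes$code,
                                cohort$patients$patient_id)
  if (ncol(incidence) == 0) return(NULL)
  feature_matrix(incidence, tag)
}

#' Assemble the candidate feature matrix from a cohort
#'
#' Builds and column-binds the requested feature blocks in source order:
#' researcher-specified covariates (continuous covariates such as age pass
#' through unchanged and are flagged non-binary in the metadata), claims code
#' indicators, EHR code indicators, then the requested NLP blocks (n-grams,
#' lexicon concepts, and/or embedding-cluster features).
#'
#' @param cohort A `noteps_cohort`.
#' @param sources Character vector of source tags to include, in order; see
#'   [feature_matrix()] for the valid tags.
#' @param stopwords Stop-word list for the n-gram block.
#' @param n_max Maximum n-gram order (1 or 2).
#' @param lex A [lexicon()]; required when `"lexicon"` is requested.
#' @param provider Embedding provider for the cluster blocks; defaults to
#'   [hash_embedder()] / [contextual_hash_embedder()] as appropriate.
#' @param k Clusters per embedding scheme.
#' @param embed_dim Embedding dimension for the default providers.
#' @param seed Seed for clustering (fanned out per scheme).
#' @param cluster_args Extra arguments passed to [cluster_features()]
#'   (e.g. `batch_size`, `iters`, `nstart`).
#' @return A `feature_matrix` over all requested blocks.
#' @export
build_feature_matrix <- function(cohort,
                                 sources = c("researcher", "claims", "ehr_code", "ngram"),
                                 stopwords = noteps_stopwords(),
                                 n_max = 2,
                                 lex = NULL,
                                 provider = NULL,
                                 k = 500,
                                 embed_dim = 16,
                                 seed = 1L,
                                 cluster_args = list()) {
  stopifnot(inherits(cohort, "noteps_cohort"))
  if (length(sources) == 0) {
    abort("`sources` is empty; request at least one feature block.")
  }
  bad <- setdiff(sources, valid_sources)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown source tag(s): ", paste(bad, collapse = ", "),
      ". Valid tags: ", paste(valid_sources, collapse = ", "), "."
    ))
  }
  pats <- cohort$patients$patient_id

  cluster_block <- function(unit, tag, prov, s) {
    cf <- do.call(cluster_features, c(
      list(notes = cohort$notes, patients = pats, provider = prov,
           unit = unit, k = k, seed = s),
      cluster_args
    ))
    feature_matrix(cf$features, tag)
  }

  blocks <- list()
  for (src in sources) {
    blocks[[src]] <- switch(
      src,
      researcher = researcher_block(cohort),
      claims = code_block(cohort, "claims", "claims"),
      ehr_code = code_block(cohort, "ehr", "ehr_code"),
      ngram = {
        ng <- extract_ngrams(cohort$notes, pats, stopwords = stopwords,
                             n_max = n_max)
        if (ncol(ng) == 0) NULL else feature_matrix(ng, "ngram")
      },
      lexicon = {
        if (is.null(lex)) abort("Source 'lexicon' requested but `lex` is NULL.")
        lx <- match_lexicon(cohort$notes, pats, lex)
        if (ncol(lx) == 0) NULL else feature_matrix(lx, "lexicon")
      },
      cluster_word = cluster_block(
        "word", "cluster_word",
        provider %||% hash_embedder(embed_dim, derive_seed(seed, 11)),
        derive_seed(seed, 1)
      ),
      cluster_contextual = cluster_block(
        "contextual_word", "cluster_contextual",
        provider %||% contextual_hash_embedder(embed_dim, derive_seed(seed, 12)),
        derive_seed(seed, 2)
      ),
      cluster_sentence = cluster_block(
        "sentence", "cluster_sentence",
        provider %||% hash_embedder(embed_dim, derive_seed(seed, 13)),
        derive_seed(seed, 3)
      )
    )
  }
  do.call(fm_bind, unname(blocks))
}

#' Write / read a feature matrix as MatrixMarket + CSV sidecars
#'
#' `write_feature_matrix()` writes `<prefix>.mtx` (sparse values),
#' `<prefix>_features.csv` (metadata) and `<prefix>_patients.csv` (row ids).
#'
#' @param fm A `feature_matrix`.
#' @param prefix File path prefix.
#' @return `read_feature_matrix()` returns the reconstructed
#'   `feature_matrix`; the writer returns `prefix` invisibly.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  Matrix::writeMM(fm$values, paste0(prefix, ".mtx"))
  write.csv(fm$meta, paste0(prefix, "_features.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = rownames(fm$values)),
            paste0(prefix, "_patients.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  values <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  meta <- read.csv(paste0(prefix, "_features.csv"), stringsAsFactors = FALSE)
  pats <- read.csv(paste0(prefix, "_patients.csv"), stringsAsFactors = FALSE)
  dimnames(values) <- list(pats$patient_id, meta$feature)
  feature_matrix(values, meta$source)
}
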