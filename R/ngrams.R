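# Bag-of-n-grams and lexicon-concept features from pre-index notes.

# Build a sparse binary patient x feature incidence matrix from long pairs.
incidence_matrix <- function(patient_id, feature, patient_universe) {
  features <- sort(unique(feature))
  if (length(features) == 0) {
    return(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(patient_universe), 0),
      dimnames = list(patient_universe, character(0))
    ))
  }
  i <- match(patient_id, patient_universe)
  keep <- !is.na(i)
  m <- Matrix::sparseMatrix(
    i = i[keep], j = match(feature[keep], features), x = 1,
    dims = c(length(patient_universe), length(features)),
    dimnames = list(patient_universe, features)
  )
  m@x[] <- 1 # presence, not counts
  methods::as(m, "CsparseMatrix")
}

#' Extract binary n-gram features from notes
#'
#' Tokenizes each note, removes stop words first, then forms unigrams and
#' (for `n_max = 2`) bigrams of consecutive surviving tokens. Bigrams never
#' span document boundaries. A feature takes value 1 for a patient if the
#' n-gram appears in any of the patient's documents (presence, not counts).
#'
#' @param notes Tibble with columns `patient_id` and `text` (one row per
#'   document), e.g. the `notes` element of a [simulate_cohort()] cohort.
#' @param patients Character vector giving the patient universe (row order of
#'   the result); patients without notes get all-zero rows.
#' @param stopwords Character vector of tokens to exclude before n-gram
#'   formation; defaults to [noteps_stopwords()].
#' @param n_max Maximum n-gram order, 1 or 2.
#' @return Sparse binary matrix (patients x n-grams); bigram names join the
#'   two tokens with `_`.
#' @export
extract_ngrams <- function(notes, patients, stopwords = noteps_stopwords(),
                           n_max = 2) {
  if (!n_max %in% c(1, 2)) {
    abort("`n_max` must be 1 or 2 (unigrams and bigrams only).")
  }
  if (nrow(notes) == 0) {
    return(incidence_matrix(character(0), character(0), patients))
  }
  toks <- tokenize(notes$text)
  if (is.character(toks)) toks <- list(toks)
  toks <- lapply(toks, function(t) t[!t %in% stopwords])

  pid <- rep(notes$patient_id, lengths(toks))
  uni <- unlist(toks, use.names = FALSE)

  all_pid <- pid
  all_feat <- uni
  if (n_max == 2) {
    bi_list <- lapply(toks, function(t) {
      if (length(t) < 2) return(character(0))
      paste(t[-length(t)], t[-1], sep = "_")
    })
    all_pid <- c(all_pid, rep(notes$patient_id, lengths(bi_list)))
    all_feat <- c(all_feat, unlist(bi_list, use.names = FALSE))
  }
  incidence_matrix(all_pid, all_feat, patients)
}

#' Create a lexicon for concept matching
#'
#' @param term Character vector of terms; multi-token terms are
#'   space-separated.
#' @param concept_id Character vector of concept identifiers, same length.
#' @return A `noteps_lexicon` tibble with columns `term`, `concept_id`.
#' @export
lexicon <- function(term, concept_id) {
  if (any(!nzchar(trimws(term)))) abort("Lexicon terms must be non-empty.")
  if (any(!nzchar(concept_id))) abort("Concept identifiers must be non-empty.")
  structure(
    tibble(term = str_to_lower(term), concept_id = as.character(concept_id)),
    class = c("noteps_lexicon", "tbl_df", "tbl", "data.frame")
  )
}

#' Match lexicon concepts in notes
#'
#' Generic stand-in for clinical term/concept extraction systems: a greedy
#' longest-match left-to-right scan over each tokenized document. A matched
#' span emits its concept and the scan resumes after the span, so nested
#' shorter matches are suppressed. A concept feature is 1 for a patient if
#' the concept matched in any of the patient's documents.
#'
#' @inheritParams extract_ngrams
#' @param lex A [lexicon()].
#' @return Sparse binary matrix (patients x concepts).
#' @export
match_lexicon <- function(notes, patients, lex) {
  stopifnot(inherits(lex, "noteps_lexicon"))
  if (nrow(lex) == 0) abort("Lexicon is empty.")
  term_toks <- tokenize(lex$term)
  if (is.character(term_toks)) term_toks <- list(term_toks)
  term_len <- lengths(term_toks)
  term_key <- vapply(term_toks, paste, "", collapse = " ")
  # index terms by first token, longest first, for the greedy scan
  first_tok <- vapply(term_toks, `[`, "", 1)
  ord <- order(first_tok, -term_len)
  by_first <- split(ord, first_tok[ord])
  max_len <- max(term_len)
  concept_of <- setNames(lex$concept_id, term_key)

  if (nrow(notes) == 0) {
    return(incidence_matrix(character(0), character(0), patients))
  }
  toks <- tokenize(notes$text)
  if (is.character(toks)) toks <- list(toks)

  pid_out <- character(0)
  con_out <- character(0)
  for (d in seq_along(toks)) {
    t <- toks[[d]]
    n <- length(t)
    i <- 1L
    while (i <= n) {
      cands <- by_first[[t[i]]]
      matched <- FALSE
      if (!is.null(cands)) {
        for (ti in cands) { # longest first within this first token
          len <- term_len[ti]
          if (i + len - 1L <= n &&
              identical(paste(t[i:(i + len - 1L)], collapse = " "), term_key[ti])) {
            pid_out <- c(pid_out, notes$patient_id[d])
            con_out <- c(con_out, concept_of[[term_key[ti]]])
            i <- i + len
            matched <- TRUE
            break
          }
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  incidence_matrix(pid_out, con_out, patients)
}
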