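#' Tokenize clinical text
#'
#' Lowercases and splits on any maximal run of non-alphanumeric characters;
#' empty tokens are dropped and order is preserved. Digits are retained as
#' tokens (e.g. blood-pressure readings).
#'
#' @param text Character vector of documents.
#' @return For a single document, a character vector of tokens; for several,
#'   a list of token vectors.
#' @examples
#' tokenize("Chest pain, worse at night.")
#' tokenize("BP 140/90")
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(list())
  toks <- str_split(str_to_lower(text), "[^a-z0-9]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (length(text) == 1) toks[[1]] else toks
}

#' Default English stop-word list
#'
#' A fixed, versioned list of ~150 English function words (articles,
#' prepositions, pronouns, auxiliaries) shipped with the package and used as
#' the default exclusion list for n-gram extraction. User-overridable by
#' passing any character vector of tokens.
#'
#' @return Character vector of lowercase stop words.
#' @export
noteps_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "noteps")
  if (nzchar(path) && file.exists(path)) {
    return(readLines(path, warn = FALSE))
  }
  # fallback during in-source development
  sim_stopwords()
}
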