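test_that("tokenizer lowercases, splits on non-alphanumerics, keeps digits", {
  expect_equal(tokenize("Chest pain, worse at night."),
               c("chest", "pain", "worse", "at", "night"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("BP 140/90"), c("bp", "140", "90"))
  expect_equal(tokenize("  --  "), character(0))
  # vectorized form returns one token vector per document
  out <- tokenize(c("a b", "c"))
  expect_equal(out, list(c("a", "b"), "c"))
})

test_that("the shipped stop-word list is a fixed English function-word list", {
  sw <- noteps_stopwords()
  expect_gte(length(sw), 140)
  expect_true(all(c("a", "the", "in", "on") %in% sw))
  expect_false(any(duplicated(sw)))
})

test_that("n-grams: stop words removed before pairing, no cross-document bigrams", {
  pats <- c("p1", "p2")
  notes <- tibble::tibble(
    patient_id = "p1",
    text = "chest pain in the morning"
  )
  m <- extract_ngrams(notes, pats, stopwords = c("in", "the"), n_max = 2)
  expect_setequal(colnames(m),
                  c("chest", "pain", "morning", "chest_pain", "pain_morning"))
  expect_equal(unname(m["p1", "pain_morning"]), 1) # filter-then-pair
  expect_true(all(m["p2", ] == 0))

  # all stop words -> no features
  all_stop <- tibble::tibble(patient_id = "p1", text = "in the the in")
  m2 <- extract_ngrams(all_stop, pats, stopwords = c("in", "the"))
  expect_equal(ncol(m2), 0)

  # bigrams never span documents
  two_docs <- tibble::tibble(patient_id = c("p1", "p1"), text = c("alpha", "beta"))
  m3 <- extract_ngrams(two_docs, pats, stopwords = character(0), n_max = 2)
  expect_setequal(colnames(m3), c("alpha", "beta"))

  expect_error(extract_ngrams(notes, pats, n_max = 3), "1 or 2")
})

test_that("duplicating a document never changes binary n-gram features", {
  notes <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    text = c("chest pain at rest", "shortness of breath", "chest pain")
  )
  pats <- c("p1", "p2")
  m1 <- extract_ngrams(notes, pats)
  m2 <- extract_ngrams(notes[c(1, 1, 2, 3, 3), ], pats)
  expect_equal(as.matrix(m1), as.matrix(m2))
})

test_that("lexicon matching is greedy longest-match with nested suppression", {
  pats <- "p1"
  lex <- lexicon(c("chest pain", "pain"), c("C1", "C2"))
  doc <- tibble::tibble(patient_id = "p1", text = "chest pain")
  m <- match_lexicon(doc, pats, lex)
  expect_equal(colnames(m), "C1") # nested "pain" suppressed

  doc2 <- tibble::tibble(patient_id = "p1", text = "no pain")
  m2 <- match_lexicon(doc2, pats, lexicon("pain", "C2"))
  expect_equal(colnames(m2), "C2")

  doc3 <- tibble::tibble(patient_id = "p1", text = "unremarkable exam")
  m3 <- match_lexicon(doc3, pats, lex)
  expect_equal(ncol(m3), 0)

  # after a match the scan resumes past the span: "chest pain pain" -> C1 + C2
  doc4 <- tibble::tibble(patient_id = "p1", text = "chest pain pain")
  m4 <- match_lexicon(doc4, pats, lex)
  expect_setequal(colnames(m4), c("C1", "C2"))

  expect_error(lexicon("", "C1"), "non-empty")
  expect_error(lexicon("pain", ""), "non-empty")
})

test_that("feature matrices are invariant to patient order up to row permutation", {
  coh <- simulate_cohort(sim_config(n_patients = 60, notes_per_patient = 2,
                                    vocab_size = 50, seed = 13))
  fm <- build_feature_matrix(coh, sources = c("claims", "ehr_code", "ngram"))
  perm <- rev(seq_len(60))
  coh2 <- coh
  coh2$patients <- coh$patients[perm, ]
  fm2 <- build_feature_matrix(coh2, sources = c("claims", "ehr_code", "ngram"))
  expect_equal(as.matrix(fm2$values)[coh$patients$patient_id, colnames(fm$values)],
               as.matrix(fm$values))
})
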