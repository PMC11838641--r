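test_that("hash embedder is deterministic with unit-norm vectors", {
  emb <- hash_embedder(dim = 32, seed = 4)
  v1 <- emb$embed("pain")
  v2 <- emb$embed("pain")
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-12)
  # a fresh provider with the same seed reproduces the vector
  emb2 <- hash_embedder(dim = 32, seed = 4)
  expect_equal(as.numeric(emb2$embed("pain")), as.numeric(v1))
  # different seed, different vector
  emb3 <- hash_embedder(dim = 32, seed = 5)
  expect_false(isTRUE(all.equal(as.numeric(emb3$embed("pain")),
                                as.numeric(v1))))
})

test_that("distinct tokens are nearly orthogonal in moderate dimension", {
  emb <- hash_embedder(dim = 64, seed = 1)
  vocab <- sprintf("w%04d", 1:1000)
  E <- emb$embed(vocab)
  # max off-diagonal cosine over a 1000-token vocabulary stays below 0.9
  G <- E %*% t(E)
  diag(G) <- 0
  expect_lt(max(abs(G)), 0.9)
})

test_that("contextual embedder depends on flanking tokens", {
  emb <- contextual_hash_embedder(dim = 16, seed = 2)
  a <- emb$embed(c("severe", "pain", "today"))
  b <- emb$embed(c("no", "pain", "today"))
  # same token, different left context -> different embedding
  expect_false(isTRUE(all.equal(a[2, ], b[2, ])))
  # identical sequences embed identically
  expect_equal(a, emb$embed(c("severe", "pain", "today")))
  expect_equal(sqrt(rowSums(a^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("mini-batch k-means recovers well-separated clouds (exact 2-means oracle)", {
  set.seed(6)
  X <- rbind(matrix(rnorm(50 * 4, 0), ncol = 4),
             matrix(rnorm(50 * 4, 10), ncol = 4))
  km <- minibatch_kmeans(X, k = 2, seed = 1, batch_size = 100, nstart = 5)
  a <- assign_clusters(km, X)
  expect_equal(length(unique(a[1:50])), 1)
  expect_equal(length(unique(a[51:100])), 1)
  expect_false(a[1] == a[51])
  # objective matches brute-force exact 2-means on the same points
  expect_lt(km$tot_withinss, oracle_best_2means(X) * 1.01)
})

test_that("full-batch restarts attain the exact 2-means objective within 1%", {
  set.seed(17)
  X <- matrix(rnorm(120 * 2), ncol = 2) # unstructured: harder objective
  km <- minibatch_kmeans(X, k = 2, seed = 3, batch_size = nrow(X),
                         iters = 60, nstart = 20)
  best <- oracle_best_2means(X)
  expect_lte(km$tot_withinss, best * 1.01)
})

test_that("k-means edge cases: k = 1, ties, k too large", {
  X <- matrix(rnorm(20), ncol = 2)
  km <- minibatch_kmeans(X, k = 1, seed = 1)
  expect_equal(assign_clusters(km, X), rep(1, 10))
  expect_error(minibatch_kmeans(X, k = 11, seed = 1), "distinct")
  # equidistant point is assigned to the lowest cluster index
  km2 <- structure(list(k = 2L, centroids = rbind(c(-1, 0), c(1, 0)),
                        seed = 1L, tot_withinss = 0),
                   class = "cluster_model")
  expect_equal(assign_clusters(km2, matrix(c(0, 5), 1)), 1)
})

test_that("cluster features: k = 1 flags any patient with notes; no-notes rows are zero", {
  coh <- simulate_cohort(sim_config(n_patients = 40, notes_per_patient = 1,
                                    vocab_size = 30, seed = 9))
  pats <- coh$patients$patient_id
  cf <- cluster_features(coh$notes, pats, hash_embedder(8, 1),
                         unit = "word", k = 1, seed = 2)
  has_notes <- pats %in% coh$notes$patient_id
  expect_equal(as.numeric(cf$features[, 1]), as.numeric(has_notes))
  expect_true(all(cf$features[!has_notes, ] == 0))
})

test_that("word-cluster features depend only on each patient's token set", {
  # two patients with identical token sets but different multiplicities
  notes <- tibble::tibble(
    patient_id = c("p1", "p2", "p2"),
    note_id = c("n1", "n2", "n3"),
    day_offset = c(-10L, -20L, -30L),
    text = c("alpha beta gamma", "alpha alpha beta", "gamma gamma")
  )
  cf <- cluster_features(notes, c("p1", "p2"), hash_embedder(8, 3),
                         unit = "word", k = 2, seed = 4, nstart = 3)
  expect_equal(as.numeric(cf$features["p1", ]), as.numeric(cf$features["p2", ]))
})
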