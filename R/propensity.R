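# Cross-fitted LASSO propensity scores and their diagnostics.

#' The eight nested covariate sets
#'
#' Maps a propensity model id (1-8) to the ordered source tags of its
#' candidate covariate set: (1) researcher-specified variables only, then
#' cumulatively (2) + claims codes, (3) + EHR codes, and (4-8) the full code
#' sets plus one NLP block each — n-grams, lexicon concepts, sentence-embedding
#' clusters, contextual-word-embedding clusters, word-embedding clusters.
#'
#' @param model_id Integer in 1..8.
#' @return Character vector of source tags.
#' @export
covariate_set_sources <- function(model_id) {
  if (!model_id %in% 1:8) abort("`model_id` must be an integer in 1..8.")
  base3 <- c("researcher", "claims", "ehr_code")
  switch(as.character(model_id),
    "1" = "researcher",
    "2" = c("researcher", "claims"),
    "3" = base3,
    "4" = c(base3, "ngram"),
    "5" = c(base3, "lexicon"),
    "6" = c(base3, "cluster_sentence"),
    "7" = c(base3, "cluster_contextual"),
    "8" = c(base3, "cluster_word")
  )
}

# Treatment-stratified fold assignment with total fold sizes differing by
# <= 1 (treated labels fill folds from index 1 upward, control labels from
# the top downward before shuffling within arm).
stratified_folds <- function(A, n_folds) {
  f <- integer(length(A))
  i1 <- which(A == 1)
  i0 <- which(A == 0)
  f[i1] <- sample(rep_len(seq_len(n_folds), length(i1)))
  f[i0] <- sample(rep_len(rev(seq_len(n_folds)), length(i0)))
  f
}

#' Cross-fitted LASSO propensity score
#'
#' Randomly splits the cohort into `n_folds` near-equal folds (stratified by
#' treatment), fits an L1-penalized logistic regression on each set of
#' `n_folds - 1` training folds with the penalty chosen by inner 5-fold
#' cross-validation minimizing binomial deviance, and assembles the held-out
#' predicted probabilities into a single cross-fitted propensity vector, so
#' that each patient's score comes from a model trained without that patient.
#' Scores are clipped to `[1e-6, 1 - 1e-6]`. Continuous columns are scaled
#' to unit variance before penalization; binary indicators enter as 0/1.
#'
#' By default (`relax = TRUE`) each fold's model is *relaxed*: the LASSO at
#' the CV-chosen penalty selects the predictors, and an unpenalized logistic
#' refit on the selected set produces the held-out predictions. Shrunk
#' propensity scores systematically under-correct weighting estimators
#' (coefficient shrinkage pulls the scores toward the treated fraction, so
#' the weights remove only part of the measured confounding); the
#' post-selection maximum-likelihood refit restores near-unshrunk scores
#' while keeping the LASSO's variable selection. `relax = FALSE` gives the
#' plain penalized predictions.
#'
#' The reported number of selected predictors comes from a full-data refit at
#' the median of the per-fold selected penalties; all inference uses the
#' cross-fitted scores, never the refit.
#'
#' @param fm A `feature_matrix` of candidate predictors.
#' @param A Binary treatment vector aligned with `fm` rows.
#' @param n_folds Number of cross-fitting folds (default 10).
#' @param seed Integer seed for fold assignment and inner CV.
#' @param inner_nfolds Inner CV folds for penalty selection.
#' @param clip Clipping bound for predicted probabilities.
#' @param relax Use an unpenalized logistic refit on each fold's selected
#'   predictors for prediction (default TRUE).
#' @param fold_id Optional explicit fold assignment (integers in
#'   `1..n_folds`); when `NULL`, folds are drawn at random stratified by
#'   treatment. Inner CV folds are assigned by a deterministic hash of the
#'   patient id where row names are available, so cross-fitted scores are
#'   invariant to patient ordering.
#' @param nlambda,lambda.min.ratio,thresh Penalty-path and convergence
#'   settings passed to glmnet; the defaults trade a negligible loss in
#'   penalty resolution for a large speedup on sparse binary designs.
#' @return A `ps_fit`: list with `ps`, `fold_id`, `n_candidate`,
#'   `n_selected`, `auc`, `nll`, `lambda_per_fold`, `A`, `patient_id`.
#' @export
crossfit_lasso_ps <- function(fm, A, n_folds = 10, seed = 1L,
                              inner_nfolds = 5, clip = 1e-6, relax = TRUE,
                              nlambda = 30, lambda.min.ratio = 0.02,
                              thresh = 1e-5, fold_id = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  A <- check_binary_treatment(A)
  n <- nrow(fm$values)
  if (length(A) != n) abort("`A` must have one entry per patient row.")
  if (sum(A) == 0 || sum(A) == n) {
    abort("Both treatment arms must be non-empty.")
  }

  X <- fm$values
  # unit-variance scaling of continuous columns only (no centering: keeps
  # sparsity; the intercept absorbs location)
  cont <- which(!fm$meta$binary)
  for (j in cont) {
    s <- sd(X[, j])
    if (is.finite(s) && s > 0) X[, j] <- X[, j] / s
  }
  # glmnet needs >= 2 columns; pad with an all-zero dummy if needed
  padded <- FALSE
  if (ncol(X) < 2) {
    pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, 2 - ncol(X)))
    colnames(pad) <- paste0(".pad", seq_len(ncol(pad)))
    X <- cbind(X, pad)
    padded <- TRUE
  }

  pid <- rownames(fm$values)
  inner_hash <- if (!is.null(pid)) {
    (vapply(pid, hash_string, 1L, seed = seed) %% as.integer(inner_nfolds)) + 1L
  }
  if (!is.null(fold_id)) {
    fold_id <- as.integer(fold_id)
    if (length(fold_id) != n || !all(fold_id %in% seq_len(n_folds))) {
      abort("`fold_id` must assign every patient to a fold in 1..n_folds.")
    }
  }

  res <- with_seed(seed, {
    if (is.null(fold_id)) fold_id <- stratified_folds(A, n_folds)
    ps <- rep(NA_real_, n)
    lambda_per_fold <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold_id != f
      if (length(unique(A[tr])) < 2) {
        abort(paste0(
          "A training split contains a single treatment class; ",
          "use a larger cohort or fewer folds."
        ))
      }
      ifid <- inner_hash[tr]
      # hash folds must leave every inner training split with both classes;
      # otherwise fall back to a seeded random split
      ok <- !is.null(ifid) &&
        all(vapply(seq_len(inner_nfolds), function(g) {
          length(unique(A[tr][ifid != g])) == 2
        }, logical(1)))
      if (!ok) ifid <- sample(rep_len(seq_len(inner_nfolds), sum(tr)))
      cvfit <- glmnet::cv.glmnet(
        X[tr, , drop = FALSE], A[tr], family = "binomial",
        foldid = ifid, type.measure = "deviance",
        alpha = 1, standardize = FALSE,
        nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
        thresh = thresh
      )
      lambda_per_fold[f] <- cvfit$lambda.min
      te <- fold_id == f
      if (relax) {
        sel <- which(as.numeric(coef(cvfit, s = "lambda.min"))[-1] != 0)
        if (length(sel) == 0) {
          ps[te] <- mean(A[tr])
        } else {
          gfit <- suppressWarnings(glm.fit(
            cbind(1, as.matrix(X[tr, sel, drop = FALSE])), A[tr],
            family = binomial()
          ))
          b <- gfit$coefficients
          b[is.na(b)] <- 0
          ps[te] <- plogis(as.numeric(
            cbind(1, as.matrix(X[te, sel, drop = FALSE])) %*% b
          ))
        }
      } else {
        ps[te] <- as.numeric(
          predict(cvfit, X[te, , drop = FALSE],
                  s = "lambda.min", type = "response")
        )
      }
    }
    ps <- pmin(pmax(ps, clip), 1 - clip)
    # reporting refit on all data at the median per-fold penalty
    full <- glmnet::glmnet(X, A, family = "binomial", alpha = 1,
                           standardize = FALSE, nlambda = nlambda,
                           lambda.min.ratio = lambda.min.ratio, thresh = thresh)
    cf <- coef(full, s = median(lambda_per_fold))
    n_selected <- sum(cf[-1, 1] != 0)
    list(ps = ps, fold_id = fold_id, lambda_per_fold = lambda_per_fold,
         n_selected = n_selected)
  })

  structure(
    list(
      ps = res$ps, fold_id = res$fold_id,
      n_candidate = ncol(fm$values),
      n_selected = res$n_selected,
      auc = compute_auc(res$ps, A),
      nll = compute_nll(res$ps, A),
      lambda_per_fold = res$lambda_per_fold,
      A = A, patient_id = rownames(fm$values)
    ),
    class = "ps_fit"
  )
}

#' @method print ps_fit
#' @export
print.ps_fit <- function(x, ...) {
  cat("<ps_fit> n =", length(x$ps),
      " candidates =", x$n_candidate,
      " selected =", x$n_selected, "\n")
  cat(sprintf("  cross-fitted AUC = %.3f  NLL = %.4f\n", x$auc, x$nll))
  invisible(x)
}

#' @describeIn crossfit_lasso_ps Per-patient tibble (patient_id, fold_id, ps).
#' @param x A `ps_fit`.
#' @param ... Unused.
#' @method tidy ps_fit
#' @export
tidy.ps_fit <- function(x, ...) {
  tibble(patient_id = x$patient_id %||% as.character(seq_along(x$ps)),
         A = x$A, fold_id = x$fold_id, ps = x$ps)
}

#' @describeIn crossfit_lasso_ps One-row diagnostics tibble.
#' @method glance ps_fit
#' @export
glance.ps_fit <- function(x, ...) {
  tibble(n = length(x$ps), n_candidate = x$n_candidate,
         n_selected = x$n_selected, auc = x$auc, nll = x$nll)
}

#' C-statistic (AUC) of a propensity model
#'
#' Probability that a randomly chosen treated patient's score exceeds a
#' randomly chosen control's, with ties counted one half (the Mann-Whitney
#' form of the concordance statistic).
#'
#' @param ps Numeric score vector.
#' @param A Binary treatment vector.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(ps, A) {
  A <- check_binary_treatment(A)
  n1 <- sum(A == 1)
  n0 <- sum(A == 0)
  if (n1 == 0 || n0 == 0) abort("Both arms must be non-empty to compute AUC.")
  r <- rank(ps) # midranks handle ties as 1/2
  (sum(r[A == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Negative log-likelihood of a propensity model
#'
#' Mean Bernoulli negative log-likelihood (natural log); lower values mean
#' better-calibrated predictions. Scores are assumed already clipped into
#' the open unit interval.
#'
#' @inheritParams compute_auc
#' @return Non-negative scalar.
#' @export
compute_nll <- function(ps, A) {
  A <- check_binary_treatment(A)
  if (any(ps <= 0 | ps >= 1)) abort("`ps` must lie strictly inside (0, 1).")
  -mean(A * log(ps) + (1 - A) * log(1 - ps))
}
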