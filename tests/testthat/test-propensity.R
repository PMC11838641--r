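random_fm <- function(n, p, prev = 0.2, seed = 1, source = "claims") {
  set.seed(seed)
  m <- Matrix::Matrix(matrix(rbinom(n * p, 1, prev), n, p), sparse = TRUE)
  colnames(m) <- sprintf("f%04d", seq_len(p))
  rownames(m) <- sprintf("p%04d", seq_len(n))
  feature_matrix(m, source)
}

test_that("cross-fitting partitions patients into near-equal folds, one prediction each", {
  fm <- random_fm(100, 10, seed = 2)
  A <- rep_len(c(1, 0), 100)
  fit <- crossfit_lasso_ps(fm, A, n_folds = 10, seed = 1)
  expect_equal(as.numeric(table(fit$fold_id)), rep(10, 10))
  expect_true(all(!is.na(fit$ps)))
  expect_true(all(fit$ps >= 1e-6 & fit$ps <= 1 - 1e-6))
  expect_lte(fit$n_selected, fit$n_candidate)
  expect_equal(length(fit$lambda_per_fold), 10)
  # fold sizes differ by <= 1 also when n is not a multiple of n_folds
  fm2 <- random_fm(103, 10, seed = 3)
  A2 <- c(rep(1, 41), rep(0, 62))
  fit2 <- crossfit_lasso_ps(fm2, A2, n_folds = 10, seed = 1)
  expect_lte(diff(range(table(fit2$fold_id))), 1)
})

test_that("a single perfect predictor separates the arms with AUC exactly 1", {
  n <- 100
  A <- rep_len(c(1, 0), n)
  m <- Matrix::Matrix(matrix(A, n, 1), sparse = TRUE)
  dimnames(m) <- list(sprintf("p%03d", 1:n), "mirror")
  fm <- feature_matrix(m, "claims")
  fit <- crossfit_lasso_ps(fm, A, n_folds = 5, seed = 2)
  expect_equal(fit$auc, 1.0)
  expect_true(all(fit$ps[A == 1] > 0.9))
  expect_true(all(fit$ps[A == 0] < 0.1))
})

test_that("degenerate treatment vectors are rejected", {
  fm <- random_fm(40, 5)
  expect_error(crossfit_lasso_ps(fm, rep(1, 40)), "non-empty")
  expect_error(crossfit_lasso_ps(fm, rep_len(c(1, 0), 40), fold_id = rep(99, 40)),
               "fold")
})

test_that("cross-fitted scores are invariant to patient ordering", {
  fm <- random_fm(120, 30, seed = 5)
  set.seed(8)
  A <- rbinom(120, 1, plogis(-0.5 + 2 * as.matrix(fm$values[, 1])))
  fold <- rep_len(1:5, 120)
  fit <- crossfit_lasso_ps(fm, A, n_folds = 5, seed = 3, fold_id = fold)
  perm <- sample(120)
  fm_p <- fm
  fm_p$values <- fm$values[perm, ]
  fm_p$meta <- fm$meta
  fit_p <- crossfit_lasso_ps(fm_p, A[perm], n_folds = 5, seed = 3,
                             fold_id = fold[perm])
  expect_equal(fit_p$ps, fit$ps[perm], tolerance = 1e-8)
})

test_that("AUC follows the Mann-Whitney form with ties counted one half", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.3, 6), rep_len(c(1, 0), 6)), 0.5)
  expect_equal(compute_auc(c(0.6, 0.4, 0.5), c(1, 1, 0)), 0.5) # (1 + 0) / 2
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "non-empty")
  # cross-check against the survival package's concordance on random data
  set.seed(10)
  ps <- runif(300)
  A <- rbinom(300, 1, ps)
  conc <- survival::concordance(A ~ ps)$concordance
  expect_equal(compute_auc(ps, A), conc, tolerance = 1e-12)
})

test_that("NLL is the mean Bernoulli negative log-likelihood", {
  expect_equal(compute_nll(rep(0.5, 10), rep_len(c(1, 0), 10)), log(2))
  expect_equal(compute_nll(c(0.8, 0.4), c(1, 0)),
               -(log(0.8) + log(0.6)) / 2)
  expect_equal(round(compute_nll(c(0.8, 0.4), c(1, 0)), 4), 0.367)
  # perfect predictions at the clip boundary
  nll <- compute_nll(c(1 - 1e-6, 1e-6), c(1, 0))
  expect_lt(nll, 2e-6)
  expect_error(compute_nll(c(0, 0.5), c(1, 0)), "inside")
})

test_that("fitted models beat the constant predictor on cohorts with signal", {
  coh <- simulate_cohort(sim_config(n_patients = 1200, notes_per_patient = 0,
                                    seed = 19))
  A <- coh$patients$A
  fm <- prevalence_filter(build_feature_matrix(coh, c("researcher", "claims", "ehr_code")))
  fit <- crossfit_lasso_ps(fm, A, seed = 4)
  const_nll <- -mean(A * log(mean(A)) + (1 - A) * log(1 - mean(A)))
  expect_lte(fit$nll, const_nll + 0.02)
  expect_gt(fit$auc, 0.5)
})

test_that("tidy and glance expose per-patient scores and one-row diagnostics", {
  fm <- random_fm(60, 8, seed = 7)
  A <- rep_len(c(1, 0), 60)
  fit <- crossfit_lasso_ps(fm, A, n_folds = 5, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  expect_named(td, c("patient_id", "A", "fold_id", "ps"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_candidate, 8)
  expect_s3_class(autoplot(fit), "ggplot")
})
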