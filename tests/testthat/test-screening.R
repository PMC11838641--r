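make_fm <- function(cols, sources, n = 200) {
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("p%03d", seq_len(n))
  feature_matrix(m, sources)
}

test_that("prevalence filter drops strictly-below-threshold code/NLP columns only", {
  n <- 200
  cols <- list(
    rare = c(1, rep(0, n - 1)),              # prevalence 0.005 -> removed
    boundary = c(1, 1, rep(0, n - 2)),       # prevalence 0.01 -> retained
    common = rep(c(1, 0), n / 2),
    rare_flag = c(rep(0, n - 1), 1)          # researcher -> exempt
  )
  fm <- make_fm(cols, c("claims", "claims", "ngram", "researcher"), n)
  out <- prevalence_filter(fm, 0.01)
  expect_setequal(out$meta$feature, c("boundary", "common", "rare_flag"))
  rep_frag <- attr(out, "screen")
  expect_equal(rep_frag$n_input, 4)
  expect_equal(rep_frag$n_after_prevalence, 3)

  # idempotence
  out2 <- prevalence_filter(out, 0.01)
  expect_equal(out2$meta, out$meta)

  # commutes with the denylist
  a <- apply_denylist(prevalence_filter(fm, 0.01), "common")
  b <- prevalence_filter(apply_denylist(fm, "common"), 0.01)
  expect_equal(a$meta, b$meta)
  expect_equal(as.matrix(a$values), as.matrix(b$values))
})

test_that("IV ranking uses the phi coefficient with |r| ordering and name ties", {
  n <- 100
  A <- rep(c(1, 0), each = 50)
  x_ind <- c(rep(1, 25), rep(0, 25), rep(1, 25), rep(0, 25)) # 25/25/25/25 table
  x_tab <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40)) # phi = 0.408
  cols <- list(same_as_a = A, independent = x_ind, tabled = x_tab,
               constant = rep(1, n))
  fm <- make_fm(cols, "claims", n)
  rk <- rank_iv_candidates(fm, A)
  expect_equal(rk$feature[1], "same_as_a")
  expect_equal(unname(rk$correlation[rk$feature == "same_as_a"]), 1.0)
  expect_equal(unname(rk$correlation[rk$feature == "independent"]), 0)
  expect_equal(unname(rk$correlation[rk$feature == "tabled"]),
               oracle_phi(x_tab, A), tolerance = 1e-12)
  expect_equal(round(unname(rk$correlation[rk$feature == "tabled"]), 3), 0.408)
  expect_equal(unname(rk$correlation[rk$feature == "constant"]), 0)
  expect_true(rk$constant[rk$feature == "constant"])
  expect_equal(nrow(rank_iv_candidates(fm, A, top_k = 2)), 2)
})

test_that("planted IVs dominate the top of the treatment-correlation ranking", {
  cfg <- sim_config(n_patients = 4000, alpha = c(0.3, 0.3), n_iv_codes = 6,
                    alpha_iv = 1.5, notes_per_patient = 0, seed = 44)
  coh <- simulate_cohort(cfg)
  fm <- prevalence_filter(build_feature_matrix(coh, c("claims", "ehr_code")))
  rk <- rank_iv_candidates(fm, coh$patients$A, top_k = 2 * 6)
  hits <- mean(coh$truth$iv_feature_ids %in% rk$feature)
  expect_gte(hits, 0.8)
})

test_that("denylist removes named columns, warns on unknown, identity when empty", {
  n <- 40
  fm <- make_fm(list(a = rep_len(c(1, 0), n), b = rep_len(c(0, 1, 1, 0), n)),
                "claims", n)
  out <- apply_denylist(fm, "a")
  expect_equal(out$meta$feature, "b")
  expect_warning(apply_denylist(fm, c("b", "zzz")), "zzz")
  same <- apply_denylist(fm, character(0))
  expect_equal(same$meta, fm$meta)
})

test_that("excluding planted IVs does not inflate the IPTW variance", {
  # IVs predict treatment but not outcome: adjusting for them widens the
  # effect-estimate distribution; the denylist removes them
  reps <- 50
  res <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_patients = 1500, alpha = c(0.5, 0.5),
                      gamma = c(0.5, 0.5), beta_true = 0,
                      baseline_hazard = 3e-4, n_iv_codes = 8, alpha_iv = 1.8,
                      notes_per_patient = 0, seed = 6200 + r)
    coh <- simulate_cohort(cfg)
    A <- coh$patients$A
    fm <- prevalence_filter(build_feature_matrix(coh, c("researcher", "claims", "ehr_code")))
    est_for <- function(f) {
      fit <- crossfit_lasso_ps(f, A, n_folds = 5, seed = r)
      w <- compute_weights(fit$ps, A, "iptw")
      weighted_cox(coh$patients$time_days, coh$patients$event, A, w,
                   scheme = "iptw")$log_hr
    }
    c(keep = est_for(fm),
      deny = est_for(suppressWarnings(apply_denylist(fm, coh$truth$iv_feature_ids))))
  }, numeric(2))
  expect_lte(sd(res["deny", ]), sd(res["keep", ]) * 1.05)
})
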