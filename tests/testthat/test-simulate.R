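test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 200, notes_per_patient = 2, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$codes, b$codes)
  expect_identical(a$notes, b$notes)
  expect_identical(a$truth$U, b$truth$U)
  # and the global RNG stream is not disturbed
  set.seed(1); x <- runif(1)
  set.seed(1); simulate_cohort(cfg); y <- runif(1)
  expect_identical(x, y)
})

test_that("cohort invariants hold: binary flags, ITT censoring, pre-index notes", {
  coh <- simulate_cohort(sim_config(n_patients = 500, seed = 3,
                                    notes_per_patient = 2))
  p <- coh$patients
  expect_true(all(p$A %in% 0:1))
  expect_true(all(p$event %in% 0:1))
  expect_true(all(p$time_days > 0 & p$time_days <= 183))
  # administrative censoring: anyone at the horizon is event-free
  expect_true(all(p$event[p$time_days == 183] == 0))
  expect_true(all(p$event[p$time_days < 183] == 1))
  expect_true(all(coh$notes$day_offset < 0))
  expect_true(all(coh$notes$day_offset >= -365))
  expect_identical(coh$truth$beta_true, coh$config$beta_true)
  expect_true(all(coh$truth$iv_feature_ids %in% coh$codes$code |
                    coh$config$n_iv_codes == 0))
})

test_that("treated fraction matches the treatment model under the null", {
  cfg <- sim_config(n_patients = 10000, alpha0 = 0, alpha = c(0, 0),
                    n_iv_codes = 0, notes_per_patient = 0, seed = 11)
  coh <- simulate_cohort(cfg)
  frac <- mean(coh$patients$A)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("without confounding the unadjusted Cox estimator recovers beta_true", {
  # gamma = 0, beta_true = log 2: unadjusted estimator is unbiased
  reps <- 50
  est <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_patients = 4000, gamma = c(0, 0), beta_true = log(2),
                      baseline_hazard = 2e-4, n_iv_codes = 0,
                      notes_per_patient = 0, seed = 8000 + r)
    coh <- simulate_cohort(cfg)
    weighted_cox(coh$patients$time_days, coh$patients$event,
                 coh$patients$A)$log_hr
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - log(2)), 3 * mc_se)
})

test_that("planted confounding biases the unadjusted estimate upward", {
  reps <- 20
  est <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_patients = 2000, alpha = c(1, 1), gamma = c(0.6, 0.6),
                      beta_true = 0, baseline_hazard = 2e-4, n_iv_codes = 0,
                      notes_per_patient = 0, seed = 9100 + r)
    coh <- simulate_cohort(cfg)
    weighted_cox(coh$patients$time_days, coh$patients$event,
                 coh$patients$A)$log_hr
  }, numeric(1))
  expect_gt(mean(est), 0) # alpha * gamma > 0 => upward bias
  expect_gt(mean(est), 3 * sd(est) / sqrt(reps))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(admin_censor_days = 0), "admin_censor_days")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(frac_note_only_confounders = 1.5), "frac_note_only")
  expect_error(sim_config(alpha = c(1, 2, 3), n_latent = 2), "alpha")
  expect_error(sim_config(alpha0 = Inf), "alpha0")
  expect_error(sim_config(vocab_size = 0, notes_per_patient = 2), "vocab")
})

test_that("summarize_cohort recounts the cohort directly", {
  coh <- tiny_cohort()
  s <- summarize_cohort(coh)
  expect_equal(s$n, 4)
  expect_equal(s$treated_pct, 50)
  expect_equal(s$outcome_pct, 25)
  expect_equal(s$median_notes_per_patient, 0.5) # 1,1,0,0 notes

  # no notes at all -> median 0
  coh2 <- coh
  coh2$notes <- coh$notes[0, ]
  expect_equal(summarize_cohort(coh2)$median_notes_per_patient, 0)
})

test_that("a config targeting one-third treated lands near 33%", {
  coh <- simulate_cohort(sim_config(n_patients = 8000, notes_per_patient = 0,
                                    seed = 21))
  s <- summarize_cohort(coh)
  # logistic-normal: E[expit(-0.85 + U1 + U2 + Z)] ~ 0.33; allow sampling slack
  expect_gt(s$treated_pct, 28)
  expect_lt(s$treated_pct, 39)
})

test_that("note-only latent components emit no code signal", {
  cfg <- sim_config(n_patients = 3000, n_latent = 2,
                    frac_note_only_confounders = 0.5, n_iv_codes = 0,
                    notes_per_patient = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$truth$note_only_latent_ids, 2)
  fm <- build_feature_matrix(coh, sources = c("claims", "ehr_code"))
  U2 <- coh$truth$U[, 2]
  cors <- apply(as.matrix(fm$values), 2, function(x) {
    if (sd(x) == 0) 0 else cor(x, U2)
  })
  # every code is conditionally independent of the note-only component
  expect_lt(max(abs(cors)), 4 / sqrt(3000) * 2)
})
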