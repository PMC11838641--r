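# Canonical evaluation scenarios. Centralized so tests, scripts and the
# vignette all refer to the same data-generating conditions.

#' Canonical simulation scenarios for method evaluation
#'
#' `scenario_note_confounding()` is the package's reference confounded
#' scenario: two latent comorbidity components with equal treatment and
#' outcome effects (`alpha * gamma > 0`, planting upward bias in the
#' unadjusted estimate), one component expressed in both codes and notes and
#' one note-only (so half the confounding signal is invisible to claims-only
#' adjustment), rich code and token proxies, a null true treatment effect by
#' default, and no instrumental codes. Event risk sits at the upper end of
#' the 0.7-4% range typical of 6-month cardiovascular outcome cohorts.
#'
#' `scenario_null()` is a randomized, unconfounded, null-effect cohort with
#' no notes, used for coverage and calibration checks.
#'
#' @param n_patients Cohort size.
#' @param beta_true True log hazard ratio.
#' @param seed Generator seed.
#' @return A [sim_config()].
#' @export
scenario_note_confounding <- function(n_patients = 2000, beta_true = 0,
                                      seed = 1L) {
  sim_config(
    n_patients = n_patients, n_latent = 2,
    alpha0 = -0.85, alpha = c(0.7, 0.7),
    beta_true = beta_true, gamma = c(0.4, 0.4),
    baseline_hazard = 1.5e-4, admin_censor_days = 183,
    n_claims_codes = 60, n_ehr_codes = 40,
    vocab_size = 300, notes_per_patient = 4, tokens_per_note = 50,
    token_loading_range = c(1.2, 2.8),
    frac_note_only_confounders = 0.5, n_iv_codes = 0,
    n_researcher_flags = 10, seed = seed
  )
}

#' @rdname scenario_note_confounding
#' @export
scenario_null <- function(n_patients = 1000, seed = 1L) {
  sim_config(
    n_patients = n_patients, n_latent = 2,
    alpha0 = -0.7, alpha = c(0, 0), beta_true = 0, gamma = c(0, 0),
    baseline_hazard = 2e-4, n_claims_codes = 40, n_ehr_codes = 20,
    notes_per_patient = 0, n_iv_codes = 0, seed = seed
  )
}
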