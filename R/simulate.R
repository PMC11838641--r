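#' Configuration for the synthetic claims+notes cohort generator
#'
#' Defines the data-generating process for a synthetic new-user cohort with
#' linked claims codes, EHR codes and pre-index free-text-like notes. A latent
#' standard-normal confounder vector `U` drives treatment choice (confounding
#' by indication), the outcome hazard, code prevalences and note token
#' emission. Instrumental-variable codes load on a separate treatment-only
#' latent factor with no outcome effect. A configurable fraction of the latent
#' components is "note-only": their code loadings are zeroed, so the signal
#' reaches the analysis only through note tokens.
#'
#' Defaults target a treated fraction near 33% and a 6-month outcome risk of
#' roughly 2-3%, the scale typical of claims-based cardiovascular safety
#' cohorts.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_latent Dimension of the latent confounder vector `U`.
#' @param alpha0 Treatment-model intercept (log-odds).
#' @param alpha Length-`n_latent` vector: confounder effects on treatment
#'   log-odds.
#' @param beta_true True treatment effect on the log hazard ratio scale.
#' @param gamma Length-`n_latent` vector: confounder effects on the log
#'   hazard.
#' @param baseline_hazard Constant baseline hazard per day (> 0).
#' @param admin_censor_days Administrative censoring horizon in days; the
#'   default 183 is a 6-month intent-to-treat window.
#' @param n_claims_codes,n_ehr_codes Numbers of non-IV claims and EHR codes.
#' @param code_loadings Optional list with elements `claims` and `ehr`, each a
#'   list of `intercept` (length n codes) and `loading` (codes x n_latent).
#'   Generated from the seed when `NULL`.
#' @param vocab_size Number of content tokens in the note vocabulary.
#' @param note_topic_loadings Optional `vocab_size` x `n_latent` matrix of
#'   token log-rate loadings on `U`. Generated from the seed when `NULL`.
#' @param notes_per_patient Mean number of pre-index notes per patient
#'   (Poisson).
#' @param tokens_per_note Mean tokens per note (Poisson, minimum 1).
#' @param frac_note_only_confounders Fraction of latent components whose code
#'   loadings are zeroed (signal visible only in notes), in `[0, 1]`.
#' @param n_iv_codes Number of instrumental-variable claims codes loading
#'   only on the treatment-linked factor.
#' @param alpha_iv Log-odds effect of the IV latent factor on treatment.
#' @param n_researcher_flags Number of binary researcher-specified covariates
#'   beyond age and sex.
#' @param stopword_frac Fraction of note tokens drawn from the stop-word
#'   stratum, which is emitted independently of `U`.
#' @param code_loading_range,token_loading_range Ranges from which per-code
#'   and per-token loadings on `U` are drawn; they control how informative
#'   the code/note proxies are about the latent state.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 2000,
                       n_latent = 2,
                       alpha0 = -0.85,
                       alpha = rep(1, n_latent),
                       beta_true = 0,
                       gamma = rep(0.6, n_latent),
                       baseline_hazard = 1e-4,
                       admin_censor_days = 183,
                       n_claims_codes = 60,
                       n_ehr_codes = 40,
                       code_loadings = NULL,
                       vocab_size = 200,
                       note_topic_loadings = NULL,
                       notes_per_patient = 3,
                       tokens_per_note = 40,
                       frac_note_only_confounders = 0,
                       n_iv_codes = 5,
                       alpha_iv = 1,
                       n_researcher_flags = 10,
                       stopword_frac = 0.35,
                       code_loading_range = c(0.8, 1.8),
                       token_loading_range = c(0.8, 2.0),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_latent = as.integer(n_latent),
    alpha0 = alpha0, alpha = as.numeric(alpha), beta_true = beta_true,
    gamma = as.numeric(gamma), baseline_hazard = baseline_hazard,
    admin_censor_days = as.numeric(admin_censor_days),
    n_claims_codes = as.integer(n_claims_codes),
    n_ehr_codes = as.integer(n_ehr_codes),
    code_loadings = code_loadings, vocab_size = as.integer(vocab_size),
    note_topic_loadings = note_topic_loadings,
    notes_per_patient = notes_per_patient, tokens_per_note = tokens_per_note,
    frac_note_only_confounders = frac_note_only_confounders,
    n_iv_codes = as.integer(n_iv_codes), alpha_iv = alpha_iv,
    n_researcher_flags = as.integer(n_researcher_flags),
    stopword_frac = stopword_frac,
    code_loading_range = as.numeric(code_loading_range),
    token_loading_range = as.numeric(token_loading_range),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 2) abort("`n_patients` must be >= 2.")
  if (cfg$admin_censor_days <= 0) abort("`admin_censor_days` must be > 0.")
  if (cfg$baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (cfg$frac_note_only_confounders < 0 || cfg$frac_note_only_confounders > 1) {
    abort("`frac_note_only_confounders` must lie in [0, 1].")
  }
  if (length(cfg$alpha) != cfg$n_latent) {
    abort("`alpha` must have length `n_latent`.")
  }
  if (length(cfg$gamma) != cfg$n_latent) {
    abort("`gamma` must have length `n_latent`.")
  }
  for (nm in c("alpha0", "alpha", "beta_true", "gamma", "alpha_iv")) {
    if (!all(is.finite(cfg[[nm]]))) {
      abort(paste0("Non-finite value in parameter `", nm, "`."))
    }
  }
  if (cfg$notes_per_patient > 0 && cfg$vocab_size < 1) {
    abort("Notes requested (`notes_per_patient` > 0) but `vocab_size` is 0.")
  }
  invisible(cfg)
}

# Draw the code/token loading structure for a config (if not user-supplied).
# Called inside simulate_cohort() under the config seed so that the structure
# is part of the deterministic data-generating process.
draw_structure <- function(cfg) {
  L <- cfg$n_latent
  n_note_only <- ceiling(cfg$frac_note_only_confounders * L)
  note_only <- if (n_note_only > 0) seq_len(L)[(L - n_note_only + 1):L] else integer(0)

  code_block <- function(p) {
    # loadings strong enough that a few dozen codes collectively carry most
    # of a latent component's signal (graded proxies of the comorbidity
    # state), as in claims databases where many codes reflect one condition
    intercept <- runif(p, -3, -1)
    loading <- matrix(0, p, L)
    if (L > 0 && p > 0) {
      comp <- sample.int(L, p, replace = TRUE)
      loading[cbind(seq_len(p), comp)] <- runif(p, cfg$code_loading_range[1],
                                                cfg$code_loading_range[2])
    }
    loading[, note_only] <- 0
    list(intercept = intercept, loading = loading)
  }

  structure_list <- list(
    claims = code_block(cfg$n_claims_codes),
    ehr = code_block(cfg$n_ehr_codes),
    iv = list(
      intercept = runif(cfg$n_iv_codes, -3, -1.5),
      loading = runif(cfg$n_iv_codes, 0.8, 1.5)
    ),
    note_only = note_only
  )
  if (!is.null(cfg$code_loadings)) {
    structure_list$claims <- cfg$code_loadings$claims
    structure_list$ehr <- cfg$code_loadings$ehr
    structure_list$claims$loading[, note_only] <- 0
    structure_list$ehr$loading[, note_only] <- 0
  }
  if (is.null(cfg$note_topic_loadings)) {
    vload <- matrix(0, cfg$vocab_size, L)
    if (L > 0 && cfg$vocab_size > 0) {
      comp <- sample.int(L, cfg$vocab_size, replace = TRUE)
      vload[cbind(seq_len(cfg$vocab_size), comp)] <-
        runif(cfg$vocab_size, cfg$token_loading_range[1],
              cfg$token_loading_range[2])
    }
    structure_list$vocab_loading <- vload
  } else {
    structure_list$vocab_loading <- cfg$note_topic_loadings
  }
  structure_list$vocab_base <- rnorm(cfg$vocab_size, 0, 1)
  structure_list
}

# Stop-word stratum used by the generator: a small fixed subset of the
# shipped stop-word list, emitted independently of U.
sim_stopwords <- function() {
  c(
    "the", "and", "of", "to", "in", "a", "is", "was", "with", "for",
    "on", "at", "no", "not", "has", "had", "be", "as", "or", "an",
    "this", "that", "by", "from", "are", "were", "it", "his", "her", "their"
  )
}

#' Simulate a linked claims+notes cohort with known ground truth
#'
#' Draws a synthetic cohort under the causal structure described in
#' [sim_config()]: latent confounders `U` (i.i.d. standard normal per
#' component) drive treatment via a logistic model, the outcome via an
#' exponential proportional-hazards model administratively censored at the
#' intent-to-treat horizon, code presence via per-code logistic models, and
#' note tokens via a per-patient log-linear (softmax) emission model. The
#' returned object carries the simulation truth (latent draws, planted IV
#' code names, note-only component indices, true log hazard ratio) for use in
#' method evaluation.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `noteps_cohort`: a list with tibbles
#'   `patients` (patient_id, A, time_days, event, age, sex, flag_*),
#'   `codes` (patient_id, code, domain) and `notes` (patient_id, note_id,
#'   day_offset, text), plus `truth` and `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' summarize_cohort(coh)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  L <- cfg$n_latent
  struct <- draw_structure(cfg)

  U <- matrix(rnorm(n * L), n, L)
  Z_iv <- rnorm(n)

  lp_treat <- cfg$alpha0 + as.vector(U %*% cfg$alpha) +
    if (cfg$n_iv_codes > 0) cfg$alpha_iv * Z_iv else 0
  if (!all(is.finite(lp_treat))) {
    abort("Non-finite treatment linear predictor; check `alpha0`/`alpha`/`alpha_iv`.")
  }
  A <- rbinom(n, 1, plogis(lp_treat))

  draw_codes <- function(block, prefix) {
    p <- length(block$intercept)
    if (p == 0) return(tibble(patient_id = character(), code = character()))
    lp <- matrix(block$intercept, n, p, byrow = TRUE)
    if (is.matrix(block$loading)) {
      lp <- lp + U %*% t(block$loading)
    } else {
      lp <- lp + outer(Z_iv, block$loading)
    }
    if (!all(is.finite(lp))) abort("Non-finite code linear predictor; check `code_loadings`.")
    present <- matrix(rbinom(n * p, 1, plogis(lp)), n, p) == 1
    idx <- which(present, arr.ind = TRUE)
    tibble(
      patient_id = patient_ids(n)[idx[, 1]],
      code = sprintf("%s%04d", prefix, idx[, 2])
    )
  }

  claims <- draw_codes(struct$claims, "clm_")
  ehr <- draw_codes(struct$ehr, "ehr_")
  iv <- draw_codes(struct$iv, "clmiv_")
  codes <- bind_rows(
    mutate(claims, domain = "claims"),
    mutate(iv, domain = "claims"),
    mutate(ehr, domain = "ehr")
  ) |> arrange(.data$patient_id, .data$code)

  age <- pmin(pmax(round(rnorm(n, 72, 8)), 40), 95)
  sex <- rbinom(n, 1, 0.5)
  flags <- NULL
  if (cfg$n_researcher_flags > 0) {
    flags <- matrix(0L, n, cfg$n_researcher_flags)
    u1 <- if (L > 0) U[, 1] else rep(0, n)
    for (j in seq_len(cfg$n_researcher_flags)) {
      # half the researcher flags are weak proxies of the first latent
      # component, half pure noise
      lp <- if (j <= cfg$n_researcher_flags / 2) -1 + 0.4 * u1 else rep(-1, n)
      flags[, j] <- rbinom(n, 1, plogis(lp))
    }
    colnames(flags) <- sprintf("flag_%02d", seq_len(cfg$n_researcher_flags))
  }

  notes <- simulate_notes(cfg, struct, U)

  lp_out <- cfg$beta_true * A + as.vector(U %*% cfg$gamma)
  if (!all(is.finite(lp_out))) {
    abort("Non-finite outcome linear predictor; check `beta_true`/`gamma`.")
  }
  latent_time <- rexp(n, rate = cfg$baseline_hazard * exp(lp_out))
  event <- as.integer(latent_time < cfg$admin_censor_days)
  time_days <- pmin(latent_time, cfg$admin_censor_days)

  patients <- tibble(
    patient_id = patient_ids(n), A = A,
    time_days = time_days, event = event, age = as.numeric(age), sex = sex
  )
  if (!is.null(flags)) patients <- dplyr::bind_cols(patients, as_tibble(flags))

  truth <- list(
    U = U, beta_true = cfg$beta_true,
    iv_feature_ids = if (cfg$n_iv_codes > 0) sprintf("clmiv_%04d", seq_len(cfg$n_iv_codes)) else character(0),
    note_only_latent_ids = struct$note_only,
    seed = cfg$seed
  )

  structure(
    list(patients = patients, codes = codes, notes = notes,
         truth = truth, config = cfg),
    class = "noteps_cohort"
  )
}

patient_ids <- function(n) sprintf("p%06d", seq_len(n))

simulate_notes <- function(cfg, struct, U) {
  n <- cfg$n_patients
  empty <- tibble(
    patient_id = character(), note_id = character(),
    day_offset = integer(), text = character()
  )
  if (cfg$notes_per_patient <= 0) return(empty)
  n_notes <- rpois(n, cfg$notes_per_patient)
  if (sum(n_notes) == 0) return(empty)

  vocab <- sprintf("tok%03d", seq_len(cfg$vocab_size))
  stopv <- sim_stopwords()
  # per-patient softmax over content vocabulary, shifted by U
  logits <- matrix(struct$vocab_base, n, cfg$vocab_size, byrow = TRUE) +
    U %*% t(struct$vocab_loading)
  if (!all(is.finite(logits))) {
    abort("Non-finite note-emission linear predictor; check `note_topic_loadings`.")
  }
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)

  out <- vector("list", n)
  ids <- patient_ids(n)
  for (i in seq_len(n)) {
    k <- n_notes[i]
    if (k == 0) next
    offs <- -sample.int(365, k, replace = TRUE)
    # draw all of the patient's tokens at once, then split into notes
    m_per_note <- pmax(1L, rpois(k, cfg$tokens_per_note))
    m_tot <- sum(m_per_note)
    toks <- character(m_tot)
    is_stop <- rbinom(m_tot, 1, cfg$stopword_frac) == 1
    if (any(is_stop)) {
      toks[is_stop] <- stopv[sample.int(length(stopv), sum(is_stop), replace = TRUE)]
    }
    if (any(!is_stop)) {
      toks[!is_stop] <- vocab[sample.int(cfg$vocab_size, sum(!is_stop),
                                         replace = TRUE, prob = probs[i, ])]
    }
    note_of <- rep.int(seq_len(k), m_per_note)
    texts <- vapply(split(toks, note_of), paste, "", collapse = " ",
                    USE.NAMES = FALSE)
    out[[i]] <- tibble(
      patient_id = ids[i],
      note_id = sprintf("%s_n%02d", ids[i], seq_len(k)),
      day_offset = as.integer(offs),
      text = texts
    )
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

#' @method print noteps_cohort
#' @export
print.noteps_cohort <- function(x, ...) {
  cat("<noteps_cohort>\n")
  cat("  patients:", nrow(x$patients), "\n")
  cat("  treated: ", sum(x$patients$A), sprintf("(%.1f%%)\n", 100 * mean(x$patients$A)))
  cat("  events:  ", sum(x$patients$event), "\n")
  cat("  code rows:", nrow(x$codes), " note documents:", nrow(x$notes), "\n")
  invisible(x)
}

#' Summarize a cohort
#'
#' Recounts the cohort directly: size, treated and outcome percentages,
#' median notes per patient and quartiles of per-code prevalence.
#'
#' @param cohort A `noteps_cohort` object.
#' @return A one-row tibble.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "noteps_cohort"))
  p <- cohort$patients
  if (nrow(p) == 0) abort("Cohort is empty.")
  notes_per <- table(factor(cohort$notes$patient_id, levels = p$patient_id))
  prev <- if (nrow(cohort$codes) > 0) {
    as.numeric(table(cohort$codes$code)) / nrow(p)
  } else {
    NA_real_
  }
  tibble(
    n = nrow(p),
    treated_pct = 100 * mean(p$A),
    outcome_pct = 100 * mean(p$event),
    median_notes_per_patient = as.numeric(median(as.numeric(notes_per))),
    code_prevalence_q25 = as.numeric(quantile(prev, 0.25, na.rm = TRUE)),
    code_prevalence_q50 = as.numeric(quantile(prev, 0.50, na.rm = TRUE)),
    code_prevalence_q75 = as.numeric(quantile(prev, 0.75, na.rm = TRUE))
  )
}
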