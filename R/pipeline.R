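# Experiment orchestration: cohort -> features -> screens -> PS per covariate
# set -> weights per scheme -> balance + effects, with per-cell failure
# isolation and a master-seed fan-out.

#' Configuration of a full experiment run
#'
#' @param sim A [sim_config()] describing the cohort to generate, or `NULL`
#'   when ingesting from `cohort_dir`.
#' @param cohort_dir Directory in the [write_cohort()] schema to ingest
#'   (ignored when `sim` is given).
#' @param model_ids Propensity models to fit, a subset of 1..8 (see
#'   [covariate_set_sources()]).
#' @param schemes Weighting schemes, a subset of
#'   `c("iptw", "overlap", "matching")`.
#' @param prevalence_min Prevalence screen threshold.
#' @param denylist Feature names to exclude after screening, or the string
#'   `"truth_ivs"` to derive the denylist from the simulation truth's planted
#'   instrumental codes (simulations only).
#' @param iv_top_k How many top treatment-correlated features to report for
#'   instrument review.
#' @param n_folds Cross-fitting folds for the propensity models.
#' @param k Clusters per embedding scheme; `embed_dim` the embedding
#'   dimension of the built-in hash providers.
#' @param n_max Maximum n-gram order.
#' @param lex Optional [lexicon()]; when model 5 is requested and `lex` is
#'   `NULL`, a synthetic frequency-based lexicon is built from the cohort's
#'   own vocabulary.
#' @param cluster_args Extra arguments for [cluster_features()].
#' @param compute_balance Compute balance tables per cell (default TRUE).
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @param seed Master seed; all stage seeds are derived from it via
#'   [derive_seed()].
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       cohort_dir = NULL,
                       model_ids = 1:8,
                       schemes = c("iptw", "overlap", "matching"),
                       prevalence_min = 0.01,
                       denylist = NULL,
                       iv_top_k = 20,
                       n_folds = 10,
                       k = 20,
                       embed_dim = 16,
                       n_max = 2,
                       lex = NULL,
                       cluster_args = list(),
                       compute_balance = TRUE,
                       output_dir = NULL,
                       seed = 1L) {
  if (is.null(sim) && is.null(cohort_dir)) {
    abort("Provide either `sim` (generate) or `cohort_dir` (ingest).")
  }
  if (length(model_ids) == 0 || !all(model_ids %in% 1:8)) {
    abort("`model_ids` must be a non-empty subset of 1..8.")
  }
  schemes <- match.arg(schemes, c("iptw", "overlap", "matching"),
                       several.ok = TRUE)
  structure(
    list(sim = sim, cohort_dir = cohort_dir, model_ids = sort(unique(model_ids)),
         schemes = schemes, prevalence_min = prevalence_min,
         denylist = denylist, iv_top_k = iv_top_k, n_folds = n_folds,
         k = k, embed_dim = embed_dim, n_max = n_max, lex = lex,
         cluster_args = cluster_args, compute_balance = compute_balance,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Frequency-based stand-in lexicon built from the cohort's own note
# vocabulary: the most frequent non-stop unigrams and bigrams, one concept
# each. Used when model 5 is requested on a synthetic cohort without a
# user-supplied lexicon.
synthetic_lexicon <- function(cohort, n_concepts = 60,
                              stopwords = noteps_stopwords()) {
  toks <- tokenize(cohort$notes$text)
  if (is.character(toks)) toks <- list(toks)
  toks <- lapply(toks, function(t) t[!t %in% stopwords])
  uni <- unlist(toks, use.names = FALSE)
  bi <- unlist(lapply(toks, function(t) {
    if (length(t) < 2) character(0) else paste(t[-length(t)], t[-1])
  }), use.names = FALSE)
  n_uni <- ceiling(n_concepts * 2 / 3)
  pick <- function(x, m) {
    tab <- sort(table(x), decreasing = TRUE)
    names(head(tab, m))
  }
  terms <- c(pick(uni, n_uni), pick(bi, n_concepts - n_uni))
  if (length(terms) == 0) abort("Cohort notes are empty; cannot build a lexicon.")
  lexicon(terms, sprintf("C%04d", seq_along(terms)))
}

#' Run the full adjustment experiment on one cohort
#'
#' Executes the stages in order — generate or ingest the cohort, build the
#' union of requested covariate blocks, screen by prevalence and denylist,
#' fit a cross-fitted LASSO propensity model per covariate set, apply each
#' weighting scheme, and compute balance tables and weighted Cox effect
#' estimates — always including the unadjusted estimate (unit weights
#' through the same code path). A failure in one (model, scheme) cell is
#' recorded and the run continues.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with tibbles `effects`, `ps_diagnostics`,
#'   `balance_summary`, `iv_candidates`, `screen`, list `balance_tables`,
#'   tibble `failures`, plus `cohort_summary`, `config`, `seeds` and
#'   `config_hash`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(
    sim = derive_seed(config$seed, 1),
    folds = derive_seed(config$seed, 2),
    cluster = derive_seed(config$seed, 3)
  )

  cohort <- if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- seeds$sim
    simulate_cohort(sim)
  } else {
    read_cohort(config$cohort_dir)
  }
  A <- cohort$patients$A

  sources_needed <- unique(unlist(lapply(config$model_ids, covariate_set_sources)))
  lex <- config$lex
  if ("lexicon" %in% sources_needed && is.null(lex)) {
    lex <- synthetic_lexicon(cohort)
  }
  fm <- build_feature_matrix(
    cohort, sources = sources_needed, n_max = config$n_max, lex = lex,
    k = config$k, embed_dim = config$embed_dim, seed = seeds$cluster,
    cluster_args = config$cluster_args
  )

  fm_screened <- prevalence_filter(fm, config$prevalence_min)
  screen <- attr(fm_screened, "screen")
  iv_candidates <- rank_iv_candidates(fm_screened, A, top_k = config$iv_top_k)
  denylist <- config$denylist
  if (identical(denylist, "truth_ivs")) {
    if (is.null(cohort$truth)) {
      abort("`denylist = \"truth_ivs\"` requires a generated cohort with truth.")
    }
    denylist <- cohort$truth$iv_feature_ids
  }
  if (length(denylist) > 0) {
    fm_screened <- suppressWarnings(apply_denylist(fm_screened, denylist))
  }
  screen$n_after_denylist <- ncol(fm_screened$values)

  effects <- list(tidy(weighted_cox(
    cohort$patients$time_days, cohort$patients$event, A,
    scheme = "unadjusted"
  )))
  ps_diag <- list()
  balance_tables <- list()
  balance_summaries <- list()
  failures <- list()

  for (m in config$model_ids) {
    cell <- paste0("model", m)
    srcs <- covariate_set_sources(m)
    fm_m <- fm_subset(fm_screened, fm_screened$meta$source %in% srcs)
    fit <- tryCatch(
      crossfit_lasso_ps(fm_m, A, n_folds = config$n_folds,
                        seed = derive_seed(seeds$folds, m)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures[[cell]] <- tibble(model_id = m, scheme = NA_character_,
                                 stage = "propensity",
                                 message = conditionMessage(fit))
      next
    }
    ps_diag[[cell]] <- mutate(glance(fit), model_id = m, .before = 1)
    cand <- fm_screened$meta$source %in% srcs
    for (s in config$schemes) {
      cell_s <- paste(cell, s, sep = "_")
      res <- tryCatch({
        w <- compute_weights(fit$ps, A, s)
        est <- weighted_cox(cohort$patients$time_days, cohort$patients$event,
                            A, w, scheme = s, model_id = m)
        bt <- if (config$compute_balance) {
          balance_table(fm_screened, cand, A, w)
        }
        list(est = est, bt = bt)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[cell_s]] <- tibble(model_id = m, scheme = s,
                                     stage = "effects",
                                     message = conditionMessage(res))
        next
      }
      effects[[cell_s]] <- tidy(res$est)
      if (!is.null(res$bt)) {
        balance_tables[[cell_s]] <- res$bt
        balance_summaries[[cell_s]] <- mutate(glance(res$bt),
                                              model_id = m, scheme = s,
                                              .before = 1)
      }
    }
  }

  report <- structure(
    list(
      effects = list_rbind(effects),
      ps_diagnostics = list_rbind(unname(ps_diag)),
      balance_summary = list_rbind(unname(balance_summaries)),
      balance_tables = balance_tables,
      iv_candidates = iv_candidates,
      screen = screen,
      failures = if (length(failures) > 0) list_rbind(unname(failures)) else
        tibble(model_id = integer(), scheme = character(),
               stage = character(), message = character()),
      cohort_summary = summarize_cohort(cohort),
      beta_true = cohort$truth$beta_true %||% NA_real_,
      config = config, seeds = seeds,
      config_hash = config_hash(config)
    ),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  hash_string(paste(deparse(cfg), collapse = ""), seed = 0L)
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", nrow(x$effects), "effect estimates,",
      nrow(x$failures), "failed cells\n")
  print(x$effects)
  invisible(x)
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$effects, file.path(dir, "effects.csv"), row.names = FALSE)
  write.csv(report$iv_candidates, file.path(dir, "iv_candidates.csv"),
            row.names = FALSE)
  if (nrow(report$ps_diagnostics) > 0) {
    jsonlite::write_json(report$ps_diagnostics,
                         file.path(dir, "ps_diagnostics.json"), digits = NA)
  }
  jsonlite::write_json(
    c(as.list(report$screen), list(config_hash = report$config_hash)),
    file.path(dir, "screen_report.json"), auto_unbox = TRUE, digits = NA
  )
  if (nrow(report$balance_summary %||% tibble()) > 0) {
    write.csv(report$balance_summary, file.path(dir, "balance_summary.csv"),
              row.names = FALSE)
  }
  for (nm in names(report$balance_tables)) {
    write.csv(report$balance_tables[[nm]],
              file.path(dir, paste0("balance_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Monte-Carlo replication harness
#'
#' Repeats [run_experiment()] over independently seeded replicates and
#' summarizes, per (model, scheme): mean and empirical SE of the log hazard
#' ratio, bias against the true effect, robust-CI coverage of the truth,
#' mean AUC/NLL, and balance-violation rates (mean fraction of features with
#' weighted |SD| at or above the threshold, and the proportion of replicates
#' with none). Failed replicates are dropped and counted.
#'
#' @param config A [run_config()] (its `seed` is replaced per replicate).
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Seed from which per-replicate seeds are derived.
#' @return List with `summary` (tibble per model/scheme), `effects` (all
#'   per-replicate estimates), `ps_diagnostics`, `balance`, `n_failed`.
#' @export
replicate_experiment <- function(config, n_reps, base_seed = 1L) {
  stopifnot(inherits(config, "run_config"), n_reps >= 1)
  eff <- list()
  diag <- list()
  bal <- list()
  n_failed <- 0L
  beta_true <- NA_real_
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, r)
    cfg$output_dir <- NULL
    rep_out <- tryCatch(run_experiment(cfg), error = function(e) e)
    if (inherits(rep_out, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    beta_true <- rep_out$beta_true
    eff[[r]] <- mutate(rep_out$effects, rep = r)
    if (nrow(rep_out$ps_diagnostics %||% tibble()) > 0) {
      diag[[r]] <- mutate(rep_out$ps_diagnostics, rep = r)
    }
    if (nrow(rep_out$balance_summary %||% tibble()) > 0) {
      bal[[r]] <- mutate(rep_out$balance_summary, rep = r)
    }
  }
  effects <- list_rbind(eff[!vapply(eff, is.null, logical(1))])
  diagnostics <- list_rbind(diag[!vapply(diag, is.null, logical(1))])
  balance <- list_rbind(bal[!vapply(bal, is.null, logical(1))])

  summ <- effects |>
    group_by(.data$model_id, .data$scheme) |>
    summarise(
      n_reps = dplyr::n(),
      mean_log_hr = mean(.data$log_hr),
      se_empirical = sd(.data$log_hr),
      mc_se = sd(.data$log_hr) / sqrt(dplyr::n()),
      bias = mean(.data$log_hr) - beta_true,
      mean_abs_bias = abs(mean(.data$log_hr) - beta_true),
      coverage = mean(.data$ci_low <= exp(beta_true) &
                        exp(beta_true) <= .data$ci_high),
      .groups = "drop"
    )
  if (nrow(diagnostics) > 0) {
    summ <- left_join(
      summ,
      diagnostics |>
        group_by(.data$model_id) |>
        summarise(mean_auc = mean(.data$auc), mean_nll = mean(.data$nll),
                  mean_n_selected = mean(.data$n_selected), .groups = "drop"),
      by = "model_id"
    )
  }
  if (nrow(balance) > 0) {
    summ <- left_join(
      summ,
      balance |>
        group_by(.data$model_id, .data$scheme) |>
        summarise(
          mean_frac_imbalanced = mean(.data$n_imbalanced_weighted / .data$n_features),
          prop_all_balanced = mean(.data$n_imbalanced_weighted == 0),
          .groups = "drop"
        ),
      by = c("model_id", "scheme")
    )
  }
  list(summary = summ, effects = effects, ps_diagnostics = diagnostics,
       balance = balance, n_failed = n_failed, beta_true = beta_true)
}
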