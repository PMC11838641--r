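# Feature screening: prevalence filter and instrumental-variable ranking.

#' Remove low-prevalence code and NLP features
#'
#' Drops binary code/NLP columns whose prevalence is strictly below
#' `prevalence_min` (default 0.01). Researcher-specified columns and
#' continuous columns are exempt: the screen applies only to automatically
#' generated claims/EHR/NLP indicators. Idempotent, and commutes with
#' [apply_denylist()].
#'
#' @param fm A `feature_matrix`.
#' @param prevalence_min Prevalence threshold in `[0, 1]`; columns at exactly
#'   the threshold are retained (strict inequality).
#' @return The filtered `feature_matrix`, with an attribute `screen` holding
#'   a one-row tibble (`n_input`, `n_after_prevalence`).
#' @export
prevalence_filter <- function(fm, prevalence_min = 0.01) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (prevalence_min < 0 || prevalence_min > 1) {
    abort("`prevalence_min` must lie in [0, 1].")
  }
  drop <- fm$meta$binary &
    fm$meta$source != "researcher" &
    fm$meta$prevalence < prevalence_min
  out <- fm_subset(fm, !drop)
  attr(out, "screen") <- tibble(
    n_input = ncol(fm$values),
    n_after_prevalence = ncol(out$values)
  )
  out
}

#' Rank features by marginal correlation with treatment
#'
#' Candidate-instrument surfacing: features most strongly associated with
#' treatment choice are ranked for review, since instruments (strong
#' treatment predictors with no outcome effect except through treatment)
#' harm causal effect estimates when adjusted for. For binary features the
#' statistic is the phi coefficient (Pearson correlation of two binaries);
#' continuous features use the point-biserial correlation. Constant features
#' get correlation 0 and are flagged.
#'
#' @param fm A `feature_matrix`.
#' @param A Binary treatment vector aligned with the rows of `fm`.
#' @param top_k Number of top-ranked features to return (default all).
#' @return Tibble (feature, source, correlation, abs_correlation, constant)
#'   in descending `abs_correlation`, ties broken by feature name.
#' @export
rank_iv_candidates <- function(fm, A, top_k = Inf) {
  stopifnot(inherits(fm, "feature_matrix"))
  A <- check_binary_treatment(A)
  V <- fm$values
  if (nrow(V) != length(A)) abort("`A` must have one entry per patient row.")
  n <- nrow(V)
  mA <- mean(A)
  vA <- mA * (1 - mA)
  mx <- Matrix::colMeans(V)
  ex2 <- Matrix::colMeans(V^2)
  vx <- ex2 - mx^2
  cov_xa <- as.numeric(Matrix::crossprod(V, A)) / n - mx * mA
  const <- vx <= 0 | vA <= 0
  corr <- ifelse(const, 0, cov_xa / sqrt(pmax(vx, .Machine$double.eps) * max(vA, .Machine$double.eps)))
  out <- tibble(
    feature = fm$meta$feature,
    source = fm$meta$source,
    correlation = corr,
    abs_correlation = abs(corr),
    constant = const
  ) |>
    arrange(desc(.data$abs_correlation), .data$feature)
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Remove denylisted features
#'
#' Machine-interface counterpart of manual instrument review: named columns
#' are removed from the candidate set. Unknown names are ignored with a
#' warning.
#'
#' @param fm A `feature_matrix`.
#' @param denylist Character vector of feature names to exclude.
#' @return The filtered `feature_matrix`.
#' @export
apply_denylist <- function(fm, denylist) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(denylist) == 0) return(fm)
  unknown <- setdiff(denylist, fm$meta$feature)
  if (length(unknown) > 0) {
    warn(paste0("Denylist names not present (ignored): ",
                paste(head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else ""))
  }
  fm_subset(fm, !(fm$meta$feature %in% denylist))
}
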