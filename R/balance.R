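# Standardized-difference covariate balance, before and after weighting.

#' Absolute standardized difference of a covariate between arms
#'
#' The scale-free two-group difference
#' `d = |m1 - m0| / sqrt((v1 + v0) / 2)`, where for a binary covariate the
#' arm moments are (weighted) prevalences with variance `p(1 - p)` and for a
#' continuous covariate (weighted) means and variances. Weighting changes
#' the moments, not the formula; the unweighted case is `w = 1`.
#'
#' @param x Covariate vector (binary 0/1 or continuous).
#' @param A Binary treatment vector.
#' @param w Optional non-negative weights with positive sums in both arms.
#' @return Non-negative scalar; 0 when both arms are constant and equal,
#'   `Inf` (with a warning) when the pooled variance is zero but means
#'   differ.
#' @export
standardized_difference <- function(x, A, w = NULL) {
  A <- check_binary_treatment(A)
  if (is.null(w)) w <- rep(1, length(A))
  if (any(w < 0)) abort("Weights must be non-negative.")
  w1 <- w * (A == 1)
  w0 <- w * (A == 0)
  if (sum(w1) <= 0 || sum(w0) <= 0) {
    abort("Both arms must carry positive total weight.")
  }
  m1 <- sum(w1 * x) / sum(w1)
  m0 <- sum(w0 * x) / sum(w0)
  v1 <- sum(w1 * x^2) / sum(w1) - m1^2
  v0 <- sum(w0 * x^2) / sum(w0) - m0^2
  pooled <- (v1 + v0) / 2
  if (pooled <= 0) {
    if (isTRUE(all.equal(m1, m0))) return(0)
    warn("Zero pooled variance with differing means; standardized difference is Inf.")
    return(Inf)
  }
  abs(m1 - m0) / sqrt(pooled)
}

#' Covariate balance table over all features
#'
#' Computes unweighted and weighted absolute standardized differences for
#' every feature in the matrix, with a flag marking which features were
#' candidate predictors of the propensity model under assessment. Balance is
#' deliberately assessed on *all* features — including those not available
#' to the model — to measure how well the weights control proxies the model
#' never saw.
#'
#' @param fm_all `feature_matrix` holding the union of all covariate sets.
#' @param candidate Logical vector per feature, or character vector of
#'   candidate feature names.
#' @param A Binary treatment vector.
#' @param w Optional weights (default unweighted).
#' @param threshold Reporting threshold for adequate balance (default 0.1);
#'   a flag, never a filter.
#' @return A `balance_table` tibble (feature, source, candidate,
#'   sd_unweighted, sd_weighted) with the threshold stored as an attribute.
#' @export
balance_table <- function(fm_all, candidate, A, w = NULL, threshold = 0.1) {
  stopifnot(inherits(fm_all, "feature_matrix"))
  A <- check_binary_treatment(A)
  V <- fm_all$values
  if (nrow(V) != length(A)) abort("`A` must align with the feature rows.")
  if (is.character(candidate)) candidate <- fm_all$meta$feature %in% candidate
  candidate <- rep_len(as.logical(candidate), ncol(V))
  if (is.null(w)) w <- rep(1, length(A))

  sd_all <- function(wt) {
    w1 <- wt * (A == 1)
    w0 <- wt * (A == 0)
    m1 <- as.numeric(Matrix::crossprod(V, w1)) / sum(w1)
    m0 <- as.numeric(Matrix::crossprod(V, w0)) / sum(w0)
    v1 <- as.numeric(Matrix::crossprod(V^2, w1)) / sum(w1) - m1^2
    v0 <- as.numeric(Matrix::crossprod(V^2, w0)) / sum(w0) - m0^2
    pooled <- pmax((v1 + v0) / 2, 0)
    d <- abs(m1 - m0) / sqrt(pooled)
    d[pooled <= 0] <- ifelse(abs(m1 - m0)[pooled <= 0] < 1e-12, 0, Inf)
    d
  }

  out <- tibble(
    feature = fm_all$meta$feature,
    source = fm_all$meta$source,
    candidate = candidate,
    sd_unweighted = sd_all(rep(1, length(A))),
    sd_weighted = sd_all(w)
  )
  structure(out, class = c("balance_table", class(tibble())),
            threshold = threshold,
            scheme = attr(w, "scheme") %||% "unweighted")
}

#' @describeIn balance_table Summary counts of imbalanced features
#'   (weighted SD at or above the threshold), split by candidate flag.
#' @param x A `balance_table`.
#' @param ... Unused.
#' @method glance balance_table
#' @export
glance.balance_table <- function(x, ...) {
  thr <- attr(x, "threshold")
  tibble(
    n_features = nrow(x),
    n_candidate = sum(x$candidate),
    n_imbalanced_weighted = sum(x$sd_weighted >= thr),
    n_imbalanced_candidate = sum(x$sd_weighted >= thr & x$candidate),
    n_imbalanced_noncandidate = sum(x$sd_weighted >= thr & !x$candidate),
    max_sd_weighted = max(x$sd_weighted),
    threshold = thr
  )
}

#' Balance scatter plot (candidate vs non-candidate features)
#'
#' Unweighted vs weighted absolute standardized differences, one point per
#' feature; candidate predictors in black, features unavailable to the model
#' in orange; dashed lines mark the adequacy threshold.
#'
#' @param object A `balance_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot balance_table
#' @export
autoplot.balance_table <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot(object, aes(x = .data$sd_unweighted, y = .data$sd_weighted,
                     colour = .data$candidate)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey80") +
    geom_hline(yintercept = thr, linetype = "dashed") +
    geom_point(alpha = 0.6, size = 1.2) +
    scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "darkorange"),
      labels = c(`TRUE` = "candidate", `FALSE` = "not available to model"),
      name = NULL
    ) +
    labs(
      x = "|standardized difference|, unweighted",
      y = sprintf("|standardized difference|, %s-weighted", attr(object, "scheme")),
      title = "Covariate balance before and after weighting"
    ) +
    theme_minimal()
}
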