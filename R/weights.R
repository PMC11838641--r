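# The three propensity-score weighting schemes.

#' Propensity-score weights (IPTW, overlap, matching)
#'
#' Exact per-patient evaluation of the three weighting schemes, with `A` the
#' binary treatment and `ps` the estimated propensity score:
#'
#' * IPTW: `w = A/ps + (1 - A)/(1 - ps)` — targets the whole population.
#' * Overlap: `w = A(1 - ps) + (1 - A)ps` — emphasizes clinical equipoise.
#' * Matching: `w = A min(ps, 1-ps)/ps + (1 - A) min(ps, 1-ps)/(1 - ps)` —
#'   the weighting analogue of 1:1 propensity matching.
#'
#' @param ps Propensity scores strictly inside (0, 1) (clip upstream).
#' @param A Binary treatment vector.
#' @param scheme One of `"iptw"`, `"overlap"`, `"matching"`.
#' @return A numeric weight vector of class `noteps_weights` with attribute
#'   `scheme`. IPTW weights are >= 1, overlap weights in (0, 1), matching
#'   weights in (0, 1].
#' @examples
#' compute_weights(c(0.25, 0.25), c(1, 0), "iptw")
#' @export
compute_weights <- function(ps, A, scheme = c("iptw", "overlap", "matching")) {
  scheme <- match.arg(scheme)
  A <- check_binary_treatment(A)
  if (length(ps) != length(A)) abort("`ps` and `A` must have equal length.")
  if (any(ps <= 0 | ps >= 1)) {
    abort("`ps` must lie strictly inside (0, 1); clip the scores upstream.")
  }
  w <- switch(scheme,
    iptw = A / ps + (1 - A) / (1 - ps),
    overlap = A * (1 - ps) + (1 - A) * ps,
    matching = A * pmin(ps, 1 - ps) / ps + (1 - A) * pmin(ps, 1 - ps) / (1 - ps)
  )
  structure(w, class = "noteps_weights", scheme = scheme)
}

#' @method print noteps_weights
#' @export
print.noteps_weights <- function(x, ...) {
  cat("<noteps_weights>", attr(x, "scheme"), "n =", length(x), "\n")
  print(summary(unclass(x)))
  invisible(x)
}
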