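# Independent oracle implementations used to check the package's code paths.
# These deliberately avoid the functions they verify.

# Breslow-tie weighted Cox partial log-likelihood for a single binary
# covariate, maximized by golden-section search (independent of coxph and of
# the package's weighted_cox()).
oracle_cox_loglik <- function(beta, time, event, A, w) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (beta * A[i] - log(sum(w[risk] * exp(beta * A[risk]))))
  }
  ll
}

oracle_cox_mle <- function(time, event, A, w = rep(1, length(A))) {
  stats::optimize(oracle_cox_loglik, c(-6, 6), maximum = TRUE,
                  tol = 1e-10, time = time, event = event, A = A, w = w)$maximum
}

# Direct evaluation of the three weighting formulas, written independently
# (scalar loop, no pmin/vector tricks shared with the implementation).
oracle_weight <- function(ps, A, scheme) {
  vapply(seq_along(ps), function(i) {
    p <- ps[i]
    m <- min(p, 1 - p)
    if (A[i] == 1) {
      switch(scheme, iptw = 1 / p, overlap = 1 - p, matching = m / p)
    } else {
      switch(scheme, iptw = 1 / (1 - p), overlap = p, matching = m / (1 - p))
    }
  }, numeric(1))
}

# Phi coefficient from the 2x2 contingency table (independent formula).
oracle_phi <- function(x, a) {
  n11 <- sum(x == 1 & a == 1); n10 <- sum(x == 1 & a == 0)
  n01 <- sum(x == 0 & a == 1); n00 <- sum(x == 0 & a == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# Standardized difference via explicit per-arm moments.
oracle_smd <- function(p1, p0) abs(p1 - p0) / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)

# Exact best 2-means objective: Lloyd's algorithm run to convergence from
# every pair of points as initial centers.
oracle_best_2means <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      centers <- X[c(i, j), , drop = FALSE]
      for (it in 1:100) {
        d1 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
        d2 <- rowSums((X - matrix(centers[2, ], n, ncol(X), byrow = TRUE))^2)
        a <- ifelse(d1 <= d2, 1, 2)
        if (length(unique(a)) < 2) break
        new_centers <- rbind(colMeans(X[a == 1, , drop = FALSE]),
                             colMeans(X[a == 2, , drop = FALSE]))
        if (max(abs(new_centers - centers)) < 1e-12) {
          centers <- new_centers
          break
        }
        centers <- new_centers
      }
      d1 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- rowSums((X - matrix(centers[2, ], n, ncol(X), byrow = TRUE))^2)
      best <- min(best, sum(pmin(d1, d2)))
    }
  }
  best
}

# Small deterministic survival fixture: 20 patients, distinct times.
cox_fixture <- function() {
  set.seed(42)
  n <- 20
  A <- rep(c(1, 0), each = 10)
  time <- round(rexp(n, 0.02) + 1, 3)
  time <- time + seq_len(n) * 1e-4 # guarantee distinct times
  event <- rbinom(n, 1, 0.7)
  event[c(1, 11)] <- 1 # at least one event per arm
  data.frame(time = time, event = event, A = A)
}

# Tiny hand-built cohort for feature-level tests.
tiny_cohort <- function(notes_text = NULL) {
  patients <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:4),
    A = c(1, 1, 0, 0),
    time_days = c(50, 183, 120, 183),
    event = c(1, 0, 0, 0),
    age = c(70, 65, 80, 75),
    sex = c(1, 0, 1, 0)
  )
  codes <- tibble::tibble(
    patient_id = c("p01", "p02", "p02", "p03"),
    code = c("clm_0001", "clm_0001", "clm_0002", "ehr_0001"),
    domain = c("claims", "claims", "claims", "ehr")
  )
  if (is.null(notes_text)) {
    notes_text <- c("chest pain in the morning", "no pain today")
  }
  notes <- tibble::tibble(
    patient_id = c("p01", "p02")[seq_along(notes_text)],
    note_id = sprintf("n%02d", seq_along(notes_text)),
    day_offset = rep(-30L, length(notes_text)),
    text = notes_text
  )
  structure(
    list(patients = patients, codes = codes, notes = notes,
         truth = NULL, config = NULL),
    class = "noteps_cohort"
  )
}
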