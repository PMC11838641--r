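# Mini-batch k-means. Deterministic given the seed; k-means++ initialization;
# per-centre learning-rate updates as in the usual mini-batch scheme.
# (stats::kmeans provides only full-batch Lloyd/Hartigan-Wong and is used as
# a small-instance cross-check in the test suite, not here.)

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (c in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1, prob = probs)
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[c, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# Nearest-centre assignment; ties broken by lowest cluster index.
assign_nearest <- function(X, centers) {
  cross <- X %*% t(centers)
  cn <- rowSums(centers^2)
  d2 <- matrix(cn, nrow(X), nrow(centers), byrow = TRUE) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' Mini-batch k-means clustering
#'
#' @param X Numeric matrix (units x dim).
#' @param k Number of clusters (>= 1, <= distinct rows).
#' @param seed Integer seed (initialization and batch sampling).
#' @param batch_size Mini-batch size; batches larger than `nrow(X)` use the
#'   full data each iteration.
#' @param iters Number of mini-batch update iterations.
#' @param nstart Number of random restarts; the run with the lowest
#'   within-cluster sum of squares on the full data is kept.
#' @return A `cluster_model`: list with `k`, `centroids` (k x dim), `seed`,
#'   and the achieved objective `tot_withinss`.
#' @export
minibatch_kmeans <- function(X, k, seed = 1L, batch_size = 1024,
                             iters = 100, nstart = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(unique(X))) {
    abort("`k` exceeds the number of distinct units to cluster.")
  }
  b <- min(batch_size, n)
  run_once <- function() {
    centers <- kmeanspp_init(X, k)
    counts <- rep(0, k)
    for (it in seq_len(iters)) {
      idx <- if (b == n) seq_len(n) else sample.int(n, b)
      B <- X[idx, , drop = FALSE]
      a <- assign_nearest(B, centers)
      for (c in unique(a)) {
        rows <- a == c
        m <- sum(rows)
        counts[c] <- counts[c] + m
        eta <- m / counts[c]
        centers[c, ] <- (1 - eta) * centers[c, ] +
          eta * colMeans(B[rows, , drop = FALSE])
      }
    }
    a_full <- assign_nearest(X, centers)
    obj <- sum((X - centers[a_full, , drop = FALSE])^2)
    list(centers = centers, obj = obj)
  }
  best <- with_seed(seed, {
    best <- run_once()
    if (nstart > 1) {
      for (r in 2:nstart) {
        cand <- run_once()
        if (cand$obj < best$obj) best <- cand
      }
    }
    best
  })
  structure(
    list(k = as.integer(k), centroids = best$centers, seed = as.integer(seed),
         tot_withinss = best$obj),
    class = "cluster_model"
  )
}

#' Assign units to the clusters of a fitted model
#'
#' @param model A `cluster_model` from [minibatch_kmeans()].
#' @param X Numeric matrix of units to assign.
#' @return Integer vector of cluster indices in `1..k`; ties go to the
#'   lowest index.
#' @export
assign_clusters <- function(model, X) {
  stopifnot(inherits(model, "cluster_model"))
  assign_nearest(as.matrix(X), model$centroids)
}
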