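# Internal helpers: seeding, RNG hygiene, light assertions.

# Park-Miller step via Schrage's trick; exact in double arithmetic.
pm_next <- function(s) {
  hi <- s %/% 127773
  lo <- s %% 127773
  t <- 16807 * lo - 2836 * hi
  if (t <= 0) t + 2147483647 else t
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out so pipeline stages (generation, folds, clustering)
#' get independent, reproducible seeds from one user-supplied master seed.
#' Child seeds always lie in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stream index (stage counter).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), index >= 0)
  s <- (abs(as.double(master)) + as.double(index) * 1000003) %% 2147483646 + 1
  s <- pm_next(s)
  s <- pm_next(s)
  as.integer(s)
}

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

is_binary_vec <- function(x) {
  x <- x[!is.na(x)]
  all(x == 0 | x == 1)
}

check_binary_treatment <- function(A) {
  if (!is.numeric(A) || !is_binary_vec(A)) {
    abort("`A` must be a binary (0/1) treatment vector.")
  }
  invisible(as.numeric(A))
}

# Deterministic 31-bit string hash (polynomial, then two Park-Miller steps
# mixed with `seed`). Platform-independent.
hash_string <- function(x, seed = 0L) {
  h <- 0
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% 2147483647
  }
  h <- (h + abs(as.double(seed))) %% 2147483646 + 1
  h <- pm_next(h)
  as.integer(pm_next(h))
}
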