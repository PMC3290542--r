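# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores
#' the previous RNG state afterwards, so library calls never perturb a
#' caller's random stream. A \code{NULL} seed evaluates the code unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  force(code)
}

# Derive a bounded sub-seed from a master seed; offsets keep the streams of
# the individual generators distinct but reproducible.
sub_seed <- function(seed, offset) {
  as.integer((abs(seed) + 7919 * offset) %% (.Machine$integer.max - 1L))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Competition ranking (1 + number of strictly larger values); ties share the
# best rank, as in "ranks in the top k".
competition_rank <- function(x) {
  vapply(x, function(v) 1L + sum(x > v), integer(1))
}

# All permutations of 1..n as a list; only used for exhaustive permutation
# nulls at tiny n.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Rescale a signed vector so that max(|x|) == 1; an all-zero vector is
# returned unchanged.
rescale_max_abs <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score recovery of planted network modules; 1 means identical
#' partitions, 0 is the expected agreement of random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \eqn{[-1, 1]}.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
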