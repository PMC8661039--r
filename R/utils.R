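#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Each stochastic stage (cohort generation, SOM initialisation, k-means
#' restarts, train/test split, bootstrap resampling, ...) draws its own
#' seed from the master seed and a stage label, so stages are decoupled:
#' changing the number of draws in one stage does not perturb another.
#'
#' The stream seed is a 31-bit hash of the label folded into the master
#' seed (multiplicative string hash mod 2^31 - 1), stable across platforms.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. `"som"` or `"bootstrap"`.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(11, "som")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (cc in utf8ToInt(label)) h <- (h * 31 + cc) %% m
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.  Used to score recovery of planted subgroups.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the adjusted Rand index, a single number `<= 1`.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(if (sij == expected) 1 else 0)
  (sij - expected) / denom
}

#' Integer percentage with half-up rounding
#'
#' Display convention for descriptive tables: `round(100 * count / n)`
#' with halves rounded up (so 0.5 -> 1), as in printed cohort tables.
#'
#' @param count numerator count(s).
#' @param n group size.
#' @return integer percentage(s).
#' @export
#' @examples
#' percent_of(269, 379) # 71
percent_of <- function(count, n) {
  stopifnot(all(count >= 0), n > 0, all(count <= n))
  as.integer(floor(100 * count / n + 0.5))
}

# round half up to `digits`; base round() uses banker's rounding
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared Euclidean cross-distance between rows of two matrices
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
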