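# small, fast study configuration used across unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(n_group1 = 25, n_group2 = 50, n_comparison = 50,
               n_predictors_per_sweep = 75, missing_cell_rate = 0.01,
               heavy_missing_rate = 0.04, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# canonical row order for comparing cohort record tables
sort_records <- function(r) {
  r <- r[order(r$participant_id, r$sweep_age, r$variable_id), ]
  rownames(r) <- NULL
  r
}

# brute-force silhouette: literal definition, pairwise loops
brute_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mine <- setdiff(which(labels == own), i)
    if (!length(mine)) { s[i] <- 0; next }
    a <- mean(vapply(mine, function(j) d(i, j), 0))
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# two far-separated Gaussian clouds, for clustering checks
two_clouds <- function(n_per = 20, sep = 20, d = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  rownames(x) <- sprintf("pt%02d", seq_len(2 * n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}
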