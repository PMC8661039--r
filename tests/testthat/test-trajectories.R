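test_that("GG epsilon hits its analytic limits", {
  expect_equal(gg_epsilon(diag(4)), 1)           # perfect sphericity
  s2 <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  expect_equal(gg_epsilon(s2), 1)                # m = 2 is always 1
  expect_error(gg_epsilon(matrix(1, 1, 1)), "at least 2")
})

test_that("GG epsilon matches a first-principles eigenvalue computation", {
  set.seed(14)
  for (rep in 1:10) {
    a <- matrix(rnorm(16), 4, 4)
    s <- crossprod(a) + diag(4)
    # oracle: epsilon from the eigenvalues of the double-centered matrix
    m <- 4
    cc <- (diag(m) - 1 / m) %*% s %*% (diag(m) - 1 / m)
    lam <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    oracle <- sum(lam)^2 / ((m - 1) * sum(lam^2))
    oracle <- min(1, max(1 / (m - 1), oracle))
    expect_equal(gg_epsilon(s), oracle, tolerance = 1e-12)
    expect_gte(gg_epsilon(s), 1 / 3)
    expect_lte(gg_epsilon(s), 1)
  }
})

test_that("toy split-plot ANOVA matches hand-computed sums of squares", {
  # 2 groups x 3 participants x 2 ages; with 2 repeated measures the
  # interaction F equals the one-way F on difference scores
  scores <- rbind(c(1, 3), c(2, 5), c(3, 4),   # group A
                  c(4, 4), c(5, 7), c(6, 5))   # group B
  d <- scores[, 2] - scores[, 1]               # 2,3,1, 0,2,-1
  g <- rep(c("A", "B"), each = 3)
  dbar_a <- mean(d[1:3]); dbar_b <- mean(d[4:6]); dbar <- mean(d)
  ss_between <- 3 * (dbar_a - dbar)^2 + 3 * (dbar_b - dbar)^2
  ss_within <- sum((d[1:3] - dbar_a)^2) + sum((d[4:6] - dbar_b)^2)
  f_hand <- (ss_between / 1) / (ss_within / 4)
  long <- data.frame(participant = rep(1:6, times = 2),
                     group = rep(g, times = 2),
                     time = rep(c(5, 7), each = 6),
                     score = c(scores[, 1], scores[, 2]))
  res <- mixed_anova_gg(long)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$epsilon, 1)                 # m = 2
  expect_equal(res$p_gg, res$p_uncorrected)
})

test_that("F is invariant to shifting and scaling the scores", {
  set.seed(3)
  long <- expand.grid(participant = 1:40, time = c(5, 7, 11, 14))
  long$group <- rep(rep(c("g1", "g2"), each = 20), times = 4)
  long$score <- rnorm(nrow(long)) + as.numeric(long$time) * (long$group == "g1")
  base <- mixed_anova_gg(long)
  shifted <- long; shifted$score <- shifted$score + 100
  scaled <- long; scaled$score <- scaled$score * 7
  expect_equal(mixed_anova_gg(shifted)$F, base$F, tolerance = 1e-9)
  expect_equal(mixed_anova_gg(scaled)$F, base$F, tolerance = 1e-9)
  expect_equal(mixed_anova_gg(scaled)$epsilon, base$epsilon, tolerance = 1e-9)
})

test_that("GG correction never reduces p above F = 1, and is exact under sphericity", {
  set.seed(8)
  for (rep in 1:10) {
    long <- expand.grid(participant = 1:30, time = 1:4)
    long$group <- rep(rep(c("a", "b"), each = 15), times = 4)
    long$score <- rnorm(nrow(long)) +
      0.3 * as.numeric(long$time) * (long$group == "a")
    res <- mixed_anova_gg(long)
    if (res$F >= 1) expect_gte(res$p_gg, res$p_uncorrected)
  }
  # whiten the within-group residuals so the pooled covariance is exactly
  # spherical: corrected and uncorrected tests must then agree
  set.seed(9)
  n <- 40
  y <- matrix(rnorm(n * 4), n, 4)
  g <- rep(c("a", "b"), each = n / 2)
  ctr <- y
  for (gg in c("a", "b")) {
    idx <- g == gg
    ctr[idx, ] <- scale(y[idx, ], center = TRUE, scale = FALSE)
  }
  s_pool <- (crossprod(ctr[g == "a", ]) + crossprod(ctr[g == "b", ])) / (n - 2)
  e <- eigen(s_pool, symmetric = TRUE)
  s_inv_half <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  yw <- ctr %*% s_inv_half
  yw[g == "a", ] <- yw[g == "a", ] + 1   # group offset, no interaction shape
  long <- data.frame(participant = rep(1:n, 4), group = rep(g, 4),
                     time = rep(c(5, 7, 11, 14), each = n),
                     score = as.vector(yw))
  res <- mixed_anova_gg(long)
  expect_equal(res$epsilon, 1, tolerance = 1e-10)
  expect_equal(res$p_gg, res$p_uncorrected, tolerance = 1e-12)
})

test_that("cohort-level trajectory ANOVA flags the planted diverging trajectories", {
  co <- simulate_cohort(cohort_config(n_group1 = 80, n_group2 = 80,
                                      n_comparison = 80, seed = 31))
  ta <- trajectory_anova(co)
  tab <- ta$table
  expect_equal(sort(unique(tab$groups)),
               sort(c("all", "group1 vs group2", "group1 vs comparison",
                      "group2 vs comparison")))
  all_rows <- tab[tab$groups == "all", ]
  expect_equal(nrow(all_rows), 5)
  # group 1 escalates against both other groups in every subdomain
  expect_true(all(all_rows$p_gg < 0.05))
  expect_true(all(tab$epsilon >= 1 / 3 & tab$epsilon <= 1))
  # errors for degenerate designs
  expect_error(mixed_anova_gg(data.frame(participant = 1:4,
                                         group = "a", time = rep(1:2, 2),
                                         score = rnorm(4))),
               "2 groups")
})
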