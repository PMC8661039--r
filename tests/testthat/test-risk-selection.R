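test_that("stratified split hits per-class targets, is deterministic, rejects bad input", {
  ids <- sprintf("p%02d", 1:20)
  y <- rep(c(1, 0), each = 10)
  sp <- split_train_test(ids, y, 0.7, seed = 3)
  expect_equal(sum(y[match(sp$train, ids)] == 1), 7)
  expect_equal(sum(y[match(sp$train, ids)] == 0), 7)
  expect_length(sp$test, 6)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_train_test(ids, y, 0.7, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_test(ids, y, 1.0), "train_fraction")
  expect_error(split_train_test(ids, rep(1, 20), 0.7), "both outcome classes")
  expect_error(split_train_test(ids[1:3], c(1, 0, 0), 0.7), "at least 2 members")
})

test_that("penalty-limit behaviour: huge lambda zeroes all slopes, signal survives CV", {
  set.seed(4)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  xs <- scale(x)
  grid <- c(5, exp(seq(log(0.5), log(0.001), length.out = 20)))
  fit_big <- glmnet::glmnet(xs, y, family = "binomial", lambda = 5,
                            standardize = FALSE)
  expect_true(all(as.numeric(fit_big$beta) == 0))
  fit <- fit_lasso_logistic_cv(xs, y, folds = 5, lambda_grid = grid, seed = 1)
  expect_gt(fit$coef["v1"], 0)
})

test_that("duplicated column coefficients sum to the single-column coefficient", {
  set.seed(7)
  n <- 400
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x1))
  lam <- 0.02
  xs1 <- cbind(a = as.numeric(scale(x1)))
  xs2 <- cbind(a = xs1[, 1], b = xs1[, 1])
  junk <- rnorm(n)
  f1 <- glmnet::glmnet(cbind(xs1, junk = junk), y, family = "binomial",
                       lambda = lam, standardize = FALSE, thresh = 1e-12)
  f2 <- glmnet::glmnet(cbind(xs2, junk = junk), y, family = "binomial",
                       lambda = lam, standardize = FALSE, thresh = 1e-12)
  expect_equal(sum(f2$beta[c("a", "b"), 1]), unname(f1$beta["a", 1]),
               tolerance = 1e-3)
})

test_that("tiny LASSO fit matches a brute-force penalized-likelihood grid search", {
  set.seed(12)
  n <- 30
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * x[, 1] - 0.5 * x[, 2]))
  xs <- scale(x) * sqrt(n / (n - 1))  # population-SD scaling, as glmnet uses
  lam <- 0.05
  fit <- glmnet::glmnet(xs, y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
  got <- c(fit$a0, as.numeric(fit$beta))
  # oracle: direct minimisation of (1/n) * neg-log-lik + lam * (|b1| + |b2|)
  obj <- function(th) {
    eta <- th[1] + xs %*% th[2:3]
    -mean(y * eta - log(1 + exp(eta))) + lam * sum(abs(th[2:3]))
  }
  best <- c(0, 0, 0)
  step <- 1
  for (sweep_i in 1:8) {
    cand <- as.matrix(expand.grid(b0 = best[1] + seq(-5, 5) * step,
                                  b1 = best[2] + seq(-5, 5) * step,
                                  b2 = best[3] + seq(-5, 5) * step))
    vals <- apply(cand, 1, obj)
    best <- cand[which.min(vals), ]
    step <- step / 3
  }
  expect_equal(unname(got), unname(best), tolerance = 1e-3)
})

test_that("bootstrap inclusion frequencies behave at the n_bootstrap = 1 limit", {
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(50, 1, plogis(2 * x[, 1]))
  cfg <- selection_config(n_bootstrap = 1, nlambda = 20, seed = 5)
  boot <- bootstrap_stability(x, y, cfg)
  expect_true(all(boot$frequency %in% c(0, 1)))
})

test_that("inclusion frequencies are invariant to predictor column order", {
  set.seed(3)
  x <- matrix(rnorm(150 * 6), 150, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rbinom(150, 1, plogis(1.5 * x[, 2]))
  cfg <- selection_config(n_bootstrap = 25, nlambda = 20, seed = 9)
  f1 <- bootstrap_stability(x, y, cfg)$frequency
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- bootstrap_stability(x[, perm], y, cfg)$frequency
  expect_equal(f1[paste0("v", 1:6)], f2[paste0("v", 1:6)])
})

test_that("stability threshold is inclusive, monotone, and orders by |beta|", {
  freqs <- c(a = 0.96, b = 0.95, c = 0.94)
  expect_setequal(select_stable(freqs, 0.95), c("a", "b"))
  expect_identical(select_stable(freqs, 1.0), character(0))
  sel_lo <- select_stable(freqs, 0.90)
  sel_hi <- select_stable(freqs, 0.95)
  expect_true(all(sel_hi %in% sel_lo))
  ordered <- select_stable(c(a = 0.99, b = 0.99), 0.95,
                           beta = c(a = 0.1, b = -0.8))
  expect_identical(ordered, c("b", "a"))
  # equal |beta| ties break by variable id
  tied <- select_stable(c(z = 0.99, m = 0.99), 0.95, beta = c(z = 0.5, m = 0.5))
  expect_identical(tied, c("m", "z"))
})

test_that("holdout validation covers empty, degenerate and separable cases", {
  empty <- validate_holdout(character(0), matrix(0, 4, 2), c(0, 1, 0, 1))
  expect_identical(empty$note, "nothing to validate")
  expect_length(empty$survived, 0)

  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  v <- validate_holdout(c("a", "b"), x, y, beta_ref = c(a = 0.8, b = 0.1))
  expect_true("a" %in% v$survived)
  expect_gt(v$accuracy, 0.6)
  # sign mismatch blocks survival even when p is small
  v2 <- validate_holdout("a", x, y, beta_ref = c(a = -0.8))
  expect_length(v2$survived, 0)

  # perfect separation flagged and treated as non-survival
  xs <- cbind(sep = c(rep(-2, 20), rep(2, 20)) + rnorm(40, sd = 0.01))
  ys <- rep(c(0, 1), each = 20)
  vs <- validate_holdout("sep", xs, ys, beta_ref = c(sep = 1))
  expect_true(vs$separation)
  expect_length(vs$survived, 0)
})

test_that("validating on the training data reproduces an ordinary refit", {
  set.seed(10)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(x[, 1]))
  v <- validate_holdout(c("a", "b"), x, y)
  ref <- glm(y ~ scale(x[, 1]) + scale(x[, 2]), family = binomial())
  expect_equal(unname(v$table$coef), unname(coef(ref)[2:3]), tolerance = 1e-8)
})

test_that("the full selection pipeline is deterministic for a fixed seed", {
  set.seed(6)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(sprintf("id%03d", 1:n),
                                                  paste0("v", 1:8)))
  y <- rbinom(n, 1, plogis(1.5 * x[, 1]))
  cfg <- selection_config(n_bootstrap = 15, nlambda = 20, seed = 42)
  r1 <- stability_selection(x, y, cfg)
  r2 <- stability_selection(x, y, cfg)
  expect_identical(r1$variables, r2$variables)
  expect_identical(r1$selected, r2$selected)
  expect_equal(r1$n_train + r1$n_test, n)
})
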