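## Bootstrapped LASSO stability selection with cross-validated penalty
## and final holdout validation -- the risk-factor discovery engine.

#' Configuration for stability selection
#'
#' Defaults follow the published procedure: a stratified 70/30
#' train/test divide, 1,000 bootstrap iterations of L1-penalised logistic
#' regression with 5-fold cross-validated penalty selection, a 95%
#' inclusion-frequency rule, and holdout validation by ordinary logistic
#' regression at alpha = 0.05.
#'
#' @param train_fraction fraction of each outcome class in the train set.
#' @param n_bootstrap number of bootstrap iterations.
#' @param cv_folds folds for cross-validated penalty selection.
#' @param stability_threshold minimum inclusion frequency for selection.
#' @param lambda_grid optional decreasing positive penalty grid; `NULL`
#'   lets the path be chosen from the data (`nlambda` values).
#' @param nlambda path length when `lambda_grid` is `NULL`.
#' @param validation_alpha Wald p-value threshold for a selected variable
#'   to "survive" holdout validation.
#' @param seed integer master seed for the stage.
#' @return an object of class `"selection_config"`.
#' @export
selection_config <- function(train_fraction = 0.70, n_bootstrap = 1000,
                             cv_folds = 5, stability_threshold = 0.95,
                             lambda_grid = NULL, nlambda = 30,
                             validation_alpha = 0.05, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            n_bootstrap >= 1, cv_folds >= 2,
            stability_threshold > 0, stability_threshold <= 1,
            validation_alpha > 0, validation_alpha < 1)
  if (!is.null(lambda_grid)) stopifnot(all(lambda_grid > 0))
  structure(list(train_fraction = train_fraction,
                 n_bootstrap = as.integer(n_bootstrap),
                 cv_folds = as.integer(cv_folds),
                 stability_threshold = stability_threshold,
                 lambda_grid = lambda_grid, nlambda = as.integer(nlambda),
                 validation_alpha = validation_alpha,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Stratified train/test split
#'
#' Randomly splits ids into train and test, stratified by the binary
#' outcome so each class hits the target fraction within one participant.
#'
#' @param ids participant ids.
#' @param labels binary outcome, same length.
#' @param train_fraction fraction in `(0, 1)` (1.0 is rejected: the test
#'   set would be empty).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
#' @examples
#' sp <- split_train_test(1:20, rep(0:1, each = 10), 0.7, seed = 1)
#' lengths(sp) # 14 and 6
split_train_test <- function(ids, labels, train_fraction = 0.70, seed = 1L) {
  stopifnot(length(ids) == length(labels),
            train_fraction > 0, train_fraction < 1)
  classes <- unique(labels)
  if (length(classes) < 2) stop("both outcome classes must be present")
  if (any(table(labels) < 2)) stop("each outcome class needs at least 2 members")
  set.seed(substream_seed(seed, "split"))
  train <- unlist(lapply(classes, function(cl) {
    pool <- ids[labels == cl]
    sample(pool, round(train_fraction * length(pool)))
  }), use.names = FALSE)
  list(train = train, test = setdiff(ids, train))
}

# stratified fold ids; re-draws (with a warning) if a fold is single-class
stratified_folds <- function(y, k) {
  for (attempt in 1:25) {
    fid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) length(unique(y[fid == f])) == 2, TRUE))
    if (ok) return(fid)
    if (attempt == 1) warning("degenerate single-class fold; refolding")
  }
  fid
}

#' LASSO logistic regression with cross-validated penalty
#'
#' L1-penalised logistic fit over a penalty path, with the penalty chosen
#' by minimum mean cross-validated binomial deviance over outcome-
#' stratified folds.  The intercept is unpenalised.  `x` is expected
#' column-standardized, so the slopes are standardized coefficients.
#'
#' @param x standardized predictor matrix, no missing cells.
#' @param y binary outcome (0/1).
#' @param folds number of CV folds.
#' @param lambda_grid optional penalty grid (decreasing); `NULL` for a
#'   data-driven path of `nlambda` values.
#' @param seed integer seed for fold assignment.
#' @param nlambda path length when `lambda_grid` is `NULL`.
#' @return list with `coef` (named vector incl. `(Intercept)`),
#'   `lambda` (selected penalty) and `fit` (the underlying `cv.glmnet`).
#' @export
fit_lasso_logistic_cv <- function(x, y, folds = 5, lambda_grid = NULL,
                                  seed = 1L, nlambda = 30) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  set.seed(substream_seed(seed, "cvfolds"))
  fid <- stratified_folds(y, folds)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = fid,
                          standardize = FALSE, lambda = lambda_grid,
                          nlambda = nlambda, type.measure = "deviance")
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(co) <- rownames(stats::coef(cv, s = "lambda.min"))
  list(coef = co, lambda = cv$lambda.min, fit = cv)
}

# standardize columns; zero-variance columns become all-zero
standardize_cols <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- Inf
  sweep(sweep(x, 2, mu), 2, sds, "/")
}

#' Bootstrap stability of LASSO selection
#'
#' For each iteration: resample participants with replacement, stratified
#' by outcome (a single-class resample is redrawn); re-standardize the
#' predictor columns on the resample; fit the cross-validated LASSO; and
#' record which coefficients are nonzero.  Inclusion frequency is the
#' fraction of iterations with a nonzero coefficient; the beta summary is
#' the mean standardized coefficient over the iterations where the
#' variable was selected.
#'
#' @param x predictor matrix (raw scale; standardized per resample).
#' @param y binary outcome.
#' @param config a [selection_config()].
#' @return list with `frequency`, `beta_mean`, `beta_mean_abs` (named per
#'   variable; `NA` beta where never selected) and `n_bootstrap`.
#' @export
bootstrap_stability <- function(x, y, config = selection_config()) {
  x <- as.matrix(x)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  p <- ncol(x)
  vars <- colnames(x) %||% paste0("V", seq_len(p))
  colnames(x) <- vars
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  nonzero <- matrix(FALSE, config$n_bootstrap, p)
  betas <- matrix(NA_real_, config$n_bootstrap, p)
  set.seed(substream_seed(config$seed, "bootstrap"))
  iter_seeds <- sample.int(.Machine$integer.max - 1, config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    set.seed(iter_seeds[b])
    repeat {
      take <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      if (length(unique(y[take])) == 2) break
      message("single-class resample; redrawing")
    }
    xb <- standardize_cols(x[take, , drop = FALSE])
    fit <- fit_lasso_logistic_cv(xb, y[take], folds = config$cv_folds,
                                 lambda_grid = config$lambda_grid,
                                 seed = iter_seeds[b], nlambda = config$nlambda)
    slopes <- fit$coef[-1]
    nz <- slopes != 0
    nonzero[b, ] <- nz
    betas[b, nz] <- slopes[nz]
  }
  freq <- colMeans(nonzero)
  beta_mean <- colMeans(betas, na.rm = TRUE)
  beta_mean[is.nan(beta_mean)] <- NA_real_
  beta_abs <- colMeans(abs(betas), na.rm = TRUE)
  beta_abs[is.nan(beta_abs)] <- NA_real_
  names(freq) <- names(beta_mean) <- names(beta_abs) <- vars
  list(frequency = freq, beta_mean = beta_mean, beta_mean_abs = beta_abs,
       n_bootstrap = config$n_bootstrap)
}

#' Apply the stability threshold
#'
#' Variables with inclusion frequency at or above the threshold, ordered
#' by descending `|beta|` (ties by variable id).
#'
#' @param frequencies named inclusion frequencies in `[0, 1]`.
#' @param threshold stability threshold (inclusive).
#' @param beta optional named mean coefficients used for ordering.
#' @return character vector of selected variable ids.
#' @export
#' @examples
#' select_stable(c(a = 0.96, b = 0.95, c = 0.94), 0.95)
select_stable <- function(frequencies, threshold = 0.95, beta = NULL) {
  stopifnot(all(frequencies >= 0 & frequencies <= 1))
  sel <- names(frequencies)[frequencies >= threshold]
  if (!is.null(beta) && length(sel)) {
    b <- abs(beta[sel]); b[is.na(b)] <- 0
    sel <- sel[order(-b, sel)]
  } else sel <- sort(sel)
  sel
}

#' Holdout validation of selected variables
#'
#' Ordinary (unpenalised) logistic regression of the outcome on the
#' selected variables in the test sample, with test-standardized columns
#' so coefficients stay on the per-SD scale.  A variable *survives* when
#' its holdout coefficient has the same sign as its mean bootstrap beta
#' and its Wald p-value is at most `alpha`.  Perfect separation is
#' flagged and treated as non-survival.
#'
#' @param selected character vector of selected variable ids (may be
#'   empty: returns a structured "nothing to validate" record).
#' @param x_test,y_test test predictors and binary outcome.
#' @param beta_ref named mean bootstrap coefficients (for the sign check;
#'   `NULL` skips it).
#' @param alpha Wald p-value threshold.
#' @return list of class `"holdout_validation"`: `table` (coef, se, z, p,
#'   survived per variable), `survived`, `accuracy`, `deviance`,
#'   `separation` flag, `n_test`, or a degenerate record with
#'   `note = "nothing to validate"`.
#' @export
validate_holdout <- function(selected, x_test, y_test, beta_ref = NULL,
                             alpha = 0.05) {
  if (!length(selected)) {
    return(structure(list(table = data.frame(), survived = character(0),
                          accuracy = NA_real_, deviance = NA_real_,
                          separation = FALSE, n_test = length(y_test),
                          note = "nothing to validate"),
                     class = "holdout_validation"))
  }
  if (length(unique(y_test)) < 2) stop("test set must contain both classes")
  xs <- standardize_cols(as.matrix(x_test)[, selected, drop = FALSE])
  df <- data.frame(y = y_test, xs, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(sm))
  pick <- function(col) {
    out <- stats::setNames(rep(NA_real_, length(selected)), selected)
    out[rn[-1]] <- sm[-1, col]
    out
  }
  co <- pick(1); se <- pick(2); z <- pick(3); pv <- pick(4)
  separation <- !fit$converged || any(abs(co) > 15, na.rm = TRUE) ||
    any(se > 100, na.rm = TRUE) || anyNA(co)
  sign_ok <- if (is.null(beta_ref)) rep(TRUE, length(selected))
             else sign(co) == sign(beta_ref[selected])
  survived_flag <- !separation & !is.na(pv) & sign_ok & pv <= alpha
  survived_flag[is.na(survived_flag)] <- FALSE
  pred <- as.numeric(stats::predict(fit, type = "response") > 0.5)
  tab <- data.frame(variable = selected, coef = co, se = se, z = z, p = pv,
                    survived = survived_flag, row.names = NULL)
  structure(list(table = tab, survived = selected[survived_flag],
                 accuracy = mean(pred == y_test),
                 deviance = stats::deviance(fit),
                 separation = separation, n_test = length(y_test)),
            class = "holdout_validation")
}

#' @export
#' @method print holdout_validation
print.holdout_validation <- function(x, ...) {
  if (!is.null(x$note)) { cat("holdout validation:", x$note, "\n"); return(invisible(x)) }
  cat(sprintf("holdout validation on n = %d: accuracy %.3f, deviance %.1f%s\n",
              x$n_test, x$accuracy, x$deviance,
              if (x$separation) " [perfect separation flagged]" else ""))
  print(x$table, digits = 3)
  invisible(x)
}

#' Bootstrapped LASSO stability selection with holdout validation
#'
#' The full risk-factor discovery procedure for one predictor matrix and
#' binary outcome: stratified 70/30 split, bootstrap stability selection
#' on the train sample ([bootstrap_stability()]), the inclusion-frequency
#' rule ([select_stable()]), and holdout validation by ordinary logistic
#' regression on the test sample ([validate_holdout()]).  Pre-supplied
#' train/test ids can be passed to reuse one split across sweeps.
#'
#' @param x predictor matrix (complete; raw scale), rownames = ids.
#' @param y binary outcome aligned with rows of `x`.
#' @param config a [selection_config()].
#' @param split optional list with `train`/`test` id vectors; `NULL`
#'   draws a fresh stratified split from the config seed.
#' @return an object of class `"selection_result"`: `variables` (data
#'   frame with frequency, beta_mean, beta_abs, selected, survived,
#'   holdout coef/p), `selected`, `holdout` (the
#'   [validate_holdout()] record), `n_train`, `n_test`, `config`.
#' @export
stability_selection <- function(x, y, config = selection_config(), split = NULL) {
  x <- as.matrix(x)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- ids
  if (is.null(split))
    split <- split_train_test(ids, y, config$train_fraction, seed = config$seed)
  tr <- intersect(split$train, ids); te <- intersect(split$test, ids)
  ytr <- y[match(tr, ids)]; yte <- y[match(te, ids)]
  boot <- bootstrap_stability(x[tr, , drop = FALSE], ytr, config)
  sel <- select_stable(boot$frequency, config$stability_threshold,
                       beta = boot$beta_mean)
  hold <- validate_holdout(sel, x[te, , drop = FALSE], yte,
                           beta_ref = boot$beta_mean,
                           alpha = config$validation_alpha)
  vars <- names(boot$frequency)
  tab <- data.frame(variable = vars,
                    frequency = boot$frequency,
                    beta_mean = boot$beta_mean,
                    beta_abs = boot$beta_mean_abs,
                    selected = vars %in% sel,
                    holdout_coef = NA_real_, holdout_p = NA_real_,
                    survived = FALSE, row.names = NULL)
  if (length(sel)) {
    m <- match(hold$table$variable, tab$variable)
    tab$holdout_coef[m] <- hold$table$coef
    tab$holdout_p[m] <- hold$table$p
    tab$survived[m] <- hold$table$survived
  }
  structure(list(variables = tab, selected = sel, holdout = hold,
                 n_train = length(tr), n_test = length(te), config = config),
            class = "selection_result")
}

#' @export
#' @method print selection_result
print.selection_result <- function(x, ...) {
  cat(sprintf("stability selection: %d bootstrap iterations, threshold %.2f\n",
              x$config$n_bootstrap, x$config$stability_threshold))
  cat(sprintf("  n_train = %d, n_test = %d; %d/%d variables selected, %d survived holdout\n",
              x$n_train, x$n_test, length(x$selected), nrow(x$variables),
              length(x$holdout$survived)))
  if (length(x$selected)) {
    sel <- x$variables[x$variables$selected, , drop = FALSE]
    sel <- sel[order(-abs(sel$beta_abs), sel$variable), ]
    print(sel, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @method summary selection_result
summary.selection_result <- function(object, ...) {
  print(object)
  print(object$holdout)
  invisible(object)
}

#' @export
#' @method coef selection_result
coef.selection_result <- function(object, ...) {
  stats::setNames(object$variables$beta_mean, object$variables$variable)
}
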