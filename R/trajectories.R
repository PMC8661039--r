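## Developmental trajectory analysis: two-factor mixed ANOVA
## (group x sweep age) per SDQ subdomain, Greenhouse-Geisser corrected.

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor estimated from the covariance matrix of
#' the repeated measures:
#' `epsilon = trace(C)^2 / ((m - 1) * sum(C^2))` where `C` is the
#' double-centered covariance, clipped to `[1/(m - 1), 1]`.  Equals 1
#' under perfect sphericity and always 1 for `m = 2`.
#'
#' @param covmat symmetric covariance matrix of the m repeated measures.
#' @return epsilon in `[1/(m - 1), 1]`.
#' @export
#' @examples
#' gg_epsilon(diag(4)) # 1
gg_epsilon <- function(covmat) {
  covmat <- as.matrix(covmat)
  m <- nrow(covmat)
  if (m < 2) stop("at least 2 repeated measures required")
  stopifnot(ncol(covmat) == m, isTRUE(all.equal(covmat, t(covmat), tolerance = 1e-8)))
  j <- diag(m) - matrix(1 / m, m, m)
  cc <- j %*% covmat %*% j
  eps <- sum(diag(cc))^2 / ((m - 1) * sum(cc^2))
  min(1, max(1 / (m - 1), eps))
}

# pooled within-group covariance of the wide repeated measures
pooled_within_cov <- function(wide, group) {
  groups <- unique(group)
  p <- ncol(wide)
  acc <- matrix(0, p, p)
  df <- 0
  for (g in groups) {
    w <- wide[group == g, , drop = FALSE]
    if (nrow(w) < 2) stop("each group needs at least 2 participants")
    acc <- acc + (nrow(w) - 1) * stats::cov(w)
    df <- df + nrow(w) - 1
  }
  acc / df
}

#' Two-factor mixed ANOVA with Greenhouse-Geisser correction
#'
#' Between-subjects factor `group`, within-subjects factor `time`
#' (repeated measures), complete cases only.  Sums of squares come from
#' the standard univariate split-plot partition (via [stats::aov()] with
#' an `Error(participant)` stratum); the group-by-time interaction test is
#' then corrected with the Greenhouse-Geisser epsilon estimated from the
#' pooled within-group covariance of the repeated measures.
#'
#' @param data data frame with columns `participant`, `group`, `time`,
#'   `score` (long format).
#' @param groups optional subset of group labels to analyse.
#' @return list with the interaction test: `F`, `df1`, `df2`
#'   (uncorrected), `epsilon`, `df1_gg`, `df2_gg`, `p_gg`,
#'   `p_uncorrected`, plus `n` (participants used) and the time main
#'   effect (`F_time`, `p_time_gg`).
#' @export
mixed_anova_gg <- function(data, groups = NULL) {
  need <- c("participant", "group", "time", "score")
  stopifnot(all(need %in% names(data)))
  d <- data[, need]
  if (!is.null(groups)) d <- d[d$group %in% groups, , drop = FALSE]
  times <- sort(unique(d$time))
  m <- length(times)
  if (m < 2) stop("at least 2 time points required")
  # complete cases: participants with all m measures
  cnt <- table(d$participant)
  keep <- names(cnt)[cnt == m]
  d <- d[d$participant %in% keep, , drop = FALSE]
  if (length(unique(d$group)) < 2) stop("at least 2 groups required")
  d$participant <- factor(d$participant)
  d$group <- factor(d$group)
  d$time <- factor(d$time, levels = times)

  fit <- stats::aov(score ~ group * time + Error(participant), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  i_int <- match("group:time", rn)
  i_time <- match("time", rn)
  i_res <- match("Residuals", rn)
  f_int <- within[i_int, "F value"]
  df1 <- within[i_int, "Df"]; df2 <- within[i_res, "Df"]

  wide <- matrix(NA_real_, length(keep), m,
                 dimnames = list(sort(keep), times))
  wide[cbind(match(as.character(d$participant), rownames(wide)),
             match(as.character(d$time), colnames(wide)))] <- d$score
  grp_of <- d$group[match(rownames(wide), as.character(d$participant))]
  eps <- gg_epsilon(pooled_within_cov(wide, grp_of))

  f_time <- within[i_time, "F value"]
  df1_t <- within[i_time, "Df"]
  list(F = f_int, df1 = df1, df2 = df2, epsilon = eps,
       df1_gg = df1 * eps, df2_gg = df2 * eps,
       p_gg = stats::pf(f_int, df1 * eps, df2 * eps, lower.tail = FALSE),
       p_uncorrected = stats::pf(f_int, df1, df2, lower.tail = FALSE),
       F_time = f_time,
       p_time_gg = stats::pf(f_time, df1_t * eps, df2 * eps, lower.tail = FALSE),
       n = nrow(wide))
}

#' Trajectory ANOVA across SDQ subdomains
#'
#' Runs the Greenhouse-Geisser corrected mixed ANOVA for every SDQ
#' subdomain across the four sweeps, for the full set of groups and for
#' each group pair.  Participants missing any sweep's score are dropped
#' from this analysis only.
#'
#' @param cohort a `cohort_table`.
#' @param groups group labels to include (default all three).
#' @return object of class `"trajectory_anova"`: data frame `table` with
#'   one row per (subdomain, group set) and columns `F`, `df1_gg`,
#'   `df2_gg`, `epsilon`, `p_gg`; plus `means` (group x sweep x
#'   subdomain mean scores for plotting).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_group1 = 40, n_group2 = 40,
#'   n_comparison = 40, n_predictors_per_sweep = 75, seed = 5))
#' ta <- trajectory_anova(co)
#' head(ta$table)
trajectory_anova <- function(cohort, groups = GROUP_LABELS) {
  sg <- cohort$truth$subgroups
  sets <- c(list(all = groups),
            if (length(groups) > 2) {
              prs <- utils::combn(groups, 2, simplify = FALSE)
              stats::setNames(prs, vapply(prs, paste, "", collapse = " vs "))
            })
  rows <- list(); means <- list()
  for (sub in SDQ_SUBDOMAINS) {
    long <- do.call(rbind, lapply(SWEEP_AGES, function(s) {
      w <- cohort_wide(cohort, s, sub)
      data.frame(participant = rownames(w), time = s, score = w[, 1],
                 stringsAsFactors = FALSE)
    }))
    long$group <- sg$subgroup[match(long$participant, sg$participant_id)]
    long <- long[!is.na(long$score) & long$group %in% groups, ]
    for (nm in names(sets)) {
      res <- mixed_anova_gg(long, groups = sets[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        subdomain = sub, groups = nm, F = res$F,
        df1_gg = res$df1_gg, df2_gg = res$df2_gg,
        epsilon = res$epsilon, p_gg = res$p_gg, n = res$n,
        stringsAsFactors = FALSE)
    }
    agg <- stats::aggregate(score ~ group + time, long, mean)
    agg$subdomain <- sub
    means[[sub]] <- agg
  }
  structure(list(table = do.call(rbind, rows),
                 means = do.call(rbind, means)),
            class = "trajectory_anova")
}

#' @export
#' @method print trajectory_anova
print.trajectory_anova <- function(x, ...) {
  cat("Mixed ANOVA (group x age), Greenhouse-Geisser corrected\n")
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$df1_gg <- round(tab$df1_gg, 2); tab$df2_gg <- round(tab$df2_gg, 2)
  tab$epsilon <- round(tab$epsilon, 3)
  tab$p_gg <- signif(tab$p_gg, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot mean trajectories per subdomain
#'
#' @param x a `trajectory_anova`.
#' @param subdomain which subdomain to plot (default the first).
#' @param ... passed to [graphics::matplot()].
#' @export
#' @method plot trajectory_anova
plot.trajectory_anova <- function(x, subdomain = SDQ_SUBDOMAINS[1], ...) {
  d <- x$means[x$means$subdomain == subdomain, ]
  wide <- stats::xtabs(score ~ time + group, d)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "b", pch = 19,
                    lty = 1, xlab = "age (years)", ylab = "mean score",
                    main = subdomain, ...)
  graphics::legend("topleft", legend = colnames(wide), col = seq_len(ncol(wide)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
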