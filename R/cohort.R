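## Synthetic cohort generator: two planted self-harm subgroups plus a
## comparison sample, with profile measures (SDQ subdomains at four sweeps,
## MFQ at 14), per-sweep candidate predictors in six domains, planted
## risk-factor effects, and controlled missingness.

SWEEP_AGES <- c(5L, 7L, 11L, 14L)
GROUP_LABELS <- c("group1", "group2", "comparison")
SDQ_SUBDOMAINS <- c("sdq_emotional", "sdq_conduct", "sdq_hyperactivity",
                    "sdq_peer", "sdq_prosocial")
PREDICTOR_DOMAINS <- c("child health", "child mental health",
                       "caregiver mental health", "home environment",
                       "peer relations", "adversity")
PROFILE_VARS <- c(SDQ_SUBDOMAINS, "mfq_total")

#' Default planted risk-factor effects
#'
#' One small set of per-sweep effects mirroring the structure the analysis
#' is designed to detect: the high-psychopathology subgroup carries effects
#' in the child mental health, adversity and caregiver mental health
#' domains; the second subgroup carries weaker effects in peer relations
#' and child health.  Effects are log-odds per 1 SD of the predictor for
#' the subgroup-versus-comparison contrast.
#'
#' @param effect_scale multiplier applied to all default effect sizes.
#' @return a data frame with columns `sweep_age`, `group`, `variable_id`,
#'   `domain`, `effect`.
#' @export
default_planted_effects <- function(effect_scale = 1) {
  rows <- do.call(rbind, lapply(SWEEP_AGES, function(s) {
    data.frame(
      sweep_age = s,
      group = c("group1", "group1", "group1", "group2", "group2"),
      variable_id = sprintf("pred_a%02d_%03d", s, c(2L, 6L, 3L, 5L, 1L)),
      domain = c("child mental health", "adversity",
                 "caregiver mental health", "peer relations", "child health"),
      effect = c(1.0, 0.9, 0.8, 0.9, 0.8),
      stringsAsFactors = FALSE
    )
  }))
  rows$effect <- rows$effect * effect_scale
  rownames(rows) <- NULL
  rows
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults reproduce the published study conditions: group sizes
#' 379 / 905 / 900; age-14 SDQ total score means (SDs) of 17.67 (5.10),
#' 6.41 (3.56) and 6.92 (5.22) for the two self-harm subgroups and the
#' comparison sample; MFQ totals 15.14 (6.72), 12.03 (6.87), 4.41 (4.43);
#' 80 candidate predictors per sweep across six domains; roughly 70--76%
#' female among groups; and about 1.5% missing predictor cells plus a
#' small fraction of participants exceeding the 30% missingness exclusion
#' threshold.  Earlier-sweep SDQ totals encode the escalating trajectory
#' of the high-psychopathology subgroup versus flat trajectories for the
#' other two groups.
#'
#' @param n_group1,n_group2,n_comparison group sizes (non-negative).
#' @param sdq_total_means 3 x 4 matrix of SDQ total-score means
#'   (groups x sweep ages 5, 7, 11, 14), raw 0--50 units.
#' @param sdq_means optional 5 x 4 x 3 array of per-subdomain means
#'   (subdomain x sweep x group); defaults to `sdq_total_means / 5` in
#'   every subdomain.
#' @param sdq_total_sd length-3 SDs of the SDQ total score per group; each
#'   subdomain is drawn independently with SD `sdq_total_sd / sqrt(5)` so
#'   the total's SD matches.
#' @param mfq_mean,mfq_sd length-3 MFQ total mean and SD per group
#'   (0--26 units, age 14 only).
#' @param n_predictors_per_sweep number of candidate predictors per sweep
#'   (75--97).
#' @param prop_binary_predictors fraction of predictors that are binary
#'   (latent-normal thresholded at 30% prevalence).
#' @param planted_effects data frame as from [default_planted_effects()],
#'   or `NULL` for none.
#' @param female_fraction length-3 probability of being female per group.
#' @param missing_cell_rate MCAR missingness rate applied to predictor
#'   cells.
#' @param heavy_missing_rate probability that a participant is given more
#'   than 30% missing predictor cells at every sweep (and is therefore
#'   excluded by [missingness_filter()]).
#' @param mar_missingness if `TRUE`, the MCAR cell rate is doubled for
#'   group 1, giving a simple missing-at-random mechanism.
#' @param seed integer master seed; all generator randomness derives from
#'   it via [substream_seed()].
#' @return an object of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_group1 = 30, n_group2 = 60, n_comparison = 60,
#'                      n_predictors_per_sweep = 75)
cohort_config <- function(n_group1 = 379,
                          n_group2 = 905,
                          n_comparison = 900,
                          sdq_total_means = rbind(
                            group1     = c(10.0, 12.0, 14.5, 17.67),
                            group2     = c(7.5, 7.0, 6.7, 6.41),
                            comparison = c(7.5, 7.2, 7.0, 6.92)),
                          sdq_means = NULL,
                          sdq_total_sd = c(5.10, 3.56, 5.22),
                          mfq_mean = c(15.14, 12.03, 4.41),
                          mfq_sd = c(6.72, 6.87, 4.43),
                          n_predictors_per_sweep = 80,
                          prop_binary_predictors = 0.25,
                          planted_effects = default_planted_effects(),
                          female_fraction = c(0.71, 0.76, 0.70),
                          missing_cell_rate = 0.015,
                          heavy_missing_rate = 0.05,
                          mar_missingness = FALSE,
                          seed = 1L) {
  sdq_total_means <- as.matrix(sdq_total_means)
  stopifnot(identical(dim(sdq_total_means), c(3L, 4L)))
  if (is.null(sdq_means)) {
    sdq_means <- array(NA_real_, dim = c(5, 4, 3),
                       dimnames = list(SDQ_SUBDOMAINS, SWEEP_AGES, GROUP_LABELS))
    for (g in 1:3) sdq_means[, , g] <- matrix(rep(sdq_total_means[g, ] / 5, each = 5), 5, 4)
  }
  cfg <- structure(list(
    n_group1 = as.integer(n_group1),
    n_group2 = as.integer(n_group2),
    n_comparison = as.integer(n_comparison),
    sdq_total_means = sdq_total_means,
    sdq_means = sdq_means,
    sdq_total_sd = sdq_total_sd,
    mfq_mean = mfq_mean,
    mfq_sd = mfq_sd,
    n_predictors_per_sweep = as.integer(n_predictors_per_sweep),
    prop_binary_predictors = prop_binary_predictors,
    planted_effects = planted_effects,
    female_fraction = female_fraction,
    missing_cell_rate = missing_cell_rate,
    heavy_missing_rate = heavy_missing_rate,
    mar_missingness = mar_missingness,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_group1 >= 0, n_group2 >= 0, n_comparison >= 0,
      n_group1 + n_group2 + n_comparison > 0,
      n_predictors_per_sweep >= 75, n_predictors_per_sweep <= 97,
      length(sdq_total_sd) == 3, all(sdq_total_sd > 0),
      length(mfq_mean) == 3, length(mfq_sd) == 3, all(mfq_sd > 0),
      all(female_fraction >= 0 & female_fraction <= 1),
      missing_cell_rate >= 0, missing_cell_rate <= 1,
      heavy_missing_rate >= 0, heavy_missing_rate <= 1,
      prop_binary_predictors >= 0, prop_binary_predictors <= 1,
      identical(dim(sdq_means), c(5L, 4L, 3L)),
      all(sdq_means >= 0 & sdq_means <= 10)
    )
    if (!is.null(planted_effects) && nrow(planted_effects) > 0) {
      stopifnot(all(c("sweep_age", "group", "variable_id", "domain", "effect")
                    %in% names(planted_effects)))
      stopifnot(all(planted_effects$group %in% c("group1", "group2")),
                all(planted_effects$sweep_age %in% SWEEP_AGES))
      reserved <- c(PROFILE_VARS, "self_harm", "female")
      if (any(planted_effects$variable_id %in% reserved))
        stop("planted effects must target predictor variables, not outcome or profile measures")
      ok_ids <- outer(SWEEP_AGES, seq_len(n_predictors_per_sweep),
                      function(s, j) sprintf("pred_a%02d_%03d", s, j))
      if (!all(planted_effects$variable_id %in% ok_ids))
        stop("planted effect variable ids must be among the generated predictor ids")
    }
  })
  invisible(cfg)
}

# truncated (clipped) and rounded normal draw on an integer scale
rnorm_int_clipped <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd))))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort under the configured study conditions.  Subgroup
#' membership is assigned first (fixed group sizes), then measures and
#' predictors are drawn conditional on group: SDQ subdomain and MFQ
#' scores are truncated-and-rounded normals at the configured means/SDs;
#' predictors are standard normal (or thresholded latent normals for
#' binary variables) with planted variables mean-shifted in the affected
#' group by the configured log-odds effect, which is the coefficient an
#' (infinite-sample) logistic regression of subgroup-versus-comparison on
#' that unit-SD predictor would recover.  MCAR missingness is applied to
#' predictor cells, and a configured fraction of participants is given
#' more than 30% missing predictor cells per sweep.
#'
#' @param config a [cohort_config()].
#' @return an object of class `"cohort_table"`: a list with
#'   * `records`: long data frame `participant_id`, `sweep_age`,
#'     `variable_id`, `value` (missing cells are absent rows);
#'   * `variables`: data frame `variable_id`, `domain`, `scale`;
#'   * `truth`: list with `subgroups` (participant, planted subgroup) and
#'     `effects` (the planted-effect table);
#'   * `config`: the generating configuration.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_group1 = 20, n_group2 = 40,
#'   n_comparison = 40, n_predictors_per_sweep = 75, seed = 3))
#' co
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  ns <- c(config$n_group1, config$n_group2, config$n_comparison)
  n <- sum(ns)
  ids <- sprintf("p%05d", seq_len(n))
  group <- rep(GROUP_LABELS, ns)
  p <- config$n_predictors_per_sweep
  n_cont <- ceiling((1 - config$prop_binary_predictors) * p)
  pred_scale <- c(rep("continuous", n_cont), rep("binary", p - n_cont))
  pred_domain <- PREDICTOR_DOMAINS[(seq_len(p) - 1L) %% 6L + 1L]

  ## --- profile measures ---------------------------------------------------
  set.seed(substream_seed(config$seed, "profile"))
  sdq <- vector("list", length(SWEEP_AGES))
  names(sdq) <- SWEEP_AGES
  for (si in seq_along(SWEEP_AGES)) {
    m <- matrix(NA_real_, n, 5, dimnames = list(ids, SDQ_SUBDOMAINS))
    for (g in 1:3) {
      idx <- which(group == GROUP_LABELS[g])
      if (!length(idx)) next
      sub_sd <- config$sdq_total_sd[g] / sqrt(5)
      for (j in 1:5)
        m[idx, j] <- rnorm_int_clipped(length(idx), config$sdq_means[j, si, g],
                                       sub_sd, 0, 10)
    }
    sdq[[si]] <- m
  }
  mfq <- rep(NA_real_, n)
  for (g in 1:3) {
    idx <- which(group == GROUP_LABELS[g])
    if (length(idx))
      mfq[idx] <- rnorm_int_clipped(length(idx), config$mfq_mean[g],
                                    config$mfq_sd[g], 0, 26)
  }
  self_harm <- as.numeric(group %in% c("group1", "group2"))
  set.seed(substream_seed(config$seed, "demographics"))
  female <- rep(NA_real_, n)
  for (g in 1:3) {
    idx <- which(group == GROUP_LABELS[g])
    if (length(idx))
      female[idx] <- stats::rbinom(length(idx), 1, config$female_fraction[g])
  }

  ## --- predictors with planted effects ------------------------------------
  set.seed(substream_seed(config$seed, "predictors"))
  pe <- config$planted_effects
  preds <- vector("list", length(SWEEP_AGES))
  names(preds) <- SWEEP_AGES
  for (si in seq_along(SWEEP_AGES)) {
    s <- SWEEP_AGES[si]
    vid <- sprintf("pred_a%02d_%03d", s, seq_len(p))
    lat <- matrix(stats::rnorm(n * p), n, p, dimnames = list(ids, vid))
    if (!is.null(pe) && nrow(pe)) {
      here <- pe[pe$sweep_age == s, , drop = FALSE]
      for (r in seq_len(nrow(here))) {
        j <- match(here$variable_id[r], vid)
        idx <- which(group == here$group[r])
        lat[idx, j] <- lat[idx, j] + here$effect[r]
      }
    }
    bin <- pred_scale == "binary"
    if (any(bin)) lat[, bin] <- (lat[, bin] > stats::qnorm(0.7)) * 1
    preds[[si]] <- lat
  }

  ## --- missingness ---------------------------------------------------------
  set.seed(substream_seed(config$seed, "missingness"))
  heavy <- stats::rbinom(n, 1, config$heavy_missing_rate) == 1
  for (si in seq_along(SWEEP_AGES)) {
    rate <- rep(config$missing_cell_rate, n)
    if (config$mar_missingness) rate[group == "group1"] <- pmin(1, 2 * rate[group == "group1"])
    drop_mcar <- matrix(stats::runif(n * p) < rate, n, p)
    preds[[si]][drop_mcar] <- NA_real_
    for (i in which(heavy)) {
      frac <- stats::runif(1, 0.35, 0.60)
      jdrop <- sample.int(p, ceiling(frac * p))
      preds[[si]][i, jdrop] <- NA_real_
    }
  }

  ## --- assemble long records ----------------------------------------------
  melt <- function(m, s) {
    v <- as.vector(m)
    keep <- !is.na(v)
    data.frame(participant_id = rep(rownames(m), ncol(m))[keep],
               sweep_age = s,
               variable_id = rep(colnames(m), each = nrow(m))[keep],
               value = v[keep], stringsAsFactors = FALSE)
  }
  parts <- list()
  for (si in seq_along(SWEEP_AGES)) {
    s <- SWEEP_AGES[si]
    parts[[length(parts) + 1L]] <- melt(sdq[[si]], s)
    parts[[length(parts) + 1L]] <- melt(preds[[si]], s)
  }
  if (n > 0) {
    m14 <- cbind(mfq_total = mfq, self_harm = self_harm, female = female)
    rownames(m14) <- ids
    parts[[length(parts) + 1L]] <- melt(m14, 14L)
  }
  records <- do.call(rbind, parts)
  rownames(records) <- NULL

  variables <- rbind(
    data.frame(variable_id = SDQ_SUBDOMAINS, domain = "profile-measure",
               scale = "ordinal", stringsAsFactors = FALSE),
    data.frame(variable_id = "mfq_total", domain = "profile-measure",
               scale = "continuous", stringsAsFactors = FALSE),
    data.frame(variable_id = "self_harm", domain = "outcome",
               scale = "binary", stringsAsFactors = FALSE),
    data.frame(variable_id = "female", domain = "demographic",
               scale = "binary", stringsAsFactors = FALSE),
    do.call(rbind, lapply(SWEEP_AGES, function(s)
      data.frame(variable_id = sprintf("pred_a%02d_%03d", s, seq_len(p)),
                 domain = pred_domain, scale = pred_scale,
                 stringsAsFactors = FALSE)))
  )
  truth <- list(
    subgroups = data.frame(participant_id = ids, subgroup = group,
                           stringsAsFactors = FALSE),
    effects = if (is.null(pe)) {
      data.frame(variable_id = character(), sweep_age = integer(),
                 group = character(), effect = numeric())
    } else pe[, c("variable_id", "sweep_age", "group", "effect"), drop = FALSE]
  )
  structure(list(records = records, variables = variables, truth = truth,
                 config = config),
            class = "cohort_table")
}

#' @export
#' @method print cohort_table
print.cohort_table <- function(x, ...) {
  tab <- table(factor(x$truth$subgroups$subgroup, levels = GROUP_LABELS))
  cat("Synthetic self-harm cohort\n")
  cat(sprintf("  participants: %d (group1 %d, group2 %d, comparison %d)\n",
              nrow(x$truth$subgroups), tab["group1"], tab["group2"],
              tab["comparison"]))
  cat(sprintf("  variables: %d (%d predictors per sweep), sweeps at ages %s\n",
              nrow(x$variables), x$config$n_predictors_per_sweep,
              paste(SWEEP_AGES, collapse = ", ")))
  cat(sprintf("  records: %d\n", nrow(x$records)))
  invisible(x)
}

## ---- wide extractors used by the analysis stages ----

# wide matrix (participants x variables) at one sweep; NA = missing record
cohort_wide <- function(cohort, sweep_age, variable_ids, participant_ids = NULL) {
  r <- cohort$records
  r <- r[r$sweep_age == sweep_age & r$variable_id %in% variable_ids, , drop = FALSE]
  pid <- participant_ids %||% sort(unique(cohort$truth$subgroups$participant_id))
  m <- matrix(NA_real_, length(pid), length(variable_ids),
              dimnames = list(pid, variable_ids))
  keep <- r$participant_id %in% pid
  r <- r[keep, , drop = FALSE]
  m[cbind(match(r$participant_id, pid), match(r$variable_id, variable_ids))] <- r$value
  m
}

#' Raw age-14 profile measures of the self-harm sample
#'
#' Extracts the clustering input: the five SDQ subdomain scores and the
#' MFQ total at age 14 for participants who reported self-harm, keeping
#' complete rows only (the subgroup analysis uses complete responders).
#'
#' @param cohort a `cohort_table`.
#' @return numeric matrix, participants x 6 profile measures.
#' @export
profile_measures <- function(cohort) {
  all_ids <- sort(unique(cohort$truth$subgroups$participant_id))
  sh <- cohort_wide(cohort, 14L, "self_harm", all_ids)
  case_ids <- rownames(sh)[!is.na(sh[, 1]) & sh[, 1] == 1]
  m <- cohort_wide(cohort, 14L, PROFILE_VARS, case_ids)
  m[stats::complete.cases(m), , drop = FALSE]
}

# predictor matrix + binary outcome for one case group vs comparison at a sweep
predictors_at <- function(cohort, sweep_age, case_group = "group1") {
  sg <- cohort$truth$subgroups
  ids <- sg$participant_id[sg$subgroup %in% c(case_group, "comparison")]
  ids <- sort(ids)
  vid <- sort(cohort$variables$variable_id[grepl(sprintf("^pred_a%02d_", sweep_age),
                                                 cohort$variables$variable_id)])
  x <- cohort_wide(cohort, sweep_age, vid, ids)
  y <- stats::setNames(
    as.numeric(sg$subgroup[match(rownames(x), sg$participant_id)] == case_group),
    rownames(x))
  scale_map <- cohort$variables$scale[match(colnames(x), cohort$variables$variable_id)]
  list(x = x, y = y, scale = scale_map,
       domain = cohort$variables$domain[match(colnames(x), cohort$variables$variable_id)])
}
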