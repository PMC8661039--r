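## Descriptive tables, domain-grouped risk-factor summaries, and the
## end-to-end pipeline driver.

#' Group descriptive table
#'
#' Counts with integer percentages (half-up rounding, denominators are
#' the group sizes) for binary variables, and means/SDs for continuous or
#' ordinal scores, per group and sweep -- the layout of printed cohort
#' descriptive tables.
#'
#' @param cohort a `cohort_table`.
#' @param assignments named vector mapping participant id to group label.
#' @param variables character vector of variable ids (must exist in the
#'   cohort).
#' @return object of class `"group_descriptives"`: `group_n` (named
#'   sizes) and `table` with one row per (variable, sweep, group):
#'   `count`/`pct` for binary variables, `mean`/`sd` otherwise.
#' @export
descriptive_table <- function(cohort, assignments, variables) {
  miss <- setdiff(variables, cohort$variables$variable_id)
  if (length(miss)) stop("variable(s) absent from cohort: ",
                         paste(miss, collapse = ", "))
  pid <- names(assignments)
  stopifnot(!is.null(pid))
  group_n <- table(assignments)
  rows <- list()
  for (v in variables) {
    sc <- cohort$variables$scale[match(v, cohort$variables$variable_id)]
    recs <- cohort$records[cohort$records$variable_id == v &
                             cohort$records$participant_id %in% pid, ]
    for (s in sort(unique(recs$sweep_age))) {
      rs <- recs[recs$sweep_age == s, ]
      g_of <- assignments[rs$participant_id]
      for (g in names(group_n)) {
        val <- rs$value[g_of == g]
        n_g <- as.integer(group_n[g])
        if (identical(sc, "binary")) {
          cnt <- sum(val == 1)
          rows[[length(rows) + 1L]] <- data.frame(
            variable_id = v, sweep_age = s, group = g, n = n_g,
            count = cnt, pct = percent_of(cnt, n_g),
            mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            variable_id = v, sweep_age = s, group = g, n = n_g,
            count = NA_integer_, pct = NA_integer_,
            mean = mean(val), sd = stats::sd(val), stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(group_n = group_n, table = do.call(rbind, rows)),
            class = "group_descriptives")
}

#' @export
#' @method print group_descriptives
print.group_descriptives <- function(x, ...) {
  cat("Group descriptives (data are n (%) or mean (SD))\n")
  tab <- x$table
  tab$mean <- round(tab$mean, 2); tab$sd <- round(tab$sd, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Domain-grouped summary of surviving risk factors
#'
#' Lists, per sweep and subgroup, the variables that survived stability
#' selection and holdout validation, grouped by predictor domain with
#' their inclusion frequency and mean `|beta|` (the arc-size quantity of
#' a domain-wheel figure).  Ordered by sweep then descending `|beta|`,
#' ties broken by variable id; sweeps with no survivors get a
#' "no stable factors" row.
#'
#' @param selections list of entries, each a list with `sweep_age`,
#'   `group`, and `result` (a `selection_result`).
#' @param variables variable metadata data frame (`variable_id`,
#'   `domain`) used to label domains.
#' @return list with `table` (data frame) and `markdown` (character
#'   vector of report lines).
#' @export
render_domain_summary <- function(selections, variables) {
  rows <- list(); md <- c("# Risk factors and concurrent correlates", "")
  for (entry in selections) {
    res <- entry$result
    surv <- res$variables[res$variables$survived, , drop = FALSE]
    md <- c(md, sprintf("## Age %d, %s", entry$sweep_age, entry$group), "")
    if (!nrow(surv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sweep_age = entry$sweep_age, group = entry$group,
        variable_id = NA_character_, domain = NA_character_,
        frequency = NA_real_, beta_abs = NA_real_, stringsAsFactors = FALSE)
      md <- c(md, "no stable factors", "")
      next
    }
    surv$domain <- variables$domain[match(surv$variable, variables$variable_id)]
    b <- surv$beta_abs; b[is.na(b)] <- 0
    surv <- surv[order(-b, surv$variable), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sweep_age = entry$sweep_age, group = entry$group,
      variable_id = surv$variable, domain = surv$domain,
      frequency = surv$frequency, beta_abs = surv$beta_abs,
      stringsAsFactors = FALSE)
    md <- c(md, sprintf("- %s [%s]: frequency %.3f, |beta| = %.3f",
                        surv$variable, surv$domain, surv$frequency,
                        surv$beta_abs), "")
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$sweep_age, tab$group)
  list(table = tab[ord, , drop = FALSE], markdown = md)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full two-stage pipeline
#'
#' Executes simulate -> cluster -> (per sweep and subgroup: missingness
#' filter -> KNN imputation -> stratified split -> bootstrap stability
#' selection -> holdout validation) -> trajectory ANOVA -> report, writing
#' every stage output plus a manifest into `out_dir`.  One train/test
#' split per subgroup-versus-comparison pair is drawn once and reused
#' across sweeps.  All randomness derives from `seed`; outputs are
#' byte-identical across reruns with the same configuration and seed.
#'
#' @param out_dir output directory (created).
#' @param config a [cohort_config()]; its own seed is overridden from
#'   `seed`.
#' @param selection a [selection_config()]; per-stage seeds are derived
#'   from `seed`.
#' @param grid,epochs,k,k_range clustering stage settings (see
#'   [fit_profile_clusters()]).
#' @param seed master integer seed.
#' @param write_cohort_files also write the generated cohort CSVs
#'   (large; default `FALSE`).
#' @return (invisibly) a list with the in-memory stage results:
#'   `cohort`, `clusters`, `selections`, `trajectories`, `manifest`.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         selection = selection_config(),
                         grid = c(8, 8), epochs = 200, k = "auto",
                         k_range = 2:4, seed = 11L,
                         write_cohort_files = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE))
  }
  config$seed <- substream_seed(seed, "cohort")
  cohort <- stage("simulate", simulate_cohort(config))
  if (write_cohort_files) stage("write-cohort",
                                write_cohort(cohort, file.path(out_dir, "cohort")))

  clus <- stage("cluster", fit_profile_clusters(
    cohort, grid = grid, epochs = epochs, k = k, k_range = k_range,
    seed = substream_seed(seed, "cluster")))
  utils::write.csv(data.frame(participant_id = names(clus$solution$participant_cluster),
                              cluster = as.integer(clus$solution$participant_cluster)),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE,
                   quote = FALSE)
  write_json_file(list(k = clus$solution$k,
                       silhouette_by_k = clus$k_profile,
                       silhouette_mean = clus$solution$silhouette_mean,
                       quantization_error = clus$som$qe_final),
                  file.path(out_dir, "cluster_metrics.json"))

  # subgroup-versus-comparison contrasts use the recovered clusters
  sg <- cohort$truth$subgroups
  comp_ids <- sg$participant_id[sg$subgroup == "comparison"]
  selections <- list()
  for (cl in seq_len(clus$solution$k)) {
    case_ids <- names(clus$solution$participant_cluster)[clus$solution$participant_cluster == cl]
    ids_all <- c(case_ids, comp_ids)
    y_all <- stats::setNames(c(rep(1, length(case_ids)), rep(0, length(comp_ids))), ids_all)
    split <- stage("split", split_train_test(
      ids_all, y_all, selection$train_fraction,
      seed = substream_seed(seed, paste0("split-cluster", cl))))
    for (s in SWEEP_AGES) {
      nm <- sprintf("age%02d_cluster%d", s, cl)
      res <- stage(nm, {
        pv <- sort(cohort$variables$variable_id[grepl(sprintf("^pred_a%02d_", s),
                                                      cohort$variables$variable_id)])
        x <- cohort_wide(cohort, s, pv, sort(ids_all))
        sc <- cohort$variables$scale[match(colnames(x), cohort$variables$variable_id)]
        imp <- impute_missing(x, threshold = 0.30, k = 25, scale = sc)
        xin <- imp$data
        yin <- y_all[rownames(xin)]
        cfg_s <- selection
        cfg_s$seed <- substream_seed(seed, paste0("select-", nm))
        r <- stability_selection(xin, yin, cfg_s, split = split)
        r$imputation <- imp$report
        r
      })
      selections[[nm]] <- list(sweep_age = s, group = paste0("cluster", cl),
                               result = res)
      vt <- res$variables
      vt$domain <- cohort$variables$domain[match(vt$variable,
                                                 cohort$variables$variable_id)]
      write_json_file(list(sweep_age = s, cluster = cl,
                           n_train = res$n_train, n_test = res$n_test,
                           imputation = res$imputation,
                           variables = vt[, c("variable", "domain", "frequency",
                                              "beta_mean", "beta_abs", "selected",
                                              "holdout_p", "survived")],
                           holdout_accuracy = res$holdout$accuracy,
                           holdout_deviance = res$holdout$deviance),
                      file.path(out_dir, paste0("selection_", nm, ".json")))
    }
  }

  traj <- stage("trajectories", trajectory_anova(cohort))
  write_json_file(traj$table, file.path(out_dir, "anova.json"))

  report <- stage("report", render_domain_summary(selections, cohort$variables))
  desc <- stage("descriptives", descriptive_table(
    cohort, stats::setNames(sg$subgroup, sg$participant_id), "female"))
  writeLines(c(report$markdown, "", "# Descriptives (female, n (%))", "",
               sprintf("- %s: %d (%d%%)", desc$table$group, desc$table$count,
                       desc$table$pct)),
             file.path(out_dir, "report.md"))

  cfg_path <- file.path(out_dir, "config.json")
  write_json_file(list(seed = seed,
                       cohort_config = config[setdiff(names(config), "sdq_means")],
                       selection_config = unclass(selection),
                       grid = grid, epochs = epochs, k = k, k_range = k_range),
                  cfg_path)
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(cohort = cohort, clusters = clus, selections = selections,
                 trajectories = traj, manifest = manifest))
}
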