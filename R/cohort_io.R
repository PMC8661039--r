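#' Write a cohort to a directory of CSV files
#'
#' Emits `cohort.csv` (long records), `variables.csv` (metadata) and, when
#' truth labels are present, the sidecars `truth_subgroups.csv` and
#' `truth_effects.csv`.  Rows are written in a canonical sort order so the
#' output is byte-identical for equal cohorts.
#'
#' @param cohort a `cohort_table`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  r <- cohort$records
  r <- r[order(r$participant_id, r$sweep_age, r$variable_id), , drop = FALSE]
  utils::write.csv(r, file.path(path, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  v <- cohort$variables
  v <- v[order(v$variable_id), , drop = FALSE]
  utils::write.csv(v, file.path(path, "variables.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    sg <- cohort$truth$subgroups
    utils::write.csv(sg[order(sg$participant_id), , drop = FALSE],
                     file.path(path, "truth_subgroups.csv"), row.names = FALSE,
                     quote = FALSE)
    ef <- cohort$truth$effects
    utils::write.csv(ef[order(ef$variable_id, ef$sweep_age), , drop = FALSE],
                     file.path(path, "truth_effects.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the long table on the way in: required columns, numeric
#' values, integer SDQ scores in 0--10, MFQ in 0--26, a binary self-harm
#' indicator present only at sweep 14, and uniqueness of
#' (participant, sweep, variable) triplets.  Violations raise an error
#' naming the offending file line.
#'
#' @param path directory containing `cohort.csv` and `variables.csv`.
#' @return a `cohort_table` (with `config = NULL`).
#' @export
read_cohort <- function(path) {
  fr <- file.path(path, "cohort.csv")
  fv <- file.path(path, "variables.csv")
  if (!file.exists(fr)) stop("no cohort.csv in ", path)
  if (!file.exists(fv)) stop("no variables.csv in ", path)
  r <- utils::read.csv(fr, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "sweep_age", "variable_id", "value")
  if (!identical(names(r), need))
    stop("cohort.csv: expected header ", paste(need, collapse = ","))
  # +1 for the header line when reporting positions
  coerce_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(r[[col]]))
    bad <- which(is.na(x) & nzchar(r[[col]]))
    if (length(bad))
      stop(sprintf("cohort.csv line %d: non-numeric %s '%s'",
                   bad[1] + 1L, what, r[[col]][bad[1]]))
    x
  }
  r$sweep_age <- as.integer(coerce_num("sweep_age", "sweep_age"))
  r$value <- coerce_num("value", "value")
  key <- paste(r$participant_id, r$sweep_age, r$variable_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("cohort.csv line %d: duplicate (participant, sweep, variable) triplet",
                 dup[1] + 1L))
  check_range <- function(vars, lo, hi, integer_valued = FALSE) {
    sel <- which(r$variable_id %in% vars)
    bad <- sel[r$value[sel] < lo | r$value[sel] > hi |
                 (integer_valued & r$value[sel] != round(r$value[sel]))]
    if (length(bad))
      stop(sprintf("cohort.csv line %d: value %g out of range for %s",
                   bad[1] + 1L, r$value[bad[1]], r$variable_id[bad[1]]))
  }
  check_range(SDQ_SUBDOMAINS, 0, 10, integer_valued = TRUE)
  check_range("mfq_total", 0, 26)
  check_range("self_harm", 0, 1, integer_valued = TRUE)
  sh_off <- which(r$variable_id == "self_harm" & r$sweep_age != 14L)
  if (length(sh_off))
    stop(sprintf("cohort.csv line %d: self_harm indicator outside sweep 14",
                 sh_off[1] + 1L))

  v <- utils::read.csv(fv, stringsAsFactors = FALSE)
  if (!all(c("variable_id", "domain", "scale") %in% names(v)))
    stop("variables.csv: expected columns variable_id,domain,scale")

  truth <- NULL
  fs <- file.path(path, "truth_subgroups.csv")
  fe <- file.path(path, "truth_effects.csv")
  if (file.exists(fs)) {
    truth <- list(subgroups = utils::read.csv(fs, stringsAsFactors = FALSE,
                                              colClasses = c("character", "character")),
                  effects = if (file.exists(fe))
                    utils::read.csv(fe, stringsAsFactors = FALSE)
                  else NULL)
  }
  structure(list(records = r, variables = v, truth = truth, config = NULL),
            class = "cohort_table")
}
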