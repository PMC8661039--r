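## Missing-data handling for the per-sweep predictor matrices: the 30%
## exclusion rule and k-nearest-neighbour imputation.

#' Exclude participants with excessive missingness
#'
#' Removes rows whose fraction of missing cells is strictly greater than
#' `threshold` ("more than 30%" is a strict inequality: exactly 30% is
#' retained).
#'
#' @param x numeric matrix with `NA` for missing cells, rownames = ids.
#' @param threshold missingness threshold in `(0, 1)`.
#' @return list with `retained` (sub-matrix) and `excluded_ids`.
#' @export
#' @examples
#' m <- rbind(a = c(1, NA, NA, NA), b = c(1, 2, 3, NA))
#' missingness_filter(m, 0.30)$excluded_ids # "a"
missingness_filter <- function(x, threshold = 0.30) {
  x <- as.matrix(x)
  stopifnot(threshold > 0, threshold < 1)
  frac <- rowMeans(is.na(x))
  out <- frac > threshold
  if (all(out))
    stop("all participants exceed the missingness threshold; review the threshold")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  list(retained = x[!out, , drop = FALSE], excluded_ids = ids[out])
}

# pairwise-observed squared distances, scaled by shared-column count
pairwise_scaled_dist <- function(z) {
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  o <- obs * 1
  zz <- z0^2
  d2 <- zz %*% t(o) + o %*% t(zz) - 2 * tcrossprod(z0)
  shared <- tcrossprod(o)
  d2[d2 < 0] <- 0
  d <- sqrt(d2 / shared)       # NaN where no shared columns
  d[shared == 0] <- Inf
  diag(d) <- Inf
  d
}

mode_smallest <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # which.max -> first = smallest value
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean (continuous columns) or mode
#' (binary/ordinal columns, ties toward the smaller category) of the k
#' nearest rows that observe that cell.  Distances are Euclidean over
#' pairwise-observed, column-standardized coordinates, scaled by the
#' number of shared observed columns; rows tied with the k-th neighbour
#' are all included in the donor set.  Observed cells are untouched.
#'
#' @param x numeric matrix with `NA`s; every row needs at least one
#'   observed cell and every column at least one.
#' @param k number of neighbours (default 25); capped at `n - 1` with a
#'   warning.
#' @param scale character vector per column: `"continuous"`, `"binary"` or
#'   `"ordinal"` (recycled; default all continuous).
#' @return list with `data` (completed matrix) and `report`, an
#'   imputation report: `imputed_fraction` (missing cells / total cells),
#'   `k_used`, `n_imputed`.
#' @export
knn_impute <- function(x, k = 25, scale = "continuous") {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 1, n >= 2)
  scale <- rep_len(scale, ncol(x))
  if (any(rowSums(!is.na(x)) == 0)) stop("every row must have at least one observed cell")
  if (any(colSums(!is.na(x)) == 0)) stop("column(s) fully missing: no donor information")
  if (k > n - 1) {
    warning(sprintf("k = %d exceeds n - 1 = %d; capped", k, n - 1))
    k <- n - 1
  }
  n_missing <- sum(is.na(x))
  out <- x
  if (n_missing > 0) {
    mu <- colMeans(x, na.rm = TRUE)
    sds <- apply(x, 2, stats::sd, na.rm = TRUE)
    sds[is.na(sds) | sds == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sds, "/")
    d <- pairwise_scaled_dist(z)
    for (i in which(rowSums(is.na(x)) > 0)) {
      for (j in which(is.na(x[i, ]))) {
        cand <- which(!is.na(x[, j]) & is.finite(d[i, ]))
        if (!length(cand)) stop("no donors share observed columns with a recipient")
        dc <- d[i, cand]
        kk <- min(k, length(cand))
        kth <- sort(dc, partial = kk)[kk]
        donors <- cand[dc <= kth]         # tie-inclusive
        vals <- x[donors, j]
        out[i, j] <- if (scale[j] %in% c("binary", "ordinal"))
          mode_smallest(vals) else mean(vals)
      }
    }
  }
  list(data = out,
       report = list(imputed_fraction = n_missing / length(x),
                     k_used = k, n_imputed = n_missing))
}

#' Filter then impute a predictor matrix
#'
#' Applies the 30% exclusion rule, then KNN imputation on the retained
#' participants.  The imputed fraction in the report is computed over the
#' retained participants' cells, exactly.
#'
#' @param x numeric matrix with `NA`s.
#' @param threshold passed to [missingness_filter()].
#' @param k,scale passed to [knn_impute()].
#' @return list with `data` (complete matrix of retained rows) and
#'   `report`: `n_excluded`, `excluded_ids`, `imputed_fraction`, `k_used`.
#' @export
impute_missing <- function(x, threshold = 0.30, k = 25, scale = "continuous") {
  flt <- missingness_filter(x, threshold)
  imp <- knn_impute(flt$retained, k = k, scale = scale)
  list(data = imp$data,
       report = list(n_excluded = length(flt$excluded_ids),
                     excluded_ids = flt$excluded_ids,
                     imputed_fraction = imp$report$imputed_fraction,
                     k_used = imp$report$k_used))
}
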