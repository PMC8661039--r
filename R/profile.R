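## Subgroup-discovery stage: z-scored profile measures -> self-organizing
## map -> k-means on node weights -> participant assignment via best
## matching unit -> silhouette validation.

#' Column-standardize a profile table
#'
#' z-scores each measure (sample SD, divisor n-1) and retains the raw
#' means/SDs for the inverse transform.  Constant columns are flagged and
#' standardized to zero.
#'
#' @param x complete numeric matrix or data frame, participants x measures.
#' @return an object of class `"profile_matrix"`: list with `values`
#'   (z-scored matrix), `participants`, `features`, `feature_means`,
#'   `feature_sds`, `constant` (logical flags).
#' @export
#' @examples
#' zscore_profiles(cbind(a = c(1, 2, 3), b = c(4, 4, 4)))$values
zscore_profiles <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("profile table must be complete (no missing cells)")
  if (nrow(x) < 2) stop("at least 2 participants required (SD undefined for 1)")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  sds_safe <- ifelse(constant, 1, sds)
  z <- sweep(sweep(x, 2, mu), 2, sds_safe, "/")
  z[, constant] <- 0
  structure(list(values = z,
                 participants = rownames(x) %||% as.character(seq_len(nrow(x))),
                 features = colnames(x) %||% as.character(seq_len(ncol(x))),
                 feature_means = mu, feature_sds = sds, constant = constant),
            class = "profile_matrix")
}

#' @export
#' @method print profile_matrix
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d participants x %d z-scored features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_values <- function(x) {
  if (inherits(x, "profile_matrix")) x$values else as.matrix(x)
}

#' Train a self-organizing map
#'
#' Batch SOM with a Gaussian neighborhood on a rectangular grid.  The
#' neighborhood radius decays linearly from `max(grid_rows, grid_cols)/2`
#' to `radius_end` over the epochs; each batch epoch assigns every point to its best
#' matching unit (BMU) and replaces every node weight by the
#' neighborhood-weighted mean of the data.  Node weights are initialised
#' linearly along the first two principal components of the data (the
#' conventional SOM initialisation; deterministic and invariant to row
#' order), or from randomly sampled data points with `init = "sample"`.
#'
#' @param profiles a `profile_matrix` or numeric matrix (rows = points).
#' @param grid_rows,grid_cols grid dimensions (`>= 1`).
#' @param epochs number of batch epochs (`>= 1`).
#' @param seed integer seed (used by the `"sample"` initialisation).
#' @param init `"linear"` (default) or `"sample"`.
#' @param radius_end final neighborhood radius; the default 0.2 makes the
#'   last epochs effectively pure vector quantization (each node converges
#'   to the mean of its own catchment), after the earlier wide-radius
#'   epochs have done the topological ordering.
#' @return an object of class `"som_model"`: grid dims, `node_weights`
#'   (nodes x features), `node_grid` (node coordinates), training
#'   settings, and the quantization error at initialisation
#'   (`qe_initial`) and after training (`qe_final`).
#' @export
som_fit <- function(profiles, grid_rows = 8, grid_cols = 8, epochs = 200,
                    seed = 1L, init = c("linear", "sample"), radius_end = 0.2) {
  x <- as_values(profiles)
  init <- match.arg(init)
  if (!all(is.finite(x))) stop("non-finite profile values")
  stopifnot(epochs >= 1, grid_rows >= 1, grid_cols >= 1)
  n <- nrow(x)
  m <- grid_rows * grid_cols
  grid <- as.matrix(expand.grid(row = seq_len(grid_rows), col = seq_len(grid_cols)))
  if (init == "sample") {
    set.seed(substream_seed(seed, "som"))
    w <- x[sample.int(n, m, replace = m > n), , drop = FALSE]
  } else {
    # span the grid over +/- 2 SD along the two leading principal axes
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    ctr <- colMeans(x)
    unit <- function(g, levels) {
      if (levels == 1) rep(0, length(g)) else (g - (levels + 1) / 2) / ((levels - 1) / 2)
    }
    c1 <- unit(grid[, 1], grid_rows)
    c2 <- unit(grid[, 2], grid_cols)
    # align the longer grid axis with the leading component
    if (grid_cols > grid_rows) { tmp <- c1; c1 <- c2; c2 <- tmp }
    w <- matrix(ctr, m, ncol(x), byrow = TRUE)
    w <- w + outer(2 * c1 * sqrt(max(ev$values[1], 0)), ev$vectors[, 1])
    if (ncol(x) >= 2)
      w <- w + outer(2 * c2 * sqrt(max(ev$values[2], 0)), ev$vectors[, 2])
  }
  rownames(w) <- NULL
  gd2 <- as.matrix(stats::dist(grid))^2
  qe <- function(w) {
    d2 <- cross_dist2(x, w)
    mean(sqrt(apply(d2, 1, min)))
  }
  qe0 <- qe(w)
  r0 <- max(max(grid_rows, grid_cols) / 2, radius_end)
  for (e in seq_len(epochs)) {
    rad <- if (epochs == 1) r0
           else r0 + (radius_end - r0) * (e - 1) / (epochs - 1)
    bmu <- max.col(-cross_dist2(x, w), ties.method = "first")
    h <- exp(-gd2 / (2 * rad^2))      # m x m node-to-node neighborhood
    hn <- h[bmu, , drop = FALSE]      # n x m influence of each point on each node
    num <- crossprod(hn, x)
    den <- colSums(hn)
    w <- num / den
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 node_weights = w, node_grid = grid,
                 training = list(epochs = epochs, radius_start = r0,
                                 radius_end = radius_end, init = init,
                                 seed = seed),
                 qe_initial = qe0, qe_final = qe(w)),
            class = "som_model")
}

#' @export
#' @method print som_model
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d grid, %d epochs; quantization error %.4f (init %.4f)\n",
              x$grid_rows, x$grid_cols, x$training$epochs, x$qe_final, x$qe_initial))
  invisible(x)
}

#' Quantization error of a SOM on data
#'
#' Mean Euclidean distance of each point to its best matching node.
#'
#' @param model a `som_model`.
#' @param profiles data (`profile_matrix` or matrix).
#' @return a single number.
#' @export
quantization_error <- function(model, profiles) {
  x <- as_values(profiles)
  mean(sqrt(apply(cross_dist2(x, model$node_weights), 1, min)))
}

#' Per-point silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a` is the mean distance
#' of point `i` to the other members of its own cluster and `b` the
#' smallest mean distance to the points of any other cluster.  Points in
#' singleton clusters score 0, as do points with `a = b = 0`.
#'
#' @param points numeric matrix of coordinates.
#' @param labels cluster labels, one per row; at least 2 distinct.
#' @return numeric vector of silhouette widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(points, labels) {
  points <- as_values(points)
  labels <- as.vector(labels)
  stopifnot(nrow(points) == length(labels))
  if (length(unique(labels)) < 2) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(stats::dist(points))
  f <- factor(labels)
  sizes <- table(f)
  # mean distance from each point to each cluster (including own)
  sums <- t(rowsum(d, f))               # n x k: sum of distances to cluster
  s <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    own <- as.integer(f[i])
    ni <- sizes[own]
    if (ni == 1) { s[i] <- 0; next }
    a <- sums[i, own] / (ni - 1)
    b <- min(sums[i, -own] / sizes[-own])
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  s
}

#' Mean silhouette coefficient
#'
#' @inheritParams silhouette_widths
#' @return mean of [silhouette_widths()], a number in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  mean(silhouette_widths(points, labels))
}

#' Cluster participants via k-means on SOM node weights
#'
#' Runs k-means (multiple random restarts, best within-cluster sum of
#' squares kept) on the trained node weights, then assigns each
#' participant the cluster of its best matching node (Euclidean distance
#' in z-score space).  Cluster labels are canonically ordered by
#' descending centroid SDQ total (sum over features named `sdq_*`, or all
#' features when none are), so cluster 1 is the high-psychopathology
#' profile.
#'
#' @param model a `som_model`.
#' @param profiles the `profile_matrix` the SOM was trained on.
#' @param k number of clusters, `2 <= k <=` number of distinct nodes.
#' @param n_restarts k-means restarts.
#' @param seed integer seed.
#' @return an object of class `"cluster_solution"`: `k`, `node_cluster`,
#'   `participant_cluster` (named vector), `centroids` (k x features,
#'   z-units, participant means), `silhouette_per_point`,
#'   `silhouette_mean`, `wcss_nodes`.
#' @export
cluster_participants <- function(model, profiles, k, n_restarts = 50, seed = 1L) {
  x <- as_values(profiles)
  w <- model$node_weights
  if (k < 2) stop("k must be >= 2")
  n_distinct <- nrow(unique(w))
  if (k > n_distinct) stop("k exceeds the number of distinct node weights")
  set.seed(substream_seed(seed, "kmeans"))
  km <- suppressWarnings(stats::kmeans(w, centers = k, nstart = n_restarts,
                                       iter.max = 100))
  bmu <- max.col(-cross_dist2(x, w), ties.method = "first")
  part <- km$cluster[bmu]
  # canonical order: descending SDQ-total of participant centroids
  feats <- colnames(x) %||% as.character(seq_len(ncol(x)))
  sdq_cols <- grep("^sdq_", feats)
  if (!length(sdq_cols)) sdq_cols <- seq_along(feats)
  cent_raw <- rowsum(x, part) / as.vector(table(factor(part, levels = sort(unique(part)))))
  present <- sort(unique(part))
  score <- rep(-Inf, k)
  score[present] <- rowSums(cent_raw[, sdq_cols, drop = FALSE])
  relab <- order(score, decreasing = TRUE)          # old label -> position
  new_of_old <- match(seq_len(k), relab)
  node_cluster <- new_of_old[km$cluster]
  part <- new_of_old[part]
  names(part) <- rownames(x)
  centroids <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, feats))
  for (cl in sort(unique(part)))
    centroids[cl, ] <- colMeans(x[part == cl, , drop = FALSE])
  sil <- silhouette_widths(x, part)
  structure(list(k = k, node_cluster = node_cluster,
                 participant_cluster = part, centroids = centroids,
                 silhouette_per_point = sil, silhouette_mean = mean(sil),
                 wcss_nodes = km$tot.withinss),
            class = "cluster_solution")
}

#' @export
#' @method print cluster_solution
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d, silhouette = %.3f\n", x$k, x$silhouette_mean))
  print(table(cluster = x$participant_cluster))
  invisible(x)
}

#' @export
#' @method summary cluster_solution
summary.cluster_solution <- function(object, ...) {
  cat(sprintf("k = %d clusters, mean silhouette %.3f\n", object$k,
              object$silhouette_mean))
  cat("cluster sizes:\n"); print(table(object$participant_cluster))
  cat("centroids (z-units):\n")
  print(round(object$centroids, 2))
  invisible(object)
}

#' Plot cluster centroid profiles
#'
#' One line per cluster across the profile measures, in z-score units.
#'
#' @param x a `cluster_solution`.
#' @param ... passed to [graphics::matplot()].
#' @export
#' @method plot cluster_solution
plot.cluster_solution <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "", ylab = "centroid (z-units)", ...)
  graphics::axis(1, at = seq_len(ncol(x$centroids)),
                 labels = colnames(x$centroids), las = 2, cex.axis = 0.8)
  graphics::legend("topright", legend = paste("cluster", seq_len(x$k)),
                   col = seq_len(x$k), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Choose k by silhouette
#'
#' Clusters the node weights for each candidate `k` and returns the
#' silhouette-maximizing solution; ties break toward smaller `k`.
#'
#' @param model a `som_model`.
#' @param profiles the `profile_matrix`.
#' @param k_range candidate k values (each `>= 2`).
#' @param n_restarts,seed passed to [cluster_participants()].
#' @return list with `best_k`, `profile` (data frame of k and mean
#'   silhouette), and `solution` (the best `cluster_solution`).
#' @export
select_k <- function(model, profiles, k_range = 2:6, n_restarts = 50, seed = 1L) {
  if (!length(k_range)) stop("empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  sols <- lapply(k_range, function(k)
    cluster_participants(model, profiles, k, n_restarts, seed))
  sil <- vapply(sols, `[[`, numeric(1), "silhouette_mean")
  best <- which.max(sil)  # first max -> smallest k on ties
  list(best_k = k_range[best],
       profile = data.frame(k = k_range, silhouette = sil),
       solution = sols[[best]])
}

#' Two-stage subgroup discovery on a cohort
#'
#' End-to-end clustering stage: extract the age-14 profile measures of
#' the self-harm sample, z-score them, train a SOM, cluster its node
#' weights with k-means (fixed `k` or silhouette-selected), and assign
#' participants through their best matching node.
#'
#' @param cohort a `cohort_table`.
#' @param grid SOM grid as `c(rows, cols)`.
#' @param epochs SOM training epochs.
#' @param k number of clusters, or `"auto"` to pick by silhouette.
#' @param k_range candidates when `k = "auto"`.
#' @param n_restarts k-means restarts.
#' @param seed integer master seed for this stage.
#' @return an object of class `"profile_clusters"`: the
#'   `cluster_solution` plus `som`, `profiles`, `k_profile` (silhouette
#'   per candidate k when selected automatically).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_group1 = 60, n_group2 = 120,
#'   n_comparison = 50, n_predictors_per_sweep = 75, seed = 7))
#' fit <- fit_profile_clusters(co, grid = c(4, 4), epochs = 40, k = 2)
#' fit$solution$silhouette_mean
fit_profile_clusters <- function(cohort, grid = c(8, 8), epochs = 200,
                                 k = "auto", k_range = 2:6, n_restarts = 50,
                                 seed = 1L) {
  raw <- profile_measures(cohort)
  prof <- zscore_profiles(raw)
  som <- som_fit(prof, grid[1], grid[2], epochs, seed = substream_seed(seed, "som-stage"))
  if (identical(k, "auto")) {
    sel <- select_k(som, prof, k_range, n_restarts, seed = substream_seed(seed, "kmeans-stage"))
    sol <- sel$solution; kp <- sel$profile
  } else {
    sol <- cluster_participants(som, prof, as.integer(k), n_restarts,
                                seed = substream_seed(seed, "kmeans-stage"))
    kp <- data.frame(k = as.integer(k), silhouette = sol$silhouette_mean)
  }
  structure(list(solution = sol, som = som, profiles = prof, k_profile = kp),
            class = "profile_clusters")
}

#' @export
#' @method print profile_clusters
print.profile_clusters <- function(x, ...) {
  cat("Two-stage profile clustering (SOM + k-means)\n")
  print(x$som)
  print(x$solution)
  invisible(x)
}
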