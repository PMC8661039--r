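test_that("z-scoring matches its definition and handles degenerate input", {
  z <- zscore_profiles(cbind(a = c(1, 2, 3)))
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))  # sample SD = 1
  # idempotent on already-standardized data
  z2 <- zscore_profiles(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # constant column flagged and zeroed
  zc <- zscore_profiles(cbind(a = c(1, 2, 3), b = c(4, 4, 4)))
  expect_equal(unname(zc$values[, "b"]), c(0, 0, 0))
  expect_true(zc$constant["b"])
  expect_error(zscore_profiles(matrix(1, 1, 2)), "2 participants")
  expect_error(zscore_profiles(cbind(c(1, NA))), "complete")
})

test_that("column standardization holds to 1e-9 on generated profiles", {
  co <- simulate_cohort(small_config(seed = 6))
  z <- zscore_profiles(profile_measures(co))
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-9)
})

test_that("a 1x1 SOM converges to the data mean", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  m <- som_fit(x, 1, 1, epochs = 10, seed = 1)
  expect_equal(as.numeric(m$node_weights), colMeans(x), tolerance = 1e-6)
})

test_that("SOM training reduces quantization error and respects cloud structure", {
  tc <- two_clouds(n_per = 25, sep = 15)
  m <- som_fit(tc$x, 2, 1, epochs = 50, seed = 3)
  expect_lte(m$qe_final, m$qe_initial)
  # each node sits inside the bounding box of one cloud
  box <- function(cloud) apply(cloud, 2, range)
  in_box <- function(w, b) all(w >= b[1, ] & w <= b[2, ])
  b1 <- box(tc$x[tc$labels == 1, ]); b2 <- box(tc$x[tc$labels == 2, ])
  hits <- apply(m$node_weights, 1, function(w) in_box(w, b1) || in_box(w, b2))
  expect_true(all(hits))
  expect_error(som_fit(matrix(c(1, NA), 2, 1), 1, 1, 1), "non-finite")
})

test_that("k-means on node weights recovers planted partitions deterministically", {
  tc <- two_clouds(n_per = 5, sep = 25)
  m <- som_fit(tc$x, 2, 2, epochs = 30, seed = 2)
  sol <- cluster_participants(m, tc$x, k = 2, n_restarts = 10, seed = 5)
  expect_equal(adjusted_rand_index(sol$participant_cluster, tc$labels), 1)
  sol2 <- cluster_participants(m, tc$x, k = 2, n_restarts = 10, seed = 5)
  expect_identical(sol$participant_cluster, sol2$participant_cluster)
  # k = number of distinct nodes: every node its own cluster, WCSS 0
  solk <- cluster_participants(m, tc$x, k = nrow(unique(m$node_weights)),
                               n_restarts = 5, seed = 1)
  expect_equal(solk$wcss_nodes, 0, tolerance = 1e-10)
  expect_error(cluster_participants(m, tc$x, k = 50, seed = 1), "distinct node")
})

test_that("silhouette matches the brute-force definition on random instances", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- 1:2
    expect_equal(silhouette_widths(x, lab), brute_silhouette(x, lab),
                 tolerance = 1e-12)
    s <- silhouette_mean(x, lab)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("silhouette agrees with the cluster package on a larger instance", {
  skip_if_not_installed("cluster")
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2)
  lab <- kmeans(x, 3)$cluster
  ours <- silhouette_widths(x, lab)
  ref <- cluster::silhouette(lab, dist(x))[, "sil_width"]
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("silhouette conventions: coincident clusters, singletons, identical points", {
  x <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  expect_equal(silhouette_mean(x, c(1, 1, 2, 2)), 1)
  # singleton cluster contributes 0
  x2 <- rbind(c(0, 0), c(1, 0), c(5, 5))
  s <- silhouette_widths(x2, c(1, 1, 2))
  expect_equal(s[3], 0)
  # all points identical: a = b = 0 -> 0
  x3 <- matrix(1, 4, 2)
  expect_equal(silhouette_mean(x3, c(1, 1, 2, 2)), 0)
  expect_error(silhouette_mean(x, c(1, 1, 1, 1)), "2 clusters")
})

test_that("select_k recovers the planted number of clouds", {
  tc <- two_clouds(n_per = 20, sep = 20)
  m <- som_fit(tc$x, 3, 3, epochs = 40, seed = 7)
  sel <- select_k(m, tc$x, k_range = 2:4, n_restarts = 20, seed = 3)
  expect_equal(sel$best_k, 2)
  expect_equal(nrow(sel$profile), 3)
  # three well-separated clouds
  set.seed(5)
  x3 <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 15), 20, 2),
              cbind(rnorm(20, 30), rnorm(20, -10)))
  m3 <- som_fit(x3, 3, 3, epochs = 40, seed = 2)
  sel3 <- select_k(m3, x3, k_range = 2:5, n_restarts = 20, seed = 3)
  expect_equal(sel3$best_k, 3)
  # singleton range is trivially best
  sel1 <- select_k(m, tc$x, k_range = 2, n_restarts = 5, seed = 1)
  expect_equal(sel1$best_k, 2)
  expect_error(select_k(m, tc$x, k_range = integer(0)), "empty")
})

test_that("participant assignment is invariant to feature and participant order", {
  co <- simulate_cohort(small_config(seed = 8))
  raw <- profile_measures(co)
  run <- function(mat) {
    prof <- zscore_profiles(mat)
    m <- som_fit(prof, 3, 3, epochs = 30, seed = 4)
    cluster_participants(m, prof, k = 2, n_restarts = 20, seed = 4)$participant_cluster
  }
  base <- run(raw)
  perm_feat <- run(raw[, rev(colnames(raw))])
  expect_equal(adjusted_rand_index(base, perm_feat[names(base)]), 1)
  set.seed(3)
  perm_rows <- sample(nrow(raw))
  reshuffled <- run(raw[perm_rows, ])
  expect_equal(adjusted_rand_index(base, reshuffled[names(base)]), 1)
})

test_that("end-to-end clustering labels the high-psychopathology profile as cluster 1", {
  co <- simulate_cohort(small_config(n_group1 = 60, n_group2 = 120, seed = 12))
  fit <- fit_profile_clusters(co, grid = c(4, 4), epochs = 50, k = 2, seed = 2)
  sdq_cols <- grep("^sdq_", colnames(fit$solution$centroids))
  tots <- rowSums(fit$solution$centroids[, sdq_cols])
  expect_true(tots[1] > tots[2])
})
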