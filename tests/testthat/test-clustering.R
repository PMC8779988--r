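test_that("kmeans solves the hand instance and the degenerate limits", {
  X <- cbind(c(0, 1, 9, 10))
  km <- cluster_kmeans(X, 2, seed = 1, n_restarts = 5)
  expect_same_partition(km$labels, c(0, 0, 1, 1))
  expect_equal(sort(km$centroids[, 1]), c(0.5, 9.5))
  expect_equal(km$sse, 0.5 + 0.5)

  km1 <- cluster_kmeans(X, 1, seed = 1)
  expect_equal(km1$centroids[1, 1], 5)
  expect_true(all(km1$labels == 0))

  kmn <- cluster_kmeans(X, 4, seed = 1)
  expect_equal(kmn$sse, 0)
  expect_equal(sort(kmn$labels), 0:3)

  expect_error(cluster_kmeans(X, 5), "exceed")
  # SSE trace never increases
  set.seed(2)
  Y <- matrix(rnorm(120), 60, 2)
  km <- cluster_kmeans(Y, 4, seed = 3, n_restarts = 1)
  expect_true(all(diff(km$sse_trace) <= 1e-9))
})

test_that("kmeans equals the exhaustive-partition SSE minimizer on small instances", {
  set.seed(20)
  for (trial in 1:20) {
    n <- sample(4:8, 1); k <- sample(2:3, 1); d <- sample(1:2, 1)
    X <- matrix(rnorm(n * d), n, d)
    km <- cluster_kmeans(X, k, seed = trial, n_restarts = 40)
    expect_equal(km$sse, oracle_min_sse(X, k), tolerance = 1e-8)
  }
})

test_that("fcm memberships behave per the update equations", {
  # symmetric point: equidistant from both centroids -> u = (0.5, 0.5)
  X <- cbind(c(0, 10, 5))
  res <- cluster_fcm(X, 2, m = 2, seed = 4, tol = 1e-9)
  expect_equal(unname(res$membership[3, ]), c(0.5, 0.5), tolerance = 1e-4)
  # rows sum to one
  expect_equal(unname(rowSums(res$membership)), rep(1, 3), tolerance = 1e-9)

  # a point exactly at a centroid takes full membership (limit convention)
  res2 <- cluster_fcm(cbind(c(0, 10)), 2, m = 2, seed = 4)
  expect_equal(sort(apply(res2$membership, 1, max)), c(1, 1))

  # objective is non-increasing
  set.seed(5)
  Y <- matrix(rnorm(100), 50, 2)
  res <- cluster_fcm(Y, 3, m = 2, seed = 6)
  expect_true(all(diff(res$model$objective_trace) <= 1e-9))
  expect_equal(unname(rowSums(res$membership)), rep(1, 50), tolerance = 1e-9)

  expect_error(cluster_fcm(Y, 3, m = 1), "m must be > 1")
})

test_that("fcm at m near 1 reduces to kmeans", {
  X <- cbind(c(0, 1, 9, 10))
  hard <- cluster_fcm(X, 2, m = 1.05, seed = 1)$model$labels
  km <- cluster_kmeans(X, 2, seed = 1, n_restarts = 10)
  expect_same_partition(hard, km$labels)
})

test_that("bandwidth estimation follows its definition", {
  X <- cbind(c(0, 4))
  expect_equal(estimate_bandwidth(X, quantile = 1), 4)
  set.seed(7)
  Y <- matrix(rnorm(60), 30, 2)
  h <- estimate_bandwidth(Y, 0.3)
  expect_equal(estimate_bandwidth(3 * Y, 0.3), 3 * h, tolerance = 1e-12)
  expect_error(estimate_bandwidth(Y, 0), "quantile")
  expect_error(estimate_bandwidth(Y[1, , drop = FALSE], 0.5), "at least 2")
})

test_that("mean shift finds the right number of modes", {
  # one Gaussian blob: a single cluster with the mode at the sample mean
  b <- make_blobs(200, rbind(c(0, 0)), sd = 1, seed = 8)
  ms <- cluster_meanshift(b$X, h = 3)
  expect_equal(ms$k, 1)
  expect_lt(sqrt(sum((ms$centroids[1, ] - colMeans(b$X))^2)), 0.2)

  # two blobs 20 sd apart: two clusters recovering the truth
  b <- make_blobs(80, rbind(c(0, 0), c(20, 0)), sd = 1, seed = 9)
  ms <- cluster_meanshift(b$X, h = 3)
  expect_equal(ms$k, 2)
  expect_same_partition(ms$labels, b$truth)

  # flat kernel with an out-of-reach seed freezes it with a warning
  expect_warning(
    cluster_meanshift(rbind(c(0, 0), c(0.1, 0)), h = 1, kernel = "flat",
                      seeds = rbind(c(50, 50))),
    "empty neighborhood")
})

test_that("agglomerative clustering merges per linkage and matches the MST oracle", {
  X <- cbind(c(0, 1, 5, 6))
  ag <- cluster_agglomerative(X, 2)
  expect_same_partition(ag$labels, c(0, 0, 1, 1))

  agn <- cluster_agglomerative(X, 4)
  expect_equal(sort(agn$labels), 0:3)
  expect_error(cluster_agglomerative(X, 5), "exceed")

  set.seed(10)
  Y <- matrix(rnorm(80), 40, 2)
  for (k in c(2, 5)) {
    got <- cluster_agglomerative(Y, k, linkage = "single")$labels
    expect_same_partition(got, oracle_mst_clusters(Y, k))
  }
  # other linkages produce valid k-partitions
  for (lk in c("complete", "average", "ward")) {
    got <- cluster_agglomerative(Y, 3, linkage = lk)
    expect_equal(sort(unique(got$labels)), 0:2)
  }
})

test_that("dbscan labels cores, borders, and outliers per the graph oracle", {
  # isolated point far from a tight cluster becomes -1
  X <- rbind(matrix(rnorm(20, sd = 0.2), 10, 2), c(100, 100))
  db <- cluster_dbscan(X, eps = 1, min_pts = 3)
  expect_equal(db$labels[11], -1L)
  expect_true(all(db$labels[1:10] == 0L))

  # everything mutually within eps: one cluster, no outliers
  X <- matrix(runif(20, 0, 0.5), 10, 2)
  db <- cluster_dbscan(X, eps = 2, min_pts = 10)
  expect_equal(unique(db$labels), 0L)

  # neighbor count includes the point itself
  X <- cbind(c(0, 1))
  db <- cluster_dbscan(X, eps = 1.5, min_pts = 2)
  expect_equal(db$labels, c(0L, 0L))

  set.seed(12)
  for (trial in 1:10) {
    b <- make_blobs(15, rbind(c(0, 0), c(8, 0)), sd = 1.2, seed = 100 + trial)
    got <- cluster_dbscan(b$X, eps = 1.5, min_pts = 4)$labels
    orc <- oracle_dbscan(b$X, eps = 1.5, min_pts = 4)
    expect_identical(got, orc)
  }
})

test_that("partitions are invariant to row shuffling and labels respect range", {
  b <- make_blobs(30, rbind(c(0, 0), c(12, 0), c(0, 12)), sd = 1, seed = 13)
  set.seed(14)
  perm <- sample(nrow(b$X))
  Xp <- b$X[perm, ]
  run_all <- function(X) list(
    kmeans = cluster_kmeans(X, 3, seed = 1, n_restarts = 10)$labels,
    fcm = cluster_fcm(X, 3, seed = 1)$model$labels,
    hier = cluster_agglomerative(X, 3)$labels,
    ms = cluster_meanshift(X, h = 4)$labels,
    dbscan = cluster_dbscan(X, eps = 2.5, min_pts = 4)$labels)
  a <- run_all(b$X); p <- run_all(Xp)
  for (alg in names(a))
    expect_equal(adjusted_rand_index(a[[alg]][perm], p[[alg]]), 1,
                 info = alg)
  # parametric methods never emit the outlier label
  expect_true(all(a$kmeans >= 0))
  expect_true(all(a$fcm >= 0))
  expect_true(all(a$hier >= 0))
})
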