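# The five clustering algorithms: k-means, fuzzy C-means, mean shift,
# agglomerative hierarchical, and DBSCAN. All are deterministic given their
# seed; ties (equidistant centroids/modes) always resolve to the lowest
# cluster index. Labels are 0-based; -1 marks density-method outliers.

# n x k matrix of squared Euclidean distances from rows of X to rows of C.
dist2_to <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

new_cluster_model <- function(labels, centroids, k, iterations_run, converged,
                              seed = NA_integer_, method, ...) {
  structure(list(labels = as.integer(labels), centroids = centroids,
                 k = as.integer(k), iterations_run = as.integer(iterations_run),
                 converged = converged, seed = seed, method = method, ...),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s: k = %d, n = %d, %d outliers, %d iterations%s\n",
              x$method, x$k, length(x$labels), sum(x$labels == -1L),
              x$iterations_run, if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

# Sample k distinct data rows as initial centroids.
init_centroids <- function(X, k) {
  ux <- unique(X)
  if (nrow(ux) >= k) ux[sample.int(nrow(ux), k), , drop = FALSE]
  else X[sample.int(nrow(X), k), , drop = FALSE]
}

#' k-means clustering
#'
#' Lloyd iterations: assign each point to its nearest centroid (squared
#' Euclidean distance, ties to the lowest index), recompute centroids as
#' member means, stop when assignments stop changing. Initial centroids are
#' k distinct data points sampled by seed; the best of `n_restarts` runs by
#' within-cluster sum of squares is returned. An empty cluster is re-seeded
#' at the point currently farthest from its assigned centroid.
#'
#' @param X numeric matrix, one row per observation.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed RNG seed; the run is fully reproducible from it.
#' @param max_iter iteration cap per restart.
#' @param n_restarts independent restarts.
#' @return a `cluster_model` with `sse` (total within-cluster sum of
#'   squares) and `sse_trace` (per-iteration, non-increasing).
#' @export
cluster_kmeans <- function(X, k, seed = 1L, max_iter = 100L, n_restarts = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of points")
  if (k < 1L) stop("k must be >= 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    C <- init_centroids(X, k)
    labels <- rep.int(0L, n)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- dist2_to(X, C)
      new_labels <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters at the point farthest from its centroid
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (length(empty)) {
        cur <- d2[cbind(seq_len(n), new_labels)]
        for (j in empty) {
          far <- which.max(cur)
          C[j, ] <- X[far, ]
          new_labels[far] <- j
          cur[far] <- -Inf
        }
        d2 <- dist2_to(X, C)
        new_labels <- max.col(-d2, ties.method = "first")
      }
      trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
      if (iter > 1L && all(new_labels == labels)) { converged <- TRUE; break }
      labels <- new_labels
      sums <- rowsum(X, labels)              # rows sorted by label
      cnt <- tabulate(labels, nbins = k)
      present <- as.integer(rownames(sums))
      C[present, ] <- sums / cnt[present]
      if (iter >= max_iter) break
    }
    # final centroids = member means
    for (j in seq_len(k)) {
      mem <- labels == j
      if (any(mem)) C[j, ] <- colMeans(X[mem, , drop = FALSE])
    }
    sse <- trace[length(trace)]
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(labels = labels, C = C, sse = sse, trace = trace,
                   iter = iter, converged = converged)
  }
  new_cluster_model(best$labels - 1L, best$C, k, best$iter, best$converged,
                    seed, "kmeans", sse = best$sse, sse_trace = best$trace)
}

#' Fuzzy C-means clustering
#'
#' Alternates the membership update
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` with the weighted centroid
#' update `mu_j = sum_i u_ij^m x_i / sum_i u_ij^m` until the largest
#' membership change falls below `tol`. A point coinciding with a centroid
#' takes membership 1 there (limit convention, split equally on ties). Hard
#' labels assign each point to its highest-membership cluster.
#'
#' @inheritParams cluster_kmeans
#' @param m fuzziness coefficient, `> 1`; 2 is the usual choice.
#' @param tol convergence threshold on max membership change.
#' @return list with elements `model` (a `cluster_model` carrying the
#'   objective trace) and `membership` (n x k matrix, rows sum to 1).
#' @export
cluster_fcm <- function(X, k, m = 2, seed = 1L, max_iter = 300L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (m <= 1) stop("fuzziness m must be > 1")
  if (k > n) stop("k must not exceed the number of points")
  set.seed(seed)
  C <- init_centroids(X, k)
  u <- matrix(1 / k, n, k)
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to(X, C)
    w <- d2^(-1 / (m - 1))            # (1/d^2)^(1/(m-1))
    zero <- d2 <= 0
    if (any(zero)) {
      hit <- rowSums(zero) > 0
      w[hit, ] <- 0
      w[zero] <- 1                     # split equally among coincident centroids
    }
    u_new <- w / rowSums(w)
    obj_trace <- c(obj_trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    um <- u^m
    C <- (t(um) %*% X) / colSums(um)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  labels <- max.col(u, ties.method = "first") - 1L
  model <- new_cluster_model(labels, C, k, iter, converged, seed, "fcm",
                             m = m, objective_trace = obj_trace)
  list(model = model, membership = u)
}

#' Mean-shift bandwidth estimate
#'
#' Mean over all points of the distance to their `ceiling(quantile * n)`-th
#' nearest neighbor (the point itself counts as its own first neighbor).
#'
#' @param X numeric matrix.
#' @param quantile in `(0, 1]`.
#' @export
estimate_bandwidth <- function(X, quantile = 0.3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points")
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  kth <- ceiling(quantile * n)
  D <- as.matrix(stats::dist(X))
  mean(apply(D, 1L, function(r) sort(r, partial = kth)[kth]))
}

#' Mean-shift clustering
#'
#' Iteratively moves every seed to the kernel-weighted mean of its
#' neighborhood until displacement falls below `tol`; converged seed
#' positions (modes) within `mode_merge_tol` of an earlier mode are merged,
#' and each point joins the closest mode.
#'
#' @param X numeric matrix.
#' @param h kernel bandwidth; default [estimate_bandwidth] at `quantile`.
#' @param kernel `"gaussian"` (all points weighted by
#'   `exp(-d^2 / (2 h^2))`) or `"flat"` (uniform weight within radius `h`).
#' @param quantile bandwidth quantile when `h` is not given.
#' @param seeds seed matrix; default all points.
#' @param max_iter iteration cap.
#' @param tol displacement threshold; default `1e-4 * h`.
#' @param mode_merge_tol mode merge radius; default `h / 2`.
#' @return a `cluster_model` (centroids = modes); `k` is discovered, not set.
#' @export
cluster_meanshift <- function(X, h = NULL, kernel = c("gaussian", "flat"),
                              quantile = 0.3, seeds = NULL, max_iter = 300L,
                              tol = NULL, mode_merge_tol = NULL) {
  X <- as.matrix(X)
  kernel <- match.arg(kernel)
  if (is.null(h)) h <- estimate_bandwidth(X, quantile)
  if (!is.finite(h) || h <= 0) stop("bandwidth h must be > 0")
  if (is.null(tol)) tol <- 1e-4 * h
  if (is.null(mode_merge_tol)) mode_merge_tol <- h / 2
  S <- if (is.null(seeds)) X else as.matrix(seeds)
  frozen <- rep(FALSE, nrow(S))
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to(S, X)
    W <- if (kernel == "gaussian") exp(-d2 / (2 * h^2)) else (d2 <= h^2) * 1
    tot <- rowSums(W)
    dead <- tot == 0
    if (any(dead & !frozen)) {
      warning(sum(dead & !frozen), " seed(s) with empty neighborhood frozen in place")
      frozen <- frozen | dead
    }
    tot[dead] <- 1
    S_new <- (W %*% X) / tot
    S_new[frozen | dead, ] <- S[frozen | dead, , drop = FALSE]
    disp <- sqrt(rowSums((S_new - S)^2))
    S <- S_new
    if (max(disp) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # merge modes in seed order
  modes <- NULL
  for (i in seq_len(nrow(S))) {
    if (is.null(modes)) { modes <- S[i, , drop = FALSE]; next }
    d <- sqrt(rowSums(sweep(modes, 2L, S[i, ])^2))
    if (min(d) > mode_merge_tol) modes <- rbind(modes, S[i, ])
  }
  labels <- max.col(-dist2_to(X, modes), ties.method = "first") - 1L
  new_cluster_model(labels, modes, nrow(modes), iter, converged, NA_integer_,
                    "meanshift", h = h, kernel = kernel)
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up merging: repeatedly join the two clusters at the smallest
#' linkage distance until `k` clusters remain (Lance-Williams updates).
#' Default linkage is `single`, the literal "merge points with the smallest
#' distance" rule; `complete`, `average` and `ward` are available.
#'
#' @inheritParams cluster_kmeans
#' @param linkage linkage criterion.
#' @return a `cluster_model` (no centroids; labels 0..k-1 ordered by first
#'   member row).
#' @export
cluster_agglomerative <- function(X, k, linkage = c("single", "complete",
                                                    "average", "ward")) {
  X <- as.matrix(X)
  linkage <- match.arg(linkage)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of points")
  if (k < 1L) stop("k must be >= 1")
  D <- as.matrix(stats::dist(X))
  if (linkage == "ward") D <- D^2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  member <- as.list(seq_len(n))
  n_clusters <- n
  while (n_clusters > k) {
    flat <- which.min(D)                   # first minimum, column-major: deterministic
    j <- ((flat - 1L) %/% n) + 1L
    i <- ((flat - 1L) %% n) + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    drow <- switch(linkage,
      single   = pmin(D[i, ], D[j, ]),
      complete = {
        r <- pmax(D[i, ], D[j, ])
        r[!is.finite(D[i, ]) | !is.finite(D[j, ])] <- Inf
        r
      },
      average  = (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j]),
      ward     = {
        nl <- size
        ((size[i] + nl) * D[i, ] + (size[j] + nl) * D[j, ] -
           nl * D[i, j]) / (size[i] + size[j] + nl)
      })
    drow[!active] <- Inf
    D[i, ] <- drow; D[, i] <- drow
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    active[j] <- FALSE
    member[[i]] <- c(member[[i]], member[[j]])
    size[i] <- size[i] + size[j]
    n_clusters <- n_clusters - 1L
  }
  labels <- integer(n)
  roots <- which(active)
  first_row <- vapply(member[roots], min, integer(1))
  roots <- roots[order(first_row)]
  for (jj in seq_along(roots)) labels[member[[roots[jj]]]] <- jj - 1L
  new_cluster_model(labels, NULL, k, n - n_clusters, TRUE, NA_integer_,
                    "hierarchical", linkage = linkage)
}

#' DBSCAN clustering
#'
#' Density-reachability expansion: a point whose epsilon-ball (inclusive,
#' counting the point itself) holds at least `min_pts` points is a core
#' point and founds or extends a cluster; points reachable from no core
#' point are outliers with label -1. Rows are visited in order, so the run
#' is deterministic; border points take the label of the first core point
#' that reaches them.
#'
#' @param X numeric matrix.
#' @param eps neighborhood radius, `> 0`.
#' @param min_pts minimum points (including self) for a core point.
#' @return a `cluster_model` (no centroids); `k` = number of clusters found.
#' @export
cluster_dbscan <- function(X, eps, min_pts = 3L) {
  X <- as.matrix(X)
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  if (min_pts < 1L) stop("min_pts must be >= 1")
  n <- nrow(X)
  D2 <- dist2_to(X, X)
  inball <- D2 <= eps^2
  nb <- lapply(seq_len(n), function(i) which(inball[i, ]))
  core <- lengths(nb) >= min_pts
  labels <- rep.int(NA_integer_, n)
  cl <- -1L
  for (p in seq_len(n)) {
    if (!is.na(labels[p]) || !core[p]) next
    cl <- cl + 1L
    labels[p] <- cl
    queue <- p
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      for (r in nb[[q]]) {
        if (is.na(labels[r])) {
          labels[r] <- cl
          if (core[r]) queue <- c(queue, r)
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  new_cluster_model(labels, NULL, cl + 1L, 1L, TRUE, NA_integer_, "dbscan",
                    eps = eps, min_pts = as.integer(min_pts))
}

#' Run the clustering algorithm named by a scenario
#'
#' Dispatch helper used by the pipeline: forwards the per-algorithm
#' parameters from a flat config list.
#'
#' @param X feature matrix.
#' @param algorithm algorithm name.
#' @param config list of parameters (`k`, `seed`, `fcm_m`, `h`, `quantile`,
#'   `eps`, `min_pts`, `linkage`, `max_iter`, `n_restarts`, `tol`).
#' @return a `cluster_model`.
#' @export
run_algorithm <- function(X, algorithm, config = list()) {
  cfg <- utils::modifyList(list(k = 4L, seed = 1L, fcm_m = 2, h = NULL,
                                quantile = 0.3, eps = NULL, min_pts = 3L,
                                linkage = "single", max_iter = 300L,
                                n_restarts = 10L, tol = 1e-6), config)
  switch(algorithm,
    kmeans = cluster_kmeans(X, cfg$k, seed = cfg$seed,
                            max_iter = cfg$max_iter, n_restarts = cfg$n_restarts),
    fcm = cluster_fcm(X, cfg$k, m = cfg$fcm_m, seed = cfg$seed,
                      max_iter = cfg$max_iter, tol = cfg$tol)$model,
    meanshift = cluster_meanshift(X, h = cfg$h, quantile = cfg$quantile,
                                  max_iter = cfg$max_iter),
    hierarchical = cluster_agglomerative(X, cfg$k, linkage = cfg$linkage),
    dbscan = {
      eps <- if (is.null(cfg$eps)) estimate_bandwidth(X, 0.01) else cfg$eps
      cluster_dbscan(X, eps, cfg$min_pts)
    },
    stop("unknown algorithm: ", algorithm))
}
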