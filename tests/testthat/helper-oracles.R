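# Independent oracles. Each deliberately takes a different computational
# route from the implementation it checks.

# Minimum within-cluster SSE over ALL assignments of n points to <= k
# clusters, by full enumeration (vectorized over the k^n assignment matrix).
oracle_min_sse <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))  # k^n x n labels
  sq <- rowSums(X^2)
  total <- numeric(nrow(A))
  for (j in seq_len(k)) {
    M <- (A == j) * 1
    cnt <- rowSums(M)
    ss <- M %*% sq                       # sum of |x|^2 over members
    cs <- M %*% X                        # cluster sums
    within <- ss - rowSums(cs^2) / pmax(cnt, 1)
    within[cnt == 0] <- 0
    total <- total + within
  }
  min(total)
}

# DBSCAN partition oracle: connected components of the eps-graph restricted
# to core points; border points attach to the earliest-discovered adjacent
# core cluster; everything else is -1. Uses igraph for the components.
oracle_dbscan <- function(X, eps, min_pts) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  adj <- D <= eps
  core <- which(rowSums(adj) >= min_pts)   # diagonal TRUE counts self
  labels <- rep(-1L, n)
  if (length(core)) {
    g <- igraph::graph_from_adjacency_matrix(
      adj[core, core, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    # renumber components by their smallest core row (discovery order)
    first <- tapply(core, comp, min)
    renum <- rank(first)
    labels[core] <- as.integer(renum[comp]) - 1L
    for (p in setdiff(seq_len(n), core)) {
      nbc <- core[adj[p, core]]
      if (length(nbc)) labels[p] <- min(labels[nbc])
    }
  }
  labels
}

# All-pairs brute-force silhouette.
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  keep <- labels >= 0
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  ids <- sort(unique(labels))
  if (length(ids) < 2) return(NA_real_)
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(vapply(setdiff(own, i), ed, numeric(1), i = i))
    b <- Inf
    for (l in setdiff(ids, labels[i])) {
      mem <- which(labels == l)
      b <- min(b, mean(vapply(mem, ed, numeric(1), i = i)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Independent group-by VRI (population variance).
oracle_vri <- function(z, labels) {
  keep <- labels >= 0
  z <- z[keep]; labels <- labels[keep]
  pv <- function(v) mean((v - mean(v))^2)
  tot <- pv(z)
  acc <- 0
  for (l in unique(labels)) {
    m <- labels == l
    acc <- acc + (sum(m) / length(z)) * pv(z[m])
  }
  (1 - acc / tot) * 100
}

# 8-connected components of the cells carrying `lab` in a label matrix,
# by grid flood fill (no distances involved).
flood_fill_components <- function(values, lab) {
  nr <- nrow(values); nc <- ncol(values)
  inset <- !is.na(values) & values == lab
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (start in which(inset)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      cix <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cix)
      r <- ((cix - 1) %% nr) + 1; cc <- ((cix - 1) %/% nr) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        nix <- (c2 - 1) * nr + rr
        if (inset[nix] && !seen[nix]) { seen[nix] <- TRUE; queue <- c(queue, nix) }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Smallest component size over all labels of a label raster.
min_component_size <- function(label_raster) {
  labs <- sort(unique(label_raster$values[!is.na(label_raster$values)]))
  min(vapply(labs, function(l)
    min(lengths(flood_fill_components(label_raster$values, l))),
    numeric(1)))
}

# Dense ordinary-kriging solve over ALL points, built independently.
oracle_ok <- function(x, y, z, tx, ty, vmodel) {
  n <- length(x)
  G <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j)
      G[i, j] <- variogram_gamma(vmodel,
                                 sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  G[n + 1, seq_len(n)] <- 1; G[seq_len(n), n + 1] <- 1
  g0 <- vapply(seq_len(n), function(i)
    variogram_gamma(vmodel, sqrt((x[i] - tx)^2 + (y[i] - ty)^2)), numeric(1))
  sol <- solve(G, c(g0, 1))
  list(pred = sum(sol[seq_len(n)] * z), weights = sol[seq_len(n)])
}

# Single-linkage oracle: cut the k-1 longest MST edges (Prim's algorithm)
# and return the connected components.
oracle_mst_clusters <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  intree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0, 0, 3)
  mind <- D[, 1]; from <- rep(1L, n)
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    nxt <- cand[which.min(mind[cand])]
    edges <- rbind(edges, c(from[nxt], nxt, mind[nxt]))
    intree[nxt] <- TRUE
    upd <- !intree & D[, nxt] < mind
    mind[upd] <- D[upd, nxt]; from[upd] <- nxt
  }
  keep <- edges[order(edges[, 3])[seq_len(n - k)], , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(keep[, 1], keep[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$membership
}

# Empirical semivariogram by an explicit double loop over pairs.
oracle_semivariogram <- function(x, y, z, n_lags, max_lag) {
  width <- max_lag / n_lags
  gsum <- numeric(n_lags); cnt <- integer(n_lags)
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d <= 0 || d > max_lag) next
    b <- min(floor(d / width) + 1, n_lags)
    gsum[b] <- gsum[b] + (z[i] - z[j])^2
    cnt[b] <- cnt[b] + 1L
  }
  ok <- cnt > 0
  list(gamma = gsum[ok] / (2 * cnt[ok]), counts = cnt[ok])
}
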