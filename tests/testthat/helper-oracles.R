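# Independent brute-force oracles used to validate the graph-measure,
# modularity and statistics implementations. These deliberately use
# different algorithms from the package (Floyd-Warshall instead of
# Dijkstra, exhaustive path/partition enumeration instead of
# Brandes/spectral methods, direct hypergeometric sums instead of
# fisher.test).

# Floyd-Warshall all-pairs distances under l = 1/w.
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Betweenness by exhaustive enumeration of all shortest paths (DFS with
# distance-bound pruning). Ordered pairs, matching the package definition.
oracle_betweenness <- function(W, eps = 1e-9) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  D <- oracle_distances(W)
  bc <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t || !is.finite(D[s, t])) next
    paths <- list()
    dfs <- function(v, len, visited) {
      if (!is.finite(D[v, t]) || len + D[v, t] > D[s, t] + eps) return()
      if (v == t) {
        paths[[length(paths) + 1]] <<- visited
        return()
      }
      for (u in which(is.finite(L[v, ]))) {
        if (!(u %in% visited)) dfs(u, len + L[v, u], c(visited, u))
      }
    }
    dfs(s, 0, s)
    sigma <- length(paths)
    if (sigma == 0) next
    inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
    if (length(inner) > 0) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      bc[idx] <- bc[idx] + as.numeric(tab) / sigma
    }
  }
  bc
}

# Onnela clustering by exhaustive triple enumeration.
oracle_clustering_onnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  ci <- numeric(n)
  for (i in 1:n) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in 1:n) for (l in 1:n) {
      if (j == i || l == i || j == l) next
      s <- s + (Wh[i, j] * Wh[j, l] * Wh[l, i])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  ci
}

# Probabilistic clustering by exhaustive triple enumeration.
oracle_clustering_prob <- function(W) {
  n <- nrow(W)
  ci <- numeric(n)
  for (i in 1:n) {
    if (sum(W[i, ] > 0) < 2) next
    num <- 0; den <- 0
    for (j in 1:n) for (l in 1:n) {
      if (j == i || l == i || j == l) next
      num <- num + W[i, j] * W[i, l] * W[j, l]
      den <- den + W[i, j] * W[i, l]
    }
    if (den > 0) ci[i] <- num / den
  }
  ci
}

# Local efficiency (neighbour-subgraph efficiency) via the FW oracle.
oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  ei <- numeric(n)
  for (i in 1:n) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    D <- oracle_distances(W[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    ei[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  ei
}

oracle_global_efficiency <- function(D) {
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_path_length <- function(D) {
  n <- nrow(D)
  li <- vapply(1:n, function(i) {
    v <- D[i, -i]
    v <- v[is.finite(v)]
    if (length(v) == 0) NaN else mean(v)
  }, numeric(1))
  mean(li[is.finite(li)])
}

# All set partitions of n elements as membership vectors (restricted
# growth strings); Bell(8) = 4140.
set_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  res
}

# Exhaustive-search maximum modularity.
oracle_best_modularity <- function(W, partitions = NULL) {
  n <- nrow(W)
  if (is.null(partitions)) partitions <- set_partitions(n)
  best <- -Inf; best_m <- NULL
  for (m in partitions) {
    q <- restnet::modularity_q(W, m)
    if (q > best) { best <- q; best_m <- m }
  }
  list(q = best, membership = best_m)
}

# Two-sided Fisher exact p by direct hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n2 == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the step-up recursion.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n / i * p[o[i]])
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  np <- choose(length(a), 2)
  expected <- sa * sb / np
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# Random symmetric weighted graph for oracle sweeps.
random_test_graph <- function(n, density = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  k <- sum(ut)
  w <- ifelse(runif(k) < density, runif(k, 0.05, 1), 0)
  W[ut] <- w
  W + t(W)
}
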