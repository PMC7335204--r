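#' Four-criterion hub score
#'
#' A node scores one point for each of four criteria it meets: belonging
#' to the top 20% of nodes by (1) strength (the weighted-degree analogue;
#' on a fully weighted partial-correlation graph binary degree is constant)
#' and (4) betweenness centrality, or to the bottom 20% by (2) nodal
#' average shortest path length and (3) nodal clustering coefficient. The
#' hub score is the number of criteria met (0-4, maximum 4) and a node
#' with score >= 2 is marked as a hub.
#'
#' Criteria use strict inequality against the 80th (resp. 20th) percentile
#' across nodes, so an all-tied graph yields no hubs. Nodes with an
#' undefined path length (fully disconnected) are treated as worst
#' (infinite) for the path-length criterion.
#'
#' @param g a [weighted_graph()].
#' @param quantile proportion defining the top/bottom slice (default 0.20).
#' @param clustering_family passed to [clustering_coefficients()].
#' @return A tibble with one row per node: `node`, `strength`,
#'   `path_length`, `clustering`, `betweenness` (the criterion values),
#'   `hit_strength`, `hit_path_length`, `hit_clustering`,
#'   `hit_betweenness`, `hub_score`, `is_hub`.
#' @examples
#' g <- star_ring_graph()
#' hub_score(g)
#' @export
hub_score <- function(g, quantile = 0.20,
                      clustering_family = c("onnela", "prob")) {
  clustering_family <- match.arg(clustering_family)
  d <- shortest_path_matrix(g)
  si <- node_strength(g)
  # fully disconnected nodes are handled explicitly below (worst rank)
  li <- suppressWarnings(path_length(d))$nodal
  li[!is.finite(li)] <- Inf
  ci <- clustering_coefficients(g, clustering_family)
  bi <- betweenness_centrality(g)

  hi_thr <- function(x) quantile(x, 1 - quantile, names = FALSE)
  lo_thr <- function(x) {
    q <- quantile(x[is.finite(x)], quantile, names = FALSE)
    if (length(q) == 0) -Inf else q
  }
  hit_s <- si > hi_thr(si)
  hit_l <- li < lo_thr(li)
  hit_c <- ci < lo_thr(ci)
  hit_b <- bi > hi_thr(bi)
  score <- hit_s + hit_l + hit_c + hit_b
  tibble::tibble(
    node = g$node_labels,
    strength = unname(si), path_length = unname(li),
    clustering = unname(ci), betweenness = unname(bi),
    hit_strength = unname(hit_s), hit_path_length = unname(hit_l),
    hit_clustering = unname(hit_c), hit_betweenness = unname(hit_b),
    hub_score = unname(as.integer(score)),
    is_hub = unname(score >= 2)
  )
}

#' Star-plus-weak-ring test graph
#'
#' A 12-node graph whose centre is connected to every leaf with weight
#' `hub_weight` while the leaves form a weak ring of weight `ring_weight`.
#' The centre dominates all four hub criteria, making this a canonical
#' positive control for [hub_score()].
#'
#' @param n_leaves number of leaves (default 11).
#' @param hub_weight centre-leaf weight (default 1).
#' @param ring_weight leaf-leaf ring weight (default 0.1).
#' @return A [weighted_graph()] with the centre as node `"hub"`.
#' @export
star_ring_graph <- function(n_leaves = 11, hub_weight = 1, ring_weight = 0.1) {
  n <- n_leaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- hub_weight
  w[2:n, 1] <- hub_weight
  for (i in seq_len(n_leaves)) {
    j <- 1 + i
    k <- 1 + (i %% n_leaves) + 1
    w[j, k] <- ring_weight
    w[k, j] <- ring_weight
  }
  weighted_graph(w, c("hub", paste0("leaf", seq_len(n_leaves))))
}

#' Newman spectral modularity partition
#'
#' Community detection by Newman's leading-eigenvector spectral bisection
#' with Kernighan-Lin-style fine-tuning, maximizing the weighted modularity
#' `Q = (1/2m) sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j)`. Recursive
#' bisection continues while a split increases `Q`; a final refinement pass
#' greedily moves single nodes between modules and merges module pairs
#' until no move improves `Q`. The algorithm is deterministic.
#'
#' @param g a [weighted_graph()].
#' @return An object of class `graph_partition`: tibble `membership`
#'   (node, module) and modularity value `q`.
#' @examples
#' g <- planted_block_graph(c(5, 5), within = 0.6, between = 0.05, seed = 1)
#' newman_partition(g)$q
#' @export
newman_partition <- function(g) {
  w <- g$weights
  n <- nrow(w)
  two_m <- sum(w)
  if (n == 0 || two_m == 0) {
    return(new_partition(g, rep(1L, n), 0))
  }
  s <- rowSums(w)
  B <- w - outer(s, s) / two_m

  membership <- rep(1L, n)
  # recursive bisection on index sets
  divide <- function(idx) {
    if (length(idx) < 2) return(list(idx))
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)   # generalized modularity matrix
    if (length(idx) <= 12) {
      # small subsets: evaluate every bisection exactly
      sv <- best_bisection(Bg)
    } else {
      eig <- eigen(Bg, symmetric = TRUE)
      if (eig$values[1] <= 1e-12) return(list(idx))
      sv <- ifelse(eig$vectors[, 1] >= 0, 1, -1)
      sv <- kl_fine_tune(Bg, sv)
    }
    dq <- as.numeric(t(sv) %*% Bg %*% sv) / (2 * two_m)
    if (dq <= 1e-12 || length(unique(sv)) == 1) return(list(idx))
    c(divide(idx[sv > 0]), divide(idx[sv < 0]))
  }
  groups <- divide(seq_len(n))
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  membership <- refine_partition(w, membership)
  q <- modularity_q(w, membership)
  # on small graphs a greedy-agglomerative start occasionally beats the
  # spectral one; keep whichever refines to the higher Q, then apply a
  # full Kernighan-Lin pass (tentative non-improving moves, best
  # intermediate kept) to escape shallow local optima
  # multiway seed from the sign pattern of the two leading eigenvectors
  # of the modularity matrix (Newman's multiple-eigenvector variant)
  seed2 <- NULL
  if (n >= 3) {
    eig2 <- eigen(B, symmetric = TRUE)
    seed2 <- as.integer(factor(paste(eig2$vectors[, 1] >= 0,
                                     eig2$vectors[, 2] >= 0)))
    m3 <- refine_partition(w, seed2)
    q3 <- modularity_q(w, m3)
    if (q3 > q + 1e-12) { membership <- m3; q <- q3 }
  }
  if (n <= 14) {
    # small graphs: Kernighan-Lin passes from every start, keep the best
    starts <- list(membership, agglom_partition(w))
    if (!is.null(seed2)) starts <- c(starts, list(seed2))
    for (st in starts) {
      kl <- kl_partition_refine(w, st)
      kl2 <- kl_partition_refine(w, refine_partition(w, st))
      for (cand in list(kl, kl2)) {
        if (cand$q > q + 1e-12) { membership <- cand$membership; q <- cand$q }
      }
    }
  }
  new_partition(g, membership, q)
}

# Kernighan-Lin style fine tuning of a +/-1 split vector against the
# (generalized) modularity matrix: repeated passes, each moving every
# vertex once in order of best gain, keeping the best intermediate state.
kl_fine_tune <- function(Bg, sv) {
  n <- length(sv)
  repeat {
    best_sv <- sv
    best_val <- as.numeric(t(sv) %*% Bg %*% sv)
    cur <- sv
    moved <- rep(FALSE, n)
    improved <- FALSE
    for (step in seq_len(n)) {
      # gain of flipping vertex i: delta = -4 * cur_i * (Bg cur)_i + 4 Bg_ii
      h <- as.numeric(Bg %*% cur)
      gains <- -4 * cur * h + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      val <- as.numeric(t(cur) %*% Bg %*% cur)
      if (val > best_val + 1e-12) {
        best_val <- val
        best_sv <- cur
        improved <- TRUE
      }
    }
    if (!improved) return(best_sv)
    sv <- best_sv
  }
}

# Exhaustive best bisection of a (generalized) modularity matrix: the
# split maximizing s' Bg s over all +/-1 vectors (feasible for <= 12
# vertices; 2^(n-1) candidates by symmetry).
best_bisection <- function(Bg) {
  n <- nrow(Bg)
  best_val <- -Inf; best_sv <- rep(1, n)
  for (code in 0:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n - 1)]
    sv <- c(1, ifelse(bits == 1, 1, -1))
    val <- as.numeric(t(sv) %*% Bg %*% sv)
    if (val > best_val) { best_val <- val; best_sv <- sv }
  }
  best_sv
}

# Kernighan-Lin refinement over full partitions: in each pass every node
# is tentatively moved once (to the momentarily best target module or a
# new singleton, even when the gain is negative) and the best
# intermediate partition of the pass is adopted if it improves Q.
kl_partition_refine <- function(w, membership, max_pass = 30) {
  n <- length(membership)
  q <- modularity_q(w, membership)
  for (pass in seq_len(max_pass)) {
    cur <- membership
    best <- cur; best_q <- q
    moved <- rep(FALSE, n)
    for (step in seq_len(n)) {
      bq <- -Inf; bi <- NA_integer_; bm <- NA_integer_
      for (i in which(!moved)) {
        mods <- unique(cur)
        for (m in c(setdiff(mods, cur[i]), max(mods) + 1L)) {
          trial <- cur
          trial[i] <- m
          tq <- modularity_q(w, trial)
          if (tq > bq) { bq <- tq; bi <- i; bm <- m }
        }
      }
      cur[bi] <- bm
      moved[bi] <- TRUE
      if (bq > best_q + 1e-12) { best_q <- bq; best <- cur }
    }
    if (best_q > q + 1e-12) {
      membership <- best
      q <- best_q
    } else break
  }
  list(membership = as.integer(factor(membership)), q = q)
}

# Greedy agglomeration from singletons, tracking the best state seen.
agglom_partition <- function(w) {
  n <- nrow(w)
  cur <- seq_len(n)
  best <- cur
  best_q <- modularity_q(w, cur)
  while (length(unique(cur)) > 1) {
    mods <- sort(unique(cur))
    bq <- -Inf; bpair <- NULL
    for (a in seq_along(mods)) for (b in seq_along(mods)) {
      if (a >= b) next
      trial <- cur
      trial[trial == mods[b]] <- mods[a]
      tq <- modularity_q(w, trial)
      if (tq > bq) { bq <- tq; bpair <- c(mods[a], mods[b]) }
    }
    cur[cur == bpair[2]] <- bpair[1]
    if (bq > best_q + 1e-12) { best_q <- bq; best <- cur }
  }
  as.integer(factor(best))
}

# Greedy node-move (including moves into a fresh singleton module) +
# module-merge refinement of a membership vector.
refine_partition <- function(w, membership) {
  q <- modularity_q(w, membership)
  repeat {
    improved <- FALSE
    for (i in seq_along(membership)) {
      mods <- sort(unique(membership))
      best_q <- q; best_m <- membership[i]
      for (m in c(mods, max(mods) + 1L)) {
        if (m == membership[i]) next
        trial <- membership; trial[i] <- m
        tq <- modularity_q(w, trial)
        if (tq > best_q + 1e-12) { best_q <- tq; best_m <- m }
      }
      if (best_m != membership[i]) {
        membership[i] <- best_m
        q <- best_q
        improved <- TRUE
      }
    }
    mods <- sort(unique(membership))
    if (length(mods) > 1) {
      for (a in seq_along(mods)) for (b in seq_along(mods)) {
        if (a >= b) next
        trial <- membership
        trial[trial == mods[b]] <- mods[a]
        tq <- modularity_q(w, trial)
        if (tq > q + 1e-12) {
          membership <- trial
          q <- tq
          improved <- TRUE
          mods <- sort(unique(membership))
        }
      }
    }
    if (!improved) break
  }
  as.integer(factor(membership))
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j)`.
#'
#' @param w symmetric weight matrix or [weighted_graph()].
#' @param membership integer module labels, one per node.
#' @return Scalar modularity in `[-1, 1]`; 0 for an empty graph.
#' @export
modularity_q <- function(w, membership) {
  if (inherits(w, "weighted_graph")) w <- w$weights
  two_m <- sum(w)
  if (two_m == 0) return(0)
  s <- rowSums(w)
  q <- 0
  for (m in unique(membership)) {
    idx <- membership == m
    q <- q + sum(w[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2
  }
  q
}

new_partition <- function(g, membership, q) {
  structure(list(
    membership = tibble::tibble(node = g$node_labels,
                                module = as.integer(membership)),
    q = q
  ), class = "graph_partition")
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf("<graph_partition: %d modules, Q = %.4f>\n",
              length(unique(x$membership$module)), x$q))
  invisible(x)
}

#' @export
tidy.graph_partition <- function(x, ...) x$membership

#' @export
glance.graph_partition <- function(x, ...) {
  tibble::tibble(n_modules = length(unique(x$membership$module)), q = x$q)
}

#' Planted block-structure graph
#'
#' Builds a weighted graph with `length(sizes)` modules: within-module
#' edges at weight `within` and between-module edges at weight `between`,
#' optionally jittered by positive multiplicative noise so that nodal
#' measures are tie-free.
#'
#' @param sizes module sizes.
#' @param within,between edge weights inside / across modules.
#' @param noise_sd sd of multiplicative log-normal jitter (0 = none).
#' @param seed RNG seed for the jitter.
#' @return A [weighted_graph()] with the planted membership in attribute
#'   `"planted"`.
#' @export
planted_block_graph <- function(sizes, within = 0.5, between = 0.05,
                                noise_sd = 0, seed = 1L) {
  n <- sum(sizes)
  memb <- rep(seq_along(sizes), sizes)
  w <- ifelse(outer(memb, memb, "=="), within, between)
  diag(w) <- 0
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    jit <- matrix(exp(rnorm(n * n, 0, noise_sd)), n, n)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    w <- pmin(w * jit, 1)
    diag(w) <- 0
  }
  g <- weighted_graph(w)
  attr(g, "planted") <- memb
  g
}

#' Per-group hub frequency table
#'
#' Percentage of subjects, per group, in which each node is a hub.
#'
#' @param hub_results list of [hub_score()] tibbles, one per subject.
#' @param groups vector of group labels parallel to `hub_results`.
#' @return A tibble: `node`, `group`, `n_subjects`, `n_hub`, `pct_hub`.
#' @export
group_hub_table <- function(hub_results, groups) {
  stopifnot(length(hub_results) == length(groups))
  df <- purrr::map2_dfr(hub_results, as.character(groups),
                        ~ dplyr::mutate(.x[, c("node", "is_hub")], group = .y))
  df |>
    dplyr::group_by(.data$group, .data$node) |>
    dplyr::summarise(n_subjects = dplyr::n(), n_hub = sum(.data$is_hub),
                     .groups = "drop") |>
    dplyr::mutate(pct_hub = 100 * .data$n_hub / .data$n_subjects)
}

#' Group-level hubs versus random equivalent networks
#'
#' Flags, per group, the nodes whose within-group hub frequency exceeds
#' the frequency expected under subject-matched random equivalent graphs
#' (one weight-permutation null per subject): threshold = null mean + 2
#' null SDs of the per-node null hub frequencies. This operationalizes
#' "hubs versus equivalent random networks" for descriptive group tables;
#' the reading is interpretive and is labelled as such in the output
#' attribute `"definition"`.
#'
#' @param graphs list of [weighted_graph()], one per subject.
#' @param groups group labels parallel to `graphs`.
#' @param seed seed for the per-subject null draws.
#' @param quantile hub-criterion quantile, see [hub_score()].
#' @return Tibble: `group`, `node`, `pct_hub`, `null_pct_mean`,
#'   `null_pct_sd` (across nodes), `threshold`, `is_group_hub`.
#' @export
group_hubs <- function(graphs, groups, seed = 1L, quantile = 0.20) {
  stopifnot(length(graphs) == length(groups))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  obs <- vector("list", length(graphs))
  nul <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    obs[[i]] <- hub_score(graphs[[i]], quantile = quantile)
    set.seed(as.integer(seed) + i)
    nul[[i]] <- hub_score(random_equivalent_graph(graphs[[i]]),
                          quantile = quantile)
  }
  ot <- group_hub_table(obs, groups)
  nt <- group_hub_table(nul, groups)
  out <- dplyr::left_join(
    ot,
    nt |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(null_pct_mean = mean(.data$pct_hub),
                       null_pct_sd = sd(.data$pct_hub), .groups = "drop"),
    by = "group"
  ) |>
    dplyr::mutate(threshold = .data$null_pct_mean + 2 * .data$null_pct_sd,
                  is_group_hub = .data$pct_hub > .data$threshold)
  attr(out, "definition") <-
    "group hub: within-group hub frequency > mean + 2 SD of per-node hub frequencies under subject-matched weight-permutation nulls (interpretive)"
  out
}

#' Per-group co-module frequency matrices
#'
#' For each group, the N x N matrix of the proportion of subjects in which
#' each pair of nodes falls in the same module (diagonal 1). Invariant to
#' module relabelling.
#'
#' @param partitions list of `graph_partition` objects, one per subject.
#' @param groups group labels parallel to `partitions`.
#' @return Named list (by group) of symmetric frequency matrices.
#' @export
comodule_matrix <- function(partitions, groups) {
  stopifnot(length(partitions) == length(groups))
  groups <- as.character(groups)
  out <- list()
  for (gname in unique(groups)) {
    idx <- which(groups == gname)
    acc <- NULL
    for (i in idx) {
      m <- partitions[[i]]$membership$module
      ind <- outer(m, m, "==") * 1
      acc <- if (is.null(acc)) ind else acc + ind
    }
    acc <- acc / length(idx)
    labs <- partitions[[idx[1]]]$membership$node
    dimnames(acc) <- list(labs, labs)
    out[[gname]] <- acc
  }
  out
}

#' Group consensus partition from the mean weight matrix
#'
#' Averages the weight matrices of a group's subjects and partitions the
#' mean graph with [newman_partition()] — the descriptive group-level
#' modularity table.
#'
#' @param graphs list of [weighted_graph()] for one group.
#' @return A `graph_partition`.
#' @export
group_consensus_partition <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  acc <- Reduce(`+`, lapply(graphs, function(g) g$weights)) / length(graphs)
  newman_partition(weighted_graph(acc, graphs[[1]]$node_labels))
}

#' Plot module membership as a tile strip
#'
#' @param object a `graph_partition`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.graph_partition <- function(object, ...) {
  df <- object$membership
  df$node <- factor(df$node, levels = df$node)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = 1,
                                   fill = factor(.data$module))) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "module",
                  title = sprintf("Q = %.3f", object$q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
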