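#' All-pairs weighted shortest-path distances
#'
#' Edge lengths are the reciprocal weights (`l_ij = 1/w_ij`, with `w_ij = 0`
#' meaning no edge, length infinite) — the convention of the Brain
#' Connectivity Toolbox for weighted graphs, where a strong connection is a
#' short distance. Disconnection is encoded as `Inf`; `d_ii = 0`.
#'
#' @param g a [weighted_graph()].
#' @return N x N numeric matrix of shortest-path distances.
#' @export
shortest_path_matrix <- function(g) {
  res <- graph_paths_cpp(g$weights)
  d <- res$distances
  dimnames(d) <- list(g$node_labels, g$node_labels)
  d
}

#' Node strength
#'
#' Sum of the weights of all edges incident to each node — the weighted
#' analogue of degree (on a fully weighted partial-correlation graph binary
#' degree is constant, so strength is the informative quantity).
#'
#' @param g a [weighted_graph()].
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(g) {
  setNames(rowSums(g$weights), g$node_labels)
}

#' Nodal and global characteristic path length
#'
#' `L_i` is the mean finite shortest-path distance from node `i` to every
#' other node; infinite entries (disconnected pairs) are excluded and
#' counted. The global `L` is the mean of the defined `L_i`.
#'
#' @param distances distance matrix from [shortest_path_matrix()].
#' @return A list with `nodal` (named vector `L_i`, `NaN` where a node
#'   reaches no other node), `global` (`L`), and `n_infinite` (count of
#'   excluded infinite ordered pairs).
#' @export
path_length <- function(distances) {
  n <- nrow(distances)
  d <- distances
  diag(d) <- NA
  finite <- is.finite(d)
  n_inf <- sum(!finite & !is.na(d))
  li <- vapply(seq_len(n), function(i) {
    v <- d[i, ][finite[i, ]]
    if (length(v) == 0) NaN else mean(v)
  }, numeric(1))
  names(li) <- rownames(distances)
  defined <- is.finite(li)
  if (!all(defined)) {
    warning(sprintf("%d node(s) reach no other node; excluded from global L",
                    sum(!defined)), call. = FALSE)
  }
  list(nodal = li,
       global = if (any(defined)) mean(li[defined]) else NaN,
       n_infinite = n_inf)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the reciprocal shortest-path distance,
#' with disconnected pairs contributing 0 — an integration measure that is
#' robust to disconnection.
#'
#' @param distances distance matrix from [shortest_path_matrix()].
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(distances) {
  n <- nrow(distances)
  if (n < 2) return(0)
  inv <- 1 / distances
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted clustering coefficients
#'
#' Two weighted generalizations of the clustering coefficient are
#' available:
#'
#' * `"onnela"` (default): geometric-mean triangle intensity,
#'   `c_i = sum_{jk} (w'_ij w'_jk w'_ik)^(1/3) / (k_i (k_i - 1))` with
#'   weights rescaled by the graph maximum (`w' = w / max(w)`) and `k_i`
#'   the number of neighbours with strictly positive weight.
#' * `"prob"`: probabilistic form treating weights as connection
#'   probabilities, `c_i = sum_{j != k} w_ij w_ik w_jk / sum_{j != k}
#'   w_ij w_ik`.
#'
#' Both reduce to the binary clustering coefficient on 0/1 weights, and
#' `c_i = 0` where a node has fewer than two neighbours.
#'
#' @param g a [weighted_graph()].
#' @param family `"onnela"` or `"prob"`.
#' @return Named numeric vector of nodal clustering coefficients.
#' @export
clustering_coefficients <- function(g, family = c("onnela", "prob")) {
  family <- match.arg(family)
  w <- g$weights
  n <- nrow(w)
  k <- rowSums(w > 0)
  if (family == "onnela") {
    mx <- max(w)
    if (mx == 0) return(setNames(rep(0, n), g$node_labels))
    wh <- (w / mx)^(1 / 3)
    numer <- diag(wh %*% wh %*% wh)
    denom <- k * (k - 1)
    ci <- ifelse(denom > 0, numer / denom, 0)
  } else {
    numer <- diag(w %*% w %*% w)
    # sum_{j != k} w_ij w_ik = (sum_j w_ij)^2 - sum_j w_ij^2
    denom <- rowSums(w)^2 - rowSums(w^2)
    ci <- ifelse(denom > 0 & k >= 2, numer / denom, 0)
  }
  setNames(as.numeric(ci), g$node_labels)
}

#' Nodal betweenness centrality
#'
#' Brandes-style counting of weighted shortest paths (`l = 1/w`):
#' `b_i = sum over ordered pairs (s, t), s != t != i, of the fraction of
#' shortest s-t paths passing through i`.
#'
#' @param g a [weighted_graph()].
#' @return Named numeric vector of nodal betweenness values.
#' @export
betweenness_centrality <- function(g) {
  res <- graph_paths_cpp(g$weights)
  setNames(as.numeric(res$betweenness), g$node_labels)
}

#' Nodal local efficiency
#'
#' For `family = "onnela"` (default) this is the global efficiency of the
#' subgraph induced on the neighbours of each node (with the graph's own
#' weights). For `family = "prob"` the probabilistic form
#' `e_i = sum_{j != k} w_ij w_ik / d_jk(N_i) / sum_{j != k} w_ij w_ik`
#' is used, where `d_jk(N_i)` is the shortest-path distance between `j`
#' and `k` in the subgraph excluding `i`.
#'
#' @inheritParams clustering_coefficients
#' @return Named numeric vector of local efficiencies.
#' @export
local_efficiency <- function(g, family = c("onnela", "prob")) {
  family <- match.arg(family)
  w <- g$weights
  n <- nrow(w)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) { ei[i] <- 0; next }
    if (family == "onnela") {
      sub <- weighted_graph(w[nb, nb, drop = FALSE])
      ei[i] <- global_efficiency(shortest_path_matrix(sub))
    } else {
      rest <- setdiff(seq_len(n), i)
      dsub <- graph_paths_cpp(w[rest, rest, drop = FALSE])$distances
      idx <- match(nb, rest)
      wi <- w[i, nb]
      num <- 0; den <- 0
      for (a in seq_along(nb)) for (b in seq_along(nb)) {
        if (a == b) next
        pr <- wi[a] * wi[b]
        den <- den + pr
        dj <- dsub[idx[a], idx[b]]
        if (is.finite(dj) && dj > 0) num <- num + pr / dj
      }
      ei[i] <- if (den > 0) num / den else 0
    }
  }
  setNames(ei, g$node_labels)
}

#' Global and nodal weighted graph measures
#'
#' Computes, for one subject's weighted graph, the four global measures
#' (characteristic path length `L`, clustering coefficient `C`, global
#' efficiency `E`, betweenness centrality `BC` = mean nodal betweenness by
#' default) and the five nodal measures (strength, average shortest path
#' length, clustering, local efficiency, betweenness).
#'
#' @param g a [weighted_graph()].
#' @param clustering_family weighted clustering generalization, see
#'   [clustering_coefficients()].
#' @param bc_aggregate how nodal betweenness is aggregated into the global
#'   `BC`: `"mean"` (default) or `"max"`.
#' @return An object of class `graph_measures` with elements `global`
#'   (tibble: measure, value) and `nodal` (tibble: node, measure, value),
#'   plus the options used.
#' @examples
#' w <- matrix(0.5, 5, 5); diag(w) <- 0
#' m <- graph_measures(weighted_graph(w))
#' m$global
#' @export
graph_measures <- function(g, clustering_family = c("onnela", "prob"),
                           bc_aggregate = c("mean", "max")) {
  clustering_family <- match.arg(clustering_family)
  bc_aggregate <- match.arg(bc_aggregate)
  d <- shortest_path_matrix(g)
  pl <- path_length(d)
  ci <- clustering_coefficients(g, clustering_family)
  bi <- betweenness_centrality(g)
  si <- node_strength(g)
  ei <- local_efficiency(g, clustering_family)
  glob <- tibble::tibble(
    measure = c("characteristic_path_length", "clustering_coefficient",
                "global_efficiency", "betweenness_centrality"),
    value = c(pl$global, mean(ci), global_efficiency(d),
              if (bc_aggregate == "mean") mean(bi) else max(bi))
  )
  nodal <- tibble::tibble(
    node = rep(g$node_labels, times = 5),
    measure = rep(c("strength", "avg_shortest_path_length", "clustering",
                    "local_efficiency", "betweenness"),
                  each = length(g$node_labels)),
    value = c(si, pl$nodal, ci, ei, bi)
  )
  structure(list(global = glob, nodal = nodal,
                 clustering_family = clustering_family,
                 bc_aggregate = bc_aggregate,
                 n_infinite_pairs = pl$n_infinite),
            class = "graph_measures")
}

#' @export
print.graph_measures <- function(x, ...) {
  cat("<graph_measures>\n")
  print(tidyr::pivot_wider(x$global, names_from = "measure",
                           values_from = "value"))
  invisible(x)
}

#' @export
tidy.graph_measures <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$global, scope = "global", node = NA_character_),
    dplyr::mutate(x$nodal, scope = "nodal")
  )[, c("scope", "node", "measure", "value")]
}

#' @export
glance.graph_measures <- function(x, ...) {
  tidyr::pivot_wider(x$global, names_from = "measure", values_from = "value")
}
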