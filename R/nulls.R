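#' Random equivalent graph (weight-permutation null)
#'
#' Draws a null graph with the same nodes and exactly the same multiset of
#' edge weights, but with the weights uniformly re-assigned to positions:
#' the complete upper triangle (including zero weights) is permuted and
#' mirrored, so symmetry and the zero diagonal are preserved. This is the
#' null model used to normalize graph measures, which destroys any
#' topological placement of weights while keeping the weight distribution.
#'
#' Uses the current R RNG state; seed with [set.seed()] or let
#' [normalize_measures()] manage the seeding.
#'
#' @param g a [weighted_graph()].
#' @return A [weighted_graph()] with permuted weights.
#' @export
random_equivalent_graph <- function(g) {
  w <- g$weights
  n <- nrow(w)
  ut <- upper.tri(w)
  vals <- w[ut]
  perm <- sample.int(length(vals))
  out <- matrix(0, n, n)
  out[ut] <- vals[perm]
  out <- out + t(out)
  weighted_graph(out, g$node_labels)
}

#' Normalize global graph measures against random equivalent graphs
#'
#' Divides each global measure of `g` by its aggregate (mean by default,
#' median selectable) over an ensemble of `n_null` weight-permutation
#' nulls. Nodal measures are left raw; only the four global measures are
#' normalized. If a null aggregate is 0 the ratio is undefined and is
#' reported as `NA`, except in the degenerate case where the raw value is
#' also exactly 0 (graph and nulls identical), which is reported as 1.
#'
#' @param g a [weighted_graph()].
#' @param n_null ensemble size (default 1000).
#' @param seed integer seed for the permutation ensemble.
#' @param statistic null aggregation, `"mean"` (default) or `"median"`.
#' @param clustering_family passed to [graph_measures()].
#' @param bc_aggregate passed to [graph_measures()].
#' @return A tibble with one row per global measure: `measure`, `raw`,
#'   `null_mean`, `null_sd`, `normalized`, `n_null`.
#' @examples
#' w <- matrix(0.5, 6, 6); diag(w) <- 0
#' normalize_measures(weighted_graph(w), n_null = 10, seed = 1)
#' @export
normalize_measures <- function(g, n_null = 1000, seed = 1L,
                               statistic = c("mean", "median"),
                               clustering_family = c("onnela", "prob"),
                               bc_aggregate = c("mean", "max")) {
  stopifnot(n_null >= 1)
  statistic <- match.arg(statistic)
  clustering_family <- match.arg(clustering_family)
  bc_aggregate <- match.arg(bc_aggregate)

  raw <- global_measures_fast(g, clustering_family, bc_aggregate)
  nulls <- matrix(NA_real_, nrow = n_null, ncol = 4,
                  dimnames = list(NULL, names(raw)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (k in seq_len(n_null)) {
    nulls[k, ] <- global_measures_fast(random_equivalent_graph(g),
                                       clustering_family, bc_aggregate)
  }
  agg <- apply(nulls, 2, if (statistic == "mean") mean else median)
  normalized <- ifelse(agg == 0, ifelse(raw == 0, 1, NA_real_), raw / agg)
  tibble::tibble(
    measure = names(raw),
    raw = unname(raw),
    null_mean = unname(colMeans(nulls)),
    null_sd = unname(apply(nulls, 2, sd)),
    normalized = unname(normalized),
    n_null = n_null
  )
}

# The four global measures without the nodal extras (used per null draw).
global_measures_fast <- function(g, clustering_family = "onnela",
                                 bc_aggregate = "mean") {
  res <- graph_paths_cpp(g$weights)
  pl <- path_length(res$distances)
  ci <- clustering_coefficients(g, clustering_family)
  bc <- if (bc_aggregate == "mean") mean(res$betweenness) else max(res$betweenness)
  c(characteristic_path_length = pl$global,
    clustering_coefficient = mean(ci),
    global_efficiency = global_efficiency(res$distances),
    betweenness_centrality = bc)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
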