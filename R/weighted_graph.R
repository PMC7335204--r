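#' Weighted graph container
#'
#' A `weighted_graph` is a symmetric N x N matrix of edge weights in
#' `[0, 1]` with a zero diagonal, plus node labels. In this pipeline the
#' weights are absolute partial correlations, so the graph is fully
#' weighted (no thresholding or binarization is ever applied).
#'
#' @param weights symmetric numeric matrix, entries in `[0, 1]`, zero
#'   diagonal (the diagonal is zeroed if not already).
#' @param node_labels character vector of node names; defaults to the
#'   matrix dimnames or `"n1".."nN"`.
#' @return An object of class `weighted_graph`.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' g <- weighted_graph(w)
#' node_strength(g)
#' @export
weighted_graph <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("`weights` must be a square matrix", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0) || any(weights > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, node_labels = node_labels),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- length(x$node_labels)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_graph: %d nodes, %d / %d nonzero edges, mean weight %.3f>\n",
              n, nz, n * (n - 1) / 2, mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' @export
as.matrix.weighted_graph <- function(x, ...) x$weights

n_nodes <- function(g) nrow(g$weights)

#' Heatmap of a weighted graph's adjacency matrix
#'
#' @param object a [weighted_graph()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.weighted_graph <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
tidy.weighted_graph <- function(x, ...) {
  w <- x$weights
  tibble::tibble(
    from = factor(rep(x$node_labels, times = ncol(w)), levels = x$node_labels),
    to = factor(rep(x$node_labels, each = nrow(w)), levels = x$node_labels),
    weight = as.vector(w)
  )
}
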