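#' Partial correlations among node time series
#'
#' Estimates the full-conditioning partial correlation matrix
#' `pcorr_ij = -P_ij / sqrt(P_ii P_jj)` where `P` is the inverse of the
#' sample correlation matrix of all N series (computed on uncensored
#' volumes only). Each off-diagonal entry is the correlation between two
#' nodes after removing the linear influence of every other node.
#'
#' By default the correlation matrix is inverted directly; when it is
#' ill-conditioned (condition number > `cond_limit`) or the number of
#' uncensored volumes is at most `2N`, a Ledoit-Wolf-style shrinkage
#' toward the identity is applied with the Schafer-Strimmer analytic
#' intensity before inversion. The estimator actually used is recorded.
#' Working on the correlation (not covariance) scale makes the result
#' invariant to per-node affine rescaling.
#'
#' @param ts T x N matrix or data frame of node time series.
#' @param mask logical censor vector or [censor_volumes()] tibble; censored
#'   rows are excluded (listwise) from the covariance computation.
#' @param shrinkage `"auto"` (default), `"always"`, or `"never"`.
#' @param cond_limit condition-number threshold triggering shrinkage in
#'   `"auto"` mode (default 1e8).
#' @return An object of class `connectivity_matrix`: `pcorr` (N x N,
#'   diagonal 1), `estimator` (`"pseudo-inverse"` or `"shrinkage"`),
#'   `shrinkage_lambda`, `condition_number`, `n_volumes_used`.
#' @examples
#' x <- matrix(rnorm(600), 200, 3)
#' partial_correlation(x)$estimator
#' @export
partial_correlation <- function(ts, mask = NULL, shrinkage = c("auto", "always", "never"),
                                cond_limit = 1e8) {
  shrinkage <- match.arg(shrinkage)
  y <- as.matrix(ts)
  n <- ncol(y)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, nrow(y))
  if (is.data.frame(mask)) mask <- mask$censored
  y <- y[!mask, , drop = FALSE]
  t_used <- nrow(y)
  if (t_used <= n && shrinkage == "never") {
    stop("ill-posed: fewer uncensored volumes than nodes and shrinkage disabled",
         call. = FALSE)
  }
  sds <- apply(y, 2, sd)
  if (any(sds == 0)) {
    if (shrinkage == "never") {
      stop("ill-posed: constant series present and shrinkage disabled",
           call. = FALSE)
    }
    sds[sds == 0] <- 1
  }
  r <- cov(y) / outer(sds, sds)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  use_shrink <- shrinkage == "always" ||
    (shrinkage == "auto" && (cond > cond_limit || t_used <= 2 * n))
  lambda <- NA_real_
  if (use_shrink) {
    lambda <- shrinkage_intensity(scale(y, center = TRUE, scale = sds))
    r <- (1 - lambda) * r + lambda * diag(n)
  } else if (!is.finite(cond)) {
    stop("ill-posed: singular correlation matrix and shrinkage disabled",
         call. = FALSE)
  }
  p <- solve(r)
  pc <- -p / sqrt(outer(diag(p), diag(p)))
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- list(colnames(ts), colnames(ts))
  structure(list(pcorr = pc,
                 estimator = if (use_shrink) "shrinkage" else "pseudo-inverse",
                 shrinkage_lambda = lambda,
                 condition_number = cond,
                 n_volumes_used = t_used),
            class = "connectivity_matrix")
}

# Schafer-Strimmer analytic shrinkage intensity toward the identity on the
# correlation scale: lambda* = sum Var(r_ij) / sum r_ij^2 (off-diagonal),
# clipped to [0, 1]; x must already be standardized columns.
shrinkage_intensity <- function(x) {
  t_len <- nrow(x)
  n <- ncol(x)
  if (t_len < 3) return(1)
  w_bar <- crossprod(x) / t_len          # mean of w_tij = x_ti x_tj
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- x[, i] * x[, j]
      v <- t_len / ((t_len - 1)^3) * sum((w - mean(w))^2)
      r_ij <- t_len / (t_len - 1) * w_bar[i, j]
      num <- num + v
      den <- den + r_ij^2
    }
  }
  if (den == 0) return(1)
  max(0, min(1, num / den))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %d nodes, estimator = %s (cond = %.3g, T = %d)>\n",
              nrow(x$pcorr), x$estimator, x$condition_number, x$n_volumes_used))
  invisible(x)
}

#' Partial correlations from a known covariance matrix
#'
#' Population version of [partial_correlation()]: applies
#' `-P_ij / sqrt(P_ii P_jj)` to the inverse of a given covariance matrix,
#' with no sampling. Used to verify estimators against planted ground
#' truth.
#'
#' @param sigma positive-definite covariance matrix.
#' @return N x N partial correlation matrix, diagonal 1.
#' @export
pcorr_from_covariance <- function(sigma) {
  p <- solve(sigma)
  pc <- -p / sqrt(outer(diag(p), diag(p)))
  diag(pc) <- 1
  (pc + t(pc)) / 2
}

#' Weighted graph from a connectivity matrix
#'
#' Takes the absolute value of the off-diagonal partial correlations as
#' edge weights (zero diagonal). Negative and positive partial
#' correlations of equal magnitude deliberately receive the same weight,
#' so all weights lie in `[0, 1]`.
#'
#' @param c a `connectivity_matrix` (or a bare partial-correlation
#'   matrix).
#' @return A [weighted_graph()].
#' @export
to_weighted_graph <- function(c) {
  pc <- if (inherits(c, "connectivity_matrix")) c$pcorr else as.matrix(c)
  w <- abs(pc)
  diag(w) <- 0
  w <- pmin(w, 1)
  weighted_graph(w, rownames(pc))
}

#' Extract mean gray-matter ROI time series from 4D NIfTI (convenience)
#'
#' Per node, averages the 4D image over voxels carrying that node's atlas
#' label whose gray-matter probability exceeds `threshold`. This is an
#' optional convenience for users with their own spatially preprocessed
#' images; the rest of the pipeline consumes plain matrices.
#'
#' @param image_4d path to a 4D NIfTI image (or an array).
#' @param atlas_labels path to an integer-labelled NIfTI atlas on the same
#'   grid (or an array); 0 = background.
#' @param gm_map path to a gray-matter probability NIfTI (or an array).
#' @param threshold gray-matter probability cut (default 0.3).
#' @return T x N matrix of mean series, columns named `node<label>`.
#' @export
extract_roi_series <- function(image_4d, atlas_labels, gm_map, threshold = 0.3) {
  if (!requireNamespace("RNifti", quietly = TRUE) &&
      (is.character(image_4d) || is.character(atlas_labels) ||
       is.character(gm_map))) {
    stop("RNifti is required to read NIfTI paths", call. = FALSE)
  }
  load_img <- function(x) if (is.character(x)) RNifti::readNifti(x) else x
  img <- load_img(image_4d)
  atl <- load_img(atlas_labels)
  gm <- load_img(gm_map)
  d <- dim(img)
  if (length(d) != 4) stop("image must be 4D", call. = FALSE)
  if (!all(dim(atl) == d[1:3]) || !all(dim(gm) == d[1:3])) {
    stop("atlas/GM map must share the image grid", call. = FALSE)
  }
  labels <- sort(unique(as.vector(atl)))
  labels <- labels[labels != 0]
  t_len <- d[4]
  vox <- matrix(img, prod(d[1:3]), t_len)
  out <- matrix(NA_real_, t_len, length(labels))
  for (k in seq_along(labels)) {
    sel <- as.vector(atl == labels[k] & gm > threshold)
    if (!any(sel)) {
      stop(sprintf("node %s has no voxels with GM > %.2f", labels[k], threshold),
           call. = FALSE)
    }
    out[, k] <- colMeans(vox[sel, , drop = FALSE])
  }
  colnames(out) <- paste0("node", labels)
  out
}
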