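#' Load the node atlas
#'
#' Reads a node-definition table (the packaged default covers the
#' pain-matrix and default-mode regions: 22 bilateral region pairs plus
#' the midline periaqueductal gray, giving 45 nodes) and expands it to the
#' lateralized node list. Each row with `lateralized = "yes"` becomes an
#' `L_`/`R_` pair; midline rows stay single. Node order is fixed as: table
#' order with L before R, midline (PAG) last — every matrix in the
#' pipeline inherits this order.
#'
#' Any table with columns `short_name`, `full_name`, `source_atlas`,
#' `lateralized` can be plugged in, so whole-brain parcellations run
#' through the same pipeline unchanged.
#'
#' @param path path to a tab-separated node table; `NULL` (default) loads
#'   the packaged atlas.
#' @return A tibble with one row per node: `node` (unique name), `region`
#'   (base short name), `full_name`, `source_atlas`, `hemisphere`
#'   (`"L"`, `"R"` or `"midline"`).
#' @examples
#' atlas <- load_node_atlas()
#' nrow(atlas)  # 45
#' @export
load_node_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "node_atlas.tsv", package = "restnet")
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("short_name", "full_name", "source_atlas", "lateralized")
  if (!all(need %in% names(raw))) {
    stop("atlas table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$short_name)) {
    stop("duplicate short_name entries in atlas table", call. = FALSE)
  }
  if (!all(raw$lateralized %in% c("yes", "no"))) {
    stop("`lateralized` must be 'yes' or 'no' for every row", call. = FALSE)
  }
  lat <- raw[raw$lateralized == "yes", , drop = FALSE]
  mid <- raw[raw$lateralized == "no", , drop = FALSE]
  expand <- function(df, hemi) {
    if (nrow(df) == 0) return(NULL)
    tibble::tibble(node = paste0(hemi, "_", df$short_name),
                   region = df$short_name, full_name = df$full_name,
                   source_atlas = df$source_atlas, hemisphere = hemi)
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(lat)), function(i) {
      dplyr::bind_rows(expand(lat[i, ], "L"), expand(lat[i, ], "R"))
    }),
    if (nrow(mid) > 0) {
      tibble::tibble(node = mid$short_name, region = mid$short_name,
                     full_name = mid$full_name,
                     source_atlas = mid$source_atlas, hemisphere = "midline")
    }
  )
  if (anyDuplicated(out$node)) {
    stop("expanded atlas has duplicate node names", call. = FALSE)
  }
  out
}
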