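#' Write / read a labelled square matrix as TSV
#'
#' Tab-separated, UTF-8, node labels as header row and first column; the
#' reader returns bit-identical values for the writer's output.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Per-subject graph analysis
#'
#' Takes one subject's (preprocessed or raw synthetic) data through
#' connectivity, graph construction, measures, null normalization, hub
#' scoring and modularity.
#'
#' @param roi T x N time-series matrix.
#' @param motion T x 6 motion parameters.
#' @param nuisance T x 3 nuisance series.
#' @param tr repetition time, seconds.
#' @param params a [preprocess_params()].
#' @param n_null null-ensemble size for [normalize_measures()].
#' @param seed seed for the subject's null ensemble.
#' @param clustering_family passed through to the measures.
#' @return List: `included`, `inclusion`, `graph`, `measures`,
#'   `normalized`, `hubs`, `partition`, `connectivity`.
#' @export
analyze_subject <- function(roi, motion, nuisance, tr,
                            params = preprocess_params(),
                            n_null = 1000, seed = 1L,
                            clustering_family = "onnela") {
  pre <- preprocess_subject(roi, motion, nuisance, tr, params)
  if (!pre$inclusion$included) {
    return(list(included = FALSE, inclusion = pre$inclusion))
  }
  conn <- partial_correlation(pre$series, pre$censor)
  g <- to_weighted_graph(conn)
  meas <- graph_measures(g, clustering_family = clustering_family)
  norm <- normalize_measures(g, n_null = n_null, seed = seed,
                             clustering_family = clustering_family)
  hubs <- hub_score(g, clustering_family = clustering_family)
  part <- newman_partition(g)
  list(included = TRUE, inclusion = pre$inclusion, connectivity = conn,
       graph = g, measures = meas, normalized = norm, hubs = hubs,
       partition = part)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> connectivity -> graph measures ->
#' null normalization -> hubs/modularity -> group statistics, writing
#' every stage's outputs and a provenance log to `out_dir`. Deterministic
#' under a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (`NULL` = don't write files).
#' @param n_null null-ensemble size per subject (default 100 for a
#'   demo-scale run; 1000 matches the reference analysis).
#' @param params a [preprocess_params()].
#' @param pair_tests run the 990 per-pair co-module Fisher tests (default
#'   TRUE).
#' @return A list of class `pipeline_result`: `cohort`, `subject_results`,
#'   `normalized` (tibble subject x measure), `group_measures` (Welch
#'   tests + FDR), `hub_table`, `hub_tests`, `comodule`, `comodule_tests`,
#'   `consensus_partitions`, `spearman`, `ancova`, `excluded`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_null = 100,
                         params = preprocess_params(), pair_tests = TRUE) {
  cohort <- simulate_cohort(config)
  subs <- cohort$subjects
  results <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    keep <- seq_len(s$n_keep)
    res <- tryCatch(
      analyze_subject(s$roi[keep, , drop = FALSE],
                      s$motion[keep, , drop = FALSE],
                      s$nuisance[keep, , drop = FALSE],
                      tr = s$tr, params = params, n_null = n_null,
                      seed = config$seed * 10000L + i),
      error = function(e) {
        stop(sprintf("pipeline failed for %s: %s",
                     s$record$subject_id, conditionMessage(e)), call. = FALSE)
      })
    results[[i]] <- res
  }
  included <- vapply(results, function(r) isTRUE(r$included), logical(1))
  excluded <- cohort$participants$subject_id[!included]
  part_tbl <- cohort$participants[included, , drop = FALSE]
  res_in <- results[included]

  normalized <- purrr::map2_dfr(res_in, part_tbl$subject_id, function(r, id) {
    dplyr::mutate(r$normalized, subject_id = id)
  }) |>
    dplyr::left_join(part_tbl[, c("subject_id", "group")], by = "subject_id")

  group_measures <- normalized |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(df, key) {
      welch_t(df$normalized[df$group == "HC"],
              df$normalized[df$group == "IBS"])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p_value))

  hub_results <- purrr::map(res_in, "hubs")
  hub_table <- group_hub_table(hub_results, part_tbl$group)
  hub_tests <- hub_fisher_tests(hub_table)

  partitions <- purrr::map(res_in, "partition")
  comod <- comodule_matrix(partitions, part_tbl$group)
  comodule_tests <- if (pair_tests && length(comod) == 2) {
    comodule_fisher_tests(partitions, part_tbl$group)
  } else NULL

  graphs <- purrr::map(res_in, "graph")
  consensus <- purrr::map(split(graphs, part_tbl$group),
                          group_consensus_partition)

  wide <- normalized |>
    dplyr::select("subject_id", "group", "measure", "normalized") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "normalized") |>
    dplyr::left_join(part_tbl, by = c("subject_id", "group"))

  score_cols <- intersect(c("ibs_sss_colonic", "ibs_sss_extracolonic", "vsi"),
                          names(wide))
  sp_measures <- c("clustering_coefficient", "betweenness_centrality",
                   "characteristic_path_length")
  spearman <- if (sum(wide$group == "IBS") >= 4) {
    spearman_assoc(wide, score_cols, sp_measures,
                   subset = wide$group == "IBS") |>
      dplyr::mutate(p_fdr = bh_fdr(.data$p_value))
  } else NULL

  ancova <- if ("distress" %in% names(wide)) {
    purrr::map(setNames(sp_measures, sp_measures), function(ms) {
      ancova_interaction(wide, ms, "group", "distress")
    })
  } else NULL

  log <- list(config = unclass(config)[setdiff(names(config), "questionnaire_params")],
              n_null = n_null, params = unclass(params),
              n_included = sum(included), excluded = excluded,
              clustering_family = "onnela", null_statistic = "mean",
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  out <- structure(list(cohort = cohort, subject_results = results,
                        normalized = normalized,
                        group_measures = group_measures,
                        hub_table = hub_table, hub_tests = hub_tests,
                        comodule = comod, comodule_tests = comodule_tests,
                        consensus_partitions = consensus,
                        spearman = spearman, ancova = ancova,
                        excluded = excluded, log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Per-node Fisher tests on hub frequencies
#'
#' Compares, for every node, the probability of being a hub between the
#' two groups with a Fisher exact test; BH-FDR adjusted over the node
#' family.
#'
#' @param hub_table output of [group_hub_table()] with two groups.
#' @return Tibble: node, per-group percentages, `p_value`, `p_fdr`.
#' @export
hub_fisher_tests <- function(hub_table) {
  wide <- tidyr::pivot_wider(hub_table, id_cols = "node",
                             names_from = "group",
                             values_from = c("n_hub", "n_subjects", "pct_hub"))
  grps <- unique(hub_table$group)
  stopifnot(length(grps) == 2)
  out <- purrr::pmap_dfr(wide, function(...) {
    row <- list(...)
    tab <- matrix(c(row[[paste0("n_hub_", grps[1])]],
                    row[[paste0("n_subjects_", grps[1])]] -
                      row[[paste0("n_hub_", grps[1])]],
                    row[[paste0("n_hub_", grps[2])]],
                    row[[paste0("n_subjects_", grps[2])]] -
                      row[[paste0("n_hub_", grps[2])]]), 2, 2)
    ft <- fisher_exact_2x2(tab)
    tibble::tibble(node = row$node,
                   pct_1 = row[[paste0("pct_hub_", grps[1])]],
                   pct_2 = row[[paste0("pct_hub_", grps[2])]],
                   p_value = ft$p_value)
  })
  names(out)[2:3] <- paste0("pct_hub_", grps)
  dplyr::mutate(out, p_fdr = bh_fdr(.data$p_value))
}

# Per-pair Fisher tests on same-module membership between groups.
comodule_fisher_tests <- function(partitions, groups) {
  groups <- as.character(groups)
  grps <- unique(groups)
  stopifnot(length(grps) == 2)
  labs <- partitions[[1]]$membership$node
  n <- length(labs)
  counts <- lapply(grps, function(gname) {
    idx <- which(groups == gname)
    acc <- matrix(0, n, n)
    for (i in idx) {
      m <- partitions[[i]]$membership$module
      acc <- acc + outer(m, m, "==")
    }
    list(same = acc, total = length(idx))
  })
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- numeric(nrow(ut))
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    tab <- matrix(c(counts[[1]]$same[i, j],
                    counts[[1]]$total - counts[[1]]$same[i, j],
                    counts[[2]]$same[i, j],
                    counts[[2]]$total - counts[[2]]$same[i, j]), 2, 2)
    p[k] <- fisher_exact_2x2(tab)$p_value
  }
  tibble::tibble(node_a = labs[ut[, 1]], node_b = labs[ut[, 2]],
                 freq_1 = counts[[1]]$same[ut] / counts[[1]]$total,
                 freq_2 = counts[[2]]$same[ut] / counts[[2]]$total,
                 p_value = p, p_fdr = bh_fdr(p))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(res$normalized, "normalized_measures.tsv")
  wr(res$group_measures, "group_measure_tests.tsv")
  wr(res$hub_table, "hub_table.tsv")
  wr(res$hub_tests, "hub_tests.tsv")
  if (!is.null(res$comodule_tests)) wr(res$comodule_tests, "comodule_tests.tsv")
  for (gname in names(res$comodule)) {
    write_matrix_tsv(res$comodule[[gname]],
                     file.path(out_dir, paste0("comodule_", gname, ".tsv")))
  }
  for (gname in names(res$consensus_partitions)) {
    wr(res$consensus_partitions[[gname]]$membership,
       paste0("partition_", gname, ".tsv"))
  }
  if (!is.null(res$spearman)) wr(res$spearman, "spearman_assoc.tsv")
  if (!is.null(res$ancova)) {
    anc <- purrr::imap_dfr(res$ancova, function(a, ms)
      dplyr::mutate(a$anova, measure = ms))
    wr(anc, "ancova_interaction.tsv")
  }
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d subjects analysed (%d excluded)>\n",
              sum(vapply(x$subject_results, function(r) isTRUE(r$included),
                         logical(1))),
              length(x$excluded)))
  print(x$group_measures)
  invisible(x)
}
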