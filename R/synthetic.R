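#' Cohort configuration for the synthetic-data generator
#'
#' Defines one simulated cohort: group sizes, acquisition (TR, volume
#' count), the planted modular covariance among nodes, motion
#' contamination, and per-group questionnaire distributions. The packaged
#' cohort presets mirror the two study sites the pipeline is designed
#' for: `"sendai"` (29 HC / 30 IBS, TR 1.8 s, 250 volumes) and
#' `"gothenburg"` (29 HC / 62 IBS, TR 2.0 s, 300 volumes of which the
#' first 250 are analysed).
#'
#' The group contrast (`group_effect`) is injected as an *increase of the
#' between-module correlation* in IBS subjects (reduced segregation);
#' the default is 0, i.e. no true group difference in network structure
#' (the null regime), with questionnaire separations still present.
#'
#' @param cohort `"sendai"`, `"gothenburg"`, or `"custom"`.
#' @param n_hc,n_ibs group sizes.
#' @param n_nodes number of nodes (default 45).
#' @param n_volumes acquired volumes.
#' @param n_keep analysed volumes (first `n_keep`; default
#'   `min(n_volumes, 250)`).
#' @param tr repetition time, seconds.
#' @param module_sizes integer vector summing to `n_nodes` (planted
#'   modules).
#' @param within_r,between_r planted within/between-module correlations,
#'   `0 <= between_r < within_r < 1`.
#' @param group_effect added to `between_r` for IBS subjects (default 0).
#' @param motion_spike_rate per-volume probability of a motion spike.
#' @param motion_spike_scale spike magnitude, mm.
#' @param motion_drift_amplitude slow drift amplitude, mm (0 disables).
#' @param nuisance_mix coefficient mixing each nuisance series into every
#'   node's signal.
#' @param questionnaire_params tibble (`instrument`, `group`, `location`,
#'   `scale`, `lo`, `hi`); `NULL` uses [default_questionnaire_params()]
#'   for the cohort.
#' @param seed master integer seed; all randomness derives from it.
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config("sendai", n_hc = 4, n_ibs = 4, n_volumes = 80)
#' cfg$tr
#' @export
cohort_config <- function(cohort = c("sendai", "gothenburg", "custom"),
                          n_hc = NULL, n_ibs = NULL,
                          n_nodes = 45L, n_volumes = NULL, n_keep = NULL,
                          tr = NULL, module_sizes = c(15L, 15L, 15L),
                          within_r = 0.3, between_r = 0.05,
                          group_effect = 0,
                          motion_spike_rate = 0.02,
                          motion_spike_scale = 1.5,
                          motion_drift_amplitude = 0.2,
                          nuisance_mix = 0.3,
                          questionnaire_params = NULL,
                          seed = 1L) {
  cohort <- match.arg(cohort)
  preset <- switch(cohort,
    sendai = list(n_hc = 29L, n_ibs = 30L, tr = 1.8, n_volumes = 250L),
    gothenburg = list(n_hc = 29L, n_ibs = 62L, tr = 2.0, n_volumes = 300L),
    custom = list(n_hc = 10L, n_ibs = 10L, tr = 2.0, n_volumes = 250L))
  n_hc <- if (is.null(n_hc)) preset$n_hc else as.integer(n_hc)
  n_ibs <- if (is.null(n_ibs)) preset$n_ibs else as.integer(n_ibs)
  tr <- if (is.null(tr)) preset$tr else tr
  n_volumes <- if (is.null(n_volumes)) preset$n_volumes else as.integer(n_volumes)
  n_keep <- if (is.null(n_keep)) min(n_volumes, 250L) else as.integer(n_keep)
  if (sum(module_sizes) != n_nodes) {
    stop("sum(module_sizes) must equal n_nodes", call. = FALSE)
  }
  if (!(between_r >= 0 && between_r < within_r && within_r < 1)) {
    stop("need 0 <= between_r < within_r < 1", call. = FALSE)
  }
  if (between_r + max(group_effect, 0) >= within_r) {
    stop("between_r + group_effect must stay below within_r", call. = FALSE)
  }
  if (n_keep > n_volumes) stop("n_keep exceeds n_volumes", call. = FALSE)
  if (is.null(questionnaire_params)) {
    questionnaire_params <- default_questionnaire_params(cohort)
  }
  # both group covariances must be positive definite
  plant_covariance(module_sizes, within_r, between_r)
  plant_covariance(module_sizes, within_r, between_r + group_effect)
  structure(list(cohort = cohort, n_hc = n_hc, n_ibs = n_ibs,
                 n_nodes = as.integer(n_nodes), n_volumes = n_volumes,
                 n_keep = n_keep, tr = tr,
                 module_sizes = as.integer(module_sizes),
                 within_r = within_r, between_r = between_r,
                 group_effect = group_effect,
                 motion_spike_rate = motion_spike_rate,
                 motion_spike_scale = motion_spike_scale,
                 motion_drift_amplitude = motion_drift_amplitude,
                 nuisance_mix = nuisance_mix,
                 questionnaire_params = questionnaire_params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default questionnaire distributions per cohort
#'
#' Latent-normal location/scale per instrument and group, derived from
#' the published group medians and interquartile ranges of the two
#' cohorts (scale = IQR / 1.349), with truncation to the instrument
#' ranges (IBS-SSS 0-500, VSI 0-75, HADS 0-21 per subscale, STAI-T and
#' SDS 20-80). Scores are drawn from a Gaussian copula truncated to these
#' ranges.
#'
#' @param cohort `"sendai"`, `"gothenburg"` or `"custom"` (custom uses
#'   the sendai instruments).
#' @return Tibble: `instrument`, `group`, `location`, `scale`, `lo`, `hi`.
#' @export
default_questionnaire_params <- function(cohort = "sendai") {
  iqr_sd <- function(lo, hi) (hi - lo) / 1.349
  sendai <- tibble::tribble(
    ~instrument, ~group, ~location, ~scale, ~lo, ~hi,
    "ibs_sss_colonic", "HC", 41, iqr_sd(12, 80), 0, 500,
    "ibs_sss_colonic", "IBS", 179.5, iqr_sd(139, 203), 0, 500,
    "stai_t", "HC", 36, iqr_sd(33, 40.5), 20, 80,
    "stai_t", "IBS", 38.5, iqr_sd(31.5, 45), 20, 80,
    "sds", "HC", 35.5, iqr_sd(32.5, 38), 20, 80,
    "sds", "IBS", 35.5, iqr_sd(31, 43.5), 20, 80,
    "vsi", "HC", 1, iqr_sd(0, 5), 0, 75,
    "vsi", "IBS", 24.5, iqr_sd(13.5, 33), 0, 75
  )
  gothenburg <- tibble::tribble(
    ~instrument, ~group, ~location, ~scale, ~lo, ~hi,
    "ibs_sss_colonic", "HC", 12, iqr_sd(4, 29), 0, 500,
    "ibs_sss_colonic", "IBS", 295, iqr_sd(197, 358), 0, 500,
    "ibs_sss_extracolonic", "HC", 33.5, iqr_sd(15.5, 52.5), 0, 500,
    "ibs_sss_extracolonic", "IBS", 155.25, iqr_sd(100.5, 223), 0, 500,
    "hads_anxiety", "HC", 4, iqr_sd(1, 5), 0, 21,
    "hads_anxiety", "IBS", 9, iqr_sd(6, 12), 0, 21,
    "hads_depression", "HC", 1, iqr_sd(0, 2), 0, 21,
    "hads_depression", "IBS", 5, iqr_sd(3, 7), 0, 21,
    "vsi", "HC", 1, iqr_sd(0, 2), 0, 75,
    "vsi", "IBS", 39, iqr_sd(24, 51), 0, 75
  )
  if (cohort == "gothenburg") gothenburg else sendai
}

#' Planted block-structured covariance matrix
#'
#' Unit-diagonal matrix with `within_r` off-diagonal inside each module
#' block and `between_r` across blocks — the modular ground truth the
#' generator samples node time series from.
#'
#' @param module_sizes integer block sizes.
#' @param within_r,between_r correlations, `0 <= between_r < within_r < 1`
#'   (equal-correlation blocks are positive definite under this
#'   constraint, but the eigenvalue check is always run).
#' @return Covariance (correlation) matrix with attribute `"membership"`.
#' @examples
#' plant_covariance(c(2, 2), 0.6, 0)  # block-diagonal, eigenvalues 2.2/0.4
#' @export
plant_covariance <- function(module_sizes, within_r, between_r = 0) {
  if (!(between_r >= 0 && within_r >= between_r && within_r < 1)) {
    stop("need 0 <= between_r <= within_r < 1", call. = FALSE)
  }
  memb <- rep(seq_along(module_sizes), module_sizes)
  sigma <- ifelse(outer(memb, memb, "=="), within_r, between_r)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf("planted covariance is not positive definite (smallest eigenvalue %.3e)",
                 min(ev)), call. = FALSE)
  }
  attr(sigma, "membership") <- memb
  sigma
}

truncnorm <- function(n, location, scale, lo, hi) {
  plo <- pnorm(lo, location, scale)
  phi <- pnorm(hi, location, scale)
  qnorm(runif(n, plo, phi), location, scale)
}

#' Simulate one subject
#'
#' Draws a subject's multivariate-Gaussian node time series from the
#' planted covariance (IBS subjects use `between_r + group_effect`),
#' builds a motion trace (smooth sinusoidal drift plus Bernoulli spikes),
#' three autocorrelated nuisance series (WM, CSF, global) that are
#' partially mixed into the node signals together with a small linear
#' trend, and questionnaire scores from the configured truncated-normal
#' distributions. Fully reproducible from `subject_seed`.
#'
#' @param config a [cohort_config()].
#' @param group `"HC"` or `"IBS"`.
#' @param subject_id subject identifier string.
#' @param subject_seed integer seed for this subject's stream.
#' @param node_labels optional node names (defaults to the packaged atlas
#'   when `n_nodes == 45`, else `n1..nN`).
#' @return A list of class `synthetic_subject`: `roi` (T x N), `motion`
#'   (T x 6), `nuisance` (T x 3: wm, csf, global), `tr`, `record`
#'   (one-row tibble), `true_partition`, `true_covariance`.
#' @export
simulate_subject <- function(config, group = c("HC", "IBS"),
                             subject_id = "sub-001", subject_seed = 1L,
                             node_labels = NULL) {
  group <- match.arg(group)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(subject_seed))
  t_len <- config$n_volumes
  n <- config$n_nodes
  if (is.null(node_labels)) {
    node_labels <- if (n == 45) load_node_atlas()$node else paste0("n", seq_len(n))
  }
  between <- config$between_r + if (group == "IBS") config$group_effect else 0
  sigma <- plant_covariance(config$module_sizes, config$within_r, between)
  z <- matrix(rnorm(t_len * n), t_len, n) %*% chol(sigma)

  ar1 <- function(t_len, phi = 0.6) {
    as.numeric(stats::filter(rnorm(t_len, sd = sqrt(1 - phi^2)), phi,
                             method = "recursive"))
  }
  nuisance <- cbind(wm = ar1(t_len), csf = ar1(t_len), global = ar1(t_len))
  mix <- config$nuisance_mix
  contamination <- nuisance %*% matrix(mix, 3, n)
  trend <- (seq_len(t_len) / t_len - 0.5) %o% rnorm(n, 0, 0.3)
  roi <- z + contamination + trend
  colnames(roi) <- node_labels

  motion <- matrix(0, t_len, 6)
  if (config$motion_drift_amplitude > 0) {
    for (j in 1:6) {
      amp <- config$motion_drift_amplitude / if (j > 3) 50 else 1
      motion[, j] <- amp *
        sin(2 * pi * (seq_len(t_len) / t_len) * runif(1, 0.5, 2) +
              runif(1, 0, 2 * pi))
    }
  }
  spikes <- which(rbinom(t_len, 1, config$motion_spike_rate) == 1)
  for (s in spikes) {
    ax <- sample.int(3, 1)
    motion[s, ax] <- motion[s, ax] +
      config$motion_spike_scale * sample(c(-1, 1), 1)
  }
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  qp <- config$questionnaire_params[config$questionnaire_params$group == group, ]
  scores <- setNames(
    purrr::pmap_dbl(qp[, c("location", "scale", "lo", "hi")],
                    function(location, scale, lo, hi)
                      truncnorm(1, location, scale, lo, hi)),
    qp$instrument)
  record <- tibble::as_tibble(c(
    list(subject_id = subject_id, group = group, cohort = config$cohort),
    as.list(scores)))
  if (all(c("hads_anxiety", "hads_depression") %in% names(record))) {
    record$distress <- record$hads_anxiety + record$hads_depression
  } else if ("stai_t" %in% names(record)) {
    record$distress <- record$stai_t
  }

  structure(list(roi = roi, motion = motion, nuisance = nuisance,
                 tr = config$tr, n_keep = config$n_keep, record = record,
                 true_partition = attr(sigma, "membership"),
                 true_covariance = sigma, seed = as.integer(subject_seed)),
            class = "synthetic_subject")
}

#' Simulate a full cohort
#'
#' Generates `n_hc + n_ibs` subjects (HC first) with per-subject seeds
#' derived from the master seed, plus a participants table. Bit-exactly
#' reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort`: `subjects` (list of
#'   [simulate_subject()] results), `participants` (tibble, one row per
#'   subject), `config`.
#' @examples
#' co <- simulate_cohort(cohort_config("custom", n_hc = 2, n_ibs = 2,
#'                                     n_volumes = 60, n_keep = 60))
#' co$participants$group
#' @export
simulate_cohort <- function(config) {
  groups <- c(rep("HC", config$n_hc), rep("IBS", config$n_ibs))
  ids <- sprintf("sub-%03d", seq_along(groups))
  node_labels <- if (config$n_nodes == 45) load_node_atlas()$node else
    paste0("n", seq_len(config$n_nodes))
  subjects <- purrr::map(seq_along(groups), function(i) {
    simulate_subject(config, groups[i], ids[i],
                     subject_seed = config$seed * 1000L + i,
                     node_labels = node_labels)
  })
  participants <- purrr::map_dfr(subjects, "record")
  structure(list(subjects = subjects, participants = participants,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort '%s': %d HC + %d IBS, %d nodes, %d volumes (TR %.1f s)>\n",
              x$config$cohort, x$config$n_hc, x$config$n_ibs,
              x$config$n_nodes, x$config$n_volumes, x$config$tr))
  invisible(x)
}

#' Write a cohort to delimiter-separated files
#'
#' Writes `sub-XXX_roi.tsv` (T x N), `sub-XXX_motion.tsv` (T x 6),
#' `sub-XXX_nuisance.tsv` (T x 3), `participants.tsv` and a JSON
#' manifest into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (s in cohort$subjects) {
    id <- s$record$subject_id
    wr(s$roi, file.path(dir, paste0(id, "_roi.tsv")))
    wr(s$motion, file.path(dir, paste0(id, "_motion.tsv")))
    wr(s$nuisance, file.path(dir, paste0(id, "_nuisance.tsv")))
  }
  wr(cohort$participants, file.path(dir, "participants.tsv"))
  manifest <- list(cohort = cohort$config$cohort,
                   n_hc = cohort$config$n_hc, n_ibs = cohort$config$n_ibs,
                   n_nodes = cohort$config$n_nodes,
                   n_volumes = cohort$config$n_volumes,
                   n_keep = cohort$config$n_keep, tr = cohort$config$tr,
                   seed = cohort$config$seed,
                   subjects = cohort$participants$subject_id)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return A list with `subjects` (each: `roi`, `motion`, `nuisance`,
#'   `tr`, `record`), `participants`, `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  participants <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "participants.tsv"), sep = "\t"))
  subjects <- purrr::map(manifest$subjects, function(id) {
    rd <- function(suffix) as.matrix(
      utils::read.delim(file.path(dir, paste0(id, "_", suffix, ".tsv")),
                        sep = "\t", check.names = FALSE))
    list(roi = rd("roi"), motion = rd("motion"), nuisance = rd("nuisance"),
         tr = manifest$tr,
         record = participants[participants$subject_id == id, ])
  })
  list(subjects = subjects, participants = participants, manifest = manifest)
}
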