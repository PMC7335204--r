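#' Descriptive group comparisons
#'
#' Compares each continuous descriptive variable between groups with a
#' Kruskal-Wallis one-way ANOVA on ranks (chi-squared approximation), and
#' categorical variables (e.g. sex) with a Pearson chi-squared test.
#'
#' @param data data frame with one row per subject.
#' @param group name of the group column.
#' @param variables character vector of columns to test; defaults to all
#'   numeric columns except the group.
#' @param categorical character vector of categorical columns to test by
#'   chi-squared (default none).
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p_value`.
#' @examples
#' d <- data.frame(group = rep(c("HC", "IBS"), each = 10),
#'                 score = c(rnorm(10), rnorm(10, 2)))
#' descriptive_group_compare(d, "group")
#' @export
descriptive_group_compare <- function(data, group = "group",
                                      variables = NULL,
                                      categorical = character()) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2 || min(table(g)) < 2) {
    stop("need at least 2 subjects in each of 2 groups", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, c(group, categorical))
  }
  rows <- purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning(sprintf("variable '%s' is constant; p = 1", v), call. = FALSE)
      return(tibble::tibble(variable = v, test = "kruskal_wallis",
                            statistic = 0, df = nlevels(g) - 1, p_value = 1))
    }
    kw <- kruskal.test(x, g)
    tibble::tibble(variable = v, test = "kruskal_wallis",
                   statistic = unname(kw$statistic), df = unname(kw$parameter),
                   p_value = kw$p.value)
  })
  cat_rows <- purrr::map_dfr(categorical, function(v) {
    tab <- table(data[[v]], g)
    cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(variable = v, test = "pearson_chisq",
                   statistic = unname(cs$statistic), df = unname(cs$parameter),
                   p_value = cs$p.value)
  })
  dplyr::bind_rows(rows, cat_rows)
}

#' Welch two-sample t test
#'
#' Two-tailed independent-samples t test assuming unequal variances
#' (Satterthwaite degrees of freedom) — the test used for all group
#' comparisons of normalized global graph measures.
#'
#' @param x,y numeric vectors (the two groups).
#' @return Tibble: `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference x - y), `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = length(x) + length(y) - 2,
                            p_value = 1, estimate = 0,
                            mean_x = mean(x), mean_y = mean(y)))
    }
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 estimate = unname(diff(rev(tt$estimate))),
                 mean_x = mean(x), mean_y = mean(y))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all hypergeometric
#' tables no more probable than the observed one (the classical
#' definition). A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Tibble: `odds_ratio` (conditional MLE), `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  tibble::tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Spearman rank correlations between symptom scores and graph measures
#'
#' Tie-corrected Spearman correlations (ranks then Pearson), with the
#' t-approximation p-value. Intended for symptom-severity versus
#' normalized-graph-measure associations tested within the patient group
#' only.
#'
#' @param data data frame.
#' @param scores character vector of score columns.
#' @param measures character vector of measure columns.
#' @param subset optional logical vector selecting rows (e.g. IBS only).
#' @return Tibble: `score`, `measure`, `n`, `rho`, `p_value` (`NA` with a
#'   warning for constant inputs).
#' @export
spearman_assoc <- function(data, scores, measures, subset = NULL) {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  purrr::map_dfr(scores, function(sc) {
    purrr::map_dfr(measures, function(ms) {
      ok <- complete.cases(data[[sc]], data[[ms]])
      x <- data[[sc]][ok]; y <- data[[ms]][ok]
      if (length(x) < 4) stop("need at least 4 paired observations",
                              call. = FALSE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        warning("constant input; rho undefined", call. = FALSE)
        return(tibble::tibble(score = sc, measure = ms, n = length(x),
                              rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      tibble::tibble(score = sc, measure = ms, n = length(x),
                     rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
}

#' Box-Cox power transformation
#'
#' `y(lambda) = (x^lambda - 1) / lambda` for `lambda != 0`, `ln x` at
#' `lambda = 0`, with `lambda` chosen by profile log-likelihood on a grid
#' over `[-3, 3]`. Values must be positive after the configured shift.
#'
#' @param x numeric vector.
#' @param shift added to `x` before transforming (default 0; use e.g.
#'   `1 - min(x)` for nonpositive data).
#' @param lambda force a fixed lambda instead of estimating it.
#' @param grid candidate lambda grid.
#' @return List: `transformed`, `lambda`, `shift`.
#' @examples
#' box_cox(exp(rnorm(100)))$lambda   # near 0 for lognormal data
#' @export
box_cox <- function(x, shift = 0, lambda = NULL,
                    grid = seq(-3, 3, by = 0.01)) {
  x <- x + shift
  if (any(x <= 0)) {
    stop("values must be positive after shift; supply `shift`", call. = FALSE)
  }
  bc <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  if (is.null(lambda)) {
    n <- length(x)
    slx <- sum(log(x))
    ll <- vapply(grid, function(l) {
      y <- bc(l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
    }, numeric(1))
    lambda <- grid[which.max(ll)]
  }
  list(transformed = bc(lambda), lambda = lambda, shift = shift)
}

#' ANCOVA with a group-by-covariate interaction
#'
#' Fits `measure ~ group + z + group:z` with the covariate standardized
#' to mean 0, SD 1, and reports F tests for the group main effect, the
#' covariate main effect, and the interaction (the difference in slope
#' between groups), plus per-group Pearson correlations and slopes.
#' When the model residuals fail a normality gate (absolute skewness > 1
#' or Shapiro-Wilk p < 0.05) and all responses are positive, the
#' dependent variable is Box-Cox transformed and the model refitted; the
#' same gate is applied to the covariate before standardization.
#'
#' @param data data frame.
#' @param measure name of the dependent-variable column.
#' @param group name of the two-level group column.
#' @param covariate name of the continuous covariate column.
#' @param transform `"auto"` (normality-gated Box-Cox, default) or
#'   `"none"`.
#' @return An object of class `ancova_fit` with `anova` (tibble: term,
#'   df1, df2, statistic, p_value), `slopes` (tibble per group: slope,
#'   pearson_r, p_value, n), `lambda` (Box-Cox lambdas applied, NA =
#'   none), and the underlying `lm` fit.
#' @examples
#' d <- data.frame(group = rep(c("HC", "IBS"), each = 20),
#'                 z = rnorm(40), y = rnorm(40))
#' tidy(ancova_interaction(d, "y", "group", "z"))
#' @export
ancova_interaction <- function(data, measure, group, covariate,
                               transform = c("auto", "none")) {
  transform <- match.arg(transform)
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  y <- data[[measure]]
  z <- data[[covariate]]
  ok <- complete.cases(y, z, g)
  y <- y[ok]; z <- z[ok]; g <- droplevels(g[ok])
  if (nlevels(g) != 2) stop("both groups must be present", call. = FALSE)

  lam <- c(y = NA_real_, z = NA_real_)
  needs_bc <- function(v) {
    sk <- mean((v - mean(v))^3) / (mean((v - mean(v))^2))^(3 / 2)
    sw <- tryCatch(shapiro.test(v)$p.value, error = function(e) 1)
    abs(sk) > 1 || sw < 0.05
  }
  if (transform == "auto" && needs_bc(z) && all(z > 0)) {
    b <- box_cox(z); z <- b$transformed; lam["z"] <- b$lambda
  }
  z <- as.numeric(scale(z))
  if (transform == "auto") {
    fit0 <- lm(y ~ g * z)
    if (needs_bc(stats::residuals(fit0)) && all(y > 0)) {
      b <- box_cox(y); y <- b$transformed; lam["y"] <- b$lambda
    }
  }
  fit <- lm(y ~ g * z)
  if (any(!is.finite(coef(fit)))) stop("singular design", call. = FALSE)
  an <- anova(fit)
  terms <- c("group", "covariate", "interaction")
  anova_tbl <- tibble::tibble(
    term = terms,
    df1 = an$Df[1:3], df2 = an$Df[4],
    statistic = an$`F value`[1:3],
    p_value = an$`Pr(>F)`[1:3]
  )
  slopes <- purrr::map_dfr(levels(g), function(lev) {
    sel <- g == lev
    ct <- suppressWarnings(cor.test(z[sel], y[sel]))
    sl <- coef(lm(y[sel] ~ z[sel]))[2]
    tibble::tibble(group = lev, n = sum(sel), slope = unname(sl),
                   pearson_r = unname(ct$estimate), p_value = ct$p.value)
  })
  structure(list(anova = anova_tbl, slopes = slopes, lambda = lam,
                 fit = fit, measure = measure, covariate = covariate),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit: %s ~ group * %s>\n", x$measure, x$covariate))
  print(x$anova)
  print(x$slopes)
  invisible(x)
}

#' @export
tidy.ancova_fit <- function(x, ...) x$anova

#' @export
glance.ancova_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma,
                 df_residual = x$fit$df.residual,
                 interaction_p = x$anova$p_value[x$anova$term == "interaction"],
                 lambda_y = x$lambda["y"], lambda_z = x$lambda["z"])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (always >= raw, <= 1).
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Type-I-error calibration of the group tests
#'
#' Simulates `n_sim` null cohorts (no true group difference: measures are
#' standard normal in both groups, covariates independent) and reports
#' the rejection rate of the Welch t test and of the ANCOVA interaction F
#' test at level `alpha`. Used to verify both tests are calibrated.
#'
#' @param n_hc,n_ibs group sizes per simulated cohort.
#' @param n_sim number of simulated cohorts.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return Tibble: `test`, `n_sim`, `rejections`, `rate`.
#' @export
calibrate_type1 <- function(n_hc = 30, n_ibs = 30, n_sim = 1000,
                            alpha = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rej_t <- 0L; rej_i <- 0L
  g <- factor(rep(c("HC", "IBS"), c(n_hc, n_ibs)))
  for (k in seq_len(n_sim)) {
    y <- rnorm(n_hc + n_ibs)
    z <- rnorm(n_hc + n_ibs)
    wt <- welch_t(y[g == "HC"], y[g == "IBS"])
    if (wt$p_value < alpha) rej_t <- rej_t + 1L
    d <- data.frame(y = y, z = z, group = g)
    af <- ancova_interaction(d, "y", "group", "z", transform = "none")
    if (af$anova$p_value[3] < alpha) rej_i <- rej_i + 1L
  }
  tibble::tibble(test = c("welch_t", "ancova_interaction"),
                 n_sim = n_sim, rejections = c(rej_t, rej_i),
                 rate = c(rej_t, rej_i) / n_sim)
}

#' Power of the interaction test for a planted slope difference
#'
#' Simulates cohorts in which the covariate-measure slope is
#' `slope_hc` in controls and `slope_ibs` in patients (additive Gaussian
#' noise with SD `noise_sd`), and reports how often the ANCOVA
#' group-by-covariate interaction is detected at level `alpha` — the
#' qualitative structure of a group-specific distress-connectivity
#' association (positive in controls, absent in patients).
#'
#' @param n_hc,n_ibs group sizes.
#' @param slope_hc,slope_ibs planted slopes per group.
#' @param noise_sd residual SD.
#' @param n_sim number of simulated cohorts.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return Tibble: `n_sim`, `detections`, `power`, plus the mean
#'   per-group Pearson r across simulations.
#' @export
interaction_power <- function(n_hc = 30, n_ibs = 30,
                              slope_hc = 0.5, slope_ibs = 0,
                              noise_sd = 1, n_sim = 1000,
                              alpha = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  g <- factor(rep(c("HC", "IBS"), c(n_hc, n_ibs)))
  slope <- ifelse(g == "HC", slope_hc, slope_ibs)
  det <- 0L
  r_hc <- numeric(n_sim); r_ibs <- numeric(n_sim)
  for (k in seq_len(n_sim)) {
    z <- rnorm(n_hc + n_ibs)
    y <- slope * z + rnorm(n_hc + n_ibs, sd = noise_sd)
    d <- data.frame(y = y, z = z, group = g)
    af <- ancova_interaction(d, "y", "group", "z", transform = "none")
    if (af$anova$p_value[3] < alpha) det <- det + 1L
    r_hc[k] <- af$slopes$pearson_r[af$slopes$group == "HC"]
    r_ibs[k] <- af$slopes$pearson_r[af$slopes$group == "IBS"]
  }
  tibble::tibble(n_sim = n_sim, detections = det, power = det / n_sim,
                 mean_r_hc = mean(r_hc), mean_r_ibs = mean(r_ibs))
}
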