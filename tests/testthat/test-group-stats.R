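test_that("Kruskal-Wallis descriptives behave at the extremes", {
  d <- data.frame(group = rep(c("HC", "IBS"), each = 6),
                  score = rep(c(5, 7, 9, 5, 7, 9), 2))
  r <- descriptive_group_compare(d, "group", "score")
  expect_lt(r$statistic, 1e-10)
  expect_gt(r$p_value, 0.99)

  # fully separated groups: H at its enumeration maximum, chi-square p
  d2 <- data.frame(group = rep(c("A", "B"), each = 3),
                   score = c(1, 2, 3, 10, 11, 12))
  r2 <- descriptive_group_compare(d2, "group", "score")
  h_all <- apply(combn(6, 3), 2, function(idx) {
    g <- factor(seq_len(6) %in% idx)
    unname(kruskal.test(c(1, 2, 3, 10, 11, 12), g)$statistic)
  })
  expect_equal(r2$statistic, max(h_all), tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(r2$statistic, 1, lower.tail = FALSE))

  expect_warning(
    descriptive_group_compare(data.frame(group = rep(c("A", "B"), 3),
                                         v = rep(1, 6)), "group", "v"),
    "constant")
})

test_that("sex distributions are compared by Pearson chi-square", {
  d <- data.frame(group = rep(c("HC", "IBS"), c(29, 30)),
                  sex = c(rep(c("m", "f"), c(15, 14)),
                          rep(c("m", "f"), c(13, 17))))
  r <- descriptive_group_compare(d, "group", variables = character(),
                                 categorical = "sex")
  expect_equal(r$test, "pearson_chisq")
  tab <- table(d$sex, d$group)
  expect_equal(r$statistic,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)))
})

test_that("Welch t matches the closed form and handles degenerate input", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4, tolerance = 1e-10)

  same <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- rnorm(10); y <- rnorm(12, 1, 2)
  manual_t <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 12)
  expect_equal(welch_t(x, y)$statistic, manual_t, tolerance = 1e-12)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  # hub-frequency style table: 2/29 HC vs 17/30 IBS
  tab <- matrix(c(2, 27, 17, 13), 2, byrow = TRUE)
  r <- fisher_exact_2x2(tab)
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$p_value, oracle_fisher_p(tab), tolerance = 1e-10)

  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value, 1)

  set.seed(13)
  for (k in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Spearman associations equal rank-then-Pearson", {
  d <- data.frame(s = 1:10, m = (1:10)^2)
  r <- spearman_assoc(d, "s", "m")
  expect_equal(r$rho, 1)
  d$m <- -d$m
  expect_equal(spearman_assoc(d, "s", "m")$rho, -1)

  set.seed(15)
  d2 <- data.frame(s = sample(1:4, 30, TRUE), m = sample(1:5, 30, TRUE))
  r2 <- spearman_assoc(d2, "s", "m")
  expect_equal(r2$rho, cor(rank(d2$s), rank(d2$m)), tolerance = 1e-12)

  expect_warning(spearman_assoc(data.frame(s = rep(1, 5), m = 1:5), "s", "m"),
                 "constant")
})

test_that("Box-Cox implements the power family and recovers lambda", {
  x <- c(1, 2, 5, 10)
  expect_equal(box_cox(x, lambda = 1)$transformed, x - 1)
  expect_equal(box_cox(x, lambda = 0)$transformed, log(x))
  expect_error(box_cox(c(-1, 2)), "positive")
  expect_equal(box_cox(c(-1, 2), shift = 2, lambda = 1)$transformed, c(0, 3))

  set.seed(16)
  x_ln <- exp(rnorm(500))
  expect_lt(abs(box_cox(x_ln)$lambda), 0.2)

  skip_if_not_installed("MASS")
  # cross-check the profile likelihood against MASS::boxcox
  y <- exp(rnorm(200, 1, 0.4))
  mb <- MASS::boxcox(y ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  expect_equal(box_cox(y)$lambda, mb$x[which.max(mb$y)], tolerance = 0.02)
})

test_that("ANCOVA reports group, covariate and interaction effects with dfs", {
  set.seed(17)
  n <- 40
  d <- data.frame(group = rep(c("HC", "IBS"), each = n / 2), z = rnorm(n))
  # outcome constructed exactly orthogonal to the design: all F ~ 0
  d$y <- unname(stats::residuals(lm(rnorm(n) ~ factor(d$group) * d$z)))
  f0 <- ancova_interaction(d, "y", "group", "z", transform = "none")
  expect_true(all(f0$anova$statistic < 1e-20))

  # planted interaction is found and slopes are reported per group
  d$y <- ifelse(d$group == "HC", 1.5, -1.5) * d$z + rnorm(n, sd = 0.3)
  f1 <- ancova_interaction(d, "y", "group", "z", transform = "none")
  expect_equal(f1$anova$term, c("group", "covariate", "interaction"))
  expect_lt(f1$anova$p_value[3], 1e-6)
  expect_equal(f1$anova$df1, rep(1, 3))
  expect_equal(f1$anova$df2, rep(n - 4, 3))
  expect_gt(f1$slopes$slope[f1$slopes$group == "HC"], 1)
  expect_lt(f1$slopes$slope[f1$slopes$group == "IBS"], -1)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$interaction_p, f1$anova$p_value[3])

  # the interaction F equals the squared t of the slope difference
  fit <- lm(y ~ group * z, data = transform(d, z = as.numeric(scale(z))))
  tt <- summary(fit)$coefficients["groupIBS:z", "t value"]
  expect_equal(f1$anova$statistic[3], tt^2, tolerance = 1e-8)
})

test_that("skewed responses pass the normality gate into Box-Cox", {
  set.seed(18)
  n <- 60
  d <- data.frame(group = rep(c("HC", "IBS"), each = n / 2), z = rnorm(n))
  d$y <- exp(1 + 0.5 * d$z + rnorm(n, sd = 0.4))
  f <- ancova_interaction(d, "y", "group", "z", transform = "auto")
  expect_false(is.na(f$lambda["y"]))
  expect_lt(abs(f$lambda["y"]), 0.6)   # near log for lognormal data
})

test_that("BH adjustment matches the step-up recursion", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(19)
  for (k in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("Welch and interaction tests are calibrated and powered as expected", {
  cal <- calibrate_type1(n_sim = 200, seed = 5)
  expect_true(all(cal$rate > 0.01 & cal$rate < 0.11))
  pw <- interaction_power(n_sim = 100, slope_hc = 1.5, slope_ibs = 0,
                          noise_sd = 1, seed = 6)
  expect_gt(pw$power, 0.9)
  expect_gt(pw$mean_r_hc, 0.5)
  expect_lt(abs(pw$mean_r_ibs), 0.15)
})
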