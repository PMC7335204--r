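test_that("framewise displacement follows the 1 mm / 50 mm-radius formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  m1 <- m; m1[5:10, 1] <- 1           # 1 mm step on x at volume 5
  fd <- framewise_displacement(m1)
  expect_equal(fd[5], 1)
  expect_equal(fd[-5], rep(0, 9))

  m2 <- m; m2[5:10, 4] <- 0.02        # 0.02 rad step -> 50 * 0.02 = 1 mm
  expect_equal(framewise_displacement(m2)[5], 1)

  expect_error(framewise_displacement(matrix(0, 1, 6)), "at least 2")
})

test_that("FD is invariant to constant parameter offsets", {
  set.seed(2)
  m <- matrix(rnorm(60, sd = 0.1), 10, 6)
  shift <- matrix(rep(runif(6, -5, 5), each = 10), 10, 6)
  expect_equal(framewise_displacement(m), framewise_displacement(m + shift))
})

test_that("censoring applies the run-position and FD rules per volume", {
  m <- matrix(0, 8, 6)
  expect_false(any(censor_volumes(m)$censored))

  m1 <- m; m1[4, 1] <- 1.5
  c1 <- censor_volumes(m1)
  expect_equal(which(c1$censored), c(4, 5))   # spike leaves by position, return by FD
  expect_true(c1$reason_translation[4])
  expect_true(c1$reason_fd[4])
  expect_false(c1$reason_translation[5])
  expect_true(c1$reason_fd[5])

  # spike at 1.2 mm: both rules on the spike, fd-only on the return
  m2 <- m; m2[3, 2] <- 1.2
  c2 <- censor_volumes(m2)
  expect_equal(c2$reason[3], "run_translation,fd")
  expect_equal(c2$reason[4], "fd")
  expect_equal(sum(c2$censored), 2)

  # rotation threshold is 1 degree, compared in radians
  m3 <- m; m3[6, 5] <- 1.1 * pi / 180
  c3 <- censor_volumes(m3)
  expect_true(c3$reason_rotation[6])
  expect_false(c3$reason_fd[6])   # FD = 50 * 0.0192 = 0.96 < 1
})

test_that("censoring is monotone in the thresholds", {
  set.seed(14)
  m <- matrix(rnorm(300, sd = 0.6), 50, 6)
  m[, 4:6] <- m[, 4:6] / 40
  base <- censor_volumes(m, preprocess_params())
  tight <- censor_volumes(m, preprocess_params(run_translation_limit = 0.5,
                                               run_rotation_limit = 0.5,
                                               fd_limit = 0.5))
  expect_true(all(base$censored <= tight$censored))
})

test_that("inclusion rule matches a sliding-window oracle", {
  p <- preprocess_params()
  clean <- rep(FALSE, 250)
  expect_true(check_inclusion(clean, 1.8, p)$included)

  alternating <- rep(c(TRUE, FALSE), 125)
  expect_false(check_inclusion(alternating, 1.8, p)$included)

  # first 100 volumes heavily censored, clean tail: included via a window
  # anchored on the clean 270 s stretch
  half <- c(rep(TRUE, 100), rep(FALSE, 150))
  r <- check_inclusion(half, 1.8, p)
  expect_true(r$included)
  expect_equal(r$best_end, 250)
  expect_lte(r$best_fraction, 0.10)

  short <- rep(FALSE, 10)
  expect_equal(check_inclusion(short, 1.8, p)$reason, "run_too_short")

  # randomized masks against an exhaustive window scan
  oracle_incl <- function(mask, tr) {
    wmin <- floor(300 / tr)
    t_len <- length(mask)
    if (t_len < wmin) return(FALSE)
    for (len in wmin:t_len) for (s in 1:(t_len - len + 1)) {
      if (mean(mask[s:(s + len - 1)]) <= 0.10) return(TRUE)
    }
    FALSE
  }
  set.seed(33)
  for (k in 1:25) {
    mask <- runif(200) < runif(1, 0.05, 0.3)
    expect_equal(check_inclusion(mask, 2.0, p)$included,
                 oracle_incl(mask, 2.0))
  }
})

test_that("nuisance regression removes trends and regressors exactly", {
  t_len <- 100
  set.seed(3)
  motion <- matrix(rnorm(t_len * 6, sd = 0.05), t_len, 6)
  nuis <- matrix(rnorm(t_len * 3), t_len, 3)

  # signal equal to the WM regressor vanishes
  y_wm <- cbind(nuis[, 1], nuis[, 1])
  r <- regress_and_detrend(y_wm, motion, nuis)
  expect_equal(max(abs(r)), 0, tolerance = 1e-10)

  # pure linear trend vanishes
  y_tr <- cbind(3 * seq_len(t_len) + 2)
  r2 <- regress_and_detrend(y_tr, motion, nuis)
  expect_equal(max(abs(r2)), 0, tolerance = 1e-8)

  # planted signal + 0.5 * global: residual orthogonal to the global signal
  sig <- rnorm(t_len)
  y3 <- cbind(sig + 0.5 * nuis[, 3])
  r3 <- regress_and_detrend(y3, motion, nuis)
  expect_lt(abs(cor(r3[, 1], nuis[, 3])), 1e-10)
})

test_that("residuals are orthogonal to every regressor on uncensored frames", {
  t_len <- 120
  set.seed(4)
  motion <- matrix(rnorm(t_len * 6, sd = 0.05), t_len, 6)
  nuis <- matrix(rnorm(t_len * 3), t_len, 3)
  y <- matrix(rnorm(t_len * 5), t_len, 5)
  mask <- runif(t_len) < 0.1
  r <- regress_and_detrend(y, motion, nuis, mask)
  x <- cbind(1, seq_len(t_len), nuis, motion)
  xs <- scale(x[!mask, -1])
  rs <- r[!mask, ]
  expect_lt(max(abs(crossprod(xs, scale(rs, scale = FALSE)) / nrow(xs))), 1e-8)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  t_len <- 60
  set.seed(5)
  motion <- matrix(rnorm(t_len * 6, sd = 0.05), t_len, 6)
  motion[, 2] <- 2 * motion[, 1]
  nuis <- matrix(rnorm(t_len * 3), t_len, 3)
  expect_error(regress_and_detrend(matrix(rnorm(t_len)), motion, nuis),
               "rank-deficient.*motion")
})

test_that("band-pass keeps in-band tones, kills out-of-band tones and DC", {
  tr <- 1.8
  t_len <- 500
  tt <- (seq_len(t_len) - 1) * tr

  tone <- function(f) sin(2 * pi * f * tt)
  amp <- function(x, f) {
    2 * abs(sum(x * exp(-2i * pi * f * tt)) / length(x))
  }
  in_band <- bandpass_censored(cbind(tone(0.05)), NULL, tr = tr)
  expect_gt(amp(in_band[, 1], 0.05), 0.95)

  out_band <- bandpass_censored(cbind(tone(0.2)), NULL, tr = tr)
  expect_lt(amp(out_band[, 1], 0.2), 0.10)

  const <- bandpass_censored(cbind(rep(5, t_len)), NULL, tr = tr)
  expect_lt(max(abs(const)), 1e-6)

  expect_error(bandpass_censored(cbind(tone(0.05)), NULL, tr = 1.8,
                                 band = c(0.009, 0.3)), "Nyquist")
})

test_that("censored frames are interpolated before filtering and stay flagged", {
  tr <- 2.0
  t_len <- 300
  tt <- (seq_len(t_len) - 1) * tr
  x <- sin(2 * pi * 0.04 * tt)
  mask <- rep(FALSE, t_len)
  mask[c(50:55, 200)] <- TRUE
  x_spiky <- x
  x_spiky[mask] <- 40   # large artifacts at censored positions
  filt <- bandpass_censored(cbind(x_spiky), mask, tr = tr)
  clean <- bandpass_censored(cbind(x), NULL, tr = tr)
  # the 40-unit artifacts are suppressed to a small local interpolation error
  expect_lt(max(abs(filt[!mask, 1] - clean[!mask, 1])), 0.25)
})

test_that("the full preprocess pipeline preserves planted correlation structure", {
  cfg <- cohort_config("custom", n_hc = 1, n_ibs = 1, n_volumes = 250,
                       n_keep = 250, tr = 1.8,
                       module_sizes = c(15, 15, 15), within_r = 0.5,
                       between_r = 0.05, motion_spike_rate = 0,
                       motion_drift_amplitude = 0, nuisance_mix = 0)
  s <- simulate_subject(cfg, "HC", subject_seed = 42)
  memb <- s$true_partition
  within <- outer(memb, memb, "==") & upper.tri(diag(length(memb)))
  pre <- preprocess_subject(s$roi, s$motion, s$nuisance, tr = cfg$tr)
  expect_false(any(pre$censor$censored))
  r_before <- abs(cor(s$roi))
  r_after <- abs(cor(pre$series))
  expect_lt(abs(mean(r_after[within]) - mean(r_before[within])), 0.05)
})
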