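#' Preprocessing parameters
#'
#' Thresholds and band for temporal preprocessing. Defaults follow common
#' resting-state practice for this pipeline: censor a volume when any
#' realignment translation exceeds 1 mm or rotation exceeds 1 degree
#' relative to the reference (first) volume, or when scan-to-scan
#' framewise displacement exceeds 1 mm; include a subject only if some
#' contiguous interval of at least 5 minutes has at most 10% of volumes
#' censored; band-pass 0.009-0.1 Hz.
#'
#' @param run_translation_limit mm (default 1).
#' @param run_rotation_limit degrees (default 1); converted to radians for
#'   comparison with the rotation parameters, which are stored in radians.
#' @param fd_limit mm (default 1).
#' @param min_interval seconds (default 300).
#' @param max_censored_fraction proportion (default 0.10).
#' @param band numeric length-2, Hz (default `c(0.009, 0.1)`).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(run_translation_limit = 1,
                              run_rotation_limit = 1,
                              fd_limit = 1,
                              min_interval = 300,
                              max_censored_fraction = 0.10,
                              band = c(0.009, 0.1)) {
  stopifnot(run_translation_limit > 0, run_rotation_limit > 0, fd_limit > 0,
            min_interval > 0, max_censored_fraction >= 0,
            length(band) == 2, band[1] > 0, band[1] < band[2])
  structure(list(run_translation_limit = run_translation_limit,
                 run_rotation_limit = run_rotation_limit,
                 fd_limit = fd_limit,
                 min_interval = min_interval,
                 max_censored_fraction = max_censored_fraction,
                 band = band),
            class = "preprocess_params")
}

as_motion_matrix <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) {
    stop("motion must have 6 columns (3 translations mm, 3 rotations rad)",
         call. = FALSE)
  }
  if (anyNA(m)) stop("motion parameters contain missing values", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Framewise displacement
#'
#' Scan-to-scan head motion summary
#' `FD[t] = sum_i |x_i[t] - x_i[t-1]| + 50 * sum_i |theta_i[t] - theta_i[t-1]|`
#' with translations `x` in mm and rotations `theta` in radians; the factor
#' 50 converts rotation angle to arc displacement on a 50 mm sphere. The
#' first volume has no predecessor and `FD[1] = 0` by convention. FD
#' depends only on parameter differences, so it is invariant to any
#' constant offset of the realignment parameters.
#'
#' @param motion data frame or matrix, T x 6: columns 1-3 translations
#'   (mm), columns 4-6 rotations (radians).
#' @return Numeric vector of length T (mm).
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 1   # 1 mm jump on x at volume 3
#' framewise_displacement(m)
#' @export
framewise_displacement <- function(motion) {
  m <- as_motion_matrix(motion)
  if (nrow(m) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor volumes by motion
#'
#' A volume is censored when any of three rules fires: (1) any translation
#' component, relative to the reference (first) volume, exceeds the run
#' translation limit; (2) any rotation component relative to the reference
#' exceeds the run rotation limit (limit given in degrees, compared in
#' radians); (3) framewise displacement exceeds the FD limit. A volume can
#' be flagged by several rules at once. Lowering any limit never
#' un-censors a volume.
#'
#' @param motion T x 6 motion parameters (see [framewise_displacement()]).
#' @param params a [preprocess_params()].
#' @return A tibble with columns `volume`, `fd`, `reason_translation`,
#'   `reason_rotation`, `reason_fd`, `censored`, `reason` (comma-joined
#'   codes, `"none"` if clean).
#' @export
censor_volumes <- function(motion, params = preprocess_params()) {
  m <- as_motion_matrix(motion)
  fd <- framewise_displacement(m)
  rel <- sweep(m, 2, m[1, ])
  rot_limit_rad <- params$run_rotation_limit * pi / 180
  r_tr <- apply(abs(rel[, 1:3, drop = FALSE]) > params$run_translation_limit,
                1, any)
  r_ro <- apply(abs(rel[, 4:6, drop = FALSE]) > rot_limit_rad, 1, any)
  r_fd <- fd > params$fd_limit
  censored <- r_tr | r_ro | r_fd
  reason <- purrr::pmap_chr(list(r_tr, r_ro, r_fd), function(a, b, c) {
    codes <- c("run_translation", "run_rotation", "fd")[c(a, b, c)]
    if (length(codes) == 0) "none" else paste(codes, collapse = ",")
  })
  tibble::tibble(volume = seq_len(nrow(m)), fd = fd,
                 reason_translation = r_tr, reason_rotation = r_ro,
                 reason_fd = r_fd, censored = censored, reason = reason)
}

#' Subject inclusion rule
#'
#' A subject is included if and only if some contiguous window covering
#' `min_interval` of acquisition has a censored fraction no greater than
#' `max_censored_fraction`. The minimal window length is
#' `floor(min_interval / tr)` volumes — a window short of the requested
#' interval by less than one TR still qualifies, so the rule does not
#' depend on whether `min_interval` is a whole multiple of the TR. All
#' contiguous windows of every admissible length are examined; the report
#' returns the best (lowest censored fraction, longest on ties) window.
#'
#' @param mask logical vector (or a [censor_volumes()] tibble) marking
#'   censored volumes.
#' @param tr repetition time, seconds.
#' @param params a [preprocess_params()].
#' @return A list: `included`, `best_start`, `best_end` (volume indices),
#'   `best_fraction`, `window_volumes` (minimum window length in volumes),
#'   and `reason` (`"ok"`, `"run_too_short"` or `"no_clean_window"`).
#' @export
check_inclusion <- function(mask, tr, params = preprocess_params()) {
  if (is.data.frame(mask)) mask <- mask$censored
  mask <- as.logical(mask)
  t_total <- length(mask)
  wmin <- max(1L, floor(params$min_interval / tr))
  if (t_total < wmin) {
    return(list(included = FALSE, best_start = NA_integer_,
                best_end = NA_integer_, best_fraction = NA_real_,
                window_volumes = wmin, reason = "run_too_short"))
  }
  cs <- c(0, cumsum(mask))
  best <- list(frac = Inf, start = NA_integer_, end = NA_integer_, len = 0L)
  for (len in wmin:t_total) {
    starts <- seq_len(t_total - len + 1)
    frac <- (cs[starts + len] - cs[starts]) / len
    i <- which.min(frac)
    if (frac[i] < best$frac - 1e-12 ||
        (abs(frac[i] - best$frac) <= 1e-12 && len > best$len)) {
      best <- list(frac = frac[i], start = starts[i],
                   end = starts[i] + len - 1L, len = len)
    }
  }
  ok <- best$frac <= params$max_censored_fraction
  list(included = ok, best_start = best$start, best_end = best$end,
       best_fraction = best$frac, window_volumes = wmin,
       reason = if (ok) "ok" else "no_clean_window")
}

#' Nuisance regression with linear detrending
#'
#' Per node, ordinary least-squares regression of the signal on an
#' intercept, a linear trend, the three physiological/global regressors
#' (WM, CSF, global signal) and the six motion parameters, fitted on
#' uncensored volumes only. Residuals at censored positions are computed
#' from the fitted model (and remain flagged for exclusion downstream).
#' Detrending is folded into the design (intercept + linear term), which
#' is equivalent to a separate detrending pass under OLS.
#'
#' @param ts T x N matrix or data frame of node time series.
#' @param motion T x 6 motion parameters.
#' @param nuisance T x 3 matrix or data frame (WM, CSF, global).
#' @param mask logical censor vector or [censor_volumes()] tibble.
#' @return Matrix of residuals, T x N, same dimnames as `ts`.
#' @export
regress_and_detrend <- function(ts, motion, nuisance, mask = NULL) {
  y <- as.matrix(ts)
  m <- as_motion_matrix(motion)
  nu <- as.matrix(nuisance)
  t_len <- nrow(y)
  stopifnot(nrow(m) == t_len, nrow(nu) == t_len, ncol(nu) == 3)
  if (is.null(mask)) mask <- rep(FALSE, t_len)
  if (is.data.frame(mask)) mask <- mask$censored
  x <- cbind(intercept = 1, trend = seq_len(t_len) - (t_len + 1) / 2,
             wm = nu[, 1], csf = nu[, 2], global = nu[, 3],
             m[, 1:6, drop = FALSE])
  colnames(x)[6:11] <- paste0("motion", 1:6)
  # constant regressors (e.g. a motionless trace) carry no nuisance signal
  # and are dropped rather than treated as collinear
  keep_col <- c(TRUE, apply(x[, -1, drop = FALSE], 2, sd) > 0)
  x <- x[, keep_col, drop = FALSE]
  keep <- !mask
  if (sum(keep) <= ncol(x)) {
    stop("too few uncensored volumes to fit the nuisance model", call. = FALSE)
  }
  qx <- qr(x[keep, , drop = FALSE])
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("nuisance design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y[keep, , drop = FALSE])
  res <- y - x %*% beta
  dimnames(res) <- dimnames(y)
  res
}

#' Band-pass filter with interpolation over censored frames
#'
#' Censored samples are first replaced by linear interpolation between the
#' nearest uncensored neighbours (edge frames held constant), then a
#' zero-phase (forward-backward) 4th-order Butterworth band-pass is
#' applied per node; the interpolated frames remain censored afterwards
#' and must be excluded from downstream correlation computations via the
#' mask.
#'
#' @param ts T x N matrix or data frame of node time series.
#' @param mask logical censor vector or [censor_volumes()] tibble (NULL =
#'   nothing censored).
#' @param tr repetition time, seconds.
#' @param band Hz pair, low < high < Nyquist.
#' @return Filtered T x N matrix.
#' @export
bandpass_censored <- function(ts, mask = NULL, tr, band = c(0.009, 0.1)) {
  y <- as.matrix(ts)
  t_len <- nrow(y)
  if (is.null(mask)) mask <- rep(FALSE, t_len)
  if (is.data.frame(mask)) mask <- mask$censored
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq) {
    stop(sprintf("band high (%.3f Hz) must be below Nyquist (%.3f Hz)",
                 band[2], nyq), call. = FALSE)
  }
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band", call. = FALSE)
  keep <- which(!mask)
  if (length(keep) < 2) stop("fewer than 2 uncensored volumes", call. = FALSE)
  if (any(mask)) {
    for (j in seq_len(ncol(y))) {
      y[, j] <- approx(keep, y[keep, j], xout = seq_len(t_len),
                       method = "linear", rule = 2)$y
    }
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  # demean and mirror-pad before the forward-backward pass to suppress
  # the filter's edge transients (the low band edge has a long impulse
  # response relative to typical run lengths)
  pad <- t_len - 1
  out <- apply(y, 2, function(col) {
    mu <- mean(col)
    col <- col - mu
    padded <- c(rev(col[2:(pad + 1)]), col, rev(col[(t_len - pad):(t_len - 1)]))
    filt <- as.numeric(signal::filtfilt(bf, padded))
    filt[(pad + 1):(pad + t_len)]
  })
  dimnames(out) <- dimnames(ts)
  out
}

#' Full temporal preprocessing for one subject
#'
#' Runs the censoring, inclusion check, nuisance regression and band-pass
#' stages on a subject's ROI time series, returning the cleaned series
#' with its censor mask.
#'
#' @param roi T x N ROI time-series matrix.
#' @param motion T x 6 motion parameters.
#' @param nuisance T x 3 nuisance series (WM, CSF, global).
#' @param tr repetition time, seconds.
#' @param params a [preprocess_params()].
#' @return A list: `series` (filtered residual T x N matrix; `NULL` when
#'   the subject fails the inclusion rule), `censor` (tibble from
#'   [censor_volumes()]), `inclusion` (report from [check_inclusion()]),
#'   `params`.
#' @export
preprocess_subject <- function(roi, motion, nuisance, tr,
                               params = preprocess_params()) {
  cens <- censor_volumes(motion, params)
  incl <- check_inclusion(cens, tr, params)
  if (!incl$included) {
    return(list(series = NULL, censor = cens, inclusion = incl,
                params = params))
  }
  res <- regress_and_detrend(roi, motion, nuisance, cens)
  filt <- bandpass_censored(res, cens, tr, params$band)
  list(series = filt, censor = cens, inclusion = incl, params = params)
}
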