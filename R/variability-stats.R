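# Boundary-variability statistics: equal-n time binning, smoothing-spline
# de-trending, two-sample variance tests, bootstrap errors, scaling
# regressions and pooled standard deviations.

#' Equal-sample-size time binning
#'
#' Sorts measurements by time and groups them into consecutive bins of
#' `n_per_bin`; the last bin takes the remainder. With fewer than
#' `n_per_bin` measurements in total a single bin is returned with a
#' warning.
#'
#' @param measurements Boundary data.frame with columns `time_min` and
#'   `position_pct_el` (as produced by [detect_boundary()]).
#' @param n_per_bin Samples per bin, `>= 2`.
#' @return A data.frame with one row per bin: `bin`, `n`, `time_mid`,
#'   `time_lo`, `time_hi`, `mean_pct_el`, `sd_pct_el`; the bin membership is
#'   attached as attribute `members` (list of row-index vectors into the
#'   time-sorted input, itself attached as attribute `sorted`).
#' @export
equal_n_time_bins <- function(measurements, n_per_bin) {
  check_scalar(n_per_bin, "n_per_bin", lower = 2)
  n <- nrow(measurements)
  if (n < 1L) stop_config("no measurements to bin")
  m <- measurements[order(measurements$time_min), , drop = FALSE]
  if (n < n_per_bin) {
    warning("fewer measurements than n_per_bin: returning a single bin")
    groups <- list(seq_len(n))
  } else {
    n_bins <- ceiling(n / n_per_bin)
    groups <- split(seq_len(n),
                    pmin(ceiling(seq_len(n) / n_per_bin), n_bins))
  }
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    p <- m$position_pct_el[idx]
    data.frame(bin = i, n = length(idx),
               time_mid = mean(m$time_min[idx]),
               time_lo = min(m$time_min[idx]),
               time_hi = max(m$time_min[idx]),
               mean_pct_el = mean(p),
               sd_pct_el = if (length(p) >= 2L) stats::sd(p) else NA_real_)
  }))
  attr(out, "members") <- groups
  attr(out, "sorted") <- m
  out
}

#' De-trend boundary positions with a smoothing spline
#'
#' Fits a smoothing spline of position against time, removing the systematic
#' developmental trend before computing the embryo-to-embryo variability.
#' The residual SD uses a degrees-of-freedom-adjusted denominator
#' `sqrt(RSS / (n - df))`, where `df` is the spline's equivalent degrees of
#' freedom, so that the trend's flexibility does not deflate the estimate.
#' Its uncertainty is estimated by case-resampling bootstrap.
#'
#' @param times Times (min into nc14); at least 10 points spanning > 10 min.
#' @param positions Boundary positions (percent EL), same length.
#' @param smoothing `"gcv"` (generalized cross-validation, default) or a
#'   numeric fixed equivalent degrees of freedom (e.g. 5).
#' @param n_boot Bootstrap replicates for the SE of the residual SD.
#' @param seed Seed for the bootstrap.
#' @return An object of class `trajectory_fit`: list with `trend` (function
#'   time -> percent EL), `times`, `positions`, `residuals`, `residual_sd`,
#'   `edf`, `bootstrap_se`.
#' @export
detrend_spline <- function(times, positions, smoothing = "gcv",
                           n_boot = 200L, seed = 1L) {
  if (length(times) != length(positions) || length(times) < 10L) {
    stop_config("need >= 10 paired (time, position) points")
  }
  if (diff(range(times)) <= 10) {
    stop_config("time span must exceed 10 min for de-trending")
  }
  fit_one <- function(t, p) {
    if (identical(smoothing, "gcv")) {
      stats::smooth.spline(t, p, cv = FALSE)
    } else {
      stats::smooth.spline(t, p, df = as.numeric(smoothing))
    }
  }
  sp <- fit_one(times, positions)
  trend <- function(t) stats::predict(sp, pmin(pmax(t, min(times)),
                                               max(times)))$y
  res <- positions - trend(times)
  n <- length(res)
  edf <- sp$df
  residual_sd <- sqrt(sum(res^2) / max(n - edf, 1))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(times[idx])) < 4L) return(NA_real_)
      spb <- tryCatch(suppressWarnings(fit_one(times[idx], positions[idx])),
                      error = function(e) NULL)
      if (is.null(spb)) return(NA_real_)
      rb <- positions[idx] - stats::predict(spb, times[idx])$y
      sqrt(sum(rb^2) / max(length(rb) - spb$df, 1))
    }, numeric(1))
  })
  structure(list(trend = trend, times = times, positions = positions,
                 residuals = res, residual_sd = residual_sd, edf = edf,
                 bootstrap_se = stats::sd(boot, na.rm = TRUE)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(paste0("<trajectory_fit> n = %d, residual SD = %.3f %%EL ",
                     "(bootstrap SE %.3f), spline edf = %.1f\n"),
              length(x$residuals), x$residual_sd, x$bootstrap_se, x$edf))
  invisible(x)
}

#' Two-sample F-test for equal variances
#'
#' Computes `F = (sd1/sd2)^2` on `(n1 - 1, n2 - 1)` degrees of freedom and
#' doubles the smaller tail probability (capped at 1) for a two-sided test.
#' Symmetric in its arguments.
#'
#' @param sd1,sd2 Sample standard deviations, `> 0`.
#' @param n1,n2 Sample sizes, `>= 2`.
#' @return Two-sided p-value.
#' @export
f_test_equal_variance <- function(sd1, n1, sd2, n2) {
  check_scalar(sd1, "sd1", lower = .Machine$double.xmin)
  check_scalar(sd2, "sd2", lower = .Machine$double.xmin)
  check_scalar(n1, "n1", lower = 2)
  check_scalar(n2, "n2", lower = 2)
  f <- (sd1 / sd2)^2
  lower <- stats::pf(f, n1 - 1, n2 - 1)
  min(1, 2 * min(lower, 1 - lower))
}

#' Bootstrap standard error of a statistic
#'
#' Case-resampling bootstrap: the SE is the standard deviation of the
#' statistic over resampled replicates.
#'
#' @param values Numeric vector.
#' @param statistic Function of a numeric vector (default [stats::sd()]).
#' @param n_reps Number of replicates, `>= 200`.
#' @param seed Integer seed; identical seeds give identical SEs.
#' @return Bootstrap SE of the statistic.
#' @export
bootstrap_se <- function(values, statistic = stats::sd, n_reps = 1000L,
                         seed = 1L) {
  if (length(values) == 0L) stop_config("empty input")
  check_scalar(n_reps, "n_reps", lower = 200)
  n <- length(values)
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps),
           function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  stats::sd(reps)
}

#' Scaling regression of boundary position on embryo length
#'
#' Tests whether boundary position scales with embryo length after removing
#' the developmental trend. In `relative` mode the de-trended relative
#' position `position / trend(time)` is regressed on normalized length
#' `L / mean(L)` (slope 0 under perfect scaling). In `absolute` mode the
#' normalized absolute position `position * L / (trend(time) * mean(L))` is
#' regressed on normalized length (slope 1 under perfect scaling, attenuated
#' toward 0 by position noise).
#'
#' @param measurements Boundary data.frame with `time_min`,
#'   `position_pct_el`, `length_um`.
#' @param mode `"relative"` or `"absolute"`.
#' @param trend A [detrend_spline()] fit providing the trend function.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
scaling_regression <- function(measurements, mode = c("relative", "absolute"),
                               trend) {
  mode <- match.arg(mode)
  stopifnot(inherits(trend, "trajectory_fit"))
  if (is.null(measurements$length_um) || anyNA(measurements$length_um)) {
    stop_config("embryo lengths are required for scaling analysis")
  }
  len_norm <- measurements$length_um / mean(measurements$length_um)
  pred <- trend$trend(measurements$time_min)
  y <- if (mode == "relative") {
    measurements$position_pct_el / pred
  } else {
    (measurements$position_pct_el * measurements$length_um) /
      (pred * mean(measurements$length_um))
  }
  fit <- stats::lm(y ~ len_norm)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = length(y))
}

#' Pooled boundary variability
#'
#' Sample SD of boundary positions pooled under an inclusion rule:
#' `all_dorsal` keeps dorsal measurements (orientation within 10 degrees of
#' the dorsal midline) over all of nc14, `dorsal_and_ventral` additionally
#' keeps ventral ones (within 10 degrees of 180), and `per_bin` returns the
#' SD of the supplied selection as-is.
#'
#' @param measurements Boundary data.frame with `orientation_deg` and
#'   `position_pct_el`.
#' @param pooling `"per_bin"`, `"all_dorsal"` or `"dorsal_and_ventral"`.
#' @return Pooled SD in percent EL.
#' @export
pooled_variability <- function(measurements,
                               pooling = c("all_dorsal", "dorsal_and_ventral",
                                           "per_bin")) {
  pooling <- match.arg(pooling)
  sel <- switch(pooling,
    per_bin = rep(TRUE, nrow(measurements)),
    all_dorsal = measurements$orientation_deg <= 10 |
      measurements$orientation_deg >= 350,
    dorsal_and_ventral = measurements$orientation_deg <= 10 |
      measurements$orientation_deg >= 350 |
      abs(measurements$orientation_deg - 180) <= 10
  )
  p <- measurements$position_pct_el[sel]
  if (length(p) < 2L) stop_config("empty or singleton selection")
  stats::sd(p)
}
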