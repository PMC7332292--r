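# Bcd gradient analytics: nuclear binning, log-linear exponential fits,
# relative-noise profiles and heat maps, and propagation of gradient noise
# into positional error with quadrature subtraction of measurement noise.

#' Bin nuclei along the AP axis
#'
#' Pools the nuclei of one or several embryos into fixed-width AP bins
#' (default 2 percent EL) and computes per-bin intensity mean, SD and
#' relative noise (CV = SD/mean). Bins with fewer than `min_n` nuclei are
#' dropped.
#'
#' @param gradients A `nuclear_gradient` (see [generate_bcd_nuclei()]) or a
#'   list of them; all nuclei are pooled.
#' @param bin_size Bin width in fraction EL (default 0.02).
#' @param min_n Minimum nuclei per retained bin (default 3).
#' @return An object of class `noise_profile`: data.frame with `center`
#'   (fraction EL), `n`, `mean`, `sd`, `cv`.
#' @export
bin_nuclei <- function(gradients, bin_size = 0.02, min_n = 3L) {
  if (inherits(gradients, "nuclear_gradient")) gradients <- list(gradients)
  x <- unlist(lapply(gradients, function(g) g$x))
  intensity <- unlist(lapply(gradients, function(g) g$intensity))
  if (length(x) == 0L) stop_config("no nuclei to bin")
  check_scalar(bin_size, "bin_size", lower = 1e-6, upper = 0.5)
  edges <- seq(0, 1 + bin_size / 2, by = bin_size)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    ii <- bin == b
    if (sum(ii) < min_n) return(NULL)
    m <- mean(intensity[ii])
    s <- stats::sd(intensity[ii])
    data.frame(center = (edges[b] + edges[b + 1L]) / 2, n = sum(ii),
               mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
  }))
  if (is.null(out)) stop_config("no bin reached the minimum nucleus count")
  structure(out, class = c("noise_profile", "data.frame"),
            bin_size = bin_size)
}

#' Mean relative gradient noise over an AP range
#'
#' Average of per-bin CVs over bins whose centers fall in `range`, with a
#' bootstrap SE over bins.
#'
#' @param noise_profile A [bin_nuclei()] result.
#' @param range AP range in fraction EL (default `c(0.1, 0.6)`).
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with `mean_cv`, `se`, `n_bins`.
#' @export
mean_relative_noise <- function(noise_profile, range = c(0.1, 0.6),
                                n_boot = 1000L, seed = 1L) {
  sel <- noise_profile$center >= range[1L] & noise_profile$center <= range[2L]
  cvs <- noise_profile$cv[sel]
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) == 0L) stop_config("no bins in the requested range")
  se <- if (length(cvs) >= 2L) {
    n <- length(cvs)
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      mean(cvs[sample.int(n, n, replace = TRUE)])
    }, numeric(1)))
    stats::sd(reps)
  } else NA_real_
  list(mean_cv = mean(cvs), se = se, n_bins = length(cvs))
}

#' Fit an exponential gradient by log-linear regression
#'
#' Ordinary least squares of `log(bin mean)` on bin center over the fit
#' range (default 0.1-0.8 EL); `amplitude = exp(intercept)` and
#' `lambda = -1/slope`. Bins with non-positive means are excluded with a
#' warning. Exact on noiseless exponentials.
#'
#' @param noise_profile A [bin_nuclei()] result.
#' @param range Fit range in fraction EL (default `c(0.1, 0.8)`).
#' @return An object of class `gradient_fit`: list with `amplitude`,
#'   `lambda`, `range`, `residual_rms`, `n_bins`.
#' @export
fit_exponential <- function(noise_profile, range = c(0.1, 0.8)) {
  sel <- noise_profile$center >= range[1L] & noise_profile$center <= range[2L]
  d <- noise_profile[sel, , drop = FALSE]
  if (any(d$mean <= 0)) {
    warning("excluding ", sum(d$mean <= 0), " bin(s) with non-positive mean")
    d <- d[d$mean > 0, , drop = FALSE]
  }
  if (nrow(d) < 5L) stop_config("need >= 5 positive bins in the fit range")
  fit <- stats::lm(log(mean) ~ center, data = d)
  cf <- stats::coef(fit)
  if (cf[2L] >= 0) warning("fitted gradient is non-decreasing in x")
  structure(list(amplitude = unname(exp(cf[1L])),
                 lambda = unname(-1 / cf[2L]),
                 range = range,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_bins = nrow(d)),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<gradient_fit> amplitude = %.4g, lambda = %.4f EL (%d bins in [%.2f, %.2f])\n",
    x$amplitude, x$lambda, x$n_bins, x$range[1L], x$range[2L]))
  invisible(x)
}

#' Gradient-noise heat map over developmental time
#'
#' Stacks per-time-point noise profiles into a CV matrix (time x AP bin) and
#' computes the range-averaged CV against time (default average over
#' 0-0.55 EL).
#'
#' @param gradients_by_time Named list: one entry per time point, each a
#'   `nuclear_gradient` or list of them; names are times in minutes.
#' @param bin_size Bin width (fraction EL).
#' @param average_range AP range for the summary curve (default
#'   `c(0, 0.55)`).
#' @return List with `times`, `centers`, `cv` (matrix, rows = times, NA for
#'   dropped bins) and `average_cv` (per-time mean CV over the range).
#' @export
noise_heatmap <- function(gradients_by_time, bin_size = 0.02,
                          average_range = c(0, 0.55)) {
  if (length(gradients_by_time) < 2L) {
    stop_config("need >= 2 time points for a noise heat map")
  }
  times <- as.numeric(names(gradients_by_time))
  if (anyNA(times)) stop_config("list names must be numeric times (min)")
  centers <- seq(bin_size / 2, 1 - bin_size / 2, by = bin_size)
  cv <- matrix(NA_real_, nrow = length(times), ncol = length(centers),
               dimnames = list(names(gradients_by_time), NULL))
  for (i in seq_along(times)) {
    np <- bin_nuclei(gradients_by_time[[i]], bin_size = bin_size)
    j <- match(round(np$center, 10), round(centers, 10))
    cv[i, j[!is.na(j)]] <- np$cv[!is.na(j)]
  }
  in_range <- centers >= average_range[1L] & centers <= average_range[2L]
  avg <- apply(cv[, in_range, drop = FALSE], 1L,
               function(r) mean(r, na.rm = TRUE))
  list(times = times, centers = centers, cv = cv, average_cv = avg)
}

#' Positional error implied by gradient noise
#'
#' Propagates relative intensity noise through an exponential gradient:
#' `sigma_x = lambda * CV_bio`, where the biological CV is obtained by
#' quadrature subtraction of the imaging and image-mask measurement noise,
#' `CV_bio^2 = max(CV_tot^2 - imaging_cv^2 - mask_cv^2, 0)` (floored at zero
#' with a warning).
#'
#' @param noise_profile A [bin_nuclei()] result.
#' @param fit A [fit_exponential()] result supplying `lambda`.
#' @param imaging_cv,mask_cv Measurement-noise CVs, `>= 0` (default 0).
#' @return Data.frame with `center` (fraction EL), `cv_bio` and
#'   `sigma_x_pct_el` (positional error in percent EL).
#' @export
positional_error <- function(noise_profile, fit, imaging_cv = 0,
                             mask_cv = 0) {
  stopifnot(inherits(fit, "gradient_fit"))
  check_scalar(imaging_cv, "imaging_cv", lower = 0)
  check_scalar(mask_cv, "mask_cv", lower = 0)
  cv2 <- noise_profile$cv^2 - imaging_cv^2 - mask_cv^2
  if (any(cv2 < 0, na.rm = TRUE)) {
    warning("measurement noise exceeds total noise in ",
            sum(cv2 < 0, na.rm = TRUE), " bin(s); flooring at zero")
    cv2 <- pmax(cv2, 0)
  }
  cv_bio <- sqrt(cv2)
  data.frame(center = noise_profile$center, cv_bio = cv_bio,
             sigma_x_pct_el = 100 * fit$lambda * cv_bio)
}
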