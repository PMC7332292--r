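# Feature extraction from 1D expression profiles: robust normalization,
# logistic boundary fits, inflection fronts, strip widths, peak calling and
# orientation heat maps.

#' Normalize a profile to [0, 1]
#'
#' Affine rescaling using robust low/high references (1st and 99th intensity
#' percentiles), then clipped to `[0, 1]`. Order-preserving and idempotent up
#' to the clipping tolerance.
#'
#' @param profile An [expression_profile()].
#' @return The profile with intensity rescaled to `[0, 1]`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  q <- stats::quantile(profile$intensity, c(0.01, 0.99), names = FALSE)
  if (q[2L] - q[1L] < .Machine$double.eps^0.5 * max(1, abs(q[2L]))) {
    stop_feature("degenerate profile: intensity is (near-)constant")
  }
  profile$intensity <- pmin(pmax((profile$intensity - q[1L]) /
                                   (q[2L] - q[1L]), 0), 1)
  profile
}

boundary_row <- function(position_pct, feature, meta) {
  n <- length(position_pct)
  if (n == 0L) {
    return(data.frame(embryo_id = character(0), genotype = character(0),
                      feature = character(0), time_min = numeric(0),
                      orientation_deg = numeric(0),
                      position_pct_el = numeric(0), length_um = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    embryo_id = meta$embryo_id %||% NA_character_,
    genotype = meta$genotype %||% NA_character_,
    feature = feature,
    time_min = meta$time_min %||% NA_real_,
    orientation_deg = meta$orientation_deg %||% NA_real_,
    position_pct_el = position_pct,
    length_um = meta$length_um %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

# last downward half-maximum crossing of a normalized profile, interpolated
half_max_crossing <- function(x, g, level = 0.5) {
  above <- g >= level
  idx <- which(above[-length(g)] & !above[-1L])
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[length(idx)]
  x[i] + (level - g[i]) * (x[i + 1L] - x[i]) / (g[i + 1L] - g[i])
}

#' Detect the boundary of an anterior-high expression domain
#'
#' Fits a logistic `1/(1 + exp((x - xb)/w))` to the normalized profile and
#' reports the midpoint `xb`; if the nonlinear fit fails, falls back to the
#' interpolated half-maximum crossing. Positions are invariant under affine
#' intensity transforms of the input.
#'
#' @param profile An [expression_profile()] with a monotone-decreasing
#'   sigmoidal segment.
#' @param feature Feature label for the output row (default `"hb_boundary"`).
#' @return A one-row data.frame (`embryo_id`, `genotype`, `feature`,
#'   `time_min`, `orientation_deg`, `position_pct_el`, `length_um`).
#' @export
detect_boundary <- function(profile, feature = "hb_boundary") {
  profile <- normalize_profile(profile)
  x <- profile$x
  g <- profile$intensity
  x0 <- half_max_crossing(x, g)
  if (is.na(x0)) {
    stop_feature("no downward half-maximum crossing: boundary not found")
  }
  # free asymptotes: with noisy plateaus a unit-asymptote logistic would
  # absorb the scale mismatch into a systematic midpoint shift
  xb <- tryCatch({
    fit <- suppressWarnings(
      stats::nls(g ~ lo + (hi - lo) / (1 + exp((x - xb) / w)),
                 start = list(lo = 0, hi = 1, xb = x0, w = 0.02),
                 control = stats::nls.control(warnOnly = TRUE)))
    cf <- stats::coef(fit)
    if (is.finite(cf[["xb"]]) && cf[["xb"]] > min(x) && cf[["xb"]] < max(x) &&
          cf[["w"]] > 0 && cf[["hi"]] > cf[["lo"]]) cf[["xb"]] else x0
  }, error = function(e) x0)
  boundary_row(100 * xb, feature, profile$meta)
}

# local quadratic (Savitzky-Golay style) smoothed first derivative
smoothed_derivative <- function(x, g, half_width = 2L) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    xi <- x[lo:hi] - x[i]
    fit <- stats::lm.fit(cbind(1, xi, xi^2), g[lo:hi])
    d[i] <- fit$coefficients[2L]
  }
  d
}

# parabolic refinement of an extremum of a sampled function
refine_extremum <- function(x, y, i, maximize = TRUE) {
  if (i <= 1L || i >= length(x)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  x[i] + delta * (x[i + 1L] - x[i])
}

#' Detect a strip inflection front
#'
#' Locates the extremum of the smoothed first derivative on the requested
#' flank of a strip-shaped profile: the steepest rise anterior of the strip
#' center (`side = "anterior"`) or the steepest fall posterior of it.
#'
#' @param profile An [expression_profile()] with a strip-shaped intensity.
#' @param side `"anterior"` or `"posterior"`.
#' @param half_width Smoothing half-width in grid points (default 4, i.e. a
#'   9-point local quadratic).
#' @return A one-row boundary data.frame with feature `"kr_front"`.
#' @export
detect_inflection_front <- function(profile,
                                    side = c("anterior", "posterior"),
                                    half_width = 4L) {
  side <- match.arg(side)
  profile <- normalize_profile(profile)
  x <- profile$x
  g <- profile$intensity
  peak <- which.max(smoothed_profile(x, g, half_width))
  if (peak <= half_width + 1L || peak >= length(x) - half_width) {
    stop_feature("profile has no interior maximum: not strip-shaped")
  }
  d <- smoothed_derivative(x, g, half_width)
  if (side == "anterior") {
    region <- seq_len(peak)
    i <- region[which.max(d[region])]
    if (d[i] <= 0) stop_feature("no rising anterior flank found")
    pos <- refine_extremum(x, d, i)
  } else {
    region <- peak:length(x)
    i <- region[which.min(d[region])]
    if (d[i] >= 0) stop_feature("no falling posterior flank found")
    pos <- refine_extremum(x, -d, i)
  }
  boundary_row(100 * pos, "kr_front", profile$meta)
}

smoothed_profile <- function(x, g, half_width = 2L) {
  n <- length(g)
  s <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    s[i] <- mean(g[lo:hi])
  }
  s
}

#' Strip width
#'
#' Distance between the posterior and anterior inflection fronts of a strip.
#'
#' @param profile An [expression_profile()].
#' @param half_width Derivative smoothing half-width (grid points).
#' @return Width in percent EL.
#' @export
strip_width <- function(profile, half_width = 4L) {
  a <- detect_inflection_front(profile, "anterior", half_width)
  p <- detect_inflection_front(profile, "posterior", half_width)
  p$position_pct_el - a$position_pct_el
}

#' Detect expression peaks
#'
#' Local maxima of the lightly smoothed profile ranked by topographic
#' prominence; at most `max_peaks` are returned, sorted anterior to
#' posterior. A flat profile yields an empty result.
#'
#' @param profile An [expression_profile()].
#' @param max_peaks Maximum number of peaks to return.
#' @param min_prominence Minimum prominence as a fraction of the intensity
#'   range (default 0.2).
#' @return A boundary data.frame with features `"eve_peak_1"`, ... (zero rows
#'   if no peaks).
#' @export
detect_peaks <- function(profile, max_peaks = 7L, min_prominence = 0.2) {
  stopifnot(inherits(profile, "expression_profile"))
  x <- profile$x
  g <- smoothed_profile(x, profile$intensity, 1L)
  rng <- diff(range(g))
  empty <- boundary_row(numeric(0), character(0), profile$meta)
  if (rng < .Machine$double.eps^0.5 * max(1, max(abs(g)))) return(empty)
  n <- length(g)
  cand <- which(diff(sign(diff(g))) < 0) + 1L
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) {
    left <- g[seq_len(i - 1L)]
    right <- g[(i + 1L):n]
    hl <- which(left >= g[i])
    hr <- which(right >= g[i])
    key_l <- if (!length(hl)) min(left)
    else if (max(hl) + 1L <= i - 1L) min(left[(max(hl) + 1L):(i - 1L)])
    else g[i]
    key_r <- if (!length(hr)) min(right)
    else if (min(hr) > 1L) min(right[seq_len(min(hr) - 1L)])
    else g[i]
    g[i] - max(key_l, key_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence * rng]
  prom <- prom[prom >= min_prominence * rng]
  if (length(keep) == 0L) return(empty)
  if (length(keep) > max_peaks) {
    ord <- order(prom, decreasing = TRUE)[seq_len(max_peaks)]
    keep <- keep[ord]
  }
  keep <- sort(keep)
  pos <- vapply(seq_along(keep),
                function(k) refine_extremum(x, g, keep[k]), numeric(1))
  out <- boundary_row(100 * pos, sprintf("eve_peak_%d", seq_along(keep)),
                      profile$meta)
  out
}

#' Build an orientation heat map
#'
#' Normalizes each of the 36 orientation profiles of one embryo
#' independently to `[0, 1]` and stacks them in canonical angle order, with
#' the dorsal midline (0 degrees) in the bottom quarter of the map and the
#' ventral side in the upper quarter.
#'
#' @param profiles List of exactly 36 [expression_profile()] objects at
#'   5 degree steps (any input order; rows are canonicalized by angle).
#' @return An object of class `orientation_heatmap`: list with `angles`
#'   (ascending from dorsal), `x`, and `values` (36 x length(x) matrix in
#'   `[0, 1]`).
#' @export
build_heatmap <- function(profiles) {
  if (length(profiles) != 36L) {
    stop_config("exactly 36 orientation profiles are required, got ",
                length(profiles))
  }
  angles <- vapply(profiles, function(p) p$meta$orientation_deg %||% NA_real_,
                   numeric(1))
  if (anyNA(angles) || anyDuplicated(angles)) {
    stop_config("each profile must carry a unique orientation_deg")
  }
  ord <- order(angles)
  profiles <- profiles[ord]
  angles <- angles[ord]
  x <- profiles[[1L]]$x
  values <- t(vapply(profiles, function(p) {
    if (!isTRUE(all.equal(p$x, x))) stop_config("profiles on different grids")
    normalize_profile(p)$intensity
  }, numeric(length(x))))
  structure(list(angles = angles, x = x, values = values,
                 meta = profiles[[1L]]$meta),
            class = "orientation_heatmap")
}

heatmap_boundaries <- function(heatmap) {
  vapply(seq_along(heatmap$angles), function(i) {
    p <- expression_profile(heatmap$x, heatmap$values[i, ],
                            meta = heatmap$meta)
    detect_boundary(p)$position_pct_el
  }, numeric(1))
}

#' Orientation sensitivity of the boundary position
#'
#' Worst-case boundary displacement within an angular window: the maximum of
#' `|boundary(theta) - boundary(center_angle)|` over rows with
#' `|theta - center_angle| <= delta`. Non-decreasing in `delta`.
#'
#' @param heatmap An [build_heatmap()] result.
#' @param center_angle Reference angle in degrees (must be one of the rows).
#' @param delta Angular window half-width in degrees, `<= 45`.
#' @return Maximum displacement in percent EL.
#' @export
orientation_sensitivity <- function(heatmap, center_angle = 0, delta = 10) {
  stopifnot(inherits(heatmap, "orientation_heatmap"))
  check_scalar(delta, "delta", lower = 0, upper = 45)
  i0 <- which(abs(heatmap$angles - center_angle) < 1e-9)
  if (length(i0) != 1L) stop_config("center_angle is not a heat-map row")
  b <- heatmap_boundaries(heatmap)
  sel <- abs(heatmap$angles - center_angle) <= delta + 1e-9
  max(abs(b[sel] - b[i0]))
}
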