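# Synthetic embryo generator
#
# Emulates the statistical structure of staged, 3D-imaged Drosophila embryo
# collections: logistic Hb boundaries riding genotype-specific time trends
# with dorsoventral modulation and embryo-to-embryo residual noise,
# exponential nuclear Bcd gradients with constant-CV intensity noise, Kr
# strips and Eve peaks, embryo-length variation, and ~1 min staging error.

#' Construct an expression profile
#'
#' A 1D expression profile of one gene along the anterior-posterior (AP)
#' axis of one embryo at one orientation and developmental time.
#'
#' @param x Numeric vector of AP positions as fraction of embryo length (EL),
#'   strictly increasing, in `[0, 1]` (anterior pole = 0).
#' @param intensity Numeric vector of intensities (a.u.), same length as `x`.
#' @param meta Named list of embryo metadata (`embryo_id`, `genotype`,
#'   `time_min`, `orientation_deg`, `length_um`, `gene`).
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(x, intensity, meta = list()) {
  if (length(x) != length(intensity)) {
    stop_config("x and intensity must have the same length")
  }
  if (length(x) < 3L || any(diff(x) <= 0)) {
    stop_config("x must be strictly increasing with at least 3 points")
  }
  structure(list(x = as.numeric(x), intensity = as.numeric(intensity),
                 meta = meta),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s, %d points on [%.2f, %.2f] EL\n",
              x$meta$gene %||% "?", length(x$x), min(x$x), max(x$x)))
  if (!is.null(x$meta$time_min)) {
    cat(sprintf("  embryo %s (%s), t = %.1f min, orientation %.0f deg\n",
                x$meta$embryo_id %||% "?", x$meta$genotype %||% "?",
                x$meta$time_min, x$meta$orientation_deg %||% 0))
  }
  invisible(x)
}

#' Boundary trend specification
#'
#' Describes the mean time trajectory of a pattern boundary over nuclear
#' cycle 14 (nc14) as anchors (time, mean position), plus embryo-to-embryo
#' residual noise, a dorsoventral modulation amplitude and the boundary
#' steepness of the underlying logistic profile.
#'
#' @param anchors Two-column matrix or data.frame `(time_min, position_pct_el)`
#'   with strictly increasing times.
#' @param residual_sd Embryo-to-embryo residual SD of boundary position
#'   (percent EL), `>= 0`.
#' @param dv_modulation Amplitude (percent EL) of the anterior offset of the
#'   boundary on the ventral side relative to the dorsal side.
#' @param boundary_steepness Logistic steepness, 1/(percent EL); the logistic
#'   width is its reciprocal.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(anchors, residual_sd = 0, dv_modulation = 0,
                       boundary_steepness = 0.5) {
  anchors <- as.matrix(anchors)
  if (is.null(dim(anchors)) || ncol(anchors) != 2L || nrow(anchors) < 1L) {
    stop_config("anchors must be a (time, position) matrix with >= 1 row")
  }
  if (nrow(anchors) > 1L && any(diff(anchors[, 1L]) <= 0)) {
    stop_config("anchor times must be strictly increasing")
  }
  check_scalar(residual_sd, "residual_sd", lower = 0)
  check_scalar(dv_modulation, "dv_modulation", lower = 0)
  check_scalar(boundary_steepness, "boundary_steepness", lower = 1e-8)
  colnames(anchors) <- c("time_min", "position_pct_el")
  structure(list(anchors = anchors, residual_sd = residual_sd,
                 dv_modulation = dv_modulation,
                 boundary_steepness = boundary_steepness),
            class = "trend_spec")
}

#' Default boundary trend per genotype
#'
#' Dorsal x_Hb trajectories over nc14. The stau mutant boundary starts at
#' 37.6 percent EL at 2.5 min, completes about 7 percent EL of its shift by
#' 30 min and stabilizes at 47.9 percent EL by 62.5 min; the wild type moves
#' 3 percent EL in the first 20 min and stabilizes at 47.8 percent EL; the
#' stauD3 allele moves from 42.8 (12.5 min) to 47.9 (52.5 min) percent EL.
#' Dorsoventral modulation defaults to 6 percent EL for stau mutants and
#' 3 percent EL for the wild type.
#'
#' @param genotype One of `"WT"`, `"stau"`, `"stauD3"`, `"Bcd1.0"`.
#' @param residual_sd Residual SD (percent EL); defaults to the genotype's
#'   de-trended boundary variability (1.45 WT, 1.67 stau).
#' @return A [trend_spec()].
#' @export
default_trend <- function(genotype = c("stau", "WT", "stauD3", "Bcd1.0"),
                          residual_sd = NULL) {
  genotype <- match.arg(genotype)
  spec <- switch(genotype,
    stau = list(anchors = rbind(c(2.5, 37.6), c(30, 44.6), c(62.5, 47.9)),
                residual_sd = 1.67, dv = 6),
    WT = list(anchors = rbind(c(2.5, 44.8), c(20, 47.8), c(62.5, 47.8)),
              residual_sd = 1.45, dv = 3),
    stauD3 = list(anchors = rbind(c(12.5, 42.8), c(52.5, 47.9)),
                  residual_sd = 1.67, dv = 6),
    `Bcd1.0` = list(anchors = rbind(c(2.5, 38.5), c(62.5, 41)),
                    residual_sd = 1.45, dv = 3)
  )
  trend_spec(spec$anchors, residual_sd %||% spec$residual_sd,
             dv_modulation = spec$dv, boundary_steepness = 0.5)
}

#' Mean boundary position at a time and orientation
#'
#' Monotone piecewise-cubic interpolation through the trend anchors, clamped
#' outside the anchor span, minus a smooth dorsoventral anterior offset
#' `dv_modulation * (1 - cos(theta)) / 2` that is zero on the dorsal midline
#' (0 degrees) and maximal on the ventral midline (180 degrees).
#'
#' @param t Time (min into nc14), vectorized.
#' @param orientation Orientation angle in degrees (0 = dorsal midline).
#' @param spec A [trend_spec()].
#' @return Boundary position(s) in percent EL.
#' @export
hb_trend <- function(t, orientation = 0, spec) {
  stopifnot(inherits(spec, "trend_spec"))
  a <- spec$anchors
  if (nrow(a) == 0L) stop_config("empty anchors")
  t <- pmin(pmax(t, a[1L, 1L]), a[nrow(a), 1L])
  base <- if (nrow(a) == 1L) {
    rep(a[1L, 2L], length(t))
  } else if (nrow(a) == 2L) {
    stats::approx(a[, 1L], a[, 2L], xout = t)$y
  } else {
    stats::splinefun(a[, 1L], a[, 2L], method = "monoH.FC")(t)
  }
  base - spec$dv_modulation * (1 - cos(orientation * pi / 180)) / 2
}

#' Generator configuration for embryo collections
#'
#' @param genotype Genotype label for the collection.
#' @param length_mean,length_sd Embryo length distribution (micrometres);
#'   draws are truncated at 3 SD. Default 500 um with 4 percent CV.
#' @param age_min,age_max Uniform developmental-age window (min into nc14).
#' @param staging_sd Staging error SD (min); truncated at 3 SD. Default 1 min.
#' @param orientation Fixed orientation (degrees) for all embryos, or `NULL`
#'   to draw uniformly on `[0, 360)`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(genotype = "stau", length_mean = 500,
                             length_sd = 20, age_min = 0, age_max = 65,
                             staging_sd = 1, orientation = 0) {
  check_scalar(length_mean, "length_mean", lower = 1e-6)
  check_scalar(length_sd, "length_sd", lower = 0)
  check_scalar(age_min, "age_min", lower = 0)
  check_scalar(age_max, "age_max", lower = age_min + 1e-9, upper = 65)
  check_scalar(staging_sd, "staging_sd", lower = 0)
  if (!is.null(orientation)) check_scalar(orientation, "orientation",
                                          lower = 0, upper = 360 - 1e-9)
  structure(list(genotype = genotype, length_mean = length_mean,
                 length_sd = length_sd, age_min = age_min, age_max = age_max,
                 staging_sd = staging_sd, orientation = orientation),
            class = "generator_config")
}

rnorm_trunc <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > k)) z[bad] <- stats::rnorm(sum(bad))
  mean + sd * z
}

#' Sample a collection of embryos
#'
#' Draws embryo lengths (truncated normal), true developmental ages
#' (uniform over the configured window), recorded ages (true age plus
#' truncated-normal staging error, clipped to the window) and orientations.
#'
#' @param config A [generator_config()].
#' @param n Number of embryos, `>= 1`.
#' @param seed Integer seed; identical `(config, n, seed)` give identical
#'   output.
#' @return A data.frame with one row per embryo: `embryo_id`, `genotype`,
#'   `length_um`, `true_age`, `recorded_age`, `orientation_deg`.
#' @export
sample_embryos <- function(config, n, seed) {
  stopifnot(inherits(config, "generator_config"))
  check_scalar(n, "n", lower = 1)
  with_seed(seed, {
    len <- rnorm_trunc(n, config$length_mean, config$length_sd)
    age <- stats::runif(n, config$age_min, config$age_max)
    rec <- age + rnorm_trunc(n, 0, config$staging_sd)
    rec <- pmin(pmax(rec, config$age_min), config$age_max)
    ori <- if (is.null(config$orientation)) {
      stats::runif(n, 0, 360)
    } else rep(config$orientation, n)
    data.frame(
      embryo_id = sprintf("%s_%03d", config$genotype, seq_len(n)),
      genotype = config$genotype,
      length_um = len,
      true_age = age,
      recorded_age = rec,
      orientation_deg = ori,
      stringsAsFactors = FALSE
    )
  })
}

#' Profile noise specification
#'
#' @param mult_cv Multiplicative intensity noise CV (default 5 percent).
#' @param add_sd Additive noise SD as a fraction of the profile amplitude
#'   (default 2 percent).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mult_cv = 0.05, add_sd = 0.02) {
  check_scalar(mult_cv, "mult_cv", lower = 0)
  check_scalar(add_sd, "add_sd", lower = 0)
  structure(list(mult_cv = mult_cv, add_sd = add_sd), class = "noise_spec")
}

logistic_profile <- function(x, midpoint_frac, width_frac) {
  1 / (1 + exp((x - midpoint_frac) / width_frac))
}

apply_profile_noise <- function(g, noise) {
  if (noise$mult_cv > 0) g <- g * (1 + stats::rnorm(length(g), 0, noise$mult_cv))
  if (noise$add_sd > 0) g <- g + stats::rnorm(length(g), 0, noise$add_sd)
  g
}

#' Generate a synthetic Hb expression profile
#'
#' A logistic anterior-high profile `1 / (1 + exp((x - xb)/w))` on a uniform
#' 101-point grid, whose midpoint `xb` follows the genotype trend at the
#' embryo's true age and orientation plus a per-embryo residual draw, with
#' multiplicative and additive intensity noise.
#'
#' @param embryo One row of [sample_embryos()] output (data.frame or list).
#' @param spec A [trend_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param n_points Grid size over `[0, 1]` EL (default 101).
#' @return An [expression_profile()] whose metadata records the realized
#'   true boundary `true_boundary_pct_el`.
#' @export
generate_hb_profile <- function(embryo, spec, noise = noise_spec(), seed,
                                n_points = 101L) {
  stopifnot(inherits(spec, "trend_spec"))
  with_seed(seed, {
    xb_pct <- hb_trend(embryo$true_age, embryo$orientation_deg, spec) +
      stats::rnorm(1, 0, spec$residual_sd)
    x <- seq(0, 1, length.out = n_points)
    g <- logistic_profile(x, xb_pct / 100, 1 / spec$boundary_steepness / 100)
    g <- apply_profile_noise(g, noise)
    expression_profile(x, g, meta = list(
      embryo_id = embryo$embryo_id, genotype = embryo$genotype,
      time_min = embryo$recorded_age, orientation_deg = embryo$orientation_deg,
      length_um = embryo$length_um, gene = "hb",
      true_boundary_pct_el = xb_pct, seed = seed))
  })
}

#' Nuclear gradient generator specification
#'
#' @param amplitude Gradient amplitude at the anterior pole (a.u.), `> 0`.
#' @param length_constant Exponential length constant (fraction EL) in (0, 1).
#' @param cv Relative intensity noise (SD/mean), `>= 0`. Default 0.18.
#' @param n_nuclei Nuclei per embryo, `>= 10`.
#' @param background Additive background (a.u.).
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(amplitude = 1000, length_constant = 0.186,
                          cv = 0.18, n_nuclei = 150L, background = 0) {
  check_scalar(amplitude, "amplitude", lower = 1e-12)
  check_scalar(length_constant, "length_constant", lower = 1e-9,
               upper = 1 - 1e-9)
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0) {
    stop_config("cv must be a non-negative scalar")
  }
  check_scalar(n_nuclei, "n_nuclei", lower = 10)
  check_scalar(background, "background", lower = 0)
  structure(list(amplitude = amplitude, length_constant = length_constant,
                 cv = cv, n_nuclei = as.integer(n_nuclei),
                 background = background),
            class = "gradient_spec")
}

#' Generate a synthetic nuclear Bcd gradient
#'
#' Places nuclei uniformly at random along the AP axis and assigns
#' `intensity = amplitude * exp(-x/lambda) * (1 + N(0, cv)) + background`,
#' the constant-CV noise model under which relative gradient noise is flat
#' in x.
#'
#' @param embryo One row of [sample_embryos()] output.
#' @param spec A [gradient_spec()].
#' @param seed Integer seed.
#' @return An object of class `nuclear_gradient`: data.frame `(x, intensity)`
#'   with attributes `time_min`, `genotype`, `embryo_id`, `session`.
#' @export
generate_bcd_nuclei <- function(embryo, spec, seed) {
  stopifnot(inherits(spec, "gradient_spec"))
  with_seed(seed, {
    x <- sort(stats::runif(spec$n_nuclei))
    mult <- 1 + stats::rnorm(spec$n_nuclei, 0, spec$cv)
    intensity <- spec$amplitude * exp(-x / spec$length_constant) * mult +
      spec$background
    structure(data.frame(x = x, intensity = intensity),
              time_min = embryo$recorded_age, genotype = embryo$genotype,
              embryo_id = embryo$embryo_id, session = "s1",
              class = c("nuclear_gradient", "data.frame"))
  })
}

#' Kr strip specification
#'
#' @param anterior,posterior Strip edge positions (fraction EL), anterior
#'   strictly less than posterior.
#' @param steepness Edge logistic steepness, 1/(percent EL).
#' @param amplitude Strip amplitude (a.u.).
#' @return An object of class `strip_spec`.
#' @export
strip_spec <- function(anterior = 0.40, posterior = 0.69, steepness = 0.5,
                       amplitude = 1) {
  check_scalar(anterior, "anterior", lower = 0, upper = 1)
  check_scalar(posterior, "posterior", lower = 0, upper = 1)
  if (anterior >= posterior) {
    stop_config("strip anterior edge must be anterior of the posterior edge")
  }
  check_scalar(steepness, "steepness", lower = 1e-8)
  check_scalar(amplitude, "amplitude", lower = 1e-12)
  structure(list(anterior = anterior, posterior = posterior,
                 steepness = steepness, amplitude = amplitude),
            class = "strip_spec")
}

#' Eve peak specification
#'
#' @param positions Peak centers (fraction EL), strictly increasing.
#' @param width Gaussian SD of each peak (fraction EL).
#' @param amplitude Peak amplitude (a.u.), recycled over peaks.
#' @return An object of class `peaks_spec`.
#' @export
peaks_spec <- function(positions = c(0.32, 0.47, 0.62, 0.77), width = 0.015,
                       amplitude = 1) {
  if (length(positions) < 1L || any(diff(positions) <= 0)) {
    stop_config("peak positions must be strictly increasing")
  }
  check_scalar(width, "width", lower = 1e-9)
  structure(list(positions = positions, width = width,
                 amplitude = rep_len(amplitude, length(positions))),
            class = "peaks_spec")
}

#' Generate synthetic Kr strip and Eve peak profiles
#'
#' The Kr strip is a difference of two logistics with the configured edges;
#' the Eve profile is a sum of Gaussian peaks. Either spec may be `NULL`.
#'
#' @param embryo One row of [sample_embryos()] output.
#' @param strip A [strip_spec()] or `NULL`.
#' @param peaks A [peaks_spec()] or `NULL`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param n_points Grid size (default 101).
#' @return A named list with elements `kr` and/or `eve`, each an
#'   [expression_profile()].
#' @export
generate_strip_and_peaks <- function(embryo, strip = strip_spec(),
                                     peaks = peaks_spec(),
                                     noise = noise_spec(), seed,
                                     n_points = 101L) {
  x <- seq(0, 1, length.out = n_points)
  out <- list()
  with_seed(seed, {
    if (!is.null(strip)) {
      stopifnot(inherits(strip, "strip_spec"))
      w <- 1 / strip$steepness / 100
      g <- strip$amplitude * (logistic_profile(x, strip$posterior, w) -
                                logistic_profile(x, strip$anterior, w))
      g <- apply_profile_noise(g, noise)
      out$kr <- expression_profile(x, g, meta = list(
        embryo_id = embryo$embryo_id, genotype = embryo$genotype,
        time_min = embryo$recorded_age,
        orientation_deg = embryo$orientation_deg,
        length_um = embryo$length_um, gene = "Kr"))
    }
    if (!is.null(peaks)) {
      stopifnot(inherits(peaks, "peaks_spec"))
      g <- rep(0, length(x))
      for (k in seq_along(peaks$positions)) {
        g <- g + peaks$amplitude[k] *
          exp(-(x - peaks$positions[k])^2 / (2 * peaks$width^2))
      }
      g <- apply_profile_noise(g, noise)
      out$eve <- expression_profile(x, g, meta = list(
        embryo_id = embryo$embryo_id, genotype = embryo$genotype,
        time_min = embryo$recorded_age,
        orientation_deg = embryo$orientation_deg,
        length_um = embryo$length_um, gene = "eve"))
    }
  })
  out
}

#' Generate the 36-orientation profile series of one embryo
#'
#' Profiles at 5 degree steps (0, 5, ..., 175) sharing the embryo's single
#' residual boundary draw, so the boundary varies across the series only
#' through the dorsoventral modulation.
#'
#' @param embryo One row of [sample_embryos()] output.
#' @param spec A [trend_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param n_points Grid size (default 101).
#' @return A list of 36 [expression_profile()] objects.
#' @export
generate_orientation_series <- function(embryo, spec, noise = noise_spec(),
                                        seed, n_points = 101L) {
  stopifnot(inherits(spec, "trend_spec"))
  angles <- seq(0, 175, by = 5)
  with_seed(seed, {
    resid <- stats::rnorm(1, 0, spec$residual_sd)
    x <- seq(0, 1, length.out = n_points)
    lapply(angles, function(th) {
      xb_pct <- hb_trend(embryo$true_age, th, spec) + resid
      g <- logistic_profile(x, xb_pct / 100,
                            1 / spec$boundary_steepness / 100)
      g <- apply_profile_noise(g, noise)
      expression_profile(x, g, meta = list(
        embryo_id = embryo$embryo_id, genotype = embryo$genotype,
        time_min = embryo$recorded_age, orientation_deg = th,
        length_um = embryo$length_um, gene = "hb",
        true_boundary_pct_el = xb_pct))
    })
  })
}
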