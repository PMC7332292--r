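# Synthesis-diffusion-degradation (SDD) model of the Bcd gradient with a
# spatially extended mRNA source and single-step immature -> mature
# fluorophore kinetics. Used to build maturation-correction curves that
# convert the observed (fluorescent) gradient into the total protein
# gradient.

#' SDD model parameters
#'
#' The steady-state length constant of a point-source SDD gradient is
#' `sqrt(D_B / omega_B)`; the defaults give 0.155 EL, the
#' maturation-corrected wild-type value. `k_mat = 0.02`/min corresponds to a
#' ~50 min fluorophore maturation time.
#'
#' @param s Synthesis rate (a.u./min), `>= 0`.
#' @param D_B Bcd diffusion constant (EL^2/min), `>= 0`.
#' @param omega_B Bcd degradation rate (1/min), `>= 0`.
#' @param k_mat Fluorophore maturation rate (1/min), `>= 0`; `Inf` means
#'   instantaneous maturation.
#' @param rho_length Length scale (fraction EL) of the truncated-exponential
#'   bcd mRNA density; 0.02 emulates tight anterior localization (WT), 0.1
#'   the spread source of stau mutants. Ignored when `rho` is supplied.
#' @param rho Optional mRNA density function of x; it is normalized to unit
#'   integral on the grid.
#' @return An object of class `sdd_params`.
#' @export
sdd_params <- function(s = 1, D_B = 9.6e-4, omega_B = 0.04, k_mat = 0.02,
                       rho_length = 0.02, rho = NULL) {
  check_scalar(s, "s", lower = 0)
  check_scalar(D_B, "D_B", lower = 0)
  check_scalar(omega_B, "omega_B", lower = 0)
  check_scalar(k_mat, "k_mat", lower = 0, allow_inf = TRUE)
  check_scalar(rho_length, "rho_length", lower = 1e-6)
  structure(list(s = s, D_B = D_B, omega_B = omega_B, k_mat = k_mat,
                 rho_length = rho_length, rho = rho),
            class = "sdd_params")
}

sdd_rho_grid <- function(params, x, dx) {
  rho <- if (is.null(params$rho)) {
    exp(-x / params$rho_length)
  } else {
    vapply(x, params$rho, numeric(1))
  }
  if (any(rho < 0)) stop_config("mRNA density must be non-negative")
  rho / grid_integral(rho, dx)
}

#' Simulate the SDD model with maturation kinetics
#'
#' Solves, with no-flux ends,
#' `dB_i/dt = s*rho(x) - (omega_B + k_mat) B_i + D_B B_i''` and
#' `dB_m/dt = k_mat B_i - omega_B B_m + D_B B_m''`
#' (immature and mature fluorophore pools) by Crank-Nicolson diffusion with
#' explicit reactions, from zero initial concentrations. With
#' `k_mat = Inf` all protein matures instantly and a single pool is evolved.
#'
#' @param params An [sdd_params()].
#' @param t_grid Output times (min), starting at 0, equally spaced.
#' @param nx Grid points (default 201).
#' @param dt Time step (min); must satisfy the explicit-reaction stability
#'   bound `dt * (omega_B + k_mat) < 1`, otherwise the solver refuses.
#' @return An object of class `sdd_state`: list with `x`, `t`, matrices
#'   `B_i`, `B_m`, `total` (rows = times) and `params`.
#' @export
simulate_sdd <- function(params, t_grid = seq(0, 300, by = 5), nx = 201L,
                         dt = 0.5) {
  stopifnot(inherits(params, "sdd_params"))
  if (t_grid[1L] != 0 || any(diff(t_grid) <= 0)) {
    stop_config("t_grid must start at 0 and increase")
  }
  instant <- !is.finite(params$k_mat)
  rate <- params$omega_B + if (instant) 0 else params$k_mat
  if (dt * rate >= 1) {
    stop_config(sprintf(
      "unstable explicit reaction step: dt * (omega_B + k_mat) = %.3g >= 1; reduce dt",
      dt * rate))
  }
  x <- seq(0, 1, length.out = nx)
  dx <- x[2L] - x[1L]
  M <- cn_propagator(nx, dx, params$D_B, dt)
  rho <- sdd_rho_grid(params, x, dx)
  src <- params$s * rho
  bi <- numeric(nx)
  bm <- numeric(nx)
  n_out <- length(t_grid)
  Bi <- matrix(0, n_out, nx)
  Bm <- matrix(0, n_out, nx)
  t_now <- 0
  out_idx <- 2L
  n_steps <- ceiling(t_grid[n_out] / dt)
  for (k in seq_len(n_steps)) {
    if (instant) {
      bm <- as.vector(M %*% (bm + dt * (src - params$omega_B * bm)))
    } else {
      bi_new <- bi + dt * (src - (params$omega_B + params$k_mat) * bi)
      bm_new <- bm + dt * (params$k_mat * bi - params$omega_B * bm)
      bi <- as.vector(M %*% bi_new)
      bm <- as.vector(M %*% bm_new)
    }
    t_now <- t_now + dt
    while (out_idx <= n_out && t_grid[out_idx] <= t_now + dt / 2) {
      Bi[out_idx, ] <- bi
      Bm[out_idx, ] <- bm
      out_idx <- out_idx + 1L
    }
  }
  structure(list(x = x, t = t_grid, B_i = Bi, B_m = Bm, total = Bi + Bm,
                 params = params),
            class = "sdd_state")
}

sdd_time_index <- function(state, t) {
  i <- which.min(abs(state$t - t))
  if (abs(state$t[i] - t) > 1e-6 * max(1, abs(t))) {
    warning(sprintf("using nearest stored time %.3g for requested %.3g",
                    state$t[i], t))
  }
  i
}

#' Maturation correction curve
#'
#' Pointwise ratio of total to mature (observed) concentration at a given
#' time. The ratio is `>= 1` everywhere and largest near the source, where
#' protein is youngest; multiplying an observed gradient by the curve
#' therefore steepens it, so the corrected length constant is smaller than
#' the observed one. Points where the mature pool is below `floor` times its
#' maximum are returned as `NA`.
#'
#' @param state An [simulate_sdd()] result.
#' @param t Evaluation time (min); the nearest stored time is used.
#' @param floor Relative guard threshold for the division (default 1e-8).
#' @return Data.frame `(x, ratio)`.
#' @export
maturation_correction_curve <- function(state, t = max(state$t),
                                        floor = 1e-8) {
  stopifnot(inherits(state, "sdd_state"))
  i <- sdd_time_index(state, t)
  bm <- state$B_m[i, ]
  tot <- state$total[i, ]
  ratio <- ifelse(bm > floor * max(bm), tot / bm, NA_real_)
  data.frame(x = state$x, ratio = ratio)
}

#' Apply a maturation correction to an observed gradient
#'
#' Multiplies an observed binned gradient pointwise by the interpolated
#' correction curve and refits the exponential over the standard 0.1-0.8 EL
#' range.
#'
#' @param observed A [bin_nuclei()] noise profile of the observed gradient.
#' @param curve A [maturation_correction_curve()] data.frame.
#' @param range Refit range (fraction EL).
#' @return List with `corrected` (the noise profile with corrected means)
#'   and `fit` (a [fit_exponential()] on the corrected means).
#' @export
apply_correction <- function(observed, curve, range = c(0.1, 0.8)) {
  stopifnot(inherits(observed, "noise_profile"))
  ok <- is.finite(curve$ratio)
  if (min(observed$center) < min(curve$x[ok]) ||
        max(observed$center) > max(curve$x[ok])) {
    stop_config("correction curve does not cover the observed range")
  }
  r <- stats::approx(curve$x[ok], curve$ratio[ok],
                     xout = observed$center)$y
  corrected <- observed
  corrected$mean <- observed$mean * r
  corrected$sd <- observed$sd * r
  list(corrected = corrected, fit = fit_exponential(corrected, range))
}
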