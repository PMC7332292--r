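test_that("the gene regulatory function has Hill limits and monotonicity", {
  p <- model_params()
  expect_equal(grf(0, 0, p), 0)
  expect_equal(grf(p$b_0, 0, p), p$alpha_b / 2, tolerance = 1e-12)
  expect_equal(grf(1e9, 0, p), p$alpha_b, tolerance = 1e-6)
  expect_equal(grf(0, 1e9, p), p$alpha_h, tolerance = 1e-6)
  b <- seq(0, 0.3, length.out = 50)
  expect_true(all(diff(grf(b, 0.2, p)) >= 0))
  h <- seq(0, 2, length.out = 50)
  expect_true(all(diff(grf(0.05, h, p)) >= 0))
  expect_true(all(grf(b, 1, p) <= max(p$alpha_b, p$alpha_h)))
  expect_error(grf(-1, 0, p), "concentrations")
})

test_that("the Bcd input decays exponentially in space and time", {
  p <- model_params()
  expect_equal(bcd_input(p$lambda, 0, p), p$b_m / exp(1), tolerance = 1e-12)
  expect_equal(bcd_input(0.3, p$t_0 + 1 / p$omega_0, p),
               bcd_input(0.3, p$t_0, p) / exp(1), tolerance = 1e-12)
  # continuity at t_0 and static gradient for omega_0 -> 0
  expect_equal(bcd_input(0.3, p$t_0 - 1e-9, p), bcd_input(0.3, p$t_0, p),
               tolerance = 1e-6)
  p0 <- do.call(model_params, modifyList(unclass(p), list(omega_0 = 0)))
  expect_equal(bcd_input(0.3, 60, p0), bcd_input(0.3, 0, p0))
})

test_that("the maternal Hb profile is an anterior-high sigmoid", {
  p <- model_params()
  expect_equal(maternal_hb_init(p$x_0, p), p$h_m / 2, tolerance = 1e-12)
  expect_true(all(diff(maternal_hb_init(seq(0, 1, 0.01), p)) <= 0))
  pinf <- do.call(model_params, modifyList(unclass(p), list(x_0 = Inf)))
  expect_equal(maternal_hb_init(c(0, 0.5, 1), pinf), rep(p$h_m, 3))
  psteep <- do.call(model_params, modifyList(unclass(p), list(k_x = 1e6)))
  expect_equal(maternal_hb_init(c(p$x_0 - 0.01, p$x_0 + 0.01), psteep),
               c(p$h_m, 0), tolerance = 1e-9)
})

test_that("genotype transforms change only the Bcd input and maternal Hb", {
  base <- model_params()
  stau <- apply_genotype(base, genotype_transform("stau"))
  expect_equal(stau$b_m, 0.35 * base$b_m)
  expect_equal(stau$lambda, 1.17 * base$lambda)
  expect_identical(stau$x_0, Inf)
  shared <- setdiff(names(unclass(base)), c("b_m", "lambda", "x_0"))
  expect_identical(unclass(stau)[shared], unclass(base)[shared])
  b1 <- apply_genotype(base, genotype_transform("Bcd1.0"))
  expect_equal(b1$b_m, 0.5 * base$b_m)
  expect_identical(unclass(b1)[c("lambda", "x_0")],
                   unclass(base)[c("lambda", "x_0")])
  expect_identical(unclass(apply_genotype(base, genotype_transform("identity"))),
                   unclass(base))
})

test_that("simulate_hb has exact limits and refuses unstable settings", {
  p <- model_params()
  expect_error(simulate_hb(p, nx = 51), "101")
  expect_error(simulate_hb(p, dt = 10), "unstable")
  # zero synthesis, zero diffusion: exact exponential decay
  p0 <- do.call(model_params, modifyList(unclass(p),
                                         list(alpha_b = 1e-12,
                                              alpha_h = 1e-12, D = 1e-15)))
  s0 <- simulate_hb(p0, nx = 101, dt = 0.05, t_end = 30,
                    output_times = c(0, 30))
  expect_equal(s0$h[2, ], maternal_hb_init(s0$x, p0) * exp(-p0$beta * 30),
               tolerance = 0.01)
  # spatially uniform inputs stay uniform
  pu <- do.call(model_params, modifyList(unclass(p),
                                         list(lambda = 0.999, x_0 = Inf)))
  su <- simulate_hb(pu, nx = 101, dt = 0.05, t_end = 10,
                    output_times = c(0, 10))
  expect_lt(diff(range(su$h[2, ])) / mean(su$h[2, ]), 1e-3)
  expect_true(all(simulate_hb(p, nx = 101, dt = 0.1)$h >= 0))
})

test_that("simulate_hb with D = 0 matches an independent ODE oracle", {
  p <- do.call(model_params, modifyList(unclass(model_params()),
                                        list(D = 1e-15)))
  s <- simulate_hb(p, nx = 101, dt = 0.01, t_end = 30,
                   output_times = c(0, 30))
  xi <- 45
  # 4th-order Runge-Kutta on the scalar reaction ODE at fixed x
  h <- maternal_hb_init(s$x[xi], p)
  f <- function(t, h) grf(bcd_input(s$x[xi], t, p), h, p) - p$beta * h
  dt <- 0.005
  t <- 0
  while (t < 30 - 1e-9) {
    k1 <- f(t, h); k2 <- f(t + dt / 2, h + dt / 2 * k1)
    k3 <- f(t + dt / 2, h + dt / 2 * k2); k4 <- f(t + dt, h + dt * k3)
    h <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  expect_lt(abs(s$h[2, xi] - h) / h, 1e-3)
})

test_that("boundary extraction reads half-plateau crossings", {
  x <- seq(0, 1, length.out = 201)
  h <- matrix(rep(1 / (1 + exp((x - 0.45) / 0.02)), 3), nrow = 3,
              byrow = TRUE)
  sim <- structure(list(x = x, t = c(0, 10, 20), h = h,
                        params = model_params()),
                   class = "hb_simulation")
  traj <- extract_xhb(sim)
  expect_equal(traj$position_pct_el, rep(45, 3), tolerance = 0.01)
  # no crossing -> NA
  sim$h[2, ] <- 1
  expect_true(is.na(extract_xhb(sim)$position_pct_el[2]))
})

test_that("x_Hb responds monotonically to the Bcd amplitude", {
  finals <- vapply(c(0.8, 1, 1.25), function(m) {
    p <- apply_genotype(model_params(), genotype_transform("dose",
                                                           bm_mult = m))
    traj <- extract_xhb(simulate_hb(p, nx = 101, dt = 0.2),
                        times = c(40, 65))
    mean(traj$position_pct_el)
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("the fit loss reduces to plain least squares with zero weights", {
  wt <- anchor_trajectory("WT")
  stau <- anchor_trajectory("stau")
  cfg <- fit_config(weights = list(early_wt = 0, final_diff = 0,
                                   final_rate = 0),
                    n_starts = 1L, maxit = 2L)
  fit <- fit_free_params(wt, stau, cfg)
  terms <- fit$loss_terms
  expect_equal(fit$loss, terms$sse, tolerance = 1e-9)
  expect_identical(fit$weights,
                   list(early_wt = 0, final_diff = 0, final_rate = 0))
  expect_error(fit_config(free = c("alpha_b", "nonsense")), "unknown")
})

test_that("anchor trajectories reproduce the printed end points", {
  wt <- anchor_trajectory("WT")
  stau <- anchor_trajectory("stau")
  expect_equal(stau$position_pct_el[1], 37.6)
  expect_equal(stau$position_pct_el[13], 47.9)
  expect_equal(wt$position_pct_el[13], 47.8)
  expect_equal(wt$position_pct_el[1], 44.8)
  # the stau trajectory completes ~7 %EL within the first 30 min
  expect_equal(hb_trend(30, 0, default_trend("stau")) - 37.6, 7,
               tolerance = 0.1)
})
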