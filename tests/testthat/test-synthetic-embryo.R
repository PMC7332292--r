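test_that("sample_embryos validates input, is reproducible and calibrated", {
  cfg <- generator_config("stau")
  expect_error(sample_embryos(cfg, 0, seed = 1), "n")
  e1 <- sample_embryos(cfg, 20, seed = 1)
  e2 <- sample_embryos(cfg, 20, seed = 1)
  expect_identical(e1, e2)
  expect_false(identical(e1, sample_embryos(cfg, 20, seed = 2)))

  big <- sample_embryos(cfg, 1000, seed = 3)
  se <- 20 / sqrt(1000)
  expect_lt(abs(mean(big$length_um) - 500), 3 * se)
  expect_true(all(abs(big$recorded_age - big$true_age) <= 3 * 1 + 1e-9))
  expect_true(all(big$true_age >= 0 & big$true_age <= 65))
})

test_that("hb_trend reproduces anchors, clamps, and modulates smoothly", {
  stau <- default_trend("stau")
  expect_equal(hb_trend(2.5, 0, stau), 37.6)
  expect_equal(hb_trend(62.5, 0, stau), 47.9)
  # clamped outside the anchor span
  expect_equal(hb_trend(0, 0, stau), 37.6)
  expect_equal(hb_trend(65, 0, stau), 47.9)
  # monotone interpolation between monotone anchors
  tgrid <- seq(2.5, 62.5, by = 0.5)
  expect_true(all(diff(hb_trend(tgrid, 0, stau)) >= -1e-9))
  # dorsal-ventral difference equals the modulation amplitude
  expect_equal(hb_trend(30, 0, stau) - hb_trend(30, 180, stau),
               stau$dv_modulation)
  # left-right symmetry of the modulation
  expect_equal(hb_trend(30, 90, stau), hb_trend(30, 270, stau))
  expect_error(trend_spec(matrix(numeric(0), 0, 2)), "anchors")
})

test_that("generate_hb_profile round-trips through boundary detection", {
  emb <- fixture_embryo("stau", age = 2.5)
  spec <- default_trend("stau", residual_sd = 0)
  p <- generate_hb_profile(emb, spec, noise_spec(0, 0), seed = 1)
  expect_equal(detect_boundary(p)$position_pct_el, 37.6, tolerance = 0.01)

  # steepness pass-through: doubling steepness halves the 25-75% rise span
  span <- function(steep) {
    sp <- trend_spec(rbind(c(2.5, 45)), boundary_steepness = steep)
    pr <- generate_hb_profile(emb, sp, noise_spec(0, 0), seed = 1,
                              n_points = 1001L)
    x75 <- approx(pr$intensity, pr$x, 0.75)$y
    x25 <- approx(pr$intensity, pr$x, 0.25)$y
    x25 - x75
  }
  expect_equal(span(1) / span(0.5), 0.5, tolerance = 1e-3)
})

test_that("generator residual noise is calibrated", {
  spec <- default_trend("stau")  # residual_sd 1.67
  cfg <- generator_config("stau")
  emb <- sample_embryos(cfg, 69, seed = 11)
  resid <- vapply(seq_len(69), function(i) {
    p <- generate_hb_profile(emb[i, ], spec, noise_spec(), derive_seed(11, i))
    p$meta$true_boundary_pct_el - hb_trend(emb$true_age[i], 0, spec)
  }, numeric(1))
  se_sd <- 1.67 / sqrt(2 * 68)
  expect_lt(abs(sd(resid) - 1.67), 3 * se_sd)
})

test_that("generate_bcd_nuclei follows the constant-CV exponential model", {
  emb <- fixture_embryo("WT", age = 16)
  # noiseless: exactly log-linear with slope -1/lambda
  gs0 <- gradient_spec(amplitude = 100, length_constant = 0.2, cv = 0,
                       n_nuclei = 200, background = 0)
  g0 <- generate_bcd_nuclei(emb, gs0, seed = 1)
  fit <- lm(log(g0$intensity) ~ g0$x)
  expect_equal(unname(coef(fit)[2]), -5, tolerance = 1e-9)
  expect_equal(unname(exp(coef(fit)[1])), 100, tolerance = 1e-9)

  # calibration: binned CV matches the configured cv in every retained bin
  gs <- gradient_spec(cv = 0.18, n_nuclei = 5000)
  np <- bin_nuclei(generate_bcd_nuclei(emb, gs, seed = 2))
  sel <- np$center <= 0.8
  se_bin <- 0.18 / sqrt(2 * (np$n[sel] - 1))
  expect_true(all(abs(np$cv[sel] - 0.18) < 5 * se_bin + 0.01))

  # halving the amplitude halves binned means pointwise (same seed)
  gs_half <- gradient_spec(amplitude = gs$amplitude / 2, cv = 0.18,
                           n_nuclei = 5000)
  np_half <- bin_nuclei(generate_bcd_nuclei(emb, gs_half, seed = 2))
  expect_equal(np_half$mean, np$mean / 2, tolerance = 1e-12)
  expect_error(gradient_spec(cv = -0.1), "cv")
})

test_that("strips and peaks are generated at configured positions", {
  emb <- fixture_embryo("stau")
  expect_error(strip_spec(0.6, 0.4), "anterior")
  sp <- generate_strip_and_peaks(emb, strip_spec(0.40, 0.69),
                                 peaks_spec(0.30, width = 0.015),
                                 noise_spec(0, 0), seed = 1)
  expect_equal(strip_width(sp$kr), 29, tolerance = 0.05)
  pk <- detect_peaks(sp$eve)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position_pct_el, 30, tolerance = 0.1)
  # four configured peaks -> four detected peaks
  sp4 <- generate_strip_and_peaks(emb, NULL, peaks_spec(), noise_spec(0, 0),
                                  seed = 1)
  expect_equal(nrow(detect_peaks(sp4$eve)), 4L)
})

test_that("orientation series shares the residual draw and shows the DV shift", {
  emb <- fixture_embryo("stau", age = 30)
  flat <- trend_spec(rbind(c(2.5, 40), c(62.5, 45)), residual_sd = 1,
                     dv_modulation = 0)
  s0 <- generate_orientation_series(emb, flat, noise_spec(0, 0), seed = 4)
  b0 <- vapply(s0, function(p) detect_boundary(p)$position_pct_el, numeric(1))
  expect_equal(max(b0) - min(b0), 0, tolerance = 1e-6)

  series <- generate_orientation_series(emb, default_trend("stau"),
                                        noise_spec(), seed = 4)
  expect_length(series, 36L)
  b <- vapply(series, function(p) detect_boundary(p)$position_pct_el,
              numeric(1))
  # dorsal (0 deg) minus near-ventral (175 deg) difference ~ 6 %EL
  expect_equal(b[1] - b[36], 6, tolerance = 0.75)
  wt <- generate_orientation_series(emb, default_trend("WT"), noise_spec(),
                                    seed = 4)
  bw <- vapply(wt, function(p) detect_boundary(p)$position_pct_el, numeric(1))
  expect_equal(bw[1] - bw[36], 3, tolerance = 0.75)
  # determinism
  series2 <- generate_orientation_series(emb, default_trend("stau"),
                                         noise_spec(), seed = 4)
  expect_identical(series, series2)
})
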