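test_that("normalize_profile rescales robustly and idempotently", {
  p <- expression_profile(c(0, 0.5, 1), c(2, 4, 6))
  n1 <- normalize_profile(p)
  expect_equal(n1$intensity, c(0, 0.5, 1), tolerance = 1e-9)
  expect_equal(normalize_profile(n1)$intensity, n1$intensity,
               tolerance = 1e-9)
  logi <- normalize_profile(fixture_logistic(0.5))
  expect_equal(max(logi$intensity), 1, tolerance = 0.02)
  expect_equal(min(logi$intensity), 0, tolerance = 0.02)
  expect_error(normalize_profile(expression_profile(1:5, rep(2, 5))),
               "degenerate")
})

test_that("detect_boundary finds logistic midpoints, invariant to affine maps", {
  p <- fixture_logistic(0.45)
  expect_equal(detect_boundary(p)$position_pct_el, 45, tolerance = 0.01)
  p2 <- p
  p2$intensity <- 3 + 40 * p$intensity
  expect_equal(detect_boundary(p2)$position_pct_el,
               detect_boundary(p)$position_pct_el, tolerance = 1e-6)
  flat <- expression_profile(seq(0, 1, length.out = 50),
                             seq(0, 1, length.out = 50))
  expect_error(detect_boundary(flat), "boundary")
})

test_that("detect_boundary is unbiased on noisy generator profiles", {
  emb <- fixture_embryo("stau", age = 30)
  spec <- default_trend("stau", residual_sd = 0)
  errs <- vapply(1:200, function(i) {
    p <- generate_hb_profile(emb, spec, noise_spec(0.05, 0.02),
                             seed = derive_seed(21, i))
    detect_boundary(p)$position_pct_el - p$meta$true_boundary_pct_el
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.2)
})

test_that("inflection fronts and strip widths match configured edges", {
  emb <- fixture_embryo("stau")
  sp <- generate_strip_and_peaks(emb, strip_spec(0.40, 0.69), NULL,
                                 noise_spec(0, 0), seed = 1)$kr
  a <- detect_inflection_front(sp, "anterior")
  p <- detect_inflection_front(sp, "posterior")
  expect_equal(a$position_pct_el, 40, tolerance = 0.05)
  expect_equal(p$position_pct_el, 69, tolerance = 0.05)
  expect_equal(strip_width(sp), 29, tolerance = 0.1)
  # symmetric strip: fronts equidistant from center
  sym <- generate_strip_and_peaks(emb, strip_spec(0.35, 0.65), NULL,
                                  noise_spec(0, 0), seed = 1)$kr
  aa <- detect_inflection_front(sym, "anterior")$position_pct_el
  pp <- detect_inflection_front(sym, "posterior")$position_pct_el
  expect_equal(50 - aa, pp - 50, tolerance = 0.05)
  # WT-like narrow strip
  wt <- generate_strip_and_peaks(emb, strip_spec(0.40, 0.57), NULL,
                                 noise_spec(0, 0), seed = 1)$kr
  expect_equal(strip_width(wt), 17, tolerance = 0.1)
  # monotone profile has no strip
  expect_error(detect_inflection_front(fixture_logistic(0.5), "anterior"),
               "strip")
})

test_that("noisy front detection has small bias", {
  emb <- fixture_embryo("stau")
  errs <- vapply(1:200, function(i) {
    sp <- generate_strip_and_peaks(emb, strip_spec(0.40, 0.69), NULL,
                                   noise_spec(0.05, 0.02),
                                   seed = derive_seed(33, i))$kr
    detect_inflection_front(sp, "anterior")$position_pct_el
  }, numeric(1))
  expect_lt(abs(mean(errs) - 40), 0.3)
})

test_that("detect_peaks orders by position and respects prominence", {
  x <- seq(0, 1, length.out = 201)
  two <- expression_profile(x, exp(-(x - 0.3)^2 / 5e-4) +
                              exp(-(x - 0.5)^2 / 5e-4))
  pk <- detect_peaks(two)
  expect_equal(pk$position_pct_el, c(30, 50), tolerance = 0.2)
  flat <- expression_profile(x, rep(1, length(x)))
  expect_equal(nrow(detect_peaks(flat)), 0L)
  # max_peaks keeps the most prominent ones
  four <- expression_profile(x, exp(-(x - 0.2)^2 / 5e-4) +
                               0.8 * exp(-(x - 0.4)^2 / 5e-4) +
                               0.6 * exp(-(x - 0.6)^2 / 5e-4) +
                               0.4 * exp(-(x - 0.8)^2 / 5e-4))
  expect_equal(detect_peaks(four, max_peaks = 2)$position_pct_el, c(20, 40),
               tolerance = 0.2)
})

test_that("heat maps canonicalize order and expose the DV ridge shift", {
  emb <- fixture_embryo("stau", age = 30)
  series <- generate_orientation_series(emb, default_trend("stau"),
                                        noise_spec(), seed = 6)
  expect_error(build_heatmap(series[1:35]), "36")
  hm <- build_heatmap(series)
  expect_equal(dim(hm$values), c(36L, 101L))
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  # row permutation of the input yields the identical heat map
  hm2 <- build_heatmap(series[sample(36)])
  expect_equal(hm2$values, hm$values)
  # stau ridge shifts ~6 %EL dorsal -> ventral
  b <- vapply(seq_len(36), function(i) {
    detect_boundary(expression_profile(hm$x, hm$values[i, ],
                                       meta = hm$meta))$position_pct_el
  }, numeric(1))
  expect_equal(b[1] - b[36], 6, tolerance = 0.75)
  # zero modulation: all rows identical
  flat <- trend_spec(rbind(c(2.5, 42), c(62.5, 44)), dv_modulation = 0)
  s0 <- generate_orientation_series(emb, flat, noise_spec(0, 0), seed = 6)
  hm0 <- build_heatmap(s0)
  expect_equal(max(apply(hm0$values, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-9)
})

test_that("orientation sensitivity is zero at delta 0 and non-decreasing", {
  emb <- fixture_embryo("stau", age = 30)
  hm <- build_heatmap(generate_orientation_series(emb, default_trend("stau"),
                                                  noise_spec(0, 0), seed = 8))
  expect_equal(orientation_sensitivity(hm, 0, 0), 0)
  vals <- vapply(c(5, 10, 20, 45), function(d) {
    orientation_sensitivity(hm, 0, d)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  expect_gt(vals[2], 0)
  expect_lte(vals[2], 0.5)
  # zero modulation: zero sensitivity at any delta
  flat <- trend_spec(rbind(c(2.5, 42), c(62.5, 44)), dv_modulation = 0)
  hm0 <- build_heatmap(generate_orientation_series(emb, flat,
                                                   noise_spec(0, 0), seed = 8))
  expect_equal(orientation_sensitivity(hm0, 0, 45), 0, tolerance = 1e-6)
})
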