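test_that("smoothing is the identity at window 1 and exact on low-order polynomials", {
  p <- gauss_profile()
  expect_identical(smooth_profile(p, no_smooth), p)
  x <- seq(-5, 5, by = 0.1)
  cub <- intensity_profile(x, 2 + 3 * x - 0.5 * x^2 + 0.1 * x^3)
  sm <- smooth_profile(cub, gcxi_config(smoothing_window = 9,
                                        smoothing_polyorder = 3))
  interior <- 5:(length(x) - 4)
  expect_equal(sm$intensities[interior], cub$intensities[interior],
               tolerance = 1e-8)
  const <- intensity_profile(x, rep(4, length(x)))
  expect_equal(smooth_profile(const, gcxi_config())$intensities,
               const$intensities, tolerance = 1e-10)
  expect_error(smooth_profile(intensity_profile(1:5, 1:5),
                              gcxi_config(smoothing_window = 7)),
               class = "gcxi_bad_config")
})

test_that("Gaussian ridge analysis matches the closed-form width, baseline and level", {
  pa <- analyze_profile(gauss_profile(sigma = 10, amplitude = 100), no_smooth)
  expect_equal(pa$a_value, 100, tolerance = 1e-6)
  expect_equal(pa$infl_left[["position"]], -10, tolerance = 0.02)
  expect_equal(pa$infl_right[["position"]], 10, tolerance = 0.02)
  expect_equal(pa$c_value, 100 * exp(-0.5), tolerance = 1e-3)
  expect_equal(pa$b_level, 100 * (0.6 + 0.4 * exp(-0.5)), tolerance = 1e-3)
  expect_equal(pa$d_px, gauss_width(10), tolerance = 0.005)
})

test_that("raised-cosine ridge analysis matches its closed form", {
  pa <- analyze_profile(raised_cos_profile(w = 20, amplitude = 100), no_smooth)
  expect_equal(pa$infl_left[["position"]], -10, tolerance = 0.02)
  expect_equal(pa$infl_right[["position"]], 10, tolerance = 0.02)
  expect_equal(pa$c_value, 50, tolerance = 1e-3)
  expect_equal(pa$b_level, 80, tolerance = 1e-3)
  expect_equal(pa$d_px, rcos_width(20), tolerance = 0.005)
})

test_that("width is invariant to affine intensity maps and equivariant to spatial scaling", {
  set.seed(7)
  for (i in 1:40) {
    sigma <- runif(1, 5, 12)
    amp <- runif(1, 50, 300)
    base <- runif(1, 0, 60)
    p <- gauss_profile(sigma = sigma, amplitude = amp, baseline = base)
    d0 <- analyze_profile(p, no_smooth)$d_px
    alpha <- runif(1, 0.2, 5); beta <- runif(1, -20, 80)
    paff <- intensity_profile(p$positions, alpha * p$intensities + beta)
    expect_equal(analyze_profile(paff, no_smooth)$d_px, d0,
                 tolerance = 1e-10)
    s <- runif(1, 0.5, 2)
    psc <- intensity_profile(p$positions * s, p$intensities)
    expect_equal(analyze_profile(psc, no_smooth)$d_px, s * d0,
                 tolerance = 1e-8)
    prev <- intensity_profile(-rev(p$positions), rev(p$intensities))
    expect_equal(analyze_profile(prev, no_smooth)$d_px, d0,
                 tolerance = 1e-10)
  }
})

test_that("width converges to the analytic value as the sampling step shrinks", {
  errs <- vapply(c(0.5, 0.2, 0.1), function(step) {
    pa <- analyze_profile(gauss_profile(sigma = 10, step = step), no_smooth)
    abs(pa$d_px - gauss_width(10)) / gauss_width(10)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], 0.005)
})

test_that("degenerate profiles raise distinct classed errors", {
  x <- seq(-10, 10, by = 0.5)
  expect_error(analyze_profile(intensity_profile(x, rep(3, length(x))),
                               no_smooth),
               class = "gcxi_no_peak")
  expect_error(analyze_profile(intensity_profile(x, x), no_smooth),
               class = "gcxi_no_peak")
  # peak prominence gate
  p <- gauss_profile(sigma = 10, amplitude = 1)
  expect_error(analyze_profile(p, gcxi_config(smoothing_window = 1,
                                              min_peak_prominence = 5)),
               class = "gcxi_no_peak")
  # peak hard against the profile edge leaves no room for a flank
  edge <- intensity_profile(x, exp(-(x - 9)^2 / 2))
  expect_error(analyze_profile(edge, no_smooth),
               class = "gcxi_no_inflection")
})

test_that("per-artery index is the mean of three line widths", {
  mk <- function(d) {
    p <- gauss_profile(sigma = d / gauss_width(1))
    analyze_profile(p, no_smooth)
  }
  a <- artery_gcxi(list(mk(3), mk(4), mk(5)), diameter_class = 40)
  expect_equal(a$gcxi_um, mean(a$line_widths_um))
  expect_equal(a$gcxi_um, 4, tolerance = 0.01)
  same <- artery_gcxi(list(mk(4), mk(4), mk(4)))
  expect_equal(same$gcxi_um, 4, tolerance = 0.01)
  expect_error(artery_gcxi(list(mk(3), mk(4))),
               class = "gcxi_unusable_artery")
  two <- artery_gcxi(list(mk(3), mk(5)), require_three = FALSE)
  expect_equal(two$gcxi_um, 4, tolerance = 0.01)
})

test_that("measure_artery drops failed lines with reasons instead of stopping", {
  r <- render_frame(wall_scene(wall_sigma_um = 4), NULL, NULL, t = 0)
  tr <- wall_trace(r$truth$wall_trace, r$truth$interstitial_side, "a", 40)
  res <- measure_artery(r$frame, tr, "FITC-WGA")
  expect_s3_class(res$artery, "artery_gcxi")
  expect_equal(nrow(res$dropped), 0)
  # a flat channel fails every line but returns a log, not an error
  flat <- image_frame(list("FITC-WGA" = matrix(1, 512, 512)),
                      pixel_scale = 0.25)
  res2 <- measure_artery(flat, tr, "FITC-WGA")
  expect_null(res2$artery)
  expect_equal(nrow(res2$dropped), 3)
  expect_true(all(res2$dropped$reason == "gcxi_no_peak"))
})
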