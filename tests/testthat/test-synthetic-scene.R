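test_that("leakage kinetics follow the saturating exponential", {
  lk <- two_tracer_leakage(I0 = 0, Imax = 100, k = 0.02)
  expect_equal(interstitial_intensity(lk, "TMR-DEX40", 15),
               100 * (1 - exp(-0.3)), tolerance = 1e-12)
  expect_equal(interstitial_intensity(lk, "TMR-DEX40", 0), 0)
  # non-decreasing in t for a grid of rates, equal to I0 at t = 0
  for (k in c(0, 0.005, 0.02, 0.1)) {
    lk <- two_tracer_leakage(I0 = 3, Imax = 50, k = k)
    v <- interstitial_intensity(lk, "FITC-HES130", seq(0, 120, by = 5))
    expect_true(all(diff(v) >= 0))
    expect_equal(v[1], 3)
  }
  expect_error(leakage_model(data.frame(channel = "x", I0 = -1, Imax = 1,
                                        k = 0.1)),
               class = "gcxi_bad_leakage")
})

test_that("rendered tracer channel carries the leakage value in the interstitium", {
  sc <- vessel_scene(height_px = 64, width_px = 64, pixel_scale = 2,
                     inner_diameter_um = 40, wall_sigma_um = 4)
  r <- render_frame(sc, two_tracer_leakage(), NULL, t = 15)
  # far interstitial pixel: distance from axis well beyond wall
  expect_equal(r$frame$channels[["TMR-DEX40"]][2, 32],
               100 * (1 - exp(-0.3)), tolerance = 1e-12)
  expect_equal(r$truth$interstitial_truth$intensity[1:4],
               100 * (1 - exp(-c(0.3, 0.6, 1.2, 1.8))), tolerance = 1e-12)
})

test_that("noise model: disabled noise is seed-independent, seeds reproduce bit-identically", {
  sc <- wall_scene(size_px = 64, pixel_scale = 2)
  r1 <- render_frame(sc, NULL, noise_model(0, 0, seed = 1), t = 0)
  r2 <- render_frame(sc, NULL, noise_model(0, 0, seed = 2), t = 0)
  expect_identical(r1$frame$channels, r2$frame$channels)
  n1 <- render_frame(sc, NULL, noise_model(5, 0.5, seed = 7), t = 0)
  n2 <- render_frame(sc, NULL, noise_model(5, 0.5, seed = 7), t = 0)
  n3 <- render_frame(sc, NULL, noise_model(5, 0.5, seed = 8), t = 0)
  expect_identical(n1$frame$channels, n2$frame$channels)
  expect_false(identical(n1$frame$channels, n3$frame$channels))
})

test_that("Poisson noise is unbiased: replicate mean near the noiseless value", {
  sc <- wall_scene(size_px = 32, pixel_scale = 4, wall_sigma_um = 4)
  clean <- render_frame(sc, NULL, NULL, t = 0)$frame$channels[[1]][16, 16]
  gain <- 0.5
  reps <- vapply(1:1000, function(s) {
    render_frame(sc, NULL, noise_model(0, gain, seed = s),
                 t = 0)$frame$channels[[1]][16, 16]
  }, 0)
  se <- sqrt(clean / gain) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - clean), 3 * se)
})

test_that("noiseless wall profile is symmetric about the crest and peaks on the trace", {
  r <- render_frame(wall_scene(wall_sigma_um = 4), NULL, NULL, t = 0)
  tr <- wall_trace(r$truth$wall_trace, r$truth$interstitial_side, "a", 40)
  for (ln in place_perpendicular_lines(tr)) {
    p <- sample_profile(r$frame, "FITC-WGA", ln)
    i_max <- which.max(p$intensities)
    step <- p$positions[2] - p$positions[1]
    expect_lte(abs(p$positions[i_max]), step + 1e-9)
    # symmetry: compare mirrored samples (equal plateaus on both sides)
    expect_equal(p$intensities, rev(p$intensities), tolerance = 1e-6)
  }
})

test_that("cohort simulation honors the (mean, sd, n) specification", {
  spec0 <- cohort_spec(data.frame(endpoint = "e", group = c("A", "B"),
                                  n = 3L, mean = 5, sd = 0), seed = 4)
  tab <- simulate_cohort(spec0)
  expect_equal(tab$value, rep(5, 6))
  # determinism
  spec <- cohort_spec(seed = 11)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  # law of large numbers on the syndecan-1 row, n inflated x100
  syn <- study_endpoint_summaries("syndecan-1")
  big <- syn; big$n <- syn$n * 100L
  tab <- simulate_cohort(cohort_spec(big, seed = 2))
  for (g in syn$group) {
    v <- tab$value[tab$group == g]
    i <- match(g, syn$group)
    se <- syn$sd[i] / sqrt(length(v))
    expect_lt(abs(mean(v) - syn$mean[i]), 3 * se + 1e-12)
  }
})

test_that("survival simulation matches the exponential model", {
  ep <- data.frame(endpoint = "e", group = c("A", "B"), n = 2L, mean = 0,
                   sd = 1)
  none <- cohort_spec(ep, weekly_death_prob = c(A = 0, B = 0), seed = 3)
  d <- simulate_survival(none, n_per_group = 20)
  expect_true(all(d$event == 0) && all(d$time == 7))
  sure <- cohort_spec(ep, weekly_death_prob = c(A = 1, B = 1), seed = 3)
  d <- simulate_survival(sure, n_per_group = 20)
  expect_true(all(d$event == 1) && all(d$time < 1e-3))
  # weekly death probability 0.5 (hazard log(2)/7): event fraction ~0.5
  half <- cohort_spec(ep, weekly_death_prob = c(A = 0.5, B = 0.5), seed = 5)
  d <- simulate_survival(half, n_per_group = 5000)
  se <- sqrt(0.25 / nrow(d))
  expect_lt(abs(mean(d$event) - 0.5), 3 * se)
  expect_error(simulate_survival(half, horizon_days = 0),
               class = "gcxi_bad_cohort")
})

test_that("scene validation rejects impossible geometry and amplitudes", {
  expect_error(vessel_scene(height_px = 32, width_px = 32, pixel_scale = 1,
                            inner_diameter_um = 40),
               class = "gcxi_bad_scene")
  amps <- data.frame(channel = "FITC-WGA", lumen = 100, wall_peak = 50,
                     interstitial = 10)
  expect_error(vessel_scene(amplitudes = amps), class = "gcxi_bad_scene")
  expect_error(render_frame(wall_scene(), NULL, NULL, t = -1),
               class = "gcxi_bad_time")
})
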