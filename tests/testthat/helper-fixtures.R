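# shared fixtures, all generated in code

# analytic profiles sampled on a fine grid
gauss_profile <- function(sigma = 10, amplitude = 100, baseline = 0,
                          step = 0.1, half = 25, pixel_scale = 1) {
  pos <- seq(-half, half, by = step)
  intensity_profile(pos, baseline + amplitude * exp(-pos^2 / (2 * sigma^2)),
                    pixel_scale = pixel_scale)
}

raised_cos_profile <- function(w = 20, amplitude = 100, baseline = 0,
                               step = 0.1, half = 25) {
  pos <- seq(-half, half, by = step)
  intensity_profile(pos, baseline + amplitude *
                      ifelse(abs(pos) <= w, (1 + cos(pi * pos / w)) / 2, 0))
}

# exact width of a Gaussian ridge at the default 40% band
gauss_width <- function(sigma) 2 * sigma * sqrt(-2 * log(0.6 + 0.4 * exp(-0.5)))
rcos_width <- function(w) (2 * w / pi) * acos(0.6)

no_smooth <- gcxi_config(smoothing_window = 1)

# single-channel wall-stain scene, cheap to render
wall_scene <- function(wall_sigma_um = 4, pixel_scale = 0.25,
                       size_px = 512, inner_diameter_um = 40,
                       family = "gaussian") {
  vessel_scene(height_px = size_px, width_px = size_px,
               pixel_scale = pixel_scale,
               inner_diameter_um = inner_diameter_um,
               wall_profile_family = family,
               wall_sigma_um = wall_sigma_um,
               amplitudes = data.frame(channel = "FITC-WGA", lumen = 40,
                                       wall_peak = 200, interstitial = 40))
}

# analysis settings for noisy acquisitions: smoothing spans about the expected
# peak width, profile long enough for the widest layer's inflections
noisy_cfg <- gcxi_config(smoothing_window = 35)
noisy_half_length <- 40
noisy_n_samples <- 161

two_tracer_leakage <- function(I0 = 0, Imax = 100, k = 0.02) {
  leakage_model(data.frame(channel = c("TMR-DEX40", "FITC-HES130"),
                           I0 = I0, Imax = Imax, k = k))
}

# Monte-Carlo oracle for the Dunnett max-|T| tail probability
mc_dunnett_tail <- function(q, lambda, df, n = 1e5, seed = 99,
                            sided = "two") {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    z0 <- rnorm(n)
    w <- sqrt(rchisq(n, df) / df)
    mx <- rep(-Inf, n)
    for (j in seq_along(lambda)) {
      y <- sqrt(1 - lambda[j]^2) * rnorm(n) + lambda[j] * z0
      tj <- y / w
      mx <- pmax(mx, if (sided == "two") abs(tj) else tj)
    }
    mean(mx >= q)
  })
}
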