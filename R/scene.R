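#' Describe a synthetic straight-vessel scene
#'
#' A `vessel_scene` is the parametric description of one intravital-microscopy
#' field of view containing a single straight artery. The vessel wall carries a
#' glycocalyx layer rendered as a bright intensity ridge of known scale on both
#' sides of the lumen; tracer channels carry a lumen plateau and an interstitial
#' level driven by a [leakage_model()]. All geometry is in pixels with a
#' configurable micron-per-pixel scale.
#'
#' @param height_px,width_px frame dimensions in pixels.
#' @param pixel_scale microns per pixel (> 0). Default 1.
#' @param centerline 2x2 matrix, rows = two endpoints of the vessel axis in
#'   0-based `(row, col)` pixel coordinates. Default: horizontal axis through
#'   the frame middle.
#' @param inner_diameter_um inner vessel diameter in microns (the study imaged
#'   arteries of roughly 40 or 60 um).
#' @param wall_profile_family `"gaussian"` or `"raised_cosine"` cross-section
#'   of the wall ridge.
#' @param wall_sigma_um true layer scale in microns: the Gaussian sigma, or the
#'   raised-cosine half-width.
#' @param amplitudes data frame with columns `channel`, `lumen`, `wall_peak`,
#'   `interstitial` (arbitrary intensity units, all >= 0). The wall ridge is
#'   rendered only in `wall_channel`, where `wall_peak` must exceed both
#'   plateaus.
#' @param channels ordered channel names. Defaults to the rows of `amplitudes`.
#' @param wall_channel name of the wall-stain channel (default first channel).
#'
#' @return An object of class `vessel_scene`.
#' @seealso [render_frame()], [leakage_model()], [noise_model()]
#' @export
vessel_scene <- function(height_px = 256L, width_px = 256L, pixel_scale = 1,
                         centerline = NULL,
                         inner_diameter_um = 40,
                         wall_profile_family = c("gaussian", "raised_cosine"),
                         wall_sigma_um = 4,
                         amplitudes = default_amplitudes(),
                         channels = NULL,
                         wall_channel = NULL) {
  wall_profile_family <- match.arg(wall_profile_family)
  stopifnot(is_count(height_px), is_count(width_px),
            is_number(pixel_scale), pixel_scale > 0,
            is_number(inner_diameter_um), inner_diameter_um > 0,
            is_number(wall_sigma_um), wall_sigma_um > 0)
  if (is.null(centerline)) {
    centerline <- rbind(c((height_px - 1) / 2, 0),
                        c((height_px - 1) / 2, width_px - 1))
  }
  centerline <- as.matrix(centerline)
  stopifnot(identical(dim(centerline), c(2L, 2L)))
  if (all(centerline[1, ] == centerline[2, ]))
    gcxi_error("centerline endpoints must be distinct", "gcxi_bad_scene")
  stopifnot(is.data.frame(amplitudes),
            all(c("channel", "lumen", "wall_peak", "interstitial") %in%
                  names(amplitudes)))
  if (any(amplitudes$lumen < 0) || any(amplitudes$wall_peak < 0) ||
      any(amplitudes$interstitial < 0))
    gcxi_error("amplitudes must be >= 0", "gcxi_bad_scene")
  channels <- channels %||% amplitudes$channel
  wall_channel <- wall_channel %||% channels[1]
  if (!wall_channel %in% channels)
    gcxi_error("wall_channel not among channels", "gcxi_bad_scene")
  wa <- amplitudes[amplitudes$channel == wall_channel, ]
  if (nrow(wa) != 1 || wa$wall_peak <= max(wa$lumen, wa$interstitial))
    gcxi_error("wall-peak amplitude must exceed lumen and interstitial plateaus in the wall-stain channel",
               "gcxi_bad_scene")
  if (inner_diameter_um / pixel_scale >= min(height_px, width_px))
    gcxi_error("vessel larger than frame", "gcxi_bad_scene")
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_scale = pixel_scale, centerline = centerline,
    inner_diameter_um = inner_diameter_um,
    wall_profile_family = wall_profile_family,
    wall_sigma_um = wall_sigma_um,
    amplitudes = amplitudes, channels = channels,
    wall_channel = wall_channel
  ), class = "vessel_scene")
}

default_amplitudes <- function() {
  data.frame(
    channel = c("FITC-WGA", "TMR-DEX40", "FITC-HES130"),
    lumen = c(40, 180, 180),
    wall_peak = c(200, 0, 0),
    interstitial = c(40, 0, 0)
  )
}

#' Interstitial tracer-leakage kinetics
#'
#' Single-compartment accumulation of an intravascular tracer into the
#' interstitium: `I(t) = I0 + Imax * (1 - exp(-k * t))`, non-decreasing in `t`
#' for `k >= 0`.
#'
#' @param channels data frame with columns `channel`, `I0` (baseline
#'   interstitial intensity), `Imax` (plateau increment) and `k` (rate, 1/min),
#'   all non-negative.
#' @param sample_times_min observation times in minutes (default the study's
#'   15, 30, 60 and 90 min).
#' @return An object of class `leakage_model`.
#' @export
leakage_model <- function(channels,
                          sample_times_min = c(15, 30, 60, 90)) {
  stopifnot(is.data.frame(channels),
            all(c("channel", "I0", "Imax", "k") %in% names(channels)))
  if (any(channels$I0 < 0) || any(channels$Imax < 0) || any(channels$k < 0))
    gcxi_error("I0, Imax and k must all be >= 0", "gcxi_bad_leakage")
  stopifnot(is.numeric(sample_times_min), all(sample_times_min >= 0))
  structure(list(channels = channels,
                 sample_times_min = sort(sample_times_min)),
            class = "leakage_model")
}

#' Interstitial intensity predicted by a leakage model
#'
#' @param leakage a [leakage_model()].
#' @param channel channel name present in the model.
#' @param t time(s) in minutes, >= 0.
#' @return numeric vector `I0 + Imax * (1 - exp(-k t))`.
#' @export
interstitial_intensity <- function(leakage, channel, t) {
  stopifnot(inherits(leakage, "leakage_model"), all(t >= 0))
  row <- leakage$channels[leakage$channels$channel == channel, ]
  if (nrow(row) != 1)
    gcxi_error(sprintf("unknown leakage channel '%s'", channel),
               "gcxi_unknown_channel")
  row$I0 + row$Imax * (1 - exp(-row$k * t))
}

#' Acquisition noise model
#'
#' Photon noise is applied first (Poisson with `poisson_gain` photons per
#' intensity unit; 0 disables), then additive Gaussian read noise. With both
#' terms disabled a render is exactly the noiseless scene regardless of seed.
#'
#' @param gaussian_sd standard deviation of the additive term, intensity units.
#' @param poisson_gain photons per intensity unit; 0 disables photon noise.
#' @param seed integer RNG seed; identical seed and scene give a bit-identical
#'   frame.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 0, poisson_gain = 0, seed = 1L) {
  stopifnot(is_number(gaussian_sd), gaussian_sd >= 0,
            is_number(poisson_gain), poisson_gain >= 0)
  structure(list(gaussian_sd = gaussian_sd, poisson_gain = poisson_gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Signed perpendicular distance (px) of every pixel centre from the vessel
# axis, plus the unit normal of the axis. Positive distances lie on the side
# the normal points to.
axis_distances <- function(scene) {
  p1 <- scene$centerline[1, ]; p2 <- scene$centerline[2, ]
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  tang <- d / len
  nrm <- c(-tang[2], tang[1])
  rows <- matrix(0:(scene$height_px - 1), scene$height_px, scene$width_px)
  cols <- matrix(0:(scene$width_px - 1), scene$height_px, scene$width_px,
                 byrow = TRUE)
  dist <- (rows - p1[1]) * nrm[1] + (cols - p1[2]) * nrm[2]
  list(dist = dist, tangent = tang, normal = nrm)
}

wall_ridge_value <- function(s, family, scale_px) {
  if (family == "gaussian") {
    exp(-s^2 / (2 * scale_px^2))
  } else {
    ifelse(abs(s) <= scale_px, (1 + cos(pi * s / scale_px)) / 2, 0)
  }
}

# Analytic width the GCXI detector should report for a noiseless ridge of the
# given family at the default upper_fraction = 0.4 band.
analytic_gcxi_width_px <- function(family, scale_px, upper_fraction = 0.4) {
  level <- (1 - upper_fraction) + upper_fraction *
    switch(family, gaussian = exp(-0.5), raised_cosine = 0.5)
  if (family == "gaussian") {
    2 * scale_px * sqrt(-2 * log(level))
  } else {
    (2 * scale_px / pi) * acos(2 * level - 1)
  }
}

#' Render a synthetic frame with ground truth
#'
#' Renders the scene at acquisition time `t`: the wall-stain channel carries
#' the glycocalyx ridge (chosen cross-section family) on both walls added to
#' the lumen/interstitial plateau; tracer channels named in the leakage model
#' take their interstitial value from `I(t)`; Poisson noise, then Gaussian
#' noise, is applied last. The returned ground truth records the crest
#' polyline of the designated (interstitial-normal) wall, the vessel mask, the
#' analytic width the GCXI detector should report, and the noiseless
#' interstitial intensities at the model's sample times.
#'
#' @param scene a [vessel_scene()].
#' @param leakage a [leakage_model()] or `NULL` (tracer channels then use the
#'   scene's interstitial amplitude).
#' @param noise a [noise_model()] or `NULL` for noiseless rendering.
#' @param t acquisition time, minutes, >= 0.
#' @param trace_margin_px margin kept between the returned wall-trace endpoints
#'   and the frame border, so that perpendicular sample lines stay in-frame.
#' @return list with elements `frame` (an `image_frame`) and `truth` (class
#'   `scene_truth`: `wall_trace`, `interstitial_side`, `vessel_mask`,
#'   `true_width_px`, `interstitial_truth`).
#' @export
render_frame <- function(scene, leakage = NULL, noise = NULL, t = 0,
                         trace_margin_px = 30) {
  stopifnot(inherits(scene, "vessel_scene"))
  if (!is_number(t) || t < 0) gcxi_error("negative time", "gcxi_bad_time")
  geo <- axis_distances(scene)
  r_px <- (scene$inner_diameter_um / 2) / scene$pixel_scale
  sigma_px <- scene$wall_sigma_um / scene$pixel_scale
  if (2 * (r_px + 3 * sigma_px) >= min(scene$height_px, scene$width_px))
    gcxi_error("vessel larger than frame", "gcxi_bad_scene")
  s <- abs(geo$dist) - r_px            # signed distance from nearest crest
  ridge <- wall_ridge_value(s, scene$wall_profile_family, sigma_px)
  lumen_mask <- abs(geo$dist) <= r_px

  grids <- list()
  for (ch in scene$channels) {
    amp <- scene$amplitudes[scene$amplitudes$channel == ch, ]
    inter_level <- amp$interstitial
    if (!is.null(leakage) && ch %in% leakage$channels$channel)
      inter_level <- interstitial_intensity(leakage, ch, t)
    g <- ifelse(lumen_mask, amp$lumen, inter_level)
    if (ch == scene$wall_channel) g <- g + amp$wall_peak * ridge
    grids[[ch]] <- g
  }

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    grids <- with_seed(noise$seed, {
      lapply(grids, function(g) {
        if (noise$poisson_gain > 0) {
          g <- matrix(rpois(length(g), noise$poisson_gain * g),
                      nrow(g), ncol(g)) / noise$poisson_gain
        }
        if (noise$gaussian_sd > 0) {
          g <- g + matrix(rnorm(length(g), 0, noise$gaussian_sd),
                          nrow(g), ncol(g))
        }
        g
      })
    })
  }

  frame <- image_frame(grids, pixel_scale = scene$pixel_scale, time_min = t)

  # crest polyline on the interstitial-designated side (normal direction);
  # shrink the border margin on small frames so a usable area remains
  margin <- min(trace_margin_px,
                (min(scene$height_px, scene$width_px) - 2) %/% 4)
  truth <- scene_truth(scene, geo, r_px, sigma_px, leakage, margin)
  list(frame = frame, truth = truth)
}

scene_truth <- function(scene, geo, r_px, sigma_px, leakage, margin) {
  p1 <- scene$centerline[1, ]; p2 <- scene$centerline[2, ]
  c1 <- p1 + r_px * geo$normal
  c2 <- p2 + r_px * geo$normal
  # clip crest segment so trace points (and sample lines) stay inside
  pts <- clip_segment(c1, c2, scene$height_px, scene$width_px, margin)
  if (is.null(pts))
    gcxi_error("wall crest does not cross the usable frame area",
               "gcxi_bad_scene")
  len <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  svals <- seq(0, len, by = 1)
  dir <- (pts[2, ] - pts[1, ]) / len
  trace_pts <- cbind(pts[1, 1] + svals * dir[1], pts[1, 2] + svals * dir[2])
  mask <- abs(geo$dist) <= r_px + 3 * sigma_px
  itruth <- NULL
  if (!is.null(leakage)) {
    itruth <- do.call(rbind, lapply(seq_len(nrow(leakage$channels)), function(i) {
      ch <- leakage$channels$channel[i]
      data.frame(channel = ch, time_min = leakage$sample_times_min,
                 intensity = interstitial_intensity(
                   leakage, ch, leakage$sample_times_min))
    }))
  }
  structure(list(
    wall_trace = trace_pts,
    interstitial_side = 1L,       # crest offset along +normal; interstitium further out
    normal = geo$normal,
    vessel_mask = mask,
    true_width_px = analytic_gcxi_width_px(scene$wall_profile_family, sigma_px),
    true_width_um = analytic_gcxi_width_px(scene$wall_profile_family, sigma_px) *
      scene$pixel_scale,
    interstitial_truth = itruth
  ), class = "scene_truth")
}

# Clip the segment a-b to the rectangle [margin, h-1-margin] x [margin, w-1-margin].
clip_segment <- function(a, b, h, w, margin) {
  d <- b - a
  tmin <- 0; tmax <- 1
  lims <- rbind(c(margin, h - 1 - margin), c(margin, w - 1 - margin))
  for (i in 1:2) {
    if (d[i] == 0) {
      if (a[i] < lims[i, 1] || a[i] > lims[i, 2]) return(NULL)
    } else {
      t1 <- (lims[i, 1] - a[i]) / d[i]
      t2 <- (lims[i, 2] - a[i]) / d[i]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  rbind(a + tmin * d, a + tmax * d)
}
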