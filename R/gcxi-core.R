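#' GCXI analysis configuration
#'
#' @param smoothing_window odd sample count for Savitzky-Golay smoothing;
#'   1 disables smoothing. Default 7, suited to noisy acquisitions; analytic
#'   or noiseless profiles are analysed with `smoothing_window = 1`.
#' @param smoothing_polyorder local polynomial order; the window must be at
#'   least `polyorder + 2` samples.
#' @param upper_fraction fraction of the peak-above-baseline range forming the
#'   measurement band. The width is read at the lower boundary of the upper
#'   `upper_fraction` of the `a - c` range, i.e. at level
#'   `c + (1 - upper_fraction) * (a - c)`; default 0.40.
#' @param min_peak_prominence minimum height of the peak above the higher of
#'   the two flanking minima, intensity units.
#' @return object of class `gcxi_config`.
#' @export
gcxi_config <- function(smoothing_window = 7L, smoothing_polyorder = 3L,
                        upper_fraction = 0.40, min_peak_prominence = 0) {
  stopifnot(is_count(smoothing_window), smoothing_window %% 2 == 1,
            is_number(upper_fraction), upper_fraction > 0, upper_fraction < 1,
            min_peak_prominence >= 0)
  if (smoothing_window > 1 &&
      smoothing_window < smoothing_polyorder + 2)
    gcxi_error("smoothing window must be >= polyorder + 2", "gcxi_bad_config")
  structure(list(smoothing_window = as.integer(smoothing_window),
                 smoothing_polyorder = as.integer(smoothing_polyorder),
                 upper_fraction = upper_fraction,
                 min_peak_prominence = min_peak_prominence),
            class = "gcxi_config")
}

#' Savitzky-Golay smoothing of an intensity profile
#'
#' Local polynomial least-squares smoothing; positions are unchanged and a
#' window of 1 is the identity. Polynomials of degree at most the configured
#' order are reproduced exactly.
#'
#' @param profile an [intensity_profile()].
#' @param cfg a [gcxi_config()].
#' @return smoothed [intensity_profile()].
#' @export
smooth_profile <- function(profile, cfg = gcxi_config()) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(cfg, "gcxi_config"))
  if (cfg$smoothing_window == 1L) return(profile)
  n <- length(profile$intensities)
  if (cfg$smoothing_window > n)
    gcxi_error("smoothing window exceeds profile length", "gcxi_bad_config")
  sm <- signal::sgolayfilt(profile$intensities, p = cfg$smoothing_polyorder,
                           n = cfg$smoothing_window)
  intensity_profile(profile$positions, sm, pixel_scale = profile$pixel_scale,
                    artery_id = profile$artery_id,
                    line_index = profile$line_index)
}

# nearest zero crossing of v (indexed by x) on each side of index `peak`,
# located to sub-sample precision by linear interpolation; returns positions
# or NA when no crossing exists on that side.
nearest_zero_crossings <- function(x, v, peak) {
  n <- length(v)
  left <- NA_real_
  if (peak >= 2) for (i in (peak - 1):1) {
    if (v[i] == 0 && v[i + 1] == 0) next
    if (v[i] * v[i + 1] <= 0) {
      left <- x[i] + (x[i + 1] - x[i]) * v[i] / (v[i] - v[i + 1])
      break
    }
  }
  right <- NA_real_
  if (peak < n) for (i in peak:(n - 1)) {
    if (v[i] == 0 && v[i + 1] == 0) next
    if (v[i] * v[i + 1] <= 0) {
      right <- x[i] + (x[i + 1] - x[i]) * v[i] / (v[i] - v[i + 1])
      break
    }
  }
  c(left, right)
}

# Sub-sample second-derivative zero crossing in the two segments bracketing
# index i (a discrete first-derivative extremum); falls back to x[i] when the
# crossing sits exactly on the node.
d2_crossing_near <- function(x, d2, i) {
  n <- length(x)
  h <- x[2] - x[1]
  for (j in c(i - 1L, i)) {
    if (j < 2L || j + 1L > n - 1L) next
    if (d2[j] == 0 && d2[j + 1] == 0) next
    if (d2[j] * d2[j + 1] <= 0)
      return(x[j] + h * d2[j] / (d2[j] - d2[j + 1]))
  }
  if (d2[i] == 0) return(x[i])
  x[i]
}

interp_at <- function(x, y, x0) {
  i <- findInterval(x0, x, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(x) - 1L)
  frac <- (x0 - x[i]) / (x[i + 1] - x[i])
  y[i] * (1 - frac) + y[i + 1] * frac
}

# nearest crossing of level `b` left/right of the peak index, sub-sample by
# linear interpolation between samples.
nearest_level_crossings <- function(x, y, peak, b) {
  nearest_zero_crossings(x, y - b, peak)
}

#' Analyse one wall-stain intensity profile
#'
#' Computes the profile-width glycocalyx score on a single perpendicular
#' profile. The (optionally smoothed) profile's global maximum is the peak
#' `a` (ties broken toward the smaller position). One inflection point is
#' located on each flank: the flank's steepest point (extremum of the central
#' difference first derivative) anchors the search, and the inflection is the
#' second-derivative zero crossing bracketing that extremum, located to
#' sub-sample precision by linear interpolation of the second derivative.
#' Anchoring at the steepest point rather than taking the crossing nearest
#' the peak makes the detection robust to curvature sign flips induced by
#' noise close to the crest; on a clean unimodal ridge the two rules select
#' the same point. The baseline `c` is the mean of the two inflection-point
#' intensities; the measurement level `b` is the lower boundary of the upper
#' `upper_fraction` of the `a - c` range,
#' `c + (1 - upper_fraction) * (a - c)`; and the width `d` is the distance
#' between the level-`b` crossings nearest the peak on each side.
#'
#' @param profile an [intensity_profile()].
#' @param cfg a [gcxi_config()].
#' @return object of class `peak_analysis`: `a_position`, `a_value`,
#'   `infl_left`, `infl_right` (each `c(position, value)`), `c_value`,
#'   `b_level`, `cross_left`, `cross_right`, `d_px`, `d_um`, plus provenance.
#'   Errors of class `gcxi_no_peak`, `gcxi_no_inflection` or
#'   `gcxi_no_crossing` identify profiles a caller should drop and log.
#' @export
analyze_profile <- function(profile, cfg = gcxi_config()) {
  sm <- smooth_profile(profile, cfg)
  x <- sm$positions
  y <- sm$intensities
  n <- length(y)
  peak <- which.max(y)           # ties -> smallest position
  if (peak == 1L || peak == n)
    gcxi_error("no interior peak in profile", "gcxi_no_peak")
  prom <- y[peak] - max(min(y[1:peak]), min(y[peak:n]))
  if (prom < cfg$min_peak_prominence || prom <= 0)
    gcxi_error("peak prominence below threshold", "gcxi_no_peak")
  h <- x[2] - x[1]
  d1 <- (y[c(2:n, n)] - y[c(1, 1:(n - 1))]) / (2 * h)
  d2 <- (y[c(2:n, n)] - 2 * y + y[c(1, 1:(n - 1))]) / h^2
  # steepest point of each flank anchors the inflection search; both central
  # differences are defined on 2..n-1 only, and the smoother's end transient
  # (half a window at each end) is excluded from the search
  margin <- max(1L, (cfg$smoothing_window - 1L) %/% 2L)
  lo <- 1L + margin
  hi <- n - margin
  if (peak - 1L < lo || peak + 1L > hi)
    gcxi_error("no inflection point on one side of the peak",
               "gcxi_no_inflection")
  iL <- which.max(d1[lo:(peak - 1L)]) + lo - 1L
  iR <- peak + which.min(d1[(peak + 1L):hi])
  if (iL <= lo || iR >= hi)
    gcxi_error("no inflection point on one side of the peak",
               "gcxi_no_inflection")
  infl <- c(d2_crossing_near(x, d2, iL), d2_crossing_near(x, d2, iR))
  if (any(is.na(infl)))
    gcxi_error("no inflection point on one side of the peak",
               "gcxi_no_inflection")
  il_val <- interp_at(x, y, infl[1])
  ir_val <- interp_at(x, y, infl[2])
  c_value <- (il_val + ir_val) / 2
  a_value <- y[peak]
  b_level <- c_value + (1 - cfg$upper_fraction) * (a_value - c_value)
  cross <- nearest_level_crossings(x, y, peak, b_level)
  if (any(is.na(cross)))
    gcxi_error("profile does not cross the measurement level within its extent",
               "gcxi_no_crossing")
  d_px <- cross[2] - cross[1]
  structure(list(
    a_position = x[peak], a_value = a_value,
    infl_left = c(position = infl[1], value = il_val),
    infl_right = c(position = infl[2], value = ir_val),
    c_value = c_value, b_level = b_level,
    cross_left = cross[1], cross_right = cross[2],
    d_px = d_px, d_um = d_px * profile$pixel_scale,
    artery_id = profile$artery_id, line_index = profile$line_index
  ), class = "peak_analysis")
}

#' @export
print.peak_analysis <- function(x, ...) {
  cat(sprintf(
    "<peak_analysis> a = %.4g @ %.3g px, c = %.4g, b = %.4g, d = %.4g px (%.4g um)\n",
    x$a_value, x$a_position, x$c_value, x$b_level, x$d_px, x$d_um))
  invisible(x)
}

#' Per-artery glycocalyx index from three line analyses
#'
#' The index of an artery is the arithmetic mean of the widths measured on its
#' three perpendicular lines. Arteries with fewer than three usable lines are
#' rejected (error class `gcxi_unusable_artery`) unless `require_three =
#' FALSE`, in which case the mean of the usable lines is taken.
#'
#' @param analyses list of [analyze_profile()] results from one artery.
#' @param diameter_class nominal diameter class label.
#' @param group group label carried into downstream statistics.
#' @param require_three reject arteries with fewer than 3 usable lines
#'   (default TRUE).
#' @return object of class `artery_gcxi`: `artery_id`, `diameter_class`,
#'   `group`, `line_widths_um`, `gcxi_um`.
#' @export
artery_gcxi <- function(analyses, diameter_class = NA, group = NA_character_,
                        require_three = TRUE) {
  stopifnot(is.list(analyses),
            all(vapply(analyses, inherits, TRUE, "peak_analysis")))
  if (require_three && length(analyses) != 3L)
    gcxi_error(sprintf("artery unusable: %d usable lines, 3 required",
                       length(analyses)), "gcxi_unusable_artery")
  if (length(analyses) < 1L)
    gcxi_error("artery unusable: no usable lines", "gcxi_unusable_artery")
  ids <- unique(vapply(analyses, function(a) a$artery_id, ""))
  if (length(ids) != 1L)
    gcxi_error("analyses come from different arteries", "gcxi_unusable_artery")
  w <- vapply(analyses, function(a) a$d_um, 0)
  structure(list(artery_id = ids, diameter_class = diameter_class,
                 group = group, line_widths_um = w, gcxi_um = mean(w)),
            class = "artery_gcxi")
}

#' Measure the GCXI of one artery on an image frame
#'
#' Convenience wrapper chaining [place_perpendicular_lines()],
#' [sample_profile()] and [analyze_profile()] over one wall trace, collecting
#' per-line failures instead of stopping.
#'
#' @param frame an [image_frame()].
#' @param trace a [wall_trace()].
#' @param channel wall-stain channel name.
#' @param cfg a [gcxi_config()].
#' @param spacing_px,half_length_px,n_samples passed to
#'   [place_perpendicular_lines()].
#' @param group group label.
#' @param require_three passed to [artery_gcxi()].
#' @return list with `artery` (an `artery_gcxi` or `NULL`), `analyses`,
#'   `dropped` (data frame of line_index + reason for failed lines).
#' @export
measure_artery <- function(frame, trace, channel, cfg = gcxi_config(),
                           spacing_px = 50, half_length_px = 25,
                           n_samples = 101, group = NA_character_,
                           require_three = TRUE) {
  lines <- place_perpendicular_lines(trace, spacing_px = spacing_px,
                                     half_length_px = half_length_px,
                                     n_samples = n_samples)
  analyses <- list()
  dropped <- data.frame(line_index = integer(), reason = character())
  for (ln in lines) {
    res <- tryCatch(
      analyze_profile(sample_profile(frame, channel, ln), cfg),
      gcxi_error = function(e) e)
    if (inherits(res, "peak_analysis")) {
      analyses[[length(analyses) + 1L]] <- res
    } else {
      dropped <- rbind(dropped, data.frame(
        line_index = ln$line_index, reason = class(res)[1]))
    }
  }
  artery <- tryCatch(
    artery_gcxi(analyses, diameter_class = trace$diameter_class,
                group = group, require_three = require_three),
    gcxi_unusable_artery = function(e) NULL)
  list(artery = artery, analyses = analyses, dropped = dropped)
}
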