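#' Square region of interest
#'
#' @param row,col 0-based top-left pixel of the square.
#' @param size_px side length in pixels (default 80, the study's ROI size).
#' @return object of class `roi`.
#' @export
roi <- function(row, col, size_px = 80L) {
  stopifnot(row >= 0, col >= 0, is_count(size_px))
  structure(list(row = as.integer(row), col = as.integer(col),
                 size_px = as.integer(size_px)), class = "roi")
}

rois_overlap <- function(a, b) {
  !(a$row + a$size_px <= b$row || b$row + b$size_px <= a$row ||
      a$col + a$size_px <= b$col || b$col + b$size_px <= a$col)
}

# 2-D integral image for O(1) "any TRUE in rectangle" queries.
mask_cumsum <- function(mask) {
  apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()
}

mask_any_in <- function(cs, r0, c0, size) {
  # 0-based r0, c0; cs is cumulative sum with cs[i, j] = sum mask[1..i, 1..j]
  r1 <- r0 + size; c1 <- c0 + size            # exclusive, 0-based -> 1-based
  tot <- cs[r1, c1] -
    (if (r0 > 0) cs[r0, c1] else 0) -
    (if (c0 > 0) cs[r1, c0] else 0) +
    (if (r0 > 0 && c0 > 0) cs[r0, c0] else 0)
  tot > 0
}

#' Randomly place vessel-free, pairwise-disjoint ROIs
#'
#' Draws `n` square ROIs by seeded rejection sampling over all in-bounds
#' top-left positions. An ROI is accepted when it contains no vessel-mask
#' pixel and does not overlap a previously accepted ROI. Placement is
#' deterministic under `seed`; if no valid placement is found within
#' `max_attempts` draws, an error of class `gcxi_infeasible_roi` is raised.
#'
#' @param vessel_mask logical matrix, `TRUE` on vessel (lumen + wall) pixels.
#' @param size_px ROI side, pixels (default 80).
#' @param n number of ROIs (default 3).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget (default 10000).
#' @return object of class `roi_set`: list of [roi()]s plus `seed`.
#' @export
select_rois <- function(vessel_mask, size_px = 80L, n = 3L, seed = 1L,
                        max_attempts = 10000L) {
  stopifnot(is.matrix(vessel_mask), is_count(size_px), is_count(n))
  h <- nrow(vessel_mask); w <- ncol(vessel_mask)
  if (h < size_px || w < size_px)
    gcxi_error("frame smaller than ROI", "gcxi_infeasible_roi")
  cs <- mask_cumsum(vessel_mask)
  rois <- with_seed(seed, {
    acc <- list()
    attempts <- 0L
    while (length(acc) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        gcxi_error(sprintf(
          "could not place %d vessel-free disjoint ROIs in %d attempts",
          n, max_attempts), "gcxi_infeasible_roi")
      r0 <- sample.int(h - size_px + 1L, 1L) - 1L
      c0 <- sample.int(w - size_px + 1L, 1L) - 1L
      cand <- roi(r0, c0, size_px)
      if (mask_any_in(cs, r0, c0, size_px)) next
      if (any(vapply(acc, rois_overlap, TRUE, cand))) next
      acc[[length(acc) + 1L]] <- cand
    }
    acc
  })
  structure(list(rois = rois, seed = as.integer(seed), size_px = size_px),
            class = "roi_set")
}

#' Mean intensity inside an ROI
#'
#' @param frame an [image_frame()].
#' @param channel channel name.
#' @param roi an [roi()].
#' @return arithmetic mean of the `size_px^2` pixel intensities.
#' @export
roi_mean <- function(frame, channel, roi) {
  stopifnot(inherits(roi, "roi"))
  m <- frame_channel(frame, channel)
  if (roi$row + roi$size_px > nrow(m) || roi$col + roi$size_px > ncol(m))
    gcxi_error("ROI outside the frame", "gcxi_roi_out_of_bounds")
  mean(m[(roi$row + 1):(roi$row + roi$size_px),
         (roi$col + 1):(roi$col + roi$size_px)])
}

#' Interstitial tracer time course over fixed ROIs
#'
#' For each channel and time point, the reported interstitial intensity is the
#' arithmetic mean of the three ROI means. The same ROI set is reused at every
#' time point (frames share geometry).
#'
#' @param frames list of [image_frame()]s, one per time point, each with
#'   `time_min` set.
#' @param rois an [roi_set()][select_rois()].
#' @param channels channel names to measure (default: tracer channels present
#'   in the first frame other than the first channel).
#' @param times_min required time points; default `c(15, 30, 60, 90)` minutes.
#' @param normalize_baseline also report series divided by their first-time
#'   value (default TRUE; zero baselines give NA).
#' @return object of class `permeability_timeseries`: `series` (data frame
#'   `channel`, `time_min`, `intensity`, optional `relative`), `per_roi`
#'   (data frame `channel`, `time_min`, `roi_index`, `intensity`).
#' @export
measure_timecourse <- function(frames, rois, channels = NULL,
                               times_min = c(15, 30, 60, 90),
                               normalize_baseline = TRUE) {
  stopifnot(inherits(rois, "roi_set"), is.list(frames), length(frames) >= 1)
  ft <- vapply(frames, function(f) f$time_min, 0)
  if (anyNA(ft)) gcxi_error("every frame needs time_min", "gcxi_missing_time")
  missing <- setdiff(times_min, ft)
  if (length(missing) > 0)
    gcxi_error(sprintf("missing time point(s): %s",
                       paste(missing, collapse = ", ")),
               "gcxi_missing_time")
  frames <- frames[match(times_min, ft)]
  dims <- unique(lapply(frames, function(f) c(f$height_px, f$width_px)))
  if (length(dims) != 1)
    gcxi_error("frames do not share geometry", "gcxi_geometry_mismatch")
  channels <- channels %||% setdiff(names(frames[[1]]$channels),
                                    names(frames[[1]]$channels)[1])
  per_roi <- do.call(rbind, lapply(channels, function(ch) {
    do.call(rbind, lapply(seq_along(times_min), function(i) {
      vals <- vapply(rois$rois, function(r) roi_mean(frames[[i]], ch, r), 0)
      data.frame(channel = ch, time_min = times_min[i],
                 roi_index = seq_along(vals), intensity = vals)
    }))
  }))
  series <- stats::aggregate(intensity ~ channel + time_min, per_roi, mean)
  series <- series[order(series$channel, series$time_min), ]
  rownames(series) <- NULL
  if (normalize_baseline) {
    series$relative <- ave(series$intensity, series$channel, FUN = function(v) {
      if (v[1] == 0) rep(NA_real_, length(v)) else v / v[1]
    })
  }
  structure(list(series = series, per_roi = per_roi,
                 times_min = times_min, channels = channels),
            class = "permeability_timeseries")
}
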