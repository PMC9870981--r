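#' Wall-trace annotation
#'
#' An ordered polyline along one side of one artery's glycocalyx-illuminated
#' wall, in 0-based `(row, col)` pixel coordinates, with the sign that orients
#' perpendicular normals toward the interstitium.
#'
#' @param points n x 2 matrix of `(row, col)` polyline vertices, n >= 2,
#'   consecutive vertices distinct.
#' @param interstitial_side `+1` or `-1`: the interstitium lies along
#'   `side * (-dc, dr)` for local tangent `(dr, dc)`.
#' @param artery_id identifier string.
#' @param diameter_class nominal diameter class label (40 or 60, microns).
#' @return object of class `wall_trace`.
#' @export
wall_trace <- function(points, interstitial_side = 1L, artery_id = "artery-1",
                       diameter_class = 40) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2,
            interstitial_side %in% c(-1L, 1L))
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0))
    gcxi_error("consecutive trace points must be distinct", "gcxi_bad_trace")
  structure(list(points = points,
                 interstitial_side = as.integer(interstitial_side),
                 artery_id = artery_id, diameter_class = diameter_class),
            class = "wall_trace")
}

trace_arc_length <- function(trace) {
  seg <- diff(trace$points)
  sum(sqrt(rowSums(seg^2)))
}

# Point and unit tangent at arc position s along the polyline. The tangent is
# a central difference of points at s +/- delta, adequate for the straight or
# near-straight traces in scope.
trace_point_at <- function(points, s) {
  seg <- diff(points)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(lens))
  frac <- (s - cum[i]) / lens[i]
  points[i, ] + frac * seg[i, ]
}

trace_tangent_at <- function(points, s, delta = 0.5) {
  seg <- diff(points)
  total <- sum(sqrt(rowSums(seg^2)))
  a <- trace_point_at(points, max(s - delta, 0))
  b <- trace_point_at(points, min(s + delta, total))
  d <- b - a
  d / sqrt(sum(d^2))
}

#' Place perpendicular sample lines on a wall trace
#'
#' Places `count` lines spaced `spacing_px` apart in arc length, centred on
#' the trace: the first line sits at offset
#' `(arc length - (count - 1) * spacing_px) / 2`, so three lines divide the
#' wall segment into four blocks. Each line is perpendicular to the local
#' tangent and oriented toward the interstitial side.
#'
#' @param trace a [wall_trace()].
#' @param spacing_px spacing between consecutive lines along the wall,
#'   pixels (default 50).
#' @param count number of lines (default 3).
#' @param half_length_px half-extent of each line, pixels.
#' @param n_samples odd number of samples per line (>= 5); the centre sample
#'   lies on the trace.
#' @return list of `sample_line` objects (fields `center`, `normal`,
#'   `half_length_px`, `n_samples`, `line_index`, `artery_id`).
#' @export
place_perpendicular_lines <- function(trace, spacing_px = 50, count = 3,
                                      half_length_px = 25, n_samples = 101) {
  stopifnot(inherits(trace, "wall_trace"), spacing_px > 0,
            half_length_px > 0)
  if (!is_count(count)) gcxi_error("count must be a positive integer",
                                   "gcxi_bad_lines")
  if (!is_count(n_samples) || n_samples < 5 || n_samples %% 2 == 0)
    gcxi_error("n_samples must be odd and >= 5", "gcxi_bad_lines")
  total <- trace_arc_length(trace)
  span <- (count - 1) * spacing_px
  if (total < span)
    gcxi_error(sprintf("trace too short: arc length %.1f px < %.1f px needed",
                       total, span), "gcxi_trace_too_short")
  s0 <- (total - span) / 2
  lapply(seq_len(count), function(i) {
    s <- s0 + (i - 1) * spacing_px
    ctr <- trace_point_at(trace$points, s)
    tang <- trace_tangent_at(trace$points, s)
    nrm <- c(-tang[2], tang[1]) * trace$interstitial_side
    sample_line(ctr, nrm, half_length_px, n_samples,
                line_index = i, artery_id = trace$artery_id)
  })
}

#' Construct a perpendicular sample line
#'
#' Usually produced by [place_perpendicular_lines()]; exposed for sampling at
#' explicit positions.
#'
#' @param center `(row, col)` point on the wall, 0-based pixels.
#' @param normal direction of increasing position; normalized to unit length.
#' @param half_length_px half-extent, pixels (> 0).
#' @param n_samples odd sample count >= 5.
#' @param line_index,artery_id provenance labels.
#' @return object of class `sample_line`.
#' @export
sample_line <- function(center, normal, half_length_px = 25, n_samples = 101,
                        line_index = 1L, artery_id = NA_character_) {
  stopifnot(length(center) == 2, length(normal) == 2, half_length_px > 0)
  if (!is_count(n_samples) || n_samples < 5 || n_samples %% 2 == 0)
    gcxi_error("n_samples must be odd and >= 5", "gcxi_bad_lines")
  nl <- sqrt(sum(normal^2))
  if (nl == 0) gcxi_error("normal must be non-zero", "gcxi_bad_lines")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / nl,
                 half_length_px = half_length_px,
                 n_samples = as.integer(n_samples),
                 line_index = as.integer(line_index), artery_id = artery_id),
            class = "sample_line")
}

# Bilinear interpolation of matrix `m` at 0-based (row, col) coordinates.
bilinear <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  if (any(r < 0 | r > h - 1 | c < 0 | c > w - 1))
    gcxi_error("sample point outside the frame", "gcxi_line_exits_frame")
  r0 <- pmin(floor(r), h - 2); c0 <- pmin(floor(c), w - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1)
  i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i01] * (1 - fr) * fc +
    m[i10] * fr * (1 - fc) + m[i11] * fr * fc
}

#' Sample an intensity profile along a perpendicular line
#'
#' Bilinearly interpolates `n_samples` uniformly spaced points from
#' `-half_length` to `+half_length` along the line's normal. Positions are
#' signed distances in pixels: negative positions lie on the lumen side,
#' positive on the interstitial side.
#'
#' @param frame an [image_frame()].
#' @param channel channel name.
#' @param line a `sample_line` from [place_perpendicular_lines()].
#' @return object of class `intensity_profile` with fields `positions`
#'   (pixels, strictly increasing, uniform), `intensities`, `pixel_scale`,
#'   `artery_id`, `line_index`.
#' @export
sample_profile <- function(frame, channel, line) {
  stopifnot(inherits(line, "sample_line"))
  m <- frame_channel(frame, channel)
  pos <- seq(-line$half_length_px, line$half_length_px,
             length.out = line$n_samples)
  r <- line$center[1] + pos * line$normal[1]
  c <- line$center[2] + pos * line$normal[2]
  intensity_profile(pos, bilinear(m, r, c),
                    pixel_scale = frame$pixel_scale,
                    artery_id = line$artery_id, line_index = line$line_index)
}

#' Construct an intensity profile
#'
#' @param positions signed distances along the normal, pixels; strictly
#'   increasing and uniformly spaced.
#' @param intensities fluorescence intensities, same length.
#' @param pixel_scale microns per pixel.
#' @param artery_id,line_index provenance labels.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, pixel_scale = 1,
                              artery_id = NA_character_, line_index = NA_integer_) {
  stopifnot(length(positions) == length(intensities), length(positions) >= 2)
  dp <- diff(positions)
  if (any(dp <= 0)) gcxi_error("positions must be strictly increasing",
                               "gcxi_bad_profile")
  if (max(abs(dp - dp[1])) > 1e-8 * max(abs(dp)))
    gcxi_error("positions must be uniformly spaced", "gcxi_bad_profile")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 pixel_scale = pixel_scale,
                 artery_id = artery_id, line_index = line_index),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, step %.3g px, range [%.3g, %.3g]\n",
              length(x$positions), x$positions[2] - x$positions[1],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read / write wall-trace annotations as JSON
#'
#' The annotation format is a JSON array of objects
#' `{artery_id, diameter_class, interstitial_side, points: [[row, col], ...]}`.
#'
#' @param path JSON file path.
#' @return `read_wall_traces()`: list of [wall_trace()] objects.
#' @export
read_wall_traces <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(ann, function(a) {
    pts <- if (is.matrix(a$points)) a$points
    else do.call(rbind, lapply(a$points, unlist))
    wall_trace(pts, interstitial_side = a$interstitial_side,
               artery_id = a$artery_id, diameter_class = a$diameter_class)
  })
}

#' @param traces list of [wall_trace()] objects.
#' @rdname read_wall_traces
#' @export
write_wall_traces <- function(traces, path) {
  ann <- lapply(traces, function(tr) {
    list(artery_id = tr$artery_id, diameter_class = tr$diameter_class,
         interstitial_side = tr$interstitial_side,
         points = apply(tr$points, 1, function(p) as.list(unname(p)),
                        simplify = FALSE))
  })
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
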