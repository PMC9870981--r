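#' Multi-channel image frame
#'
#' Container for one acquisition: a named list of equal-size intensity
#' matrices (floating point, arbitrary units), pixel scale in microns per
#' pixel, and an optional acquisition time in minutes. Pixel coordinates used
#' throughout the package are 0-based `(row, col)` with the origin at the
#' top-left pixel centre.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param pixel_scale microns per pixel (> 0).
#' @param time_min acquisition time in minutes, or `NA`.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(channels, pixel_scale = 1, time_min = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            is_number(pixel_scale), pixel_scale > 0)
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1)
    gcxi_error("all channels must share dimensions", "gcxi_bad_frame")
  structure(list(channels = lapply(channels, function(m) {
    storage.mode(m) <- "double"; m
  }),
  height_px = nrow(channels[[1]]), width_px = ncol(channels[[1]]),
  pixel_scale = pixel_scale, time_min = time_min),
  class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px, channels: %s\n",
              x$height_px, x$width_px, x$pixel_scale,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

frame_channel <- function(frame, channel) {
  stopifnot(inherits(frame, "image_frame"))
  if (!channel %in% names(frame$channels))
    gcxi_error(sprintf("unknown channel '%s'", channel), "gcxi_unknown_channel")
  frame$channels[[channel]]
}

#' Write a frame as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Intensities are floating point internally; quantization to 16 bits happens
#' only here. All channels are divided by a common `intensity_scale` (default:
#' the frame maximum mapped to 65535) and the scale is recorded in the sidecar
#' JSON (`<path>.json`) together with channel names, pixel scale and
#' acquisition time, so [read_frame()] restores the original values up to
#' quantization error.
#'
#' @param frame an [image_frame()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param intensity_scale intensity units per 65535 counts; `NULL` picks the
#'   frame maximum (or 1 for an all-zero frame).
#' @param extra named list merged into the sidecar (e.g. scene ground truth).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, intensity_scale = NULL, extra = list()) {
  stopifnot(inherits(frame, "image_frame"))
  mx <- max(vapply(frame$channels, max, 0))
  intensity_scale <- intensity_scale %||% (if (mx > 0) mx else 1)
  pages <- lapply(frame$channels, function(m) {
    m <- m / intensity_scale
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- c(list(
    channels = names(frame$channels),
    pixel_scale = frame$pixel_scale,
    time_min = frame$time_min,
    intensity_scale = intensity_scale
  ), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF frame
#'
#' Channel names and the intensity scale come from the JSON sidecar written by
#' [write_frame()]; if the sidecar is absent a `channel_map` (ordered channel
#' names) and `pixel_scale` must be supplied.
#'
#' @param path TIFF path.
#' @param channel_map ordered channel names used when no sidecar exists.
#' @param pixel_scale microns per pixel when no sidecar exists.
#' @param intensity_scale intensity units per 65535 counts when no sidecar.
#' @return an [image_frame()].
#' @export
read_frame <- function(path, channel_map = NULL, pixel_scale = NULL,
                       intensity_scale = 1) {
  if (!file.exists(path))
    gcxi_error(sprintf("unreadable file '%s'", path), "gcxi_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  time_min <- NA_real_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    channel_map <- meta$channels
    pixel_scale <- meta$pixel_scale
    intensity_scale <- meta$intensity_scale %||% 1
    time_min <- meta$time_min %||% NA_real_
    if (is.null(time_min)) time_min <- NA_real_
  }
  if (is.null(channel_map))
    gcxi_error("no channel metadata: sidecar missing and no channel_map given",
               "gcxi_missing_metadata")
  if (is.null(pixel_scale))
    gcxi_error("no pixel_scale: sidecar missing and none given",
               "gcxi_missing_metadata")
  if (length(pages) != length(channel_map))
    gcxi_error(sprintf("channel count mismatch: %d pages, %d names",
                       length(pages), length(channel_map)),
               "gcxi_channel_mismatch")
  grids <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * intensity_scale
  })
  names(grids) <- channel_map
  image_frame(grids, pixel_scale = pixel_scale, time_min = time_min)
}
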