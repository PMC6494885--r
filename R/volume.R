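#' Calibrated 5-D image series
#'
#' Container for a time-lapse multi-channel z-stack with physical
#' calibration. Pixels are stored as a 5-D array ordered
#' `(time, channel, z, y, x)`; voxel size is `(dx, dy, dz)` in micrometres
#' and the frame interval is in hours.
#'
#' @param pixels 5-D numeric array `(t, c, z, y, x)`, nonnegative.
#' @param voxel_size numeric length-3 `(dx, dy, dz)` in micrometres.
#'   Defaults to the platform calibration 0.3225 x 0.3225 x 0.5.
#' @param frame_interval_h hours between consecutive timepoints.
#' @param channel_names character vector, one name per channel.
#' @param origin_h time label of the first frame (hours post
#'   transfection/infection); purely a label on the time axis.
#'
#' @return An object of class `VolumeSeries`.
#' @export
volume_series <- function(pixels,
                          voxel_size = c(0.3225, 0.3225, 0.5),
                          frame_interval_h = 24,
                          channel_names = NULL,
                          origin_h = 24) {
  if (!is.array(pixels) || length(dim(pixels)) != 5L)
    stop("`pixels` must be a 5-D array (time, channel, z, y, x)")
  if (any(dim(pixels) < 1L)) stop("all five extents must be >= 1")
  if (min(pixels) < 0) stop("pixel intensities must be nonnegative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (dx, dy, dz) in um")
  if (is.null(channel_names))
    channel_names <- paste0("channel", seq_len(dim(pixels)[2]))
  if (length(channel_names) != dim(pixels)[2])
    stop("`channel_names` length must equal the channel extent")
  structure(
    list(pixels = pixels,
         voxel_size = setNames(voxel_size, c("dx", "dy", "dz")),
         frame_interval_h = frame_interval_h,
         channel_names = as.character(channel_names),
         origin_h = origin_h),
    class = "VolumeSeries")
}

#' @export
print.VolumeSeries <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<VolumeSeries> %d t x %d c x %d z x %d y x %d x\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel %.4f x %.4f x %.2f um, frame interval %g h, origin %g h\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$frame_interval_h, x$origin_h))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Timepoints of a series, in hours
#'
#' @param series a `VolumeSeries`.
#' @return numeric vector `origin_h + (0:(T-1)) * frame_interval_h`.
#' @export
series_timepoints <- function(series) {
  stopifnot(inherits(series, "VolumeSeries"))
  series$origin_h + (seq_len(dim(series$pixels)[1]) - 1) * series$frame_interval_h
}

#' Calibrated 2-D projection
#'
#' A single-channel, single-timepoint 2-D image (rows = y, columns = x)
#' with pixel size, timepoint and channel carried along so that downstream
#' operations never lose physical units.
#'
#' @param pixels numeric matrix (y, x).
#' @param pixel_size numeric length-2 `(dx, dy)` micrometres.
#' @param timepoint_h timepoint label in hours.
#' @param channel channel name.
#' @return An object of class `Projection`.
#' @export
projection <- function(pixels, pixel_size = c(0.3225, 0.3225),
                       timepoint_h = NA_real_, channel = NA_character_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix (y, x)")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) != 2L || any(pixel_size <= 0))
    stop("`pixel_size` must be two positive numbers (dx, dy) in um")
  structure(
    list(pixels = pixels,
         pixel_size = setNames(pixel_size, c("dx", "dy")),
         timepoint_h = timepoint_h,
         channel = channel),
    class = "Projection")
}

#' @export
print.Projection <- function(x, ...) {
  cat(sprintf("<Projection> %d y x %d x, pixel %.4f x %.4f um, t = %s h, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size[1], x$pixel_size[2],
              format(x$timepoint_h), x$channel))
  invisible(x)
}

#' Maximum z-projection
#'
#' Collapses one `(timepoint, channel)` z-stack of a [volume_series()] to a
#' 2-D image whose every pixel is the maximum intensity along z, propagating
#' the in-plane calibration.
#'
#' @param series a `VolumeSeries`.
#' @param timepoint 1-based timepoint index.
#' @param channel 1-based channel index or channel name.
#' @return A [projection()].
#' @export
max_project <- function(series, timepoint, channel) {
  stopifnot(inherits(series, "VolumeSeries"))
  d <- dim(series$pixels)
  if (is.character(channel))
    channel <- match(channel, series$channel_names)
  if (is.na(timepoint) || timepoint < 1 || timepoint > d[1])
    stop("`timepoint` index out of range")
  if (is.na(channel) || channel < 1 || channel > d[2])
    stop("`channel` index out of range")
  stack <- series$pixels[timepoint, channel, , , , drop = FALSE]
  dim(stack) <- d[3:5]                       # (z, y, x)
  proj <- apply(stack, c(2, 3), max)
  projection(proj,
             pixel_size = series$voxel_size[c("dx", "dy")],
             timepoint_h = series_timepoints(series)[timepoint],
             channel = series$channel_names[channel])
}

#' Two-colour overlay of two timepoints
#'
#' Renders an earlier projection in green and a later one in magenta
#' (red + blue), so that co-located signal appears white/grey and movement
#' appears as pure colour — the standard before/after overlap display.
#' Each input is normalised by its own maximum before compositing.
#'
#' @param earlier,later `Projection`s of identical shape.
#' @return A `(y, x, 3)` RGB array in `[0, 1]` with attribute `pixel_size`.
#' @export
overlay_timepoints <- function(earlier, later) {
  stopifnot(inherits(earlier, "Projection"), inherits(later, "Projection"))
  if (!all(dim(earlier$pixels) == dim(later$pixels)))
    stop("projections must have identical shape")
  norm1 <- function(m) { mx <- max(m); if (mx > 0) m / mx else m }
  g <- norm1(earlier$pixels)
  m <- norm1(later$pixels)
  out <- array(0, dim = c(dim(g), 3L))
  out[, , 1] <- m   # red
  out[, , 2] <- g   # green
  out[, , 3] <- m   # blue
  attr(out, "pixel_size") <- earlier$pixel_size
  out
}
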