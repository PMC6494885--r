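#' Write a calibrated image series to OME-style TIFF
#'
#' Pixel data go to a multi-page 16-bit TIFF with planes ordered z-fastest,
#' then channel, then time (OME dimension order `XYZCT`); calibration
#' metadata (axis sizes, voxel size in um, frame interval in hours, channel
#' names) is written to an OME-XML companion file next to the TIFF
#' (`<basename>.companion.ome.xml`). Intensities must fit the 16-bit range;
#' non-integer intensities are rounded with a warning, so integer-valued
#' series round-trip bit-exactly.
#'
#' @param series a [volume_series()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "VolumeSeries"))
  px <- series$pixels
  if (max(px) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  if (any(px != round(px))) {
    warning("non-integer intensities rounded to 16-bit for storage")
    px <- round(px)
  }
  d <- dim(px)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- matrix(px[t, ch, z, , ], d[4], d[5]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  xml2::write_xml(ome_companion_xml(series), companion_path(path))
  invisible(path)
}

companion_path <- function(path) {
  paste0(sub("\\.(ome\\.)?tiff?$", "", path, ignore.case = TRUE),
         ".companion.ome.xml")
}

ome_companion_xml <- function(series) {
  d <- dim(series$pixels)
  doc <- xml2::xml_new_root(
    "OME", xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0")
  pix <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYZCT", Type = "uint16",
    SizeX = d[5], SizeY = d[4], SizeZ = d[3], SizeC = d[2], SizeT = d[1],
    PhysicalSizeX = series$voxel_size[["dx"]],
    PhysicalSizeY = series$voxel_size[["dy"]],
    PhysicalSizeZ = series$voxel_size[["dz"]],
    PhysicalSizeXUnit = "um", PhysicalSizeYUnit = "um",
    PhysicalSizeZUnit = "um",
    TimeIncrement = series$frame_interval_h, TimeIncrementUnit = "h",
    TimeOrigin = series$origin_h)
  for (k in seq_len(d[2]))
    xml2::xml_add_child(pix, "Channel", ID = paste0("Channel:0:", k - 1L),
                        Name = series$channel_names[k])
  doc
}

#' Read a calibrated image series from TIFF
#'
#' Reads a multi-page TIFF written by [write_series()], reconstructing the
#' `(time, channel, z, y, x)` array from the OME-XML companion file. A plain
#' TIFF without a companion is interpreted as a single-timepoint,
#' single-channel z-stack and given the supplied default calibration, with a
#' warning.
#'
#' @param path TIFF path.
#' @param default_voxel_size fallback `(dx, dy, dz)` in um when no metadata
#'   is found (platform default 0.3225 x 0.3225 x 0.5).
#' @param default_frame_interval_h fallback frame interval, hours.
#' @param default_origin_h fallback first-frame time label, hours.
#' @return A [volume_series()].
#' @export
read_series <- function(path,
                        default_voxel_size = c(0.3225, 0.3225, 0.5),
                        default_frame_interval_h = 24,
                        default_origin_h = 24) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]      # grey stored as RGB
    round(p * 65535)
  })
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  comp <- companion_path(path)
  if (file.exists(comp)) {
    meta <- parse_ome_companion(comp)
    if (meta$size_x != nx || meta$size_y != ny)
      stop("metadata/pixel shape mismatch in '", path, "'")
    n_expect <- meta$size_t * meta$size_c * meta$size_z
    if (n_expect != length(pages))
      stop("axis order not inferable: companion declares ",
           n_expect, " planes (T*C*Z) but TIFF holds ", length(pages))
    arr <- array(0, dim = c(meta$size_t, meta$size_c, meta$size_z, ny, nx))
    i <- 0L
    for (t in seq_len(meta$size_t)) for (ch in seq_len(meta$size_c))
      for (z in seq_len(meta$size_z)) {
        i <- i + 1L
        arr[t, ch, z, , ] <- pages[[i]]
      }
    volume_series(arr, voxel_size = meta$voxel_size,
                  frame_interval_h = meta$frame_interval_h,
                  channel_names = meta$channel_names,
                  origin_h = meta$origin_h)
  } else {
    warning("no calibration metadata found for '", path,
            "'; assuming a single-timepoint single-channel z-stack ",
            "with default voxel size ",
            paste(default_voxel_size, collapse = " x "), " um")
    arr <- array(0, dim = c(1L, 1L, length(pages), ny, nx))
    for (z in seq_along(pages)) arr[1, 1, z, , ] <- pages[[z]]
    volume_series(arr, voxel_size = default_voxel_size,
                  frame_interval_h = default_frame_interval_h,
                  origin_h = default_origin_h)
  }
}

parse_ome_companion <- function(comp) {
  doc <- xml2::read_xml(comp)
  xml2::xml_ns_strip(doc)
  pix <- xml2::xml_find_first(doc, ".//Pixels")
  att <- function(a) xml2::xml_attr(pix, a)
  dimord <- att("DimensionOrder")
  if (!identical(dimord, "XYZCT"))
    stop("axis order not inferable: unsupported DimensionOrder '",
         dimord, "' (expected XYZCT)")
  list(size_x = as.integer(att("SizeX")), size_y = as.integer(att("SizeY")),
       size_z = as.integer(att("SizeZ")), size_c = as.integer(att("SizeC")),
       size_t = as.integer(att("SizeT")),
       voxel_size = as.numeric(c(att("PhysicalSizeX"), att("PhysicalSizeY"),
                                 att("PhysicalSizeZ"))),
       frame_interval_h = as.numeric(att("TimeIncrement")),
       origin_h = as.numeric(att("TimeOrigin")),
       channel_names = xml2::xml_attr(
         xml2::xml_find_all(pix, ".//Channel"), "Name"))
}

#' Stitch a grid of projection tiles into a mosaic
#'
#' Tiles are laid out row-major on a `(rows, cols)` grid with a fixed
#' fractional overlap between neighbours; overlap zones are blended by
#' linear feathering (each tile's weight ramps linearly to zero towards an
#' interior edge), so identical overlapping content is recovered exactly.
#'
#' @param tiles list of [projection()]s, row-major, all the same shape and
#'   calibration.
#' @param grid integer `(rows, cols)`; `rows * cols` must equal the tile
#'   count.
#' @param overlap_fraction fraction of tile width/height shared with each
#'   neighbour (0 = abutting).
#' @return A [projection()] of the mosaic.
#' @export
stitch_tiles <- function(tiles, grid, overlap_fraction = 0.1) {
  stopifnot(is.list(tiles), length(grid) == 2L)
  rows <- grid[1]; cols <- grid[2]
  if (rows * cols != length(tiles))
    stop("grid size does not match the number of tiles")
  shapes <- vapply(tiles, function(t) dim(t$pixels), integer(2))
  if (any(shapes != shapes[, 1])) stop("inconsistent tile shapes")
  h <- shapes[1, 1]; w <- shapes[2, 1]
  oy <- round(h * overlap_fraction); ox <- round(w * overlap_fraction)
  step_y <- h - oy; step_x <- w - ox
  H <- rows * h - (rows - 1) * oy; W <- cols * w - (cols - 1) * ox
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  feather <- function(n, ov, at_start, at_end) {
    wgt <- rep(1, n)
    if (ov > 0) {
      ramp <- seq_len(ov) / (ov + 1)
      if (at_start) wgt[seq_len(ov)] <- pmin(wgt[seq_len(ov)], ramp)
      if (at_end) wgt[n - ov + seq_len(ov)] <-
          pmin(wgt[n - ov + seq_len(ov)], rev(ramp))
    }
    wgt
  }
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    tile <- tiles[[(r - 1) * cols + cc]]$pixels
    wy <- feather(h, oy, r > 1, r < rows)
    wx <- feather(w, ox, cc > 1, cc < cols)
    wgt <- outer(wy, wx)
    ys <- (r - 1) * step_y + seq_len(h)
    xs <- (cc - 1) * step_x + seq_len(w)
    num[ys, xs] <- num[ys, xs] + wgt * tile
    den[ys, xs] <- den[ys, xs] + wgt
  }
  out <- num
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  projection(out, pixel_size = tiles[[1]]$pixel_size,
             timepoint_h = tiles[[1]]$timepoint_h,
             channel = tiles[[1]]$channel)
}

#' Split a projection into an overlapping tile grid
#'
#' Inverse of [stitch_tiles()] for testing and for mosaicking workflows:
#' cuts a projection into a `(rows, cols)` row-major grid of tiles with
#' the given fractional overlap.
#'
#' @inheritParams stitch_tiles
#' @param proj the [projection()] to split.
#' @return list of tiles (row-major).
#' @export
split_tiles <- function(proj, grid, overlap_fraction = 0.1) {
  stopifnot(inherits(proj, "Projection"))
  rows <- grid[1]; cols <- grid[2]
  H <- nrow(proj$pixels); W <- ncol(proj$pixels)
  # tile size such that rows*h - (rows-1)*oy = H with oy = round(h*ov)
  solve_h <- function(total, n, ov) {
    for (sz in seq_len(total)) {
      o <- round(sz * ov)
      if (n * sz - (n - 1) * o == total) return(sz)
    }
    stop("no integer tile size fits this grid/overlap")
  }
  h <- solve_h(H, rows, overlap_fraction)
  w <- solve_h(W, cols, overlap_fraction)
  oy <- round(h * overlap_fraction); ox <- round(w * overlap_fraction)
  tiles <- vector("list", rows * cols)
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    ys <- (r - 1) * (h - oy) + seq_len(h)
    xs <- (cc - 1) * (w - ox) + seq_len(w)
    tiles[[(r - 1) * cols + cc]] <-
      projection(proj$pixels[ys, xs, drop = FALSE],
                 pixel_size = proj$pixel_size,
                 timepoint_h = proj$timepoint_h, channel = proj$channel)
  }
  tiles
}

#' Translation registration by phase correlation
#'
#' Estimates the integer-pixel translation that maps `moving` onto
#' `reference` by locating the peak of the normalised cross-power spectrum
#' (phase correlation). Constant images yield a zero shift with a warning.
#'
#' @param reference,moving `Projection`s of identical shape and calibration.
#' @return list with `shift_px` `(dy, dx)` in pixels and `shift_um`
#'   `(dy, dx)` in micrometres: the displacement of `moving` relative to
#'   `reference` (positive dy/dx = moved down/right); translating `moving`
#'   by the negated shift aligns it onto `reference`.
#' @export
register_translation <- function(reference, moving) {
  stopifnot(inherits(reference, "Projection"), inherits(moving, "Projection"))
  a <- reference$pixels; b <- moving$pixels
  if (!all(dim(a) == dim(b))) stop("projections must have identical shape")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("degenerate (constant) image; returning zero shift")
    shift <- c(dy = 0, dx = 0)
  } else {
    fa <- fft(a); fb <- fft(b)
    cp <- fa * Conj(fb)
    mag <- Mod(cp)
    mag[mag == 0] <- 1
    r <- Re(fft(cp / mag, inverse = TRUE))
    pk <- which(r == max(r), arr.ind = TRUE)[1, ]
    nr <- nrow(a); nc <- ncol(a)
    dy <- unname(pk[1]) - 1; dx <- unname(pk[2]) - 1
    if (dy > nr / 2) dy <- dy - nr
    if (dx > nc / 2) dx <- dx - nc
    # the correlation peak sits at minus the displacement of `moving`
    shift <- c(dy = -dy, dx = -dx)
  }
  list(shift_px = shift,
       shift_um = shift * reference$pixel_size[c("dy", "dx")])
}

translate_pixels <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  ys_to <- ys + dy; xs_to <- xs + dx
  ky <- ys_to >= 1 & ys_to <= nrow(m); kx <- xs_to >= 1 & xs_to <= ncol(m)
  out[ys_to[ky], xs_to[kx]] <- m[ys[ky], xs[kx]]
  out
}

#' Align a time series of projections to its first frame
#'
#' Registers each consecutive frame pair by phase correlation, chains the
#' pairwise displacements cumulatively relative to the first timepoint, and
#' applies the negated integer-pixel translations (zero fill at the exposed
#' border) so every frame sits in the first frame's coordinates.
#'
#' @param projections list of `Projection`s over time, same shape.
#' @return list with `aligned` (list of shifted `Projection`s) and `shifts`
#'   (data frame: timepoint_h, dy_px, dx_px, dy_um, dx_um — each frame's
#'   cumulative drift relative to the first timepoint).
#' @export
align_series <- function(projections) {
  stopifnot(length(projections) >= 1L)
  n <- length(projections)
  cum <- matrix(0, n, 2)
  for (k in seq_len(n)[-1]) {
    step <- register_translation(projections[[k - 1]], projections[[k]])$shift_px
    cum[k, ] <- cum[k - 1, ] + step
  }
  aligned <- vector("list", n)
  for (k in seq_len(n)) {
    p <- projections[[k]]
    aligned[[k]] <- projection(
      translate_pixels(p$pixels, -cum[k, 1], -cum[k, 2]),
      pixel_size = p$pixel_size, timepoint_h = p$timepoint_h,
      channel = p$channel)
  }
  shifts <- data.frame(
    timepoint_h = vapply(projections, function(p) p$timepoint_h, numeric(1)),
    dy_px = cum[, 1], dx_px = cum[, 2],
    dy_um = cum[, 1] * projections[[1]]$pixel_size[["dy"]],
    dx_um = cum[, 2] * projections[[1]]$pixel_size[["dx"]])
  list(aligned = aligned, shifts = shifts)
}
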