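#' Segmentation configuration
#'
#' Parameters for normalised-threshold segmentation of single cells in a
#' 2-D projection.
#'
#' @param normalize_percentile robust-maximum percentile used to scale
#'   intensities into `[0, 1]` (must lie in (50, 100]).
#' @param threshold_fraction fraction of the normalised range above which a
#'   pixel is foreground (in (0, 1)).
#' @param min_area_um2,max_area_um2 retained component area range in square
#'   micrometres. The 20 um2 minimum is this package's default, not a
#'   published value.
#' @param min_mean_intensity optional minimum mean raw intensity (a.u.) of a
#'   component.
#' @param method `"fraction"` (fixed fraction of the normalised range,
#'   default) or `"otsu"` (Otsu's threshold on the normalised image, for
#'   comparison).
#' @return A `SegmentConfig` list.
#' @export
segment_config <- function(normalize_percentile = 99.9,
                           threshold_fraction = 0.2,
                           min_area_um2 = 20,
                           max_area_um2 = Inf,
                           min_mean_intensity = NULL,
                           method = c("fraction", "otsu")) {
  if (!(normalize_percentile > 50 && normalize_percentile <= 100))
    stop("`normalize_percentile` must be in (50, 100]")
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop("`threshold_fraction` must be in (0, 1)")
  if (min_area_um2 < 0) stop("`min_area_um2` must be nonnegative")
  if (max_area_um2 < min_area_um2) stop("empty area range")
  structure(list(normalize_percentile = normalize_percentile,
                 threshold_fraction = threshold_fraction,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 min_mean_intensity = min_mean_intensity,
                 method = match.arg(method)),
            class = "SegmentConfig")
}

#' Normalise a projection to the unit range
#'
#' Scales intensities by the configured robust maximum (a high percentile of
#' the pixel distribution) and clips to `[0, 1]`, making downstream
#' thresholding invariant to global intensity rescaling. An all-zero image
#' is returned unchanged with a warning.
#'
#' @param proj a [projection()].
#' @param percentile robust-maximum percentile (default 99.9).
#' @return A [projection()] with pixels in `[0, 1]`.
#' @export
normalize_projection <- function(proj, percentile = 99.9) {
  stopifnot(inherits(proj, "Projection"))
  q <- quantile(proj$pixels, percentile / 100, names = FALSE)
  if (q <= 0) {
    warning("image has no positive signal at the normalisation percentile; ",
            "returning zeros")
    out <- proj$pixels * 0
  } else {
    out <- pmin(proj$pixels / q, 1)
  }
  projection(out, pixel_size = proj$pixel_size,
             timepoint_h = proj$timepoint_h, channel = proj$channel)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge label
# pairs that touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  if (nrow(pairs) > 0) {
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(pairs))) {
        ra <- pairs[k, 1]; rb <- pairs[k, 2]
        while (parent[ra] != ra) ra <- parent[ra]
        while (parent[rb] != rb) rb <- parent[rb]
        if (ra != rb) { parent[max(ra, rb)] <- min(ra, rb); changed <- TRUE }
      }
      if (!changed) break
    }
  }
  root <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

otsu_threshold <- function(x) {
  # Otsu on 256-bin histogram of values in [0, 1]
  h <- tabulate(pmin(floor(x * 255) + 1L, 256L), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 1) / 255
}

#' Segment cells in a projection
#'
#' Normalised thresholding followed by 8-connected component labelling and
#' size/intensity filtering. The binary mask is `normalised >= threshold`;
#' components with calibrated area outside `[min_area_um2, max_area_um2]`
#' or mean raw intensity below `min_mean_intensity` are discarded. Centroids
#' are intensity-weighted (raw intensities), in micrometres, so bright
#' somata dominate over dim neurites.
#'
#' @param proj calibrated [projection()].
#' @param config a [segment_config()].
#' @return A data frame of detections (one row per retained object):
#'   `timepoint_h, label, x_um, y_um, area_um2, area_px, mean_intensity,
#'   xmin_px, xmax_px, ymin_px, ymax_px`, with the filtered label matrix in
#'   attribute `"labels"` (0 = background).
#' @export
segment_cells <- function(proj, config = segment_config()) {
  stopifnot(inherits(proj, "Projection"), inherits(config, "SegmentConfig"))
  dx <- proj$pixel_size[["dx"]]; dy <- proj$pixel_size[["dy"]]
  px_area_um2 <- dx * dy
  norm <- suppressWarnings(
    normalize_projection(proj, config$normalize_percentile))
  thr <- if (config$method == "otsu") otsu_threshold(norm$pixels)
         else config$threshold_fraction
  mask <- norm$pixels >= thr & norm$pixels > 0
  empty <- function() {
    out <- data.frame(timepoint_h = numeric(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0),
                      xmin_px = integer(0), xmax_px = integer(0),
                      ymin_px = integer(0), ymax_px = integer(0))
    attr(out, "labels") <- matrix(0L, nrow(proj$pixels), ncol(proj$pixels))
    out
  }
  if (!any(mask)) return(empty())
  lab <- label_components8(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  inten <- proj$pixels[lab > 0]
  area_px <- tabulate(labs)
  # intensity-weighted centroids at pixel centres: coord = (index - 0.5) * d
  wsum <- tapply(inten, labs, sum)
  wx <- tapply(inten * (idx[, 2] - 0.5) * dx, labs, sum) / wsum
  wy <- tapply(inten * (idx[, 1] - 0.5) * dy, labs, sum) / wsum
  mean_int <- tapply(inten, labs, mean)
  keep <- area_px * px_area_um2 >= config$min_area_um2 &
          area_px * px_area_um2 <= config$max_area_um2
  if (!is.null(config$min_mean_intensity))
    keep <- keep & mean_int >= config$min_mean_intensity
  keep_ids <- which(keep)
  if (length(keep_ids) == 0L) return(empty())
  relab <- integer(max(labs)); relab[keep_ids] <- seq_along(keep_ids)
  out_lab <- lab
  out_lab[lab > 0] <- relab[labs]
  bb <- function(f, col) vapply(keep_ids, function(i) f(idx[labs == i, col]),
                                numeric(1))
  out <- data.frame(
    timepoint_h = proj$timepoint_h,
    label = seq_along(keep_ids),
    x_um = as.numeric(wx[keep_ids]), y_um = as.numeric(wy[keep_ids]),
    area_um2 = area_px[keep_ids] * px_area_um2,
    area_px = area_px[keep_ids],
    mean_intensity = as.numeric(mean_int[keep_ids]),
    xmin_px = as.integer(bb(min, 2)), xmax_px = as.integer(bb(max, 2)),
    ymin_px = as.integer(bb(min, 1)), ymax_px = as.integer(bb(max, 1)))
  attr(out, "labels") <- out_lab
  out
}

#' Mean intensity of labelled objects in another channel
#'
#' Samples a second channel's projection under an existing label matrix,
#' returning the mean intensity of each label. Used to attach per-channel
#' intensities to detections segmented on the morphology channel.
#'
#' @param labels integer label matrix (0 = background), e.g. the
#'   `"labels"` attribute of [segment_cells()].
#' @param proj a [projection()] of identical shape.
#' @return numeric vector of mean intensities indexed by label.
#' @export
measure_labels <- function(labels, proj) {
  stopifnot(inherits(proj, "Projection"),
            all(dim(labels) == dim(proj$pixels)))
  n <- max(labels)
  if (n == 0L) return(numeric(0))
  as.numeric(tapply(proj$pixels[labels > 0], labels[labels > 0], mean))
}
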