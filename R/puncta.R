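#' Puncta analysis configuration
#'
#' Parameters of inclusion-body particle detection inside neuron masks.
#' The reporter image is masked, min-max rescaled to 8-bit, thresholded on
#' the 5-255 range, and connected components of at least
#' `min_particle_area_um2` (calibrated square micrometres) become puncta.
#' Puncta strictly below `small_large_boundary_um2` (80 um2) are "small";
#' 80 um2 and above are "large" — the boundary itself is assigned to the
#' large class so the two classes partition all areas.
#'
#' @param min_particle_area_um2 minimum particle area, um2 (default 10).
#' @param small_large_boundary_um2 small/large class boundary (default 80).
#' @param threshold_low,threshold_high inclusive foreground range on the
#'   8-bit scale (defaults 5 and 255).
#' @param pixel_units if `TRUE`, `min_particle_area_um2` is interpreted in
#'   pixels instead of calibrated um2.
#' @return A `PunctaConfig` list.
#' @export
puncta_config <- function(min_particle_area_um2 = 10,
                          small_large_boundary_um2 = 80,
                          threshold_low = 5, threshold_high = 255,
                          pixel_units = FALSE) {
  if (!(min_particle_area_um2 > 0 &&
        min_particle_area_um2 < small_large_boundary_um2))
    stop("need 0 < min_particle_area < small/large boundary")
  if (!(threshold_low < threshold_high))
    stop("`threshold_low` must be below `threshold_high`")
  structure(list(min_particle_area_um2 = min_particle_area_um2,
                 small_large_boundary_um2 = small_large_boundary_um2,
                 threshold_low = threshold_low,
                 threshold_high = threshold_high,
                 pixel_units = isTRUE(pixel_units)),
            class = "PunctaConfig")
}

#' Neuron mask from the morphology channel
#'
#' Segments the morphology projection with [segment_cells()] and returns
#' the union of retained components as a binary mask, with the per-cell
#' label map and the detections for linking mask regions to track IDs.
#' An empty segmentation yields an empty mask (valid, not an error).
#'
#' @param morphology_proj calibrated morphology-channel [projection()].
#' @param config a [segment_config()].
#' @return list: `mask` (logical matrix), `labels` (integer label matrix),
#'   `detections` (the [segment_cells()] table).
#' @export
neuron_mask <- function(morphology_proj, config = segment_config()) {
  det <- segment_cells(morphology_proj, config)
  labels <- attr(det, "labels")
  list(mask = labels > 0, labels = labels, detections = det)
}

#' Detect puncta in a masked reporter projection
#'
#' Zeroes reporter signal outside the neuron mask, min-max rescales the
#' masked image to 8-bit (0-255), keeps pixels whose value lies in the
#' configured threshold range, labels 8-connected components, and retains
#' those at or above the minimum particle area. Each punctum is assigned
#' to the neuron-mask label containing its centroid (`owner_label` 0 if
#' the labels map is not supplied).
#'
#' @param reporter_proj calibrated reporter-channel [projection()].
#' @param mask logical neuron mask of identical shape (see
#'   [neuron_mask()]).
#' @param config a [puncta_config()].
#' @param labels optional integer label matrix linking mask pixels to
#'   cells.
#' @return data frame of puncta: `timepoint_h, punctum_label, x_um, y_um,
#'   area_um2, mean_8bit, owner_label, size_class`.
#' @export
detect_puncta <- function(reporter_proj, mask, config = puncta_config(),
                          labels = NULL) {
  stopifnot(inherits(reporter_proj, "Projection"),
            inherits(config, "PunctaConfig"))
  if (!all(dim(mask) == dim(reporter_proj$pixels)))
    stop("mask and projection geometry differ")
  dx <- reporter_proj$pixel_size[["dx"]]
  dy <- reporter_proj$pixel_size[["dy"]]
  px_area <- dx * dy
  img <- reporter_proj$pixels
  img[!mask] <- 0
  empty <- data.frame(timepoint_h = numeric(0), punctum_label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_8bit = numeric(0),
                      owner_label = integer(0), size_class = character(0))
  if (!any(mask)) return(empty)
  rng <- range(img[mask])       # min-max of the masked signal, FIJI-style
  if (rng[2] <= rng[1]) return(empty)
  img8 <- round((img - rng[1]) / (rng[2] - rng[1]) * 255)
  fg <- img8 >= config$threshold_low & img8 <= config$threshold_high & mask
  if (!any(fg)) return(empty)
  lab <- label_components8(fg)
  labs <- lab[lab > 0]
  idx <- which(lab > 0, arr.ind = TRUE)
  area_px <- tabulate(labs)
  min_area_px <- if (config$pixel_units) config$min_particle_area_um2
                 else config$min_particle_area_um2 / px_area
  keep <- which(area_px >= min_area_px)
  if (!length(keep)) return(empty)
  v8 <- img8[lab > 0]
  cx <- tapply((idx[, 2] - 0.5) * dx, labs, mean)
  cy <- tapply((idx[, 1] - 0.5) * dy, labs, mean)
  m8 <- tapply(v8, labs, mean)
  owner <- vapply(keep, function(i) {
    if (is.null(labels)) return(0L)
    px <- round(cx[[i]] / dx + 0.5); py <- round(cy[[i]] / dy + 0.5)
    px <- min(max(px, 1), ncol(labels)); py <- min(max(py, 1), nrow(labels))
    as.integer(labels[py, px])
  }, integer(1))
  out <- data.frame(
    timepoint_h = reporter_proj$timepoint_h,
    punctum_label = seq_along(keep),
    x_um = as.numeric(cx[keep]), y_um = as.numeric(cy[keep]),
    area_um2 = area_px[keep] * px_area,
    mean_8bit = as.numeric(m8[keep]),
    owner_label = owner)
  out$size_class <- classify_size(out$area_um2, config)
  out
}

#' Classify puncta by area
#'
#' Small iff area < 80 um2 (strict); areas at or above the boundary are
#' large, so the classes partition every area.
#'
#' @param area_um2 numeric vector of punctum areas.
#' @param config a [puncta_config()].
#' @return character vector, `"small"` or `"large"`.
#' @export
classify_size <- function(area_um2, config = puncta_config()) {
  ifelse(area_um2 < config$small_large_boundary_um2, "small", "large")
}

#' Match puncta across timepoints within cells
#'
#' A punctum observed at one timepoint is considered the same object as one
#' at the previous timepoint when both lie in the same cell and their
#' centroids are within `match_radius_um`; unmatched puncta are first
#' appearances. This makes "cumulative formation" well defined.
#'
#' @param puncta data frame from [detect_puncta()] over several timepoints
#'   (must carry `owner_label` or `cell_id`).
#' @param match_radius_um matching radius, um (one soma radius by default).
#' @return the puncta table with `punctum_id` and `first_seen` columns
#'   added.
#' @export
match_puncta <- function(puncta, match_radius_um = 8) {
  key <- if ("cell_id" %in% names(puncta)) "cell_id" else "owner_label"
  tps <- sort(unique(puncta$timepoint_h))
  puncta$punctum_id <- NA_integer_
  puncta$first_seen <- FALSE
  next_id <- 1L
  prev <- NULL
  for (t in tps) {
    cur <- which(puncta$timepoint_h == t)
    for (j in cur) {
      matched <- NA_integer_
      if (!is.null(prev) && length(prev)) {
        cand <- prev[puncta[[key]][prev] == puncta[[key]][j]]
        if (length(cand)) {
          d <- sqrt((puncta$x_um[cand] - puncta$x_um[j])^2 +
                    (puncta$y_um[cand] - puncta$y_um[j])^2)
          if (min(d) <= match_radius_um)
            matched <- puncta$punctum_id[cand[which.min(d)]]
        }
      }
      if (is.na(matched)) {
        puncta$punctum_id[j] <- next_id
        puncta$first_seen[j] <- TRUE
        next_id <- next_id + 1L
      } else puncta$punctum_id[j] <- matched
    }
    prev <- cur
  }
  puncta
}

#' Group comparison of cumulative puncta accumulation
#'
#' Builds (or accepts) per-slice cumulative small-puncta count series,
#' compares groups at the final timepoint with a two-sample t-test, and
#' compares accumulation rates with the shared ANCOVA slope test
#' ([compare_slopes_ancova()]).
#'
#' @param slice_series data frame: `slice_id, group, timepoint_h,
#'   cumulative_count` (e.g. from [simulate_puncta_accumulation()] or from
#'   counting first appearances of matched puncta per slice).
#' @return list: `endpoint` (t-test result: `t, p, mean_a, mean_b`),
#'   `rates` (ANCOVA list from [compare_slopes_ancova()]), `groups`
#'   (labels), `per_slice_final` (final counts).
#' @export
accumulation_analysis <- function(slice_series) {
  stopifnot(all(c("slice_id", "group", "timepoint_h", "cumulative_count")
                %in% names(slice_series)))
  groups <- sort(unique(slice_series$group))
  if (length(groups) != 2) stop("need exactly two groups")
  tmax <- max(slice_series$timepoint_h)
  fin <- slice_series[slice_series$timepoint_h == tmax, ]
  n_per <- table(fin$group)
  if (any(n_per < 2)) {
    warning("a group has a single slice; endpoint t-test refused")
    endpoint <- NULL
  } else {
    tt <- t.test(cumulative_count ~ group, data = fin)
    endpoint <- list(t = unname(tt$statistic), p = tt$p.value,
                     mean_a = tt$estimate[[1]], mean_b = tt$estimate[[2]])
  }
  g <- function(gr) {
    d <- slice_series[slice_series$group == gr, ]
    data.frame(time_h = d$timepoint_h, value = d$cumulative_count)
  }
  rates <- compare_slopes_ancova(g(groups[1]), g(groups[2]), labels = groups)
  list(endpoint = endpoint, rates = rates, groups = groups,
       per_slice_final = fin[, c("slice_id", "group", "cumulative_count")])
}
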