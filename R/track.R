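#' Tracker configuration
#'
#' Parameters of the proximity-based longitudinal tracker. The distance
#' cutoff defaults to 64.5 um, the furthest a cell is expected to travel
#' between 24 h imaging sessions; a candidate exactly at the cutoff links
#' (the cutoff is the maximum allowed move, inclusive).
#'
#' @param d_max_um hard distance cutoff in micrometres (default 64.5).
#' @param one_to_one if `TRUE` (default), two detections may not inherit the
#'   same previous-frame ID: competing claims are resolved in ascending
#'   distance order and losers receive fresh IDs. With `FALSE` the raw
#'   per-object closest-predecessor rule is applied, which can duplicate
#'   IDs; this mode exists for oracle comparisons.
#' @param initial_closest_distance_um starting value of the closest-distance
#'   search variable; `NULL` (default) means the longest image dimension in
#'   micrometres (effectively unbounded).
#' @return A `TrackerConfig` list.
#' @export
tracker_config <- function(d_max_um = 64.5, one_to_one = TRUE,
                           initial_closest_distance_um = NULL) {
  if (d_max_um <= 0) stop("`d_max_um` must be positive")
  structure(list(d_max_um = d_max_um, one_to_one = isTRUE(one_to_one),
                 initial_closest_distance_um = initial_closest_distance_um),
            class = "TrackerConfig")
}

#' Link one frame's detections to the previous frame's cell IDs
#'
#' For each detection in the next frame, the nearest previous-frame
#' detection is found by scanning previous objects in ascending cell-ID
#' order, starting the closest-distance variable at
#' `initial_closest_distance_um` and updating it whenever a strictly closer
#' object is found (ties therefore resolve to the lowest previous ID). If
#' the final closest distance is within the cutoff `d_max_um` the previous
#' ID is inherited, otherwise the detection is flagged as new. With
#' `one_to_one` enabled, claims on one previous ID are granted in ascending
#' distance order and losing detections are flagged new.
#'
#' @param prev data frame of previous-frame detections with columns
#'   `cell_id`, `x_um`, `y_um` (may have zero rows: every next detection is
#'   then new).
#' @param nxt data frame of next-frame detections with columns `x_um`,
#'   `y_um`.
#' @param config a [tracker_config()].
#' @return data frame, one row per `nxt` row: `cell_id` (inherited ID, or
#'   `NA` for a new cell), `distance_um` (distance to the matched previous
#'   detection, `NA` if none within reach), `new` (logical).
#' @export
link_frames <- function(prev, nxt, config = tracker_config()) {
  stopifnot(inherits(config, "TrackerConfig"))
  n_next <- nrow(nxt)
  out <- data.frame(cell_id = rep(NA_integer_, n_next),
                    distance_um = rep(NA_real_, n_next),
                    new = rep(TRUE, n_next))
  if (n_next == 0L || is.null(prev) || nrow(prev) == 0L) return(out)
  if (anyNA(prev$x_um) || anyNA(nxt$x_um))
    stop("detections carry missing coordinates (uncalibrated input?)")
  init <- config$initial_closest_distance_um
  if (is.null(init)) init <- Inf
  ord <- order(prev$cell_id)
  px <- prev$x_um[ord]; py <- prev$y_um[ord]; pid <- prev$cell_id[ord]
  # vectorised scan over previous objects in ascending-ID order: the first
  # strict minimum wins, reproducing the closest-distance-variable update
  # rule (ties resolve to the lowest previous ID)
  D <- sqrt(outer(nxt$x_um, px, "-")^2 + outer(nxt$y_um, py, "-")^2)
  hit <- max.col(-D, ties.method = "first")
  closest <- D[cbind(seq_len(n_next), hit)]
  ok <- closest < init & closest <= config$d_max_um
  best_id <- ifelse(ok, pid[hit], NA_integer_)
  best_d <- ifelse(ok, closest, NA_real_)
  if (config$one_to_one) {
    claimed <- integer(0)
    for (j in order(best_d, seq_len(n_next), na.last = TRUE)) {
      if (is.na(best_id[j])) next
      if (best_id[j] %in% claimed) { best_id[j] <- NA; best_d[j] <- NA }
      else claimed <- c(claimed, best_id[j])
    }
  }
  out$cell_id <- best_id
  out$distance_um <- best_d
  out$new <- is.na(best_id)
  out
}

#' Build longitudinal tracks from per-timepoint detections
#'
#' Initialises every first-frame object with a unique cell ID, then applies
#' [link_frames()] to each consecutive frame pair: matched detections
#' inherit the previous ID, unmatched ones open new tracks. A track whose ID
#' is claimed by no detection at the next frame is closed; objects that
#' reappear later start fresh IDs (no gap closing, no motion model, no
#' division linking). Linking uses 2-D projection centroids only.
#'
#' @param detections data frame with columns `timepoint_h`, `x_um`, `y_um`
#'   (plus any measurement columns, which are carried through), all from one
#'   aligned imaging well/field.
#' @param config a [tracker_config()].
#' @param first_id first cell ID to issue (default 1).
#' @return the detections data frame with columns `cell_id` and
#'   `link_distance_um` prepended, class `"track_table"`; the tracker config
#'   is attached as attribute `"tracker_config"`.
#' @export
build_tracks <- function(detections, config = tracker_config(),
                         first_id = 1L) {
  stopifnot(is.data.frame(detections),
            all(c("timepoint_h", "x_um", "y_um") %in% names(detections)))
  tps <- sort(unique(detections$timepoint_h))
  next_id <- as.integer(first_id)
  if (nrow(detections) == 0L) {
    res <- cbind(data.frame(cell_id = integer(0),
                            link_distance_um = numeric(0)), detections)
    class(res) <- c("track_table", "data.frame")
    attr(res, "tracker_config") <- config
    return(res)
  }
  frames <- lapply(tps, function(t)
    detections[detections$timepoint_h == t, , drop = FALSE])
  out <- vector("list", length(tps))
  prev <- NULL
  for (k in seq_along(tps)) {
    fr <- frames[[k]]
    if (k == 1L || is.null(prev) || nrow(prev) == 0L) {
      ids <- if (nrow(fr)) next_id + seq_len(nrow(fr)) - 1L else integer(0)
      next_id <- next_id + nrow(fr)
      dist <- rep(NA_real_, nrow(fr))
    } else {
      lk <- link_frames(prev, fr, config)
      ids <- lk$cell_id
      n_new <- sum(lk$new)
      ids[lk$new] <- next_id + seq_len(n_new) - 1L
      next_id <- next_id + n_new
      dist <- lk$distance_um
    }
    out[[k]] <- cbind(data.frame(cell_id = ids, link_distance_um = dist), fr)
    prev <- data.frame(cell_id = ids, x_um = fr$x_um, y_um = fr$y_um)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("track_table", "data.frame")
  attr(res, "tracker_config") <- config
  res
}

#' Per-timepoint tracked-cell counts
#'
#' @param tracks a track table from [build_tracks()].
#' @return data frame per timepoint: `timepoint_h`, `n_active` (tracks with
#'   a detection at that frame) and `n_cumulative` (distinct IDs first seen
#'   at or before that frame).
#' @export
count_tracked <- function(tracks) {
  stopifnot(is.data.frame(tracks), "cell_id" %in% names(tracks))
  tps <- sort(unique(tracks$timepoint_h))
  first_seen <- tapply(tracks$timepoint_h, tracks$cell_id, min)
  data.frame(
    timepoint_h = tps,
    n_active = vapply(tps, function(t)
      sum(tracks$timepoint_h == t), integer(1)),
    n_cumulative = vapply(tps, function(t)
      sum(first_seen <= t), integer(1)))
}

#' Track summaries (first/last seen, length)
#'
#' @param tracks a track table from [build_tracks()].
#' @return data frame per cell ID: `cell_id`, `first_seen_h`, `last_seen_h`,
#'   `n_detections`.
#' @export
track_summary <- function(tracks) {
  ids <- sort(unique(tracks$cell_id))
  data.frame(
    cell_id = ids,
    first_seen_h = as.numeric(tapply(tracks$timepoint_h, tracks$cell_id, min)[as.character(ids)]),
    last_seen_h = as.numeric(tapply(tracks$timepoint_h, tracks$cell_id, max)[as.character(ids)]),
    n_detections = as.integer(table(tracks$cell_id)[as.character(ids)]))
}
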