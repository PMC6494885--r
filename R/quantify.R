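#' Motility classification configuration
#'
#' A tracked cell is called motile when the maximum centroid separation
#' between any two of its detections exceeds a multiple of its soma length
#' (strictly greater — "more than"). The soma length is defined as the
#' equivalent-circle diameter of the track's median detection area, which is
#' robust to neurite-driven area fluctuations.
#'
#' @param soma_lengths_threshold multiples of the soma length (default 2).
#' @return A `MotilityConfig` list.
#' @export
motility_config <- function(soma_lengths_threshold = 2) {
  if (soma_lengths_threshold <= 0) stop("threshold must be positive")
  structure(list(soma_lengths_threshold = soma_lengths_threshold),
            class = "MotilityConfig")
}

#' Per-track kinematics
#'
#' Step distances between consecutive detections, net (first-to-last)
#' displacement, total path length, and mean velocity. Tracks with a single
#' detection are flagged (`defined = FALSE`) rather than erred.
#'
#' @param tracks a track table from [build_tracks()] (columns `cell_id`,
#'   `timepoint_h`, `x_um`, `y_um`).
#' @return list with `steps` (data frame: `cell_id, timepoint_h, step_um`,
#'   one row per inter-frame interval, assigned to the interval's later
#'   timepoint) and `per_track` (data frame: `cell_id, n_detections,
#'   path_length_um, net_displacement_um, mean_velocity_um_per_h, max_span_um,
#'   defined`). `max_span_um` is the maximum centroid separation over all
#'   detection pairs.
#' @export
track_kinematics <- function(tracks) {
  stopifnot(all(c("cell_id", "timepoint_h", "x_um", "y_um") %in% names(tracks)))
  sp <- split(tracks[, c("timepoint_h", "x_um", "y_um")], tracks$cell_id)
  steps <- vector("list", length(sp))
  per <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    tr <- sp[[i]][order(sp[[i]]$timepoint_h), ]
    id <- names(sp)[i]
    n <- nrow(tr)
    if (n < 2) {
      per[[i]] <- data.frame(cell_id = as.integer(id), n_detections = n,
                             path_length_um = NA_real_,
                             net_displacement_um = NA_real_,
                             mean_velocity_um_per_h = NA_real_,
                             max_span_um = 0, defined = FALSE)
      next
    }
    dxs <- diff(tr$x_um); dys <- diff(tr$y_um)
    st <- sqrt(dxs^2 + dys^2)
    dts <- diff(tr$timepoint_h)
    span <- max(dist(cbind(tr$x_um, tr$y_um)))
    steps[[i]] <- data.frame(cell_id = as.integer(id),
                             timepoint_h = tr$timepoint_h[-1],
                             step_um = st, interval_h = dts)
    per[[i]] <- data.frame(cell_id = as.integer(id), n_detections = n,
                           path_length_um = sum(st),
                           net_displacement_um = sqrt(
                             (tr$x_um[n] - tr$x_um[1])^2 +
                             (tr$y_um[n] - tr$y_um[1])^2),
                           mean_velocity_um_per_h = sum(st) / sum(dts),
                           max_span_um = span, defined = TRUE)
  }
  steps <- do.call(rbind, steps[!vapply(steps, is.null, logical(1))])
  if (is.null(steps))
    steps <- data.frame(cell_id = integer(0), timepoint_h = numeric(0),
                        step_um = numeric(0), interval_h = numeric(0))
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(cell_id = integer(0), n_detections = integer(0),
                      path_length_um = numeric(0),
                      net_displacement_um = numeric(0),
                      mean_velocity_um_per_h = numeric(0),
                      max_span_um = numeric(0), defined = logical(0))
  rownames(steps) <- NULL
  rownames(per) <- NULL
  list(steps = steps, per_track = per)
}

#' Classify tracks as motile
#'
#' @param tracks a track table from [build_tracks()]; needs an `area_um2`
#'   column to derive the soma length.
#' @param config a [motility_config()].
#' @return data frame per cell: `cell_id, soma_length_um, max_span_um,
#'   motile` (motile iff `max_span_um > threshold * soma_length_um`,
#'   strict).
#' @export
classify_motile <- function(tracks, config = motility_config()) {
  stopifnot(inherits(config, "MotilityConfig"),
            "area_um2" %in% names(tracks))
  kin <- track_kinematics(tracks)$per_track
  med_area <- tapply(tracks$area_um2, tracks$cell_id, median)
  soma_len <- 2 * sqrt(as.numeric(med_area[as.character(kin$cell_id)]) / pi)
  data.frame(cell_id = kin$cell_id,
             soma_length_um = soma_len,
             max_span_um = kin$max_span_um,
             motile = kin$max_span_um >
               config$soma_lengths_threshold * soma_len)
}

trend_result <- function(slope, intercept, r_squared, n,
                         statistic = NA_real_, p_value = NA_real_,
                         units = "") {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n = n, statistic = statistic,
                 p_value = p_value, units = units),
            class = "TrendResult")
}

#' @export
print.TrendResult <- function(x, ...) {
  cat(sprintf("<TrendResult> slope %.4g %s (intercept %.4g, R2 %.3f, n %d)\n",
              x$slope, x$units, x$intercept, x$r_squared, x$n))
  if (!is.na(x$statistic))
    cat(sprintf("  comparison: F = %.3f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Compare two groups' linear time trends (ANCOVA)
#'
#' Fits `value ~ time * group` and reports the F-test of the group x time
#' interaction — the standard common-slope (ANCOVA) comparison of two
#' accumulation or drift rates.
#'
#' @param group_a,group_b data frames with columns `time_h` and `value`.
#' @param labels length-2 character labels for the groups.
#' @return list: `F`, `p`, `df`, `slope_a`, `slope_b`.
#' @export
compare_slopes_ancova <- function(group_a, group_b,
                                  labels = c("a", "b")) {
  stopifnot(nrow(group_a) >= 2, nrow(group_b) >= 2)
  dat <- rbind(
    data.frame(time_h = group_a$time_h, value = group_a$value,
               group = labels[1]),
    data.frame(time_h = group_b$time_h, value = group_b$value,
               group = labels[2]))
  dat$group <- factor(dat$group, levels = labels)  # a = reference slope
  if (length(unique(dat$time_h)) < 2)
    stop("degenerate design: need at least two distinct timepoints")
  fit <- lm(value ~ time_h * group, data = dat)
  an <- suppressWarnings(anova(fit))   # noiseless inputs fit perfectly
  row <- grep(":", rownames(an))
  sl <- coef(fit)
  list(F = an[row, "F value"], p = an[row, "Pr(>F)"],
       df = unname(an[row, "Df"]),
       slope_a = unname(sl["time_h"]),
       slope_b = unname(sl["time_h"] + sl[grep(":", names(sl))]))
}

#' Pooled intensity trend of tracked cells vs background
#'
#' Pools per-cell mean-intensity traces and fits a linear regression of
#' intensity on time; when background traces are supplied, the cell slope is
#' compared against the background slope by ANCOVA (group x time interaction
#' F-test) and the background-subtracted slope is reported.
#'
#' @param cell_traces data frame: `trace_id` (or `cell_id`), `time_h`,
#'   `intensity_au`.
#' @param background_traces optional data frame with the same columns.
#' @return A `TrendResult` (slope in a.u./h); when background is given, the
#'   ANCOVA F and p fill the comparison fields and
#'   `$background_subtracted_slope` holds the slope difference.
#' @export
intensity_trend <- function(cell_traces, background_traces = NULL) {
  ct <- normalise_trace_cols(cell_traces)
  if (length(unique(ct$time_h)) < 3)
    stop("need at least 3 shared timepoints")
  fit <- lm(intensity_au ~ time_h, data = ct)
  s <- suppressWarnings(summary(fit))
  res <- trend_result(slope = unname(coef(fit)["time_h"]),
                      intercept = unname(coef(fit)[1]),
                      r_squared = s$r.squared, n = nrow(ct),
                      units = "a.u./h")
  if (!is.null(background_traces)) {
    bg <- normalise_trace_cols(background_traces)
    cmp <- compare_slopes_ancova(
      data.frame(time_h = ct$time_h, value = ct$intensity_au),
      data.frame(time_h = bg$time_h, value = bg$intensity_au),
      labels = c("cell", "background"))
    res$statistic <- cmp$F
    res$p_value <- cmp$p
    res$background_slope <- cmp$slope_b
    res$background_subtracted_slope <- res$slope - cmp$slope_b
  }
  res
}

normalise_trace_cols <- function(df) {
  if (!"trace_id" %in% names(df) && "cell_id" %in% names(df))
    df$trace_id <- df$cell_id
  stopifnot(all(c("time_h", "intensity_au") %in% names(df)))
  df
}

#' Rate of tracked-cell accumulation (cells/day)
#'
#' Ordinary least-squares slope of the cumulative tracked-cell count
#' against time in days.
#'
#' @param counts the per-timepoint count table from [count_tracked()].
#' @return A `TrendResult` with slope in cells/day.
#' @export
cell_count_rate <- function(counts) {
  stopifnot(all(c("timepoint_h", "n_cumulative") %in% names(counts)))
  if (nrow(counts) < 3) stop("need at least 3 timepoints")
  day <- (counts$timepoint_h - counts$timepoint_h[1]) / 24
  fit <- lm(counts$n_cumulative ~ day)
  s <- suppressWarnings(summary(fit))
  trend_result(slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = s$r.squared, n = nrow(counts),
               units = "cells/day")
}

#' Trend of mean per-interval travel distance (nm/day)
#'
#' "Distance travelled" is the mean per-interval step distance of all
#' tracks at each timepoint (not the cumulative path, which could not
#' decline). Reports the OLS slope of the per-timepoint mean in nm/day,
#' plus a one-way ANOVA over timepoints with Tukey HSD pairwise
#' comparisons on the step distances.
#'
#' @param tracks a track table from [build_tracks()].
#' @return A `TrendResult` (slope in nm/day; ANOVA F and p in the
#'   comparison fields) with extra elements `per_timepoint` (data frame:
#'   `timepoint_h, mean_step_um, n`) and `tukey` (Tukey HSD table over
#'   timepoints).
#' @export
mean_distance_trend <- function(tracks) {
  steps <- track_kinematics(tracks)$steps
  if (nrow(steps) == 0) stop("no multi-detection tracks")
  per_tp <- data.frame(
    timepoint_h = sort(unique(steps$timepoint_h)),
    mean_step_um = as.numeric(tapply(steps$step_um, steps$timepoint_h, mean)),
    n = as.integer(table(steps$timepoint_h)))
  if (nrow(per_tp) < 3) stop("need at least 3 timepoints with steps")
  day <- (per_tp$timepoint_h - per_tp$timepoint_h[1]) / 24
  fit <- lm(per_tp$mean_step_um ~ day)
  s <- suppressWarnings(summary(fit))
  steps$tp <- factor(steps$timepoint_h)
  av <- aov(step_um ~ tp, data = steps)
  an <- suppressWarnings(summary(av))[[1]]
  res <- trend_result(slope = unname(coef(fit)[2]) * 1000,  # um/day -> nm/day
                      intercept = unname(coef(fit)[1]) * 1000,
                      r_squared = s$r.squared, n = nrow(per_tp),
                      statistic = an[1, "F value"],
                      p_value = an[1, "Pr(>F)"],
                      units = "nm/day")
  res$per_timepoint <- per_tp
  res$tukey <- if (nlevels(steps$tp) > 1 &&
                   all(table(steps$tp) > 1)) TukeyHSD(av)$tp else NULL
  res
}
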