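#' Simulation configuration
#'
#' Parameters of the synthetic 4D movie generator. Defaults reproduce the
#' imaging conditions the analysis pipeline is designed for: a confocal
#' voxel of 0.3225 x 0.3225 x 0.5 um, one imaging session every 24 h, an
#' ~8 um soma radius, and a slow linear rise in fluorophore intensity of
#' 0.7 a.u. per hour in stably expressing cells. Death is rendered as a hard
#' step to background at the first frame after the event time (abrupt loss
#' of the freely diffusing morphology marker); arrivals (newly labelled
#' cells) and divisions are Poisson processes.
#'
#' @param seed integer; fully determines all generated output.
#' @param image_shape integer `(n_z, n_y, n_x)` voxels.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param n_timepoints number of imaging sessions.
#' @param frame_interval_h hours between sessions.
#' @param origin_h time label of the first session (hours post
#'   transfection/infection).
#' @param n_cells cells present at the first session.
#' @param neurite_count thin processes rendered per cell.
#' @param soma_radius_um soma radius, um.
#' @param base_intensity_au soma intensity at a cell's birth, a.u.
#' @param intensity_drift_au_per_h linear intensity rise of live cells.
#' @param background_au background level added everywhere.
#' @param noise_sd_au SD of additive Gaussian noise.
#' @param motile_fraction probability that a cell is motile; non-motile
#'   somata are exactly stationary.
#' @param motile_step_um mean per-frame step length of motile cells.
#' @param motile_step_sd_um SD (jitter) of the step length.
#' @param division_rate_per_day per-cell division rate; one daughter is
#'   displaced by one soma diameter (a crude mitotic-somal-translocation
#'   proxy).
#' @param arrival_rate_per_day rate of new labelled cells appearing.
#' @param death_hazard_per_h baseline exponential death hazard.
#' @param group_log_hr log hazard ratio applied to the "disease" group.
#' @param disease_fraction probability a cell belongs to the disease group.
#' @param puncta_rate_per_h inclusion-body puncta formed per cell-hour.
#' @param puncta_area_mean_um2,puncta_area_sd_um2 punctum area distribution
#'   (normal, truncated at 5 um2).
#' @param death_fade_rate fractional intensity fade per hour after death;
#'   0 (default) means the hard step to background.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       image_shape = c(3L, 256L, 256L),
                       voxel_size = c(0.3225, 0.3225, 0.5),
                       n_timepoints = 8L,
                       frame_interval_h = 24,
                       origin_h = 24,
                       n_cells = 3L,
                       neurite_count = 3L,
                       soma_radius_um = 8,
                       base_intensity_au = 100,
                       intensity_drift_au_per_h = 0.7,
                       background_au = 5,
                       noise_sd_au = 2,
                       motile_fraction = 0,
                       motile_step_um = 5,
                       motile_step_sd_um = 0,
                       division_rate_per_day = 0,
                       arrival_rate_per_day = 0,
                       death_hazard_per_h = 0,
                       group_log_hr = 0,
                       disease_fraction = 0,
                       puncta_rate_per_h = 0,
                       puncta_area_mean_um2 = 30,
                       puncta_area_sd_um2 = 15,
                       death_fade_rate = 0) {
  cfg <- list(seed = as.integer(seed),
              image_shape = as.integer(image_shape),
              voxel_size = as.numeric(voxel_size),
              n_timepoints = as.integer(n_timepoints),
              frame_interval_h = frame_interval_h, origin_h = origin_h,
              n_cells = as.integer(n_cells),
              neurite_count = as.integer(neurite_count),
              soma_radius_um = soma_radius_um,
              base_intensity_au = base_intensity_au,
              intensity_drift_au_per_h = intensity_drift_au_per_h,
              background_au = background_au, noise_sd_au = noise_sd_au,
              motile_fraction = motile_fraction,
              motile_step_um = motile_step_um,
              motile_step_sd_um = motile_step_sd_um,
              division_rate_per_day = division_rate_per_day,
              arrival_rate_per_day = arrival_rate_per_day,
              death_hazard_per_h = death_hazard_per_h,
              group_log_hr = group_log_hr,
              disease_fraction = disease_fraction,
              puncta_rate_per_h = puncta_rate_per_h,
              puncta_area_mean_um2 = puncta_area_mean_um2,
              puncta_area_sd_um2 = puncta_area_sd_um2,
              death_fade_rate = death_fade_rate)
  nonneg <- c("n_timepoints", "frame_interval_h", "n_cells", "neurite_count",
              "soma_radius_um", "base_intensity_au", "background_au",
              "noise_sd_au", "motile_fraction", "motile_step_um",
              "motile_step_sd_um", "division_rate_per_day",
              "arrival_rate_per_day", "death_hazard_per_h",
              "disease_fraction", "puncta_rate_per_h",
              "puncta_area_mean_um2", "puncta_area_sd_um2",
              "death_fade_rate")
  bad <- nonneg[vapply(nonneg, function(f) any(cfg[[f]] < 0), logical(1))]
  if (length(bad)) stop("negative value(s) for: ", paste(bad, collapse = ", "))
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 1L))
    stop("`image_shape` must be three positive extents (n_z, n_y, n_x)")
  if (any(cfg$voxel_size <= 0)) stop("`voxel_size` must be positive")
  if (cfg$motile_fraction > 1 || cfg$disease_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (cfg$n_timepoints < 1L) stop("need at least one timepoint")
  structure(cfg, class = "SimConfig")
}

# rendering geometry: the soma disk plus PSF blur must stay clear of the
# border so that the intensity-weighted centroid of the rendered component
# equals the true centre (neurites are dim and may clip harmlessly)
sim_margin_um <- function(config) {
  config$soma_radius_um + 2 * config$voxel_size[2] + 2
}

place_new_cell <- function(existing_xy, ext_x, ext_y, margin, min_sep) {
  if (ext_x <= 2 * margin || ext_y <= 2 * margin)
    stop("`image_shape` too small: no soma fits without clipping")
  for (try in 1:100) {
    x <- runif(1, margin, ext_x - margin)
    y <- runif(1, margin, ext_y - margin)
    if (is.null(existing_xy) || nrow(existing_xy) == 0L ||
        all((existing_xy[, 1] - x)^2 + (existing_xy[, 2] - y)^2 >= min_sep^2))
      return(c(x, y))
  }
  stop("cell placement capacity exceeded: could not place a soma with ",
       min_sep, " um separation after 100 retries; enlarge `image_shape` ",
       "or reduce the expected cell count")
}

# Event-level simulation shared by simulate_movie and
# simulate_detection_series: cells, positions, intensities, puncta.
simulate_events <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nz <- config$image_shape[1]
  ext_x <- config$image_shape[3] * config$voxel_size[1]
  ext_y <- config$image_shape[2] * config$voxel_size[2]
  margin <- sim_margin_um(config)
  # 2x radius keeps somata disjoint; the extra 2 um absorbs the PSF blur so
  # tangent disks never merge into one segmented component
  min_sep <- 2 * config$soma_radius_um + 2
  Tn <- config$n_timepoints
  dt_h <- config$frame_interval_h
  times <- config$origin_h + (seq_len(Tn) - 1) * dt_h

  cells <- list()   # each: id, group, parent, motile, z, birth_frame,
                    # death_time_h (absolute, NA), pos matrix Tn x 2,
                    # neurite_angles
  new_cell <- function(id, frame, xy = NULL, parent = NA_integer_) {
    cl <- list(id = id,
         group = if (runif(1) < config$disease_fraction) "disease" else "control",
         parent = parent,
         motile = runif(1) < config$motile_fraction,
         z = sample.int(nz, 1),
         birth_frame = frame,
         death_time_h = NA_real_,
         neurite_angles = runif(config$neurite_count, 0, 2 * pi),
         pos = matrix(NA_real_, Tn, 2))
    if (!is.null(xy)) cl$pos[frame, ] <- xy
    cl
  }
  draw_death <- function(cell) {
    hz <- config$death_hazard_per_h *
      if (cell$group == "disease") exp(config$group_log_hr) else 1
    if (hz > 0) times[cell$birth_frame] + rexp(1, hz) else NA_real_
  }
  alive_at <- function(cell, k) {
    k >= cell$birth_frame &&
      (is.na(cell$death_time_h) || times[k] < cell$death_time_h)
  }
  cur_xy <- function(k) {
    live <- Filter(function(cl) alive_at(cl, k), cells)
    if (!length(live)) return(NULL)
    do.call(rbind, lapply(live, function(cl) cl$pos[k, ]))
  }

  next_id <- 1L
  for (i in seq_len(config$n_cells)) {
    xy <- place_new_cell(
      if (length(cells))
        do.call(rbind, lapply(cells, function(c2) c2$pos[1, , drop = TRUE]))
      else NULL,
      ext_x, ext_y, margin, min_sep)
    cl <- new_cell(next_id, 1L, xy)
    cl$death_time_h <- draw_death(cl)
    cells[[next_id]] <- cl
    next_id <- next_id + 1L
  }

  puncta <- list()
  punct_id <- 0L
  p_div <- 1 - exp(-config$division_rate_per_day * dt_h / 24)
  lambda_arr <- config$arrival_rate_per_day * dt_h / 24

  for (k in seq_len(Tn)) {
    if (k > 1L) {
      # motility steps for cells alive across the interval
      for (i in seq_along(cells)) {
        cl <- cells[[i]]
        if (!alive_at(cl, k) || cl$birth_frame >= k) next
        if (cl$motile) {
          len <- max(0, config$motile_step_um +
                       if (config$motile_step_sd_um > 0)
                         rnorm(1, 0, config$motile_step_sd_um) else 0)
          for (try in 1:50) {
            th <- runif(1, 0, 2 * pi)
            cand <- cl$pos[k - 1, ] + len * c(cos(th), sin(th))
            if (cand[1] >= margin && cand[1] <= ext_x - margin &&
                cand[2] >= margin && cand[2] <= ext_y - margin) break
            cand <- pmin(pmax(cl$pos[k - 1, ], margin),
                         c(ext_x, ext_y) - margin)
          }
          cells[[i]]$pos[k, ] <- cand
        } else {
          cells[[i]]$pos[k, ] <- cl$pos[k - 1, ]
        }
      }
      # divisions
      if (p_div > 0) {
        for (i in seq_along(cells)) {
          cl <- cells[[i]]
          if (cl$birth_frame >= k || !alive_at(cl, k - 1) ||
              !alive_at(cl, k)) next
          if (runif(1) < p_div) {
            for (try in 1:100) {
              th <- runif(1, 0, 2 * pi)
              cand <- cl$pos[k, ] + 2 * config$soma_radius_um *
                c(cos(th), sin(th))
              if (cand[1] >= margin && cand[1] <= ext_x - margin &&
                  cand[2] >= margin && cand[2] <= ext_y - margin) break
            }
            child <- new_cell(next_id, k, parent = cl$id)
            child$pos[k, ] <- cand
            child$death_time_h <- draw_death(child)
            cells[[next_id]] <- child
            next_id <- next_id + 1L
          }
        }
      }
      # arrivals
      if (lambda_arr > 0) {
        n_arr <- rpois(1, lambda_arr)
        for (a in seq_len(n_arr)) {
          xy <- place_new_cell(cur_xy(k), ext_x, ext_y, margin, min_sep)
          arr <- new_cell(next_id, k)
          arr$pos[k, ] <- xy
          arr$death_time_h <- draw_death(arr)
          cells[[next_id]] <- arr
          next_id <- next_id + 1L
        }
      }
    }
    # puncta formation in live cells over the preceding interval
    if (config$puncta_rate_per_h > 0) {
      for (i in seq_along(cells)) {
        cl <- cells[[i]]
        if (!alive_at(cl, k)) next
        n_new <- rpois(1, config$puncta_rate_per_h * dt_h)
        for (p in seq_len(n_new)) {
          punct_id <- punct_id + 1L
          rad <- runif(1, 0, 0.6 * config$soma_radius_um)
          th <- runif(1, 0, 2 * pi)
          area <- max(5, rnorm(1, config$puncta_area_mean_um2,
                               config$puncta_area_sd_um2))
          puncta[[punct_id]] <- data.frame(
            punctum_id = punct_id, cell_id = cl$id,
            appear_h = times[k],
            offset_x_um = rad * cos(th), offset_y_um = rad * sin(th),
            area_um2 = area)
        }
      }
    }
  }

  states <- do.call(rbind, lapply(cells, function(cl) {
    ks <- which(vapply(seq_len(Tn), function(k) alive_at(cl, k), logical(1)))
    if (!length(ks)) return(NULL)
    data.frame(cell_id = cl$id, timepoint_h = times[ks],
               x_um = cl$pos[ks, 1], y_um = cl$pos[ks, 2],
               area_um2 = pi * config$soma_radius_um^2,
               intensity_au = config$base_intensity_au +
                 config$intensity_drift_au_per_h *
                 (times[ks] - times[cl$birth_frame]))
  }))
  if (is.null(states))
    states <- data.frame(cell_id = integer(0), timepoint_h = numeric(0),
                         x_um = numeric(0), y_um = numeric(0),
                         area_um2 = numeric(0), intensity_au = numeric(0))
  cells_df <- if (length(cells)) do.call(rbind, lapply(cells, function(cl)
    data.frame(cell_id = cl$id, group = cl$group, parent_id = cl$parent,
               motile = cl$motile, z_index = cl$z,
               birth_h = times[cl$birth_frame],
               death_h = cl$death_time_h,
               censored = is.na(cl$death_time_h) ||
                 cl$death_time_h > times[Tn])))
  else data.frame(cell_id = integer(0), group = character(0),
                  parent_id = integer(0), motile = logical(0),
                  z_index = integer(0), birth_h = numeric(0),
                  death_h = numeric(0), censored = logical(0))
  puncta_df <- if (length(puncta)) do.call(rbind, puncta)
  else data.frame(punctum_id = integer(0), cell_id = integer(0),
                  appear_h = numeric(0), offset_x_um = numeric(0),
                  offset_y_um = numeric(0), area_um2 = numeric(0))
  list(cells = cells_df, states = states, puncta = puncta_df,
       times = times, internal = cells, config = config)
}

#' Simulate per-timepoint detection tables with ground truth
#'
#' Generates the detections that perfect segmentation of the corresponding
#' rendered movie would produce — centroids, soma areas and per-channel
#' mean intensities per timepoint — without rendering any pixels. Arrivals,
#' divisions, deaths and motility follow the configured rates.
#'
#' @param config a [sim_config()].
#' @return list with `detections` (data frame: `timepoint_h, label, x_um,
#'   y_um, area_um2, mean_intensity_morphology, mean_intensity_reporter`)
#'   and `truth` (list of `cells`, `states`, `puncta` ground-truth tables).
#' @export
simulate_detection_series <- function(config) {
  ev <- simulate_events(config)
  st <- ev$states
  st <- st[order(st$timepoint_h, st$cell_id), , drop = FALSE]
  label <- unlist(lapply(split(seq_len(nrow(st)), st$timepoint_h),
                         seq_along), use.names = FALSE)
  det <- data.frame(timepoint_h = st$timepoint_h,
                    label = if (nrow(st)) label else integer(0),
                    x_um = st$x_um, y_um = st$y_um,
                    area_um2 = st$area_um2,
                    mean_intensity_morphology = st$intensity_au,
                    mean_intensity_reporter = st$intensity_au)
  rownames(det) <- NULL
  list(detections = det,
       truth = ev[c("cells", "states", "puncta")])
}

draw_disk <- function(canvas, cx_px, cy_px, r_px, value, add = FALSE) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  ys <- max(1, floor(cy_px - r_px)):min(nr, ceiling(cy_px + r_px))
  xs <- max(1, floor(cx_px - r_px)):min(nc, ceiling(cx_px + r_px))
  for (y in ys) for (x in xs) {
    if ((x - cx_px)^2 + (y - cy_px)^2 <= r_px^2) {
      canvas[y, x] <- if (add) canvas[y, x] + value
                      else max(canvas[y, x], value)
    }
  }
  canvas
}

draw_stroke <- function(canvas, x0, y0, x1, y1, value) {
  n <- max(2, ceiling(max(abs(x1 - x0), abs(y1 - y0))) * 2)
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  keep <- xs >= 1 & xs <= ncol(canvas) & ys >= 1 & ys <= nrow(canvas)
  idx <- cbind(ys[keep], xs[keep])
  canvas[idx] <- pmax(canvas[idx], value)
  canvas
}

#' Simulate a full two-channel 4D movie with ground truth
#'
#' Renders the event simulation of [simulate_detection_series()] to pixels:
#' each live cell is a soma disk plus thin neurite strokes (rendered at 12%
#' of the soma intensity, below the default segmentation threshold, so
#' segmentation stays soma-centric) on its z-slice, blurred with a Gaussian
#' PSF proxy (sigma 1 px); the reporter channel additionally carries
#' inclusion-body puncta as bright disks. After a
#' cell's death time its fluorescence is absent from subsequent frames
#' (abrupt loss). Background plus Gaussian noise is added everywhere and
#' intensities are rounded to nonnegative integers (16-bit camera counts).
#'
#' @param config a [sim_config()].
#' @return list with `series` (a two-channel [volume_series()], channels
#'   `morphology`, `reporter`) and `truth` (ground-truth tables as in
#'   [simulate_detection_series()]).
#' @export
simulate_movie <- function(config) {
  ev <- simulate_events(config)
  nz <- config$image_shape[1]; ny <- config$image_shape[2]
  nx <- config$image_shape[3]
  dx <- config$voxel_size[1]; dy <- config$voxel_size[2]
  Tn <- config$n_timepoints
  r_px <- config$soma_radius_um / dx
  neur_len_px <- 1.5 * r_px
  arr <- array(0, dim = c(Tn, 2L, nz, ny, nx))
  for (k in seq_len(Tn)) {
    morph <- rep(list(matrix(0, ny, nx)), nz)
    repo <- rep(list(matrix(0, ny, nx)), nz)
    st_k <- ev$states[ev$states$timepoint_h == ev$times[k], , drop = FALSE]
    for (i in seq_len(nrow(st_k))) {
      cl <- ev$internal[[st_k$cell_id[i]]]
      cx <- st_k$x_um[i] / dx + 0.5   # pixel-centre convention
      cy <- st_k$y_um[i] / dy + 0.5
      I <- st_k$intensity_au[i]
      z <- cl$z
      morph[[z]] <- draw_disk(morph[[z]], cx, cy, r_px, I)
      for (th in cl$neurite_angles)
        morph[[z]] <- draw_stroke(morph[[z]],
                                  cx + r_px * cos(th), cy + r_px * sin(th),
                                  cx + (r_px + neur_len_px) * cos(th),
                                  cy + (r_px + neur_len_px) * sin(th),
                                  I * 0.12)
      repo[[z]] <- draw_disk(repo[[z]], cx, cy, r_px, I)
      pk <- ev$puncta[ev$puncta$cell_id == cl$id &
                        ev$puncta$appear_h <= ev$times[k], , drop = FALSE]
      for (p in seq_len(nrow(pk))) {
        pr_px <- sqrt(pk$area_um2[p] / pi) / dx
        repo[[z]] <- draw_disk(repo[[z]],
                               cx + pk$offset_x_um[p] / dx,
                               cy + pk$offset_y_um[p] / dy,
                               pr_px, 2 * I, add = TRUE)
      }
    }
    for (z in seq_len(nz)) {
      m <- morph[[z]]; rp <- repo[[z]]
      if (any(m > 0)) m <- as.matrix(EBImage::gblur(m, sigma = 1))
      if (any(rp > 0)) rp <- as.matrix(EBImage::gblur(rp, sigma = 1))
      arr[k, 1, z, , ] <- m
      arr[k, 2, z, , ] <- rp
    }
  }
  arr <- arr + config$background_au
  if (config$noise_sd_au > 0)
    arr <- arr + rnorm(length(arr), 0, config$noise_sd_au)
  arr <- round(pmax(arr, 0))
  series <- volume_series(arr, voxel_size = config$voxel_size,
                          frame_interval_h = config$frame_interval_h,
                          channel_names = c("morphology", "reporter"),
                          origin_h = config$origin_h)
  list(series = series, truth = ev[c("cells", "states", "puncta")])
}

#' Simulate two-group single-cell survival data
#'
#' Exponential event times with the disease-group hazard equal to
#' `baseline_rate_per_h * exp(log_hr)`. Event times are discretised upward
#' to the imaging frame grid (a death between sessions is scored at the
#' next session); times beyond `censor_time_h` are right-censored there.
#'
#' @param n_control,n_disease group sizes (> 0).
#' @param log_hr log hazard ratio of disease vs control.
#' @param baseline_rate_per_h control-group hazard, events per hour (> 0).
#' @param censor_time_h end of observation, hours.
#' @param frame_interval_h imaging grid spacing, hours (0 = continuous).
#' @param seed RNG seed.
#' @return data frame of survival records: `cell_id, group, time_h, event`
#'   (`event` 1 = death observed, 0 = censored).
#' @export
simulate_survival <- function(n_control, n_disease, log_hr,
                              baseline_rate_per_h, censor_time_h,
                              frame_interval_h = 24, seed = 1L) {
  stopifnot(n_control > 0, n_disease > 0, baseline_rate_per_h > 0,
            censor_time_h >= 0)
  set.seed(seed)
  n <- n_control + n_disease
  group <- rep(c("control", "disease"), c(n_control, n_disease))
  rate <- ifelse(group == "disease",
                 baseline_rate_per_h * exp(log_hr), baseline_rate_per_h)
  raw <- rexp(n, rate)
  if (frame_interval_h > 0)
    obs <- ceiling(raw / frame_interval_h) * frame_interval_h
  else obs <- raw
  event <- as.integer(obs <= censor_time_h)
  time_h <- ifelse(event == 1L, obs, censor_time_h)
  data.frame(cell_id = seq_len(n), group = group,
             time_h = time_h, event = event)
}

#' Simulate single-cell intensity traces with linear drift
#'
#' Each cell trace is `intercept + slope * t` plus Gaussian noise, sampled
#' on the frame grid; an equal number of flat background traces (slope 0,
#' level `background_au`) with the same noise is emitted alongside.
#'
#' @param n_traces number of cell traces.
#' @param slope_au_per_h generating drift (default 0.7 a.u./h).
#' @param duration_h total imaged time; must be divisible by
#'   `frame_interval_h`.
#' @param frame_interval_h sampling interval, hours.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param seed RNG seed.
#' @param n_background number of background traces (default `n_traces`).
#' @param intercept_range uniform range of cell-trace intercepts, a.u.
#' @param background_au background level, a.u.
#' @return data frame: `trace_id, role` ("cell"/"background"), `time_h`,
#'   `intensity_au`.
#' @export
simulate_traces <- function(n_traces, slope_au_per_h = 0.7,
                            duration_h = 384, frame_interval_h = 24,
                            noise_sd = 10, seed = 1L,
                            n_background = n_traces,
                            intercept_range = c(50, 150),
                            background_au = 5) {
  if (duration_h %% frame_interval_h != 0)
    stop("`duration_h` must be divisible by `frame_interval_h`")
  set.seed(seed)
  times <- seq(0, duration_h, by = frame_interval_h)
  mk <- function(n, role, slopes, intercepts) {
    if (n == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(trace_id = paste0(role, i), role = role, time_h = times,
                 intensity_au = intercepts[i] + slopes[i] * times +
                   if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0)))
  }
  out <- rbind(
    mk(n_traces, "cell", rep(slope_au_per_h, n_traces),
       runif(n_traces, intercept_range[1], intercept_range[2])),
    mk(n_background, "background", rep(0, n_background),
       rep(background_au, n_background)))
  rownames(out) <- NULL
  out
}

#' Simulate random-walk tracks with linearly declining step length
#'
#' Emulates a population of cells whose per-interval travel distance slows
#' over the imaging course: the mean step length starts at `step_start_um`
#' and declines by `step_decline_nm_per_day` nanometres per day, with
#' Gaussian jitter. Cells start on a wide grid so that proximity tracking
#' is unambiguous.
#'
#' @param n_tracks number of cells.
#' @param n_timepoints daily imaging sessions.
#' @param frame_interval_h hours between sessions.
#' @param step_start_um mean step length of the first interval, um.
#' @param step_decline_nm_per_day linear decline of the mean step, nm/day.
#' @param step_sd_um step-length jitter SD, um.
#' @param spacing_um grid spacing between cells, um.
#' @param seed RNG seed.
#' @param origin_h first-session time label, hours.
#' @return detections data frame (`timepoint_h, label, x_um, y_um,
#'   area_um2, mean_intensity_morphology, mean_intensity_reporter`) ready
#'   for [build_tracks()].
#' @export
simulate_walk_tracks <- function(n_tracks = 700, n_timepoints = 20,
                                 frame_interval_h = 24, step_start_um = 3,
                                 step_decline_nm_per_day = 150,
                                 step_sd_um = 0.3, spacing_um = 200,
                                 seed = 1L, origin_h = 24) {
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_tracks))
  times <- origin_h + (seq_len(n_timepoints) - 1) * frame_interval_h
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    x <- ((i - 1) %% ncol_grid) * spacing_um + spacing_um / 2
    y <- ((i - 1) %/% ncol_grid) * spacing_um + spacing_um / 2
    xs <- numeric(n_timepoints); ys <- numeric(n_timepoints)
    xs[1] <- x; ys[1] <- y
    for (k in 2:n_timepoints) {
      mu <- step_start_um -
        step_decline_nm_per_day / 1000 * (k - 2) * frame_interval_h / 24
      len <- abs(mu + rnorm(1, 0, step_sd_um))
      th <- runif(1, 0, 2 * pi)
      xs[k] <- xs[k - 1] + len * cos(th)
      ys[k] <- ys[k - 1] + len * sin(th)
    }
    out[[i]] <- data.frame(timepoint_h = times, label = i, x_um = xs,
                           y_um = ys, area_um2 = pi * 8^2,
                           mean_intensity_morphology = 100,
                           mean_intensity_reporter = 100)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$timepoint_h, res$label), ]
  rownames(res) <- NULL
  res
}

#' Simulate per-slice cumulative puncta accumulation
#'
#' Poisson formation of new inclusion-body puncta per slice: in each frame
#' interval, `Pois(rate_per_h * n_cells * interval)` new puncta appear, and
#' the cumulative count is the running total of first appearances.
#'
#' @param n_slices slices in the group.
#' @param rate_per_h puncta formed per cell-hour.
#' @param n_cells_per_slice labelled neurons per slice.
#' @param duration_h imaging span, hours.
#' @param frame_interval_h hours between sessions.
#' @param seed RNG seed.
#' @param group group label attached to every row.
#' @return data frame: `slice_id, group, timepoint_h, new_count,
#'   cumulative_count`.
#' @export
simulate_puncta_accumulation <- function(n_slices, rate_per_h,
                                         n_cells_per_slice = 20,
                                         duration_h = 336,
                                         frame_interval_h = 24,
                                         seed = 1L, group = "group") {
  set.seed(seed)
  times <- seq(0, duration_h, by = frame_interval_h)
  lambda <- rate_per_h * n_cells_per_slice * frame_interval_h
  do.call(rbind, lapply(seq_len(n_slices), function(s) {
    new <- c(0, rpois(length(times) - 1, lambda))
    data.frame(slice_id = paste0(group, "_slice", s), group = group,
               timepoint_h = times, new_count = new,
               cumulative_count = cumsum(new))
  }))
}
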