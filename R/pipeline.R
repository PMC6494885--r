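#' Pipeline configuration
#'
#' Ties the per-stage configurations together with either an input movie
#' path or a simulator configuration (exactly one of the two), an output
#' directory and a seed. The seed and full configuration are echoed into
#' every output for provenance.
#'
#' @param input_path OME-TIFF movie to analyse, or `NULL` to simulate.
#' @param simulate a [sim_config()], or `NULL` to read `input_path`.
#' @param segment a [segment_config()].
#' @param tracker a [tracker_config()].
#' @param motility a [motility_config()].
#' @param puncta a [puncta_config()].
#' @param death a [death_call_config()].
#' @param out_dir output directory (created if absent).
#' @param seed integer random seed recorded in all outputs.
#' @param manual_deaths optional CSV path (`cell_id, death_time_h`)
#'   overriding automated death calls.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(input_path = NULL, simulate = NULL,
                            segment = segment_config(),
                            tracker = tracker_config(),
                            motility = motility_config(),
                            puncta = puncta_config(),
                            death = death_call_config(),
                            out_dir = "slicetrack_out", seed = 1L,
                            manual_deaths = NULL) {
  if (is.null(input_path) == is.null(simulate))
    stop("exactly one of `input_path` or `simulate` must be given")
  structure(list(input_path = input_path, simulate = simulate,
                 segment = segment, tracker = tracker, motility = motility,
                 puncta = puncta, death = death, out_dir = out_dir,
                 seed = as.integer(seed), manual_deaths = manual_deaths),
            class = "PipelineConfig")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()] (for writing).
#' @return [read_pipeline_config()] returns a `PipelineConfig`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate)
  cfg <- function(ctor, part) if (is.null(part)) ctor() else
    do.call(ctor, part[names(part) %in% names(formals(ctor))])
  pipeline_config(
    input_path = y$input_path, simulate = sim,
    segment = cfg(segment_config, y$segment),
    tracker = cfg(tracker_config, y$tracker),
    motility = cfg(motility_config, y$motility),
    puncta = cfg(puncta_config, y$puncta),
    death = cfg(death_call_config, y$death),
    out_dir = if (is.null(y$out_dir)) "slicetrack_out" else y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed,
    manual_deaths = y$manual_deaths)
}

pipeline_log <- function(lines, file) {
  cat(paste0(format(lines), "\n"), file = file, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Stages run in order: image input (read or simulate) -> max projection
#' per timepoint/channel -> alignment -> segmentation of the morphology
#' channel -> tracking -> quantification -> puncta analysis (when a
#' reporter channel exists) -> survival analysis. Outputs are CSV tables
#' plus a JSON report and a run log in `out_dir`; rerunning with the same
#' configuration and seed reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param align whether to run translation alignment across timepoints
#'   (default `TRUE`).
#' @return invisibly, a list with all intermediate tables (`tracks`,
#'   `counts`, `kinematics`, `motility`, `puncta`, `survival_records`,
#'   `survival_fit`, `report`).
#' @export
run_pipeline <- function(config, align = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  if (file.exists(logf)) unlink(logf)
  stage <- function(name, expr) {
    pipeline_log(sprintf("[stage %s] start", name), logf)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)

  sim_truth <- NULL
  series <- stage("imgio", {
    if (!is.null(config$simulate)) {
      mv <- simulate_movie(config$simulate)
      sim_truth <- mv$truth
      mv$series
    } else read_series(config$input_path)
  })
  d <- dim(series$pixels)
  tps <- series_timepoints(series)
  morph_ch <- if ("morphology" %in% series$channel_names)
    match("morphology", series$channel_names) else 1L
  rep_ch <- if ("reporter" %in% series$channel_names)
    match("reporter", series$channel_names) else if (d[2] >= 2) 2L else NA

  projs <- stage("imgio", lapply(seq_len(d[1]), function(t)
    max_project(series, t, morph_ch)))
  if (align && d[1] > 1) {
    al <- stage("imgio", align_series(projs))
    projs <- al$aligned
    write.csv(al$shifts, file.path(config$out_dir, "shifts.csv"),
              row.names = FALSE)
  }

  seg_cfg <- config$segment
  if (is.null(seg_cfg$min_mean_intensity)) {
    # automatic intensity floor: objects must clear the background, so a
    # frame with no real signal segments to nothing instead of noise
    bg0 <- estimate_background(projs)
    seg_cfg$min_mean_intensity <- bg0$mean + 3 * bg0$sd
  }
  detections <- stage("segment", {
    det_list <- lapply(seq_len(d[1]), function(t) {
      det <- segment_cells(projs[[t]], seg_cfg)
      if (!is.na(rep_ch) && nrow(det)) {
        rp <- max_project(series, t, rep_ch)
        det$mean_intensity_reporter <-
          measure_labels(attr(det, "labels"), rp)
      }
      det
    })
    do.call(rbind, det_list)
  })

  if (nrow(detections) == 0)
    warning("no cells detected in any frame; outputs will be empty")
  tracks <- stage("track", build_tracks(detections, config$tracker))
  counts <- count_tracked(tracks)
  kin <- stage("quantify", track_kinematics(tracks))
  mot <- stage("quantify", classify_motile(tracks, config$motility))

  puncta_tab <- NULL
  if (!is.na(rep_ch)) {
    puncta_tab <- stage("puncta", {
      out <- lapply(seq_len(d[1]), function(t) {
        nm <- neuron_mask(projs[[t]], seg_cfg)
        if (!any(nm$mask)) return(NULL)
        detect_puncta(max_project(series, t, rep_ch), nm$mask,
                      config$puncta, labels = nm$labels)
      })
      out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
      if (!is.null(out) && nrow(out))
        match_puncta(out, match_radius_um =
                       sqrt(stats::median(detections$area_um2) / pi))
      else out
    })
  }

  surv <- stage("survival", {
    bg <- estimate_background(projs)
    manual <- if (!is.null(config$manual_deaths))
      read.csv(config$manual_deaths) else NULL
    survival_records(tracks, bg, config$death,
                     movie_end_h = max(tps),
                     frame_interval_h = series$frame_interval_h,
                     manual = manual)
  })
  surv_fit <- if (length(unique(surv$group)) >= 2 && sum(surv$event) > 0)
    cph_fit(surv) else NULL

  prov <- list(seed = config$seed, package = "slicetrack",
               version = as.character(utils::packageVersion("slicetrack")))
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(config$out_dir, name)
    hdr <- sprintf("# slicetrack seed=%d", config$seed)
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                                 row.names = FALSE, qmethod = "double"))
    invisible(path)
  }
  wr(as.data.frame(tracks), "tracks.csv")
  wr(counts, "counts.csv")
  wr(kin$per_track, "features.csv")
  wr(mot, "motility.csv")
  wr(puncta_tab, "puncta.csv")
  wr(surv, "survival.csv")
  report <- list(provenance = prov,
                 n_timepoints = d[1],
                 n_detections = nrow(detections),
                 n_tracks = length(unique(tracks$cell_id)),
                 n_events = sum(surv$event),
                 n_censored = sum(surv$event == 0),
                 n_puncta = if (is.null(puncta_tab)) 0L
                            else length(unique(puncta_tab$punctum_id)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  plot_counts(counts, file.path(config$out_dir, "counts.png"))
  pipeline_log("[done]", logf)
  invisible(list(series = series, tracks = tracks, counts = counts,
                 kinematics = kin, motility = mot, puncta = puncta_tab,
                 survival_records = surv, survival_fit = surv_fit,
                 truth = sim_truth, report = report))
}

# background statistics from the dimmest quartile of pixels across frames
estimate_background <- function(projs) {
  px <- unlist(lapply(projs, function(p) {
    v <- as.vector(p$pixels)
    v[v <= quantile(v, 0.25)]
  }))
  list(mean = mean(px), sd = max(sd(px), 1e-8))
}

plot_counts <- function(counts, path) {
  if (nrow(counts) == 0) return(invisible(NULL))
  grDevices::png(path, width = 600, height = 400)
  on.exit(grDevices::dev.off())
  graphics::plot(counts$timepoint_h, counts$n_cumulative, type = "b", pch = 16,
       xlab = "time (h)", ylab = "cells tracked (cumulative)")
  fit <- lm(counts$n_cumulative ~ counts$timepoint_h)
  graphics::abline(fit, col = "grey40")
}
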