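test_that("empty configuration yields background-only movie and empty truth", {
  cfg <- sim_config(seed = 3, n_cells = 0, n_timepoints = 3,
                    image_shape = c(2L, 96L, 96L), noise_sd_au = 2,
                    background_au = 5)
  mv <- simulate_movie(cfg)
  expect_equal(nrow(mv$truth$cells), 0)
  expect_equal(nrow(mv$truth$states), 0)
  # every frame is background + noise only
  expect_lt(abs(mean(mv$series$pixels) - 5), 1)
  expect_lt(max(mv$series$pixels), 5 + 6 * 2)
})

test_that("identical config and seed give bit-identical movies and tables", {
  cfg <- tiny_movie_config(seed = 11, death_hazard_per_h = 0.003)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$series$pixels, b$series$pixels)
  expect_identical(a$truth, b$truth)
  d1 <- simulate_detection_series(cfg)
  d2 <- simulate_detection_series(cfg)
  expect_identical(d1, d2)
})

test_that("rendered reporter signal dies exactly for the ground-truth deaths", {
  # brute-force pixel inspection: a cell is "rendered alive" at a frame iff
  # the mean reporter intensity in a soma-radius disk around its true
  # centroid clearly exceeds background
  n_dead <- 0; n_checked <- 0
  for (seed in c(2, 5, 9)) {
    cfg <- sim_config(seed = seed, image_shape = c(2L, 224L, 224L),
                      n_timepoints = 6L, n_cells = 4L,
                      death_hazard_per_h = 0.006)
    mv <- simulate_movie(cfg)
    tps <- series_timepoints(mv$series)
    dx <- mv$series$voxel_size[["dx"]]
    r_px <- cfg$soma_radius_um / dx
    rendered_alive <- function(cell, t_idx) {
      st <- mv$truth$states
      row <- st[st$cell_id == cell$cell_id & st$timepoint_h == tps[t_idx], ]
      pos <- if (nrow(row)) c(row$x_um, row$y_um) else {
        last <- st[st$cell_id == cell$cell_id, ]
        last <- last[which.max(last$timepoint_h), ]
        c(last$x_um, last$y_um)
      }
      cx <- pos[1] / dx + 0.5; cy <- pos[2] / dx + 0.5
      vals <- c()
      for (z in seq_len(dim(mv$series$pixels)[3])) {
        sl <- matrix(mv$series$pixels[t_idx, 2, z, , ],
                     dim(mv$series$pixels)[4], dim(mv$series$pixels)[5])
        ys <- round(cy + seq(-r_px / 2, r_px / 2, by = 1))
        xs <- round(cx + seq(-r_px / 2, r_px / 2, by = 1))
        vals <- c(vals, as.vector(sl[ys, xs]))
      }
      mean(vals) > cfg$background_au + 10
    }
    for (i in seq_len(nrow(mv$truth$cells))) {
      cell <- mv$truth$cells[i, ]
      for (k in seq_along(tps)) {
        if (tps[k] < cell$birth_h) next
        truth_alive <- is.na(cell$death_h) || tps[k] < cell$death_h
        expect_identical(rendered_alive(cell, k), truth_alive)
        n_checked <- n_checked + 1
        if (!truth_alive) n_dead <- n_dead + 1
      }
    }
  }
  expect_gt(n_dead, 0)   # the scenario actually exercised deaths
  expect_gt(n_checked, 20)
})

test_that("rendered soma centroids match ground truth within one pixel", {
  cfg <- tiny_movie_config(seed = 4)
  mv <- simulate_movie(cfg)
  p <- max_project(mv$series, 1, "morphology")
  det <- segment_cells(p, segment_config())
  truth <- mv$truth$states[mv$truth$states$timepoint_h ==
                             series_timepoints(mv$series)[1], ]
  expect_equal(nrow(det), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2)
    expect_lt(min(d), cfg$voxel_size[1])   # within 1 pixel
  }
})

test_that("arrival counts follow the configured Poisson rate", {
  cfg <- sim_config(seed = 21, n_cells = 10,
                    image_shape = c(3L, 4096L, 4096L),
                    n_timepoints = 20L, arrival_rate_per_day = 10)
  ds <- simulate_detection_series(cfg)
  n_total <- nrow(ds$truth$cells)
  expected <- 10 + 19 * 10
  expect_lt(abs(n_total - expected), 3 * sqrt(190) + 1)
})

test_that("motility settings control per-frame displacement exactly", {
  base <- list(seed = 8, n_cells = 6, n_timepoints = 6,
               image_shape = c(2L, 1024L, 1024L))
  still <- do.call(sim_config, c(base, list(motile_fraction = 0)))
  ds <- simulate_detection_series(still)
  tr <- build_tracks(ds$detections)
  kin <- track_kinematics(tr)
  expect_true(all(kin$per_track$net_displacement_um == 0))
  moving <- do.call(sim_config, c(base, list(motile_fraction = 1,
                                             motile_step_um = 5)))
  ds2 <- simulate_detection_series(moving)
  tr2 <- build_tracks(ds2$detections)
  steps <- track_kinematics(tr2)$steps$step_um
  expect_true(all(abs(steps - 5) < 1e-9))
})

test_that("cells are conserved and never detected after their death", {
  cfg <- sim_config(seed = 13, n_cells = 8, n_timepoints = 10,
                    image_shape = c(2L, 2048L, 2048L),
                    arrival_rate_per_day = 2, division_rate_per_day = 0.05,
                    death_hazard_per_h = 0.004)
  ds <- simulate_detection_series(cfg)
  cells <- ds$truth$cells
  n_children <- sum(!is.na(cells$parent_id))
  n_arrivals <- sum(is.na(cells$parent_id) & cells$birth_h > min(cells$birth_h))
  expect_equal(nrow(cells), 8 + n_arrivals + n_children)
  st <- merge(ds$truth$states, cells[, c("cell_id", "death_h")])
  after_death <- !is.na(st$death_h) & st$timepoint_h >= st$death_h
  expect_false(any(after_death))
  # children are born at their parent's division time, after the parent
  kids <- cells[!is.na(cells$parent_id), ]
  if (nrow(kids)) {
    parents <- cells[match(kids$parent_id, cells$cell_id), ]
    expect_true(all(kids$birth_h > parents$birth_h))
  }
})

test_that("overcrowded placement is rejected with a clear error", {
  cfg <- sim_config(seed = 1, n_cells = 200, image_shape = c(2L, 128L, 128L))
  expect_error(simulate_detection_series(cfg), "placement capacity")
})

test_that("survival simulator honours hazards, censoring and the frame grid", {
  # degenerate censoring
  rec0 <- simulate_survival(5, 5, 0, 0.01, censor_time_h = 0, seed = 1)
  expect_true(all(rec0$event == 0) && all(rec0$time_h == 0))
  # null case: groups exchangeable
  rec <- simulate_survival(4000, 4000, 0, 0.005, censor_time_h = Inf,
                           frame_interval_h = 0, seed = 2)
  ks <- suppressWarnings(ks.test(rec$time_h[rec$group == "control"],
                                 rec$time_h[rec$group == "disease"]))
  expect_gt(ks$p.value, 0.01)
  # closed-form hazard ratio: events per person-time ratio ~ 2
  rec2 <- simulate_survival(10000, 10000, log(2), 0.005,
                            censor_time_h = 336, frame_interval_h = 24,
                            seed = 3)
  rate <- sapply(split(rec2, rec2$group),
                 function(d) sum(d$event) / sum(d$time_h))
  expect_lt(abs(rate[["disease"]] / rate[["control"]] - 2), 0.15)
  # grid discretisation: all event times on the 24 h grid
  expect_true(all(rec2$time_h[rec2$event == 1] %% 24 == 0))
})

test_that("trace simulator produces the configured linear drift", {
  tr <- simulate_traces(3, slope_au_per_h = 0.7, duration_h = 96,
                        frame_interval_h = 24, noise_sd = 0, seed = 1)
  cells <- tr[tr$role == "cell", ]
  for (id in unique(cells$trace_id)) {
    one <- cells[cells$trace_id == id, ]
    expect_equal(unname(coef(lm(intensity_au ~ time_h, one))[2]), 0.7,
                 tolerance = 1e-10)
  }
  expect_error(simulate_traces(3, duration_h = 100, frame_interval_h = 24),
               "divisible")
})
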