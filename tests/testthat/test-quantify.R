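test_that("kinematics handle stationary, collinear and single-point tracks", {
  stat <- data.frame(cell_id = 1L, timepoint_h = c(24, 48, 72),
                     x_um = 10, y_um = 10)
  k <- track_kinematics(stat)
  expect_true(all(k$steps$step_um == 0))
  expect_equal(k$per_track$net_displacement_um, 0)
  lin <- data.frame(cell_id = 1L, timepoint_h = 24 * (1:5),
                    x_um = 3 * (0:4), y_um = 0)
  k2 <- track_kinematics(lin)$per_track
  expect_equal(k2$path_length_um, 12)
  expect_equal(k2$net_displacement_um, 12)
  expect_equal(k2$mean_velocity_um_per_h, 12 / 96)
  single <- data.frame(cell_id = 2L, timepoint_h = 24, x_um = 0, y_um = 0)
  k3 <- track_kinematics(single)$per_track
  expect_false(k3$defined)
  expect_true(is.na(k3$path_length_um))
})

test_that("path length is never below net displacement (triangle inequality)", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(3:10, 1)
    tr <- data.frame(cell_id = 1L, timepoint_h = 24 * seq_len(n),
                     x_um = cumsum(rnorm(n, 0, 5)),
                     y_um = cumsum(rnorm(n, 0, 5)))
    k <- track_kinematics(tr)$per_track
    expect_gte(k$path_length_um, k$net_displacement_um - 1e-12)
  }
})

test_that("kinematics scale linearly with the spatial calibration", {
  tr <- data.frame(cell_id = 1L, timepoint_h = 24 * (1:4),
                   x_um = c(0, 3, 1, 6), y_um = c(0, 4, 4, 0))
  tr2 <- transform(tr, x_um = x_um * 2, y_um = y_um * 2)
  a <- track_kinematics(tr)$per_track
  b <- track_kinematics(tr2)$per_track
  expect_equal(b$path_length_um, 2 * a$path_length_um)
  expect_equal(b$net_displacement_um, 2 * a$net_displacement_um)
})

test_that("motility calls follow the two-somata-lengths rule strictly", {
  # soma length from median area: area pi*8^2 -> diameter 16 um
  area <- pi * 8^2
  mk <- function(xmax) data.frame(cell_id = 1L, timepoint_h = 24 * (1:3),
                                  x_um = c(0, xmax / 2, xmax), y_um = 0,
                                  area_um2 = area)
  expect_true(classify_motile(mk(40))$motile)        # 40 > 32
  expect_false(classify_motile(mk(32))$motile)       # exactly 2.0x: not motile
  expect_false(classify_motile(mk(0))$motile)        # stationary
  got <- classify_motile(mk(40))
  expect_equal(got$soma_length_um, 16)
  expect_equal(got$max_span_um, 40)
})

test_that("intensity trend recovers the generating drift against background", {
  slopes <- numeric(20); ps <- numeric(20)
  for (s in 1:20) {
    tr <- simulate_traces(12, slope_au_per_h = 0.7, duration_h = 384,
                          frame_interval_h = 24, noise_sd = 10, seed = s)
    res <- intensity_trend(tr[tr$role == "cell", ],
                           tr[tr$role == "background", ])
    slopes[s] <- res$background_subtracted_slope
    ps[s] <- res$p_value
  }
  expect_lt(abs(mean(slopes) - 0.7), 0.07)           # within 10 %
  expect_gte(sum(ps < 0.01), 11)                     # 20-seed majority
})

test_that("noiseless linear traces give a perfect fit", {
  tr <- simulate_traces(5, slope_au_per_h = 0.7, duration_h = 96,
                        frame_interval_h = 24, noise_sd = 0, seed = 1,
                        intercept_range = c(80, 80))
  res <- intensity_trend(tr[tr$role == "cell", ])
  expect_equal(res$slope, 0.7, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("the slope-interaction p-value is calibrated under the null", {
  ps <- sapply(1:200, function(s) {
    set.seed(s + 1000)
    t <- rep(0:9 * 24, 4)
    a <- data.frame(time_h = t, value = 0.5 * t + rnorm(length(t), 0, 5))
    b <- data.frame(time_h = t, value = 0.5 * t + rnorm(length(t), 0, 5))
    compare_slopes_ancova(a, b)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ancova separates different slopes and reports both estimates", {
  set.seed(5)
  t <- rep(0:9 * 24, 10)
  a <- data.frame(time_h = t, value = 1.0 * t + rnorm(length(t), 0, 2))
  b <- data.frame(time_h = t, value = 2.0 * t + rnorm(length(t), 0, 2))
  cmp <- compare_slopes_ancova(a, b)
  expect_lt(cmp$p, 0.001)
  expect_equal(cmp$slope_a, 1, tolerance = 0.05)
  expect_equal(cmp$slope_b, 2, tolerance = 0.05)
  # degenerate separation still produces a positive F
  z <- data.frame(time_h = t, value = 0 * t)
  o <- data.frame(time_h = t, value = 1 * t)
  expect_gt(compare_slopes_ancova(z, o)$F, 0)
})

test_that("cell count rate is exact for deterministic arrivals", {
  counts <- data.frame(timepoint_h = 24 * (1:10),
                       n_cumulative = 50 + 10 * (0:9))
  expect_equal(cell_count_rate(counts)$slope, 10, tolerance = 1e-10)
  flat <- data.frame(timepoint_h = 24 * (1:5), n_cumulative = rep(7, 5))
  expect_equal(cell_count_rate(flat)$slope, 0, tolerance = 1e-12)
})

test_that("cell count rate recovers Poisson arrivals at 10 per day", {
  rates <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_cells = 50, n_timepoints = 20,
                      image_shape = c(3L, 4096L, 4096L),
                      arrival_rate_per_day = 10)
    ds <- simulate_detection_series(cfg)
    cell_count_rate(count_tracked(build_tracks(ds$detections)))$slope
  })
  expect_lt(abs(mean(rates) - 10), 1.5)              # within 15 %
})

test_that("mean distance trend recovers a 150 nm/day decline", {
  slopes <- sapply(1:20, function(s)
    mean_distance_trend(build_tracks(simulate_walk_tracks(seed = s)))$slope)
  expect_lt(abs(mean(slopes) + 150), 22.5)           # within 15 % of -150
})

test_that("distance trend of stationary tracks is exactly zero with null Tukey", {
  det <- do.call(rbind, lapply(1:4, function(k)
    data.frame(timepoint_h = 24 * k, label = 1:6,
               x_um = seq(0, 500, by = 100), y_um = 0)))
  res <- mean_distance_trend(build_tracks(det))
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_true(all(res$per_timepoint$mean_step_um == 0))
  # equal step distributions at two timepoints: Tukey p ~ 1
  set.seed(2)
  steps <- rnorm(40, 3, 0.1)
  det2 <- do.call(rbind, lapply(1:4, function(k)
    data.frame(timepoint_h = 24 * k, label = 1:40,
               x_um = (k - 1) * steps + seq(0, 3900, by = 100), y_um = 0)))
  res2 <- mean_distance_trend(build_tracks(det2))
  pair <- res2$tukey
  expect_gt(min(pair[, "p adj"]), 0.9)
})
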