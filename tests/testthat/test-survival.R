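test_that("death calling follows the background-drop rule arithmetic", {
  trace <- data.frame(timepoint_h = c(24, 48, 72, 96, 120),
                      intensity_au = c(100, 102, 98, 6, 5))
  bg <- list(mean = 5, sd = 1)
  rec <- call_death(trace, bg, death_call_config(drop_to_background_k = 3,
                                                 persistence_frames = 2))
  expect_equal(rec$time_h, 96)          # 4th timepoint
  expect_equal(rec$event, 1L)
  expect_equal(rec$call, "intensity")
  # a bright trace to movie end is censored at the last observation
  bright <- data.frame(timepoint_h = c(24, 48, 72),
                       intensity_au = c(100, 101, 99))
  rec2 <- call_death(bright, bg, movie_end_h = 72)
  expect_equal(rec2$event, 0L)
  expect_equal(rec2$time_h, 72)
  # a track that vanishes mid-movie is scored dead at the missing frame
  rec3 <- call_death(bright, bg, movie_end_h = 120, frame_interval_h = 24)
  expect_equal(rec3$event, 1L)
  expect_equal(rec3$time_h, 96)
  expect_equal(rec3$call, "disappearance")
  # manual annotation overrides everything
  rec4 <- call_death(trace, bg, manual_death_h = 48)
  expect_equal(rec4[, c("time_h", "event")],
               data.frame(time_h = 48, event = 1L))
  expect_error(call_death(trace, list(mean = NA, sd = 1)), "background")
})

test_that("KM estimator reproduces the hand product-limit example", {
  rec <- data.frame(time_h = c(24, 48, 72, 72), event = c(1, 1, 0, 0))
  km <- km_curve(rec)
  expect_equal(km$survival[km$time_h == 24], 0.75)
  expect_equal(km$survival[km$time_h == 48], 0.50)
  # no events: survival stays at 1
  cen <- data.frame(time_h = c(24, 48), event = c(0, 0))
  expect_true(all(km_curve(cen)$survival == 1))
  # duplication invariance of the estimator
  km2 <- km_curve(rbind(rec, rec))
  expect_equal(km2$survival[km2$time_h %in% c(24, 48)],
               km$survival[km$time_h %in% c(24, 48)])
  # nonincreasing from 1
  set.seed(6)
  r <- simulate_survival(80, 80, log(2), 0.004, 336, 24, seed = 8)
  k3 <- km_curve(r)
  for (g in unique(k3$group)) {
    s <- k3$survival[k3$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
})

test_that("record order does not change KM or the rank test", {
  set.seed(12)
  rec <- simulate_survival(40, 40, log(1.5), 0.005, 336, 24, seed = 12)
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(km_curve(rec)$survival, km_curve(perm)$survival)
  expect_equal(gbw_test(rec)$statistic, gbw_test(perm)$statistic)
})

test_that("the Gehan-Breslow-Wilcoxon statistic matches independent algebra", {
  rec <- data.frame(
    group = c("a", "a", "a", "b", "b", "b"),
    time_h = c(24, 48, 96, 24, 72, 120),
    event = c(1, 1, 0, 1, 1, 1))
  got <- gbw_test(rec)
  # independent recomputation straight from the definition, one event
  # time at a time, written as explicit risk-set counting
  U <- 0; V <- 0
  for (t in sort(unique(rec$time_h[rec$event == 1]))) {
    risk <- rec[rec$time_h >= t, ]
    n <- nrow(risk); n1 <- sum(risk$group == "a")
    d <- sum(rec$time_h == t & rec$event == 1)
    d1 <- sum(rec$time_h == t & rec$event == 1 & rec$group == "a")
    U <- U + n * (d1 - d * n1 / n)
    V <- V + n^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
  }
  expect_equal(got$U, U)
  expect_equal(got$var_U, V)
  expect_equal(got$statistic, U^2 / V)
  # identical groups: shared event times -> zero statistic
  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     time_h = rep(c(24, 48, 72), 2), event = 1)
  expect_equal(gbw_test(same)$statistic, 0)
  # complete early/late separation: strongly significant
  sep <- data.frame(group = rep(c("a", "b"), each = 30),
                    time_h = c(rep(c(24, 48), 15), rep(c(240, 264), 15)),
                    event = 1)
  expect_lt(gbw_test(sep)$p, 0.01)
})

test_that("Cox fits return HR 1 for exchangeable groups and recover ratio 2", {
  same <- data.frame(group = rep(c("a", "b"), each = 4),
                     time_h = rep(c(24, 48, 72, 96), 2), event = 1)
  fit <- cph_fit(same)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-6)
  big <- simulate_survival(5000, 5000, log(2), 0.003, Inf,
                           frame_interval_h = 0, seed = 99)
  fit2 <- cph_fit(big)
  expect_equal(fit2$hazard_ratio, 2, tolerance = 0.05)
  expect_true(fit2$ci_low <= fit2$hazard_ratio &&
              fit2$hazard_ratio <= fit2$ci_high)
})

test_that("CPH recovers the 1.9 hazard ratio under the imaging design", {
  hrs <- sapply(1:20, function(s) {
    rec <- simulate_survival(161, 180, log(1.9), -log(0.4) / 336, 336, 24,
                             seed = s)
    cph_fit(rec)$hazard_ratio
  })
  expect_lt(abs(mean(hrs) - 1.9), 0.285)    # within 15 %
  expect_true(mean(hrs) > 1.5 && mean(hrs) < 2.5)
})

test_that("CPH is invariant to dataset duplication and flags separation", {
  rec <- simulate_survival(60, 60, log(1.5), 0.004, 336, 24, seed = 5)
  f1 <- cph_fit(rec)
  f2 <- cph_fit(rbind(rec, rec))
  # duplication introduces ties, so Efron's correction makes the
  # replication invariance approximate rather than exact
  expect_equal(f2$hazard_ratio, f1$hazard_ratio, tolerance = 0.01)
  sep <- data.frame(group = rep(c("a", "b"), each = 12),
                    time_h = c(rep(24, 12), rep(336, 12)),
                    event = c(rep(1, 12), rep(0, 12)))
  expect_warning(cph_fit(sep), "separation")
})

test_that("log-HR recovery is nearly unbiased across the design grid", {
  for (hr in c(1, 1.9)) {
    lhr <- sapply(1:12, function(s) {
      rec <- simulate_survival(170, 171, log(hr), -log(0.4) / 336, 336, 24,
                               seed = 7000 + s * 13 + round(hr * 10))
      cph_fit(rec)$coef
    })
    expect_lt(abs(mean(lhr) - log(hr)), 0.1)
  }
})

test_that("cumulative hazard is nondecreasing from zero and near-linear when constant", {
  rec <- simulate_survival(300, 300, 0, 0.004, 336, 24, seed = 3)
  ch <- cumulative_hazard(rec)
  for (g in unique(ch$group)) {
    v <- ch$cum_hazard[ch$group == g]
    expect_true(all(diff(v) >= 0))
    expect_gte(v[1], 0)
    # straight-line fit through the origin explains almost everything
    t <- ch$time_h[ch$group == g]
    fit <- lm(v ~ 0 + t)
    expect_gt(summary(fit)$r.squared, 0.98)
  }
})

test_that("hazard linearity test is calibrated and has power", {
  # constant hazard: rarely rejected
  null_p <- sapply(1:20, function(s) {
    rec <- simulate_survival(150, 150, 0, 0.004, Inf, 0, seed = s + 40)
    hazard_linearity(rec)$p
  })
  expect_gte(sum(null_p > 0.05), 18)
  # increasing (Weibull shape 2) hazard: reliably rejected
  pow_p <- sapply(1:20, function(s) {
    set.seed(s + 80)
    rec <- data.frame(group = rep(c("a", "b"), each = 150),
                      time_h = rweibull(300, shape = 2, scale = 200),
                      event = 1L)
    hazard_linearity(rec)$p
  })
  expect_gte(sum(pow_p < 0.05), 18)
  few <- data.frame(group = "a", time_h = c(24, 48, 200), event = c(1, 1, 0))
  expect_error(hazard_linearity(few), "too few events")
})

test_that("automated death calls match scripted ground truth on movies", {
  false_pos <- 0; missed <- 0; n_deaths <- 0; wrong_time <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, image_shape = c(2L, 224L, 224L),
                      n_timepoints = 6L, n_cells = 4L,
                      death_hazard_per_h = 0.006)
    mv <- simulate_movie(cfg)
    tps <- series_timepoints(mv$series)
    projs <- lapply(seq_along(tps), function(t)
      max_project(mv$series, t, "morphology"))
    # intensity floor: real somata must clear background + 3 sd, so frames
    # whose cells have all died do not segment noise into objects
    seg <- segment_config(min_mean_intensity =
                            cfg$background_au + 3 * cfg$noise_sd_au)
    det <- do.call(rbind, lapply(projs, segment_cells, config = seg))
    tracks <- build_tracks(det)
    bg <- list(mean = cfg$background_au, sd = cfg$noise_sd_au)
    rec <- survival_records(tracks, bg, movie_end_h = max(tps),
                            frame_interval_h = 24, time_origin_h = 0)
    # map recovered tracks to true cells via first-detection position
    first <- tracks[!duplicated(tracks$cell_id), ]
    truth <- mv$truth
    called_death_frames <- c()
    for (i in seq_len(nrow(first))) {
      d <- sqrt((truth$states$x_um - first$x_um[i])^2 +
                (truth$states$y_um - first$y_um[i])^2) +
        1000 * (truth$states$timepoint_h != first$timepoint_h[i])
      true_cell <- truth$states$cell_id[which.min(d)]
      tc <- truth$cells[truth$cells$cell_id == true_cell, ]
      r <- rec[rec$cell_id == first$cell_id[i], ]
      died_in_movie <- !is.na(tc$death_h) && tc$death_h <= max(tps)
      if (died_in_movie) {
        n_deaths <- n_deaths + 1
        expected_frame <- min(tps[tps >= tc$death_h])
        if (r$event != 1L) missed <- missed + 1
        else if (r$time_h != expected_frame) wrong_time <- wrong_time + 1
      } else if (r$event == 1L) false_pos <- false_pos + 1
    }
  }
  expect_gt(n_deaths, 5)      # the 20-seed suite really contains deaths
  expect_equal(missed, 0)
  expect_equal(wrong_time, 0)
  expect_equal(false_pos, 0)
})
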