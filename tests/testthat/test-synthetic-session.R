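test_that("cell map respects bounds, ensemble radius, and the empty case", {
  set.seed(1)
  cfg <- sim_config(n_cells = 100, fov_width = 600, fov_height = 600,
                    n_ensembles = 2, ensemble_radius = 50)
  cm <- generate_cell_map(cfg)
  expect_equal(nrow(cm$centroids), 100)
  expect_true(all(cm$centroids$x_um >= 0 & cm$centroids$x_um <= 600))
  expect_true(all(cm$centroids$y_um >= 0 & cm$centroids$y_um <= 600))
  # brute-force distance recomputation for every member cell
  for (i in which(!is.na(cm$membership))) {
    e <- cm$membership[i]
    d <- sqrt((cm$centroids$x_um[i] - cm$ensemble_centers$x_um[e])^2 +
                (cm$centroids$y_um[i] - cm$ensemble_centers$y_um[e])^2)
    expect_lte(d, 50)
  }
  empty <- generate_cell_map(sim_config(n_cells = 0))
  expect_equal(nrow(empty$centroids), 0)
  expect_error(sim_config(fov_width = -1), "fov_width")
})

test_that("locomotion has the configured bout structure and speeds", {
  set.seed(7)
  cfg <- sim_config(duration = 600, mean_move_speed = 4, seed = 7)
  loco <- simulate_locomotion(cfg)
  move <- loco$state == "move"
  expect_lt(abs(mean(loco$speed[move]) - 4) / 4, 0.2)
  expect_gt(mean(loco$speed[!move] < 0.5), 0.95)
  # near-infinite bout length: a single movement epoch fills the session
  set.seed(8)
  one <- simulate_locomotion(sim_config(duration = 120,
                                        bout_mean_length = 1e6,
                                        rest_mean_length = 0.01))
  expect_gt(mean(one$state == "move"), 0.99)
  runs <- rle(as.character(one$state))
  expect_equal(sum(runs$values == "move"), 1)
})

test_that("event trains follow base rate, coincidence, and velocity slope", {
  set.seed(11)
  cfg <- sim_config(n_cells = 40, duration = 600, base_rate = 0.05,
                    rate_velocity_slope = 0, n_ensembles = 0,
                    p_coactivate = 0)
  cm <- generate_cell_map(cfg)
  loco <- simulate_locomotion(cfg)
  gt <- simulate_event_trains(cfg, cm, loco)
  n_ev <- sum(lengths(gt$event_times))
  expected <- 0.05 * 600 * 40
  expect_lt(abs(n_ev - expected), 3 * sqrt(expected))

  # forced coincidence: every member shares the ensemble event times
  set.seed(12)
  cfg2 <- sim_config(n_cells = 20, duration = 120, base_rate = 0,
                     rate_velocity_slope = 0, n_ensembles = 1,
                     ensemble_radius = 500, p_coactivate = 1,
                     rest_shared_drive = 0.1, move_shared_drive = 0.1)
  cm2 <- generate_cell_map(cfg2)
  loco2 <- simulate_locomotion(cfg2)
  gt2 <- simulate_event_trains(cfg2, cm2, loco2)
  et <- sort(gt2$ensemble_event_times[[1]])
  for (i in which(!is.na(cm2$membership)))
    expect_equal(sort(gt2$event_times[[i]]), et)

  # velocity coupling: top velocity quartile fires more than bottom
  set.seed(13)
  cfg3 <- sim_config(n_cells = 40, duration = 600, base_rate = 0.02,
                     rate_velocity_slope = 0.02, n_ensembles = 0)
  cm3 <- generate_cell_map(cfg3)
  loco3 <- simulate_locomotion(cfg3)
  gt3 <- simulate_event_trains(cfg3, cm3, loco3)
  qv <- stats::quantile(loco3$speed, c(0.25, 0.75))
  all_t <- unlist(gt3$event_times)
  vi <- loco3$speed[pmin(floor(all_t * cfg3$track_rate) + 1,
                         length(loco3$speed))]
  t_lo <- sum(loco3$speed <= qv[1]) / cfg3$track_rate
  t_hi <- sum(loco3$speed >= qv[2]) / cfg3$track_rate
  expect_gt(sum(vi >= qv[2]) / t_hi, sum(vi <= qv[1]) / t_lo)
})

test_that("fluorescence rendering matches the kernel and noise model", {
  cfg <- sim_config(n_cells = 1, duration = 30, noise_sd = 0)
  gt0 <- structure(list(event_times = list(numeric(0))),
                   class = "ground_truth")
  sess0 <- render_fluorescence(gt0, cfg)
  expect_true(all(sess0$traces == 0))

  set.seed(2)
  gt1 <- structure(list(event_times = list(10)), class = "ground_truth")
  sess1 <- render_fluorescence(gt1, cfg)
  t_peak <- (which.max(sess1$traces[1, ]) - 1) / cfg$acq_rate
  expect_gte(t_peak, 10)
  expect_lte(t_peak, 10 + 5 * cfg$kernel_decay)

  set.seed(3)
  cfgn <- sim_config(n_cells = 1, duration = 120, noise_sd = 0.1)
  sessn <- render_fluorescence(gt0, cfgn)
  expect_lt(abs(stats::sd(sessn$traces[1, ]) - 0.1) / 0.1, 0.1)
})

test_that("a fixed seed reproduces the session bit-for-bit", {
  cfg <- small_cfg()
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session$traces, b$session$traces)
  expect_identical(a$loco$track, b$loco$track)
  expect_identical(a$ground_truth$event_times, b$ground_truth$event_times)
})

test_that("within-ensemble coincidence exceeds cross-ensemble by construction", {
  set.seed(21)
  cfg <- sim_config(n_cells = 30, duration = 400, n_ensembles = 2,
                    ensemble_radius = 80, p_coactivate = 0.7,
                    base_rate = 0.01, rate_velocity_slope = 0)
  cm <- generate_cell_map(cfg)
  loco <- simulate_locomotion(cfg)
  gt <- simulate_event_trains(cfg, cm, loco)
  coincidences <- function(i, j) {
    ti <- gt$event_times[[i]]; tj <- gt$event_times[[j]]
    if (!length(ti) || !length(tj)) return(0)
    sum(vapply(ti, function(t) any(abs(tj - t) <= 1), TRUE))
  }
  memb <- cm$membership
  within <- cross <- numeric(0)
  for (i in 1:29) for (j in (i + 1):30) {
    if (is.na(memb[i]) || is.na(memb[j])) next
    cc <- coincidences(i, j)
    if (memb[i] == memb[j]) within <- c(within, cc)
    else cross <- c(cross, cc)
  }
  expect_gt(mean(within), mean(cross))
})
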