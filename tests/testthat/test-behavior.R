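test_that("velocity computation matches hand arithmetic and closed forms", {
  still <- make_track(rep(5, 100), rep(5, 100))
  expect_equal(compute_velocity(still), rep(0, 100))

  # 1 px per frame at 30 fps and 0.1 cm/px -> 3 cm/s
  line <- make_track((0:99) * 0.1, rep(0, 100))
  expect_equal(compute_velocity(line), c(0, rep(3, 99)))

  # circle of radius r and period T -> speed 2*pi*r/T
  r <- 10; T <- 20; rate <- 30
  th <- 2 * pi * (0:(T * rate - 1)) / (T * rate)
  circ <- make_track(r * cos(th) + 15, r * sin(th) + 15, rate = rate)
  v <- compute_velocity(circ)[-1]
  expect_lt(max(abs(v - 2 * pi * r / T)) / (2 * pi * r / T), 0.01)

  bad <- make_track(1:10, 1:10)
  attr(bad, "cm_per_px") <- NULL
  expect_error(compute_velocity(bad), "cm_per_px")
})

test_that("median filtering removes spikes and matches a sliding oracle", {
  grid5 <- function(n_track, rate = 30) {
    t_track <- (seq_len(n_track) - 1) / rate
    sess <- structure(list(traces = matrix(0, 1, n_track),
                           timestamps_ms = t_track * 1000, acq_rate = rate,
                           cell_ids = "a"),
                      class = "fluorescence_session")
    align_streams(sess, data.frame(ts_ms = t_track * 1000))
  }
  n <- 600
  grid <- grid5(n)
  track <- make_track(rep(0, n), rep(0, n))

  lt <- filter_velocity(rep(2, n), track, grid)
  expect_true(all(abs(lt$velocity - 2) < 1e-12))

  spike <- rep(1, n); spike[300] <- 50
  lt2 <- filter_velocity(spike, track, grid)
  expect_true(all(abs(lt2$velocity - 1) < 1e-12))

  set.seed(9)
  v <- stats::rexp(n)
  lt3 <- filter_velocity(v, track, grid)
  oracle <- oracle_median_filter(v, 31)
  expect_equal(lt3$filtered_velocity, oracle)
  skip_if_not_installed("zoo")
  zoo_oracle <- zoo::rollapply(v, 31, stats::median, partial = TRUE)
  expect_equal(lt3$filtered_velocity, as.numeric(zoo_oracle))
})

test_that("epoch classification partitions time and counts bouts", {
  all_rest <- classify_epochs(make_loco(rep(0, 100)))
  expect_equal(nrow(all_rest$intervals), 1)
  expect_equal(all_rest$n_bouts, 0)
  expect_equal(all_rest$fraction_rest, 1)

  v <- rep(c(0, 1), 50)
  ep <- classify_epochs(make_loco(v))
  runs <- rle(v > 0.5)
  expect_equal(ep$n_bouts, sum(runs$values))

  # the boundary value 0.5 cm/s is rest
  epb <- classify_epochs(make_loco(c(0.5, 0.5, 1, 1)))
  expect_equal(as.character(epb$labels), c("rest", "rest", "move", "move"))

  # rest + move = total valid time, exactly
  set.seed(10)
  vv <- stats::rexp(500)
  valid <- stats::runif(500) > 0.1
  epv <- classify_epochs(make_loco(vv, valid = valid))
  expect_equal(sum(epv$intervals$n_bins), sum(valid))
})

# piecewise trace builder: segments of (duration s, speed cm/s); moving
# segments advance along x, "dither" segments jump back and forth in place
onset_track <- function(segments, rate = 30) {
  x <- numeric(0); y <- numeric(0)
  pos <- 0
  for (s in segments) {
    n <- s$dur * rate
    if (identical(s$kind, "dither")) {
      dx <- rep(c(0, s$speed / rate), length.out = n)
      x <- c(x, pos + dx); y <- c(y, rep(0, n))
    } else {
      step <- s$speed / rate
      x <- c(x, pos + cumsum(rep(step, n))); y <- c(y, rep(0, n))
      pos <- pos + step * n
    }
  }
  make_track(x, y, rate = rate)
}

test_that("onset detection applies displacement, smoothing, and rest rules", {
  # 10 s rest, 3 s at 5 cm/s, 10 s rest, 1 s at 5 cm/s
  tr <- onset_track(list(list(dur = 10, speed = 0),
                         list(dur = 3, speed = 5),
                         list(dur = 10, speed = 0),
                         list(dur = 1, speed = 5)))
  on <- detect_onsets(tr)
  expect_equal(length(on$onsets_s), 1)
  expect_lt(abs(on$onsets_s - 10), 0.2)

  # dithering in place: high frame speed, < 1 cm net over any 1 s
  di <- onset_track(list(list(dur = 10, speed = 0),
                         list(dur = 5, speed = 9, kind = "dither"),
                         list(dur = 10, speed = 0)))
  expect_equal(length(detect_onsets(di)$onsets_s), 0)

  # movement starting at t = 2 s lacks the 4 s pre-rest
  early <- onset_track(list(list(dur = 2, speed = 0),
                            list(dur = 5, speed = 5),
                            list(dur = 10, speed = 0)))
  expect_equal(length(detect_onsets(early)$onsets_s), 0)

  # too-short trace warns and returns none
  short <- onset_track(list(list(dur = 3, speed = 0)))
  expect_warning(res <- detect_onsets(short), "shorter")
  expect_equal(length(res$onsets_s), 0)
})

test_that("onsets sit on rest-to-move transitions of the filtered trace", {
  tr <- onset_track(list(list(dur = 6, speed = 0),
                         list(dur = 4, speed = 4),
                         list(dur = 8, speed = 0),
                         list(dur = 3, speed = 6)))
  on <- detect_onsets(tr)
  expect_gte(length(on$onsets_s), 1)
  for (t0 in on$onsets_s) {
    i <- which.min(abs(on$time_s - t0))
    expect_gt(on$velocity[i], 0.5)
    expect_lte(on$velocity[i - 1], 0.5)
  }
})

test_that("translating all positions leaves velocity and onsets unchanged", {
  tr <- onset_track(list(list(dur = 6, speed = 0),
                         list(dur = 4, speed = 4),
                         list(dur = 6, speed = 0)))
  tr2 <- tr
  tr2$x_px <- tr2$x_px + 123
  tr2$y_px <- tr2$y_px - 45
  attr(tr2, "cm_per_px") <- attr(tr, "cm_per_px")
  expect_equal(compute_velocity(tr), compute_velocity(tr2))
  expect_equal(detect_onsets(tr)$onsets_s, detect_onsets(tr2)$onsets_s)
})
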