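#' Place cells and spatial ensembles in the field of view
#'
#' Centroids are uniform over the field; ensemble centers are uniform as
#' well, and every cell lying within `ensemble_radius` of a center becomes a
#' member of that ensemble (nearest center wins if several are in range).
#'
#' Consumes the current RNG stream; seed via [simulate_session()] or
#' `set.seed()` for reproducibility.
#'
#' @param cfg a [sim_config()].
#' @return a `cell_map`: list with `centroids` (data.frame cell, x_um, y_um),
#'   `fov` (width, height in um), `ensemble_centers`, and `membership`
#'   (integer ensemble id per cell, `NA` for unaffiliated cells).
#' @export
generate_cell_map <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_cells
  cent <- data.frame(
    cell = cell_labels(n),
    x_um = quantize(stats::runif(n, 0, cfg$fov_width), 6),
    y_um = quantize(stats::runif(n, 0, cfg$fov_height), 6),
    stringsAsFactors = FALSE
  )
  k <- cfg$n_ensembles
  centers <- data.frame(
    ensemble = seq_len(k),
    x_um = stats::runif(k, 0, cfg$fov_width),
    y_um = stats::runif(k, 0, cfg$fov_height)
  )
  membership <- rep(NA_integer_, n)
  if (n > 0L && k > 0L) {
    d2 <- outer(cent$x_um, centers$x_um, "-")^2 +
      outer(cent$y_um, centers$y_um, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_len(n), nearest)] <= cfg$ensemble_radius^2
    membership[ok] <- nearest[ok]
  }
  structure(
    list(centroids = cent,
         fov = c(width = cfg$fov_width, height = cfg$fov_height),
         ensemble_centers = centers,
         membership = membership,
         ensemble_radius = cfg$ensemble_radius),
    class = "cell_map"
  )
}

cell_labels <- function(n) {
  if (n == 0L) return(character(0))
  sprintf("cell_%03d", seq_len(n))
}

#' Simulate open-field locomotion
#'
#' Rest and movement epochs alternate with exponentially distributed
#' lengths.  During movement the instantaneous speed follows a lognormal
#' AR(1) process (1 s correlation time) with the configured mean; at rest
#' the speed is half-normal jitter with 0.1 cm/s scale, keeping rest frames
#' well below the 0.5 cm/s movement threshold.  The centroid follows a
#' persistent random walk reflected at the arena walls and is emitted at the
#' tracking camera rate in pixels, exercising the calibration/alignment
#' path.
#'
#' @param cfg a [sim_config()].
#' @return a `locomotion_sim`: list with `track` (data.frame frame, ts_ms,
#'   x_px, y_px), `time_s`, `speed` (true cm/s per tracking frame) and
#'   `state` (factor rest/move per tracking frame).
#' @export
simulate_locomotion <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  dt <- 1 / cfg$track_rate
  n <- as.integer(round(cfg$duration * cfg$track_rate))
  time_s <- (seq_len(n) - 1L) * dt

  ## alternating rest/move epochs (rest first)
  state <- character(0)
  lab <- "rest"
  total <- 0L
  while (total < n) {
    mu <- if (lab == "rest") cfg$rest_mean_length else cfg$bout_mean_length
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / mu) * cfg$track_rate)))
    state <- c(state, rep(lab, len))
    total <- total + len
    lab <- if (lab == "rest") "move" else "rest"
  }
  state <- state[seq_len(n)]
  moving <- state == "move"

  ## speed: lognormal AR(1) during movement, half-normal jitter at rest
  sigma <- 0.5
  rho <- exp(-dt / 1)
  l <- stats::rnorm(n)           # innovations, drawn for every frame
  for (i in seq_len(n)[-1]) l[i] <- rho * l[i - 1] + sqrt(1 - rho^2) * l[i]
  speed <- numeric(n)
  speed[moving] <- cfg$mean_move_speed *
    exp(sigma * l[moving] - sigma^2 / 2)
  speed[!moving] <- abs(stats::rnorm(sum(!moving), 0, 0.1))

  ## persistent random walk, reflected at the arena walls
  theta <- cumsum(stats::rnorm(n, 0, 0.3))
  x <- numeric(n); y <- numeric(n)
  x[1] <- cfg$arena_cm / 2; y[1] <- cfg$arena_cm / 2
  stepx <- speed * dt * cos(theta)
  stepy <- speed * dt * sin(theta)
  for (i in seq_len(n)[-1]) {
    x[i] <- reflect01(x[i - 1] + stepx[i], cfg$arena_cm)
    y[i] <- reflect01(y[i - 1] + stepy[i], cfg$arena_cm)
  }

  track <- data.frame(
    frame = seq_len(n) - 1L,
    ts_ms = quantize(time_s * 1000, 3),
    x_px = quantize(x / cfg$cm_per_px, 6),
    y_px = quantize(y / cfg$cm_per_px, 6)
  )
  attr(track, "cm_per_px") <- cfg$cm_per_px
  structure(
    list(track = track, time_s = time_s, speed = speed,
         state = factor(state, levels = c("rest", "move")),
         cm_per_px = cfg$cm_per_px, track_rate = cfg$track_rate),
    class = "locomotion_sim"
  )
}

## quantize to a fixed number of decimals via the printed representation,
## so values survive a CSV write/read cycle bit-identically
quantize <- function(x, digits) {
  as.numeric(sprintf(paste0("%.", digits, "f"), x))
}

reflect01 <- function(p, hi) {
  if (p < 0) p <- -p
  if (p > hi) p <- 2 * hi - p
  min(max(p, 0), hi)
}

#' Simulate per-cell event trains with velocity coupling and ensemble drive
#'
#' Each cell fires as an inhomogeneous Poisson process with instantaneous
#' rate `base_rate + rate_velocity_slope * velocity(t)` (thinning).  On top,
#' each ensemble emits shared events as a Poisson process whose rate depends
#' on behavioral state (`rest_shared_drive` at rest, `move_shared_drive`
#' during movement); at each ensemble event every member cell fires with
#' probability `p_coactivate`, at the identical time.
#'
#' @param cfg a [sim_config()].
#' @param cell_map from [generate_cell_map()].
#' @param loco from [simulate_locomotion()].
#' @return a `ground_truth`: list with `event_times` (per-cell sorted
#'   vectors, s), `ensemble_membership`, `ensemble_event_times`,
#'   `state` and `true_velocity` at the tracking rate.
#' @export
simulate_event_trains <- function(cfg, cell_map, loco) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_cells
  dur <- cfg$duration
  vel_at <- function(t) {
    i <- pmin(pmax(floor(t * cfg$track_rate) + 1, 1), length(loco$speed))
    loco$speed[i]
  }
  state_at <- function(t) {
    i <- pmin(pmax(floor(t * cfg$track_rate) + 1, 1), length(loco$state))
    loco$state[i]
  }

  events <- vector("list", n)
  vmax <- max(loco$speed, 0)
  rmax <- cfg$base_rate + cfg$rate_velocity_slope * vmax
  for (c in seq_len(n)) {
    times <- numeric(0)
    if (rmax > 0) {
      m <- stats::rpois(1, rmax * dur)
      cand <- sort(stats::runif(m, 0, dur))
      acc <- stats::runif(m) * rmax <
        cfg$base_rate + cfg$rate_velocity_slope * vel_at(cand)
      times <- cand[acc]
    }
    events[[c]] <- times
  }

  k <- cfg$n_ensembles
  ens_times <- vector("list", k)
  dmax <- max(cfg$rest_shared_drive, cfg$move_shared_drive)
  if (k > 0L && dmax > 0) {
    for (e in seq_len(k)) {
      m <- stats::rpois(1, dmax * dur)
      cand <- sort(stats::runif(m, 0, dur))
      drive <- ifelse(state_at(cand) == "rest",
                      cfg$rest_shared_drive, cfg$move_shared_drive)
      et <- cand[stats::runif(m) * dmax < drive]
      ens_times[[e]] <- et
      members <- which(!is.na(cell_map$membership) &
                         cell_map$membership == e)
      for (t0 in et) {
        fire <- members[stats::runif(length(members)) < cfg$p_coactivate]
        for (c in fire) events[[c]] <- c(events[[c]], t0)
      }
    }
  }
  events <- lapply(events, sort)
  structure(
    list(event_times = events,
         ensemble_membership = cell_map$membership,
         ensemble_event_times = ens_times,
         state = loco$state,
         true_velocity = loco$speed),
    class = "ground_truth"
  )
}

#' Transient kernel (difference of exponentials, unit peak)
#' @keywords internal
transient_kernel <- function(rise, decay, rate, n_tail = 8) {
  tt <- seq(0, decay * n_tail, by = 1 / rate)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

#' Render fluorescence traces from ground-truth event times
#'
#' Each event contributes a difference-of-exponentials transient with unit
#' amplitude times lognormal jitter (sdlog 0.25); Gaussian noise with SD
#' `noise_sd` is added, and traces are quantized to 1e-6 (finite-precision
#' export, so text round-trips are exact).
#'
#' @param gt a `ground_truth`.
#' @param cfg a [sim_config()].
#' @return a `fluorescence_session`: list with `traces` (cells x frames),
#'   `timestamps_ms`, `acq_rate`, `cell_ids`.
#' @export
render_fluorescence <- function(gt, cfg) {
  cfg <- validate_sim_config(cfg)
  n_frames <- as.integer(round(cfg$duration * cfg$acq_rate))
  n <- length(gt$event_times)
  kern <- transient_kernel(cfg$kernel_rise, cfg$kernel_decay, cfg$acq_rate)
  traces <- matrix(0, nrow = n, ncol = n_frames)
  for (c in seq_len(n)) {
    et <- gt$event_times[[c]]
    if (any(et < 0 | et > cfg$duration))
      stop("render_fluorescence: event times outside [0, duration]")
    x <- numeric(n_frames)
    if (length(et)) {
      amp <- stats::rlnorm(length(et), 0, 0.25)
      idx <- pmin(floor(et * cfg$acq_rate) + 1L, n_frames)
      imp <- numeric(n_frames)
      for (j in seq_along(idx)) imp[idx[j]] <- imp[idx[j]] + amp[j]
      x <- conv_causal(imp, kern)
    }
    if (cfg$noise_sd > 0)
      x <- x + stats::rnorm(n_frames, 0, cfg$noise_sd)
    traces[c, ] <- quantize(x, 6)
  }
  structure(
    list(traces = traces,
         timestamps_ms = quantize((seq_len(n_frames) - 1L) * 1000 /
                                    cfg$acq_rate, 3),
         acq_rate = cfg$acq_rate,
         cell_ids = cell_labels(n)),
    class = "fluorescence_session"
  )
}

## causal convolution, output truncated to length(x)
conv_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

#' Generate a full annotated synthetic session
#'
#' Runs the whole generator under a single seed: cell map, locomotion,
#' event trains, fluorescence.  A fixed config (including seed) yields a
#' bit-identical session.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_session`: list with `config`, `cell_map`, `loco`,
#'   `ground_truth`, `session`.
#' @export
simulate_session <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  cell_map <- generate_cell_map(cfg)
  loco <- simulate_locomotion(cfg)
  gt <- simulate_event_trains(cfg, cell_map, loco)
  sess <- render_fluorescence(gt, cfg)
  structure(
    list(config = cfg, cell_map = cell_map, loco = loco,
         ground_truth = gt, session = sess),
    class = "sim_session"
  )
}

#' Write a synthetic session to disk in the documented CSV/JSON layout
#'
#' Files: `traces.csv` (one column per cell, one row per frame),
#' `timestamps.csv` (frame, ts_ms), `centroids.csv` (cell, x_um, y_um),
#' `tracking.csv` (frame, ts_ms, x_px, y_px), `ground_truth.json`,
#' `config.json`.
#'
#' @param sim a `sim_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- as.data.frame(t(sim$session$traces))
  names(tr) <- sim$session$cell_ids
  data.table::fwrite(tr, file.path(dir, "traces.csv"))
  data.table::fwrite(
    data.frame(frame = seq_along(sim$session$timestamps_ms) - 1L,
               ts_ms = sim$session$timestamps_ms),
    file.path(dir, "timestamps.csv"))
  data.table::fwrite(sim$cell_map$centroids, file.path(dir, "centroids.csv"))
  data.table::fwrite(sim$loco$track, file.path(dir, "tracking.csv"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(event_times = gt$event_times,
         ensemble_membership = gt$ensemble_membership,
         state = as.character(gt$state),
         true_velocity = gt$true_velocity),
    file.path(dir, "ground_truth.json"),
    auto_unbox = FALSE, digits = NA, na = "null")
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
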