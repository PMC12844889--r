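# Shared fixtures, built in code at load time.

# small, fast session used by several suites
small_cfg <- function(...) {
  sim_config(n_cells = 12, duration = 240, n_ensembles = 1,
             ensemble_radius = 120, fov_width = 300, fov_height = 300,
             seed = 42, ...)
}

run_small_pipeline <- function(cfg = small_cfg()) {
  sim <- simulate_session(cfg)
  grid <- align_streams(sim$session, sim$loco$track)
  raster <- normalize_session(sim$session, grid)
  ev <- detect_events(raster)
  loco <- filter_velocity(compute_velocity(sim$loco$track, cfg$cm_per_px),
                          sim$loco$track, grid)
  list(sim = sim, grid = grid, raster = raster, ev = ev,
       act = binary_raster(ev), loco = loco,
       epochs = classify_epochs(loco))
}

# wrap a plain z matrix as a normalized_raster (for constructed traces)
make_raster <- function(z, dt = 0.2, t0 = 0) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  structure(
    list(z = z, time = t0 + (seq_len(ncol(z)) - 1) * dt,
         bin_duration = dt,
         cell_ids = sprintf("cell_%03d", seq_len(nrow(z))),
         valid = rep(TRUE, ncol(z)),
         scale = rep(1, nrow(z)), mu = rep(0, nrow(z)),
         sd = rep(1, nrow(z))),
    class = "normalized_raster")
}

# wrap a velocity vector as a locomotion_trace on a 5 Hz grid
make_loco <- function(v, dt = 0.2, t0 = 0, valid = NULL) {
  structure(
    list(velocity = v, raw_velocity = v, filtered_velocity = v,
         time = t0 + (seq_along(v) - 1) * dt,
         valid = valid %||% rep(TRUE, length(v)), dt = dt),
    class = "locomotion_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tracking table from cm positions at a given rate
make_track <- function(x_cm, y_cm, rate = 30, cm_per_px = 0.1) {
  n <- length(x_cm)
  tr <- data.frame(frame = seq_len(n) - 1L,
                   ts_ms = (seq_len(n) - 1L) * 1000 / rate,
                   x_px = x_cm / cm_per_px, y_px = y_cm / cm_per_px)
  attr(tr, "cm_per_px") <- cm_per_px
  tr
}

# brute-force reference implementations (independent of the package paths)
oracle_dilate <- function(active, k) {
  out <- active
  for (r in seq_len(nrow(active)))
    for (j in which(active[r, ]))
      out[r, j:min(ncol(active), j + k)] <- TRUE
  out
}

oracle_jaccard <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) NA_real_ else i / u
}

oracle_scan_events <- function(z, thr, min_bins) {
  n <- length(z)
  above <- !is.na(z) & z >= thr
  runs <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_bins) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

oracle_median_filter <- function(x, k) {
  h <- (k - 1) %/% 2
  vapply(seq_along(x), function(i)
    stats::median(x[max(1, i - h):min(length(x), i + h)]), 0)
}
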