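#' Event-detection parameters
#'
#' Threshold-crossing detection on the z-scored 5 Hz raster: an event is a
#' maximal run of bins at or above `threshold` z-units lasting at least
#' `min_duration` seconds.
#'
#' @param threshold z-score threshold (default 2.5 SD above baseline).
#' @param min_duration minimum time above threshold (s; default 1 s = 5
#'   bins at 5 Hz).
#' @return list of class `event_params`.
#' @export
event_params <- function(threshold = 2.5, min_duration = 1) {
  stopifnot(threshold > 0, min_duration > 0)
  structure(list(threshold = threshold, min_duration = min_duration),
            class = "event_params")
}

#' Detect calcium events on the normalized raster
#'
#' Finds, per cell, maximal runs of 5 Hz bins with z >= threshold that last
#' at least `min_duration`.  The event time is the midpoint between the
#' time of the run's maximum and the preceding local minimum (searching
#' left from the run start; the first sample acts as the minimum at the
#' trace edge); amplitude is the run maximum (z-units), duration the time
#' above threshold.  Supra-threshold runs separated by a single
#' sub-threshold bin are not merged.  Invalid (NA) bins break runs.
#'
#' @param raster a `normalized_raster`.
#' @param p an [event_params()].
#' @return an `event_series`: data.frame with columns `cell`, `time_s`,
#'   `amplitude_z`, `duration_s`, `start_bin`, `end_bin`, `peak_bin`;
#'   attributes `n_bins`, `bin_duration`, `cell_ids`, `time`.
#' @export
detect_events <- function(raster, p = event_params()) {
  stopifnot(inherits(raster, "normalized_raster"))
  min_bins <- as.integer(round(p$min_duration / raster$bin_duration))
  if (min_bins < 1L) min_bins <- 1L
  out <- vector("list", nrow(raster$z))
  for (c in seq_len(nrow(raster$z))) {
    z <- raster$z[c, ]
    out[[c]] <- scan_runs(z, raster$time, raster$cell_ids[c],
                          p$threshold, min_bins)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(cell = character(0), time_s = numeric(0),
                     amplitude_z = numeric(0), duration_s = numeric(0),
                     start_bin = integer(0), end_bin = integer(0),
                     peak_bin = integer(0))
  rownames(ev) <- NULL
  structure(ev, class = c("event_series", "data.frame"),
            n_bins = ncol(raster$z), bin_duration = raster$bin_duration,
            cell_ids = raster$cell_ids, time = raster$time)
}

## run-length scan of one z trace; returns the per-cell event data.frame
scan_runs <- function(z, time, cell, threshold, min_bins) {
  above <- !is.na(z) & z >= threshold
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bins
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(starts)
  peak <- integer(n); amp <- numeric(n); tmid <- numeric(n)
  dt <- if (length(time) > 1) time[2] - time[1] else 0.2
  for (i in seq_len(n)) {
    seg <- starts[i]:ends[i]
    pk <- seg[which.max(z[seg])]
    j <- starts[i]
    while (j > 1L && !is.na(z[j - 1L]) && z[j - 1L] < z[j]) j <- j - 1L
    peak[i] <- pk
    amp[i] <- z[pk]
    tmid[i] <- (time[pk] + time[j]) / 2
  }
  data.frame(cell = cell, time_s = tmid, amplitude_z = amp,
             duration_s = (ends - starts + 1L) * dt,
             start_bin = starts, end_bin = ends, peak_bin = peak,
             stringsAsFactors = FALSE)
}

#' Binary activity raster from detected events
#'
#' Active bins are exactly the supra-threshold spans of the detected
#' events (no smoothing; see [forward_smooth()] for the co-activity
#' dilation).
#'
#' @param events an `event_series`.
#' @return logical matrix cells x bins.
#' @export
binary_raster <- function(events) {
  ids <- attr(events, "cell_ids")
  n_bins <- attr(events, "n_bins")
  active <- matrix(FALSE, length(ids), n_bins,
                   dimnames = list(ids, NULL))
  for (i in seq_len(nrow(events))) {
    r <- match(events$cell[i], ids)
    active[r, events$start_bin[i]:events$end_bin[i]] <- TRUE
  }
  active
}

#' Event rate as a function of animal velocity
#'
#' For each velocity bin, the number of events whose event time falls in
#' 5 Hz frames with velocity in that bin, divided by the total time spent
#' in the bin, averaged across cells.  Velocity bins with no occupancy are
#' reported as `NA` (flagged, never zero).
#'
#' @param events an `event_series`.
#' @param loco a `locomotion_trace` on the same grid.
#' @param bin_edges velocity bin edges (cm/s).
#' @return data.frame `v_lo`, `v_hi`, `v_mid`, `time_s`, `n_events`,
#'   `rate` (events/s per cell).
#' @export
event_rate_by_velocity <- function(events, loco,
                                   bin_edges = seq(0, 10, by = 1)) {
  stopifnot(inherits(loco, "locomotion_trace"))
  n_cells <- length(attr(events, "cell_ids"))
  dt <- attr(events, "bin_duration")
  v <- loco$velocity
  ok <- loco$valid & !is.na(v)
  vbin_frame <- findInterval(v, bin_edges, left.open = FALSE)
  vbin_frame[!ok | vbin_frame < 1L | vbin_frame >= length(bin_edges)] <-
    NA_integer_
  time_in <- tabulate(vbin_frame, nbins = length(bin_edges) - 1L) * dt

  ev_frame <- frame_of_time(events$time_s, attr(events, "time"), dt)
  ev_vbin <- vbin_frame[ev_frame]
  counts <- tabulate(ev_vbin[!is.na(ev_vbin)],
                     nbins = length(bin_edges) - 1L)
  rate <- ifelse(time_in > 0, counts / (time_in * n_cells), NA_real_)
  data.frame(v_lo = bin_edges[-length(bin_edges)], v_hi = bin_edges[-1],
             v_mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
             time_s = time_in, n_events = counts, rate = rate)
}

## map event times onto grid bins (clamped to the grid)
frame_of_time <- function(t, time, dt) {
  f <- floor((t - time[1]) / dt) + 1L
  pmin(pmax(f, 1L), length(time))
}

#' Event probability around movement onsets
#'
#' Fraction of (cell, onset) pairs with at least one event in each offset
#' bin of the peri-onset window, averaged across onsets.
#'
#' @param events an `event_series`.
#' @param onsets onset times (s); must be non-empty.
#' @param window half-width of the peri-onset window (s).
#' @return data.frame `offset_s`, `prob`.
#' @export
event_prob_around_movement <- function(events, onsets, window = 2) {
  if (!length(onsets)) stop("event_prob_around_movement: no onsets",
                            call. = FALSE)
  dt <- attr(events, "bin_duration")
  ids <- attr(events, "cell_ids")
  offsets <- seq(-window, window - dt, by = dt)
  total <- length(ids) * length(onsets)
  prob <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    nhit <- 0L
    for (on in onsets) {
      lo <- on + offsets[k]; hi <- lo + dt
      sel <- events$time_s >= lo & events$time_s < hi
      nhit <- nhit + length(unique(events$cell[sel]))
    }
    prob[k] <- nhit / total
  }
  data.frame(offset_s = offsets, prob = prob)
}

#' Descriptive summary of event amplitudes and durations
#'
#' @param events an `event_series`.
#' @return list with `pooled` (data.frame metric, mean, sd, n) and
#'   `per_cell` (data.frame cell, n, mean_amplitude, mean_duration).
#' @export
event_summary <- function(events) {
  if (!nrow(events))
    return(list(pooled = data.frame(metric = character(0),
                                    mean = numeric(0), sd = numeric(0),
                                    n = integer(0)),
                per_cell = data.frame(cell = character(0), n = integer(0),
                                      mean_amplitude = numeric(0),
                                      mean_duration = numeric(0))))
  pooled <- data.frame(
    metric = c("amplitude_z", "duration_s"),
    mean = c(mean(events$amplitude_z), mean(events$duration_s)),
    sd = c(stats::sd(events$amplitude_z), stats::sd(events$duration_s)),
    n = nrow(events))
  cells <- split(events, events$cell)
  per_cell <- data.frame(
    cell = names(cells),
    n = vapply(cells, nrow, 0L),
    mean_amplitude = vapply(cells, function(d) mean(d$amplitude_z), 0),
    mean_duration = vapply(cells, function(d) mean(d$duration_s), 0),
    row.names = NULL)
  list(pooled = pooled, per_cell = per_cell)
}

#' Precision/recall of detected events against ground truth
#'
#' Greedy one-to-one matching of detected to true event times per cell
#' within a tolerance.
#'
#' @param events an `event_series`.
#' @param gt a `ground_truth` from the synthetic generator.
#' @param tol matching tolerance (s).
#' @return list `precision`, `recall`, `n_detected`, `n_true`.
#' @export
event_recovery <- function(events, gt, tol = 1) {
  ids <- attr(events, "cell_ids")
  n_match <- 0L; n_det <- 0L; n_true <- 0L
  for (c in seq_along(ids)) {
    det <- sort(events$time_s[events$cell == ids[c]])
    tru <- sort(gt$event_times[[c]])
    n_det <- n_det + length(det)
    n_true <- n_true + length(tru)
    used <- rep(FALSE, length(tru))
    for (t in det) {
      if (!length(tru)) next
      d <- abs(tru - t)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tol) { used[j] <- TRUE; n_match <- n_match + 1L }
    }
  }
  list(precision = if (n_det) n_match / n_det else NA_real_,
       recall = if (n_true) n_match / n_true else NA_real_,
       n_detected = n_det, n_true = n_true)
}
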