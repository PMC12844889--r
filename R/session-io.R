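#' Load a session from its on-disk CSV layout
#'
#' Reads and validates the extracted-trace, centroid and tracking files
#' written by [write_session()] (or exported by an upstream segmentation /
#' tracking pipeline with the same column contract).  Timestamps must be
#' strictly increasing (miniscope) / nondecreasing (tracking); traces must
#' be gap-free; the centroid file must contain exactly the cell ids present
#' in the trace file.
#'
#' @param dir session directory containing `traces.csv`, `timestamps.csv`,
#'   `centroids.csv`, `tracking.csv` and optionally `config.json`.
#' @param config optional list overriding `cm_per_px`, `fov_width`,
#'   `fov_height`, `acq_rate`, `track_rate`; defaults are taken from
#'   `config.json` when present.
#' @return list with `session` (`fluorescence_session`), `cell_map`
#'   (`cell_map` with centroids only) and `tracking` (data.frame `frame`,
#'   `ts_ms`, `x_px`, `y_px`, attribute `cm_per_px`).
#' @export
load_session <- function(dir, config = list()) {
  need <- c("traces.csv", "timestamps.csv", "centroids.csv", "tracking.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("load_session: missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfgfile <- file.path(dir, "config.json")
  base <- if (file.exists(cfgfile)) jsonlite::read_json(cfgfile,
                                                        simplifyVector = TRUE)
          else list()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  cm_per_px <- base$cm_per_px %||% 0.1

  tr <- data.table::fread(file.path(dir, "traces.csv"), data.table = FALSE)
  ts <- data.table::fread(file.path(dir, "timestamps.csv"),
                          data.table = FALSE)
  cent <- data.table::fread(file.path(dir, "centroids.csv"),
                            data.table = FALSE)
  track <- data.table::fread(file.path(dir, "tracking.csv"),
                             data.table = FALSE)

  if (nrow(tr) != nrow(ts))
    stop("load_session: traces have ", nrow(tr), " frames but timestamps ",
         nrow(ts), call. = FALSE)
  if (any(diff(ts$ts_ms) <= 0))
    stop("load_session: miniscope timestamps are not strictly increasing",
         call. = FALSE)
  if (any(diff(track$ts_ms) < 0))
    stop("load_session: tracking timestamps are not nondecreasing",
         call. = FALSE)
  bad <- which(is.na(as.matrix(tr)), arr.ind = TRUE)
  if (nrow(bad))
    stop("load_session: missing values in traces (first: cell ",
         names(tr)[bad[1, 2]], ", frame ", bad[1, 1], ")", call. = FALSE)
  ids <- names(tr)
  only_tr <- setdiff(ids, cent$cell)
  only_ct <- setdiff(cent$cell, ids)
  if (length(only_tr) || length(only_ct))
    stop("load_session: cell ids mismatch between traces and centroids",
         if (length(only_tr)) paste0("; missing centroids for: ",
                                     paste(only_tr, collapse = ", ")),
         if (length(only_ct)) paste0("; centroids without traces: ",
                                     paste(only_ct, collapse = ", ")),
         call. = FALSE)
  cent <- cent[match(ids, cent$cell), , drop = FALSE]
  if (any(!is.finite(cent$x_um)) || any(!is.finite(cent$y_um)))
    stop("load_session: non-finite centroid coordinates", call. = FALSE)

  acq_rate <- base$acq_rate %||%
    (1000 * (nrow(ts) - 1) / (ts$ts_ms[nrow(ts)] - ts$ts_ms[1]))
  sess <- structure(
    list(traces = t(as.matrix(tr)), timestamps_ms = ts$ts_ms,
         acq_rate = acq_rate, cell_ids = ids),
    class = "fluorescence_session")
  fov <- c(width = base$fov_width %||% max(cent$x_um),
           height = base$fov_height %||% max(cent$y_um))
  cell_map <- structure(
    list(centroids = cent, fov = fov, ensemble_centers = NULL,
         membership = rep(NA_integer_, length(ids)), ensemble_radius = NA),
    class = "cell_map")
  attr(track, "cm_per_px") <- cm_per_px
  list(session = sess, cell_map = cell_map, tracking = track)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align miniscope and tracking streams onto a common 5 Hz grid
#'
#' Builds half-open 200 ms bins `[t, t + 1/rate)` anchored at the later of
#' the two stream starts and spanning the overlap.  Every frame whose
#' timestamp falls inside a bin maps to that bin; grid bins with no tracking
#' sample within 500 ms of the bin center are marked invalid and excluded
#' from all downstream statistics (shorter gaps inherit the nearest
#' sample).
#'
#' @param sess a `fluorescence_session`.
#' @param track tracking data.frame with `ts_ms`.
#' @param target_rate grid rate (Hz), default 5.
#' @return an `align_grid`: list with `t0`, `dt`, `n_bins`, `time` (bin
#'   starts, s), `mini_bin` (grid bin per miniscope frame, NA outside the
#'   overlap), `track_bin`, `track_nearest` (tracking row per bin after
#'   nearest-neighbor fill, NA if invalid) and `valid`.
#' @export
align_streams <- function(sess, track, target_rate = 5) {
  t_mini <- sess$timestamps_ms / 1000
  t_track <- track$ts_ms / 1000
  dt <- 1 / target_rate
  t0 <- max(t_mini[1], t_track[1])
  t1 <- min(t_mini[length(t_mini)], t_track[length(t_track)])
  dur_m <- t_mini[length(t_mini)] - t_mini[1]
  dur_t <- t_track[length(t_track)] - t_track[1]
  if (t1 - t0 < 0.5 * max(dur_m, dur_t))
    stop("align_streams: streams overlap for less than 50% of the session",
         call. = FALSE)
  n_bins <- as.integer(floor((t1 - t0) / dt))
  if (n_bins < 1L) stop("align_streams: no full grid bin in the overlap",
                        call. = FALSE)
  edges <- t0 + (0:n_bins) * dt

  bin_of <- function(t) {
    b <- findInterval(t, edges, left.open = FALSE)
    b[b < 1L | b > n_bins] <- NA_integer_
    # half-open bins: a timestamp equal to the right edge belongs outside
    b[!is.na(b) & t >= edges[n_bins + 1L]] <- NA_integer_
    b
  }
  mini_bin <- bin_of(t_mini)
  track_bin <- bin_of(t_track)

  centers <- t0 + (seq_len(n_bins) - 0.5) * dt
  # nearest tracking sample per bin center (two-pointer over sorted times)
  nearest <- findInterval(centers, t_track)
  lo <- pmax(nearest, 1L)
  hi <- pmin(nearest + 1L, length(t_track))
  pick_hi <- abs(t_track[hi] - centers) < abs(t_track[lo] - centers)
  track_nearest <- ifelse(pick_hi, hi, lo)
  gap <- abs(t_track[track_nearest] - centers)
  valid <- gap <= 0.5
  track_nearest[!valid] <- NA_integer_

  structure(
    list(t0 = t0, dt = dt, n_bins = n_bins,
         time = t0 + (seq_len(n_bins) - 1L) * dt,
         mini_bin = mini_bin, track_bin = track_bin,
         track_nearest = track_nearest, valid = valid),
    class = "align_grid")
}
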