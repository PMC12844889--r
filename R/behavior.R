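#' Frame-by-frame centroid velocity from tracking output
#'
#' `v[t] = cm_per_px * ||pos[t] - pos[t-1]|| / dt`, with the first frame set
#' to 0.  Time steps come from the tracking timestamps.
#'
#' @param track tracking data.frame (`ts_ms`, `x_px`, `y_px`).
#' @param cm_per_px calibration (cm per pixel); defaults to the attribute
#'   set by [load_session()].
#' @return numeric velocity (cm/s) at the tracking rate.
#' @export
compute_velocity <- function(track, cm_per_px = attr(track, "cm_per_px")) {
  if (is.null(cm_per_px) || !is.finite(cm_per_px) || cm_per_px <= 0)
    stop("compute_velocity: missing or invalid cm_per_px calibration",
         call. = FALSE)
  n <- nrow(track)
  if (n < 2L) return(numeric(n))
  dt <- diff(track$ts_ms) / 1000
  if (any(dt <= 0)) stop("compute_velocity: non-increasing timestamps",
                         call. = FALSE)
  step <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2) * cm_per_px
  c(0, step / dt)
}

## centered median filter with truncated (shrinking) windows at the edges
median_filter <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n < 2L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  if (k >= n) {
    return(vapply(seq_len(n),
                  function(i) stats::median(x[max(1, i - h):min(n, i + h)]),
                  0))
  }
  out <- stats::runmed(x, k, endrule = "keep")
  for (i in seq_len(h)) {
    out[i] <- stats::median(x[1:(i + h)])
    out[n - i + 1L] <- stats::median(x[(n - i + 1L - h):n])
  }
  as.numeric(out)
}

#' Median-filter and downsample velocity onto the 5 Hz grid
#'
#' Applies a 1 s centered median filter at the tracking rate, then
#' downsamples to the aligned 5 Hz grid using the within-bin mean.  Grid
#' bins without a tracking sample inherit the nearest sample when the gap
#' is at most 500 ms; longer gaps are invalid.
#'
#' @param raw velocity at the tracking rate from [compute_velocity()].
#' @param track the tracking data.frame (for timestamps).
#' @param grid an `align_grid`.
#' @param median_window filter window (s).
#' @return a `locomotion_trace`: list with `velocity` (cm/s at 5 Hz),
#'   `raw_velocity`, `filtered_velocity` (tracking rate), `time` (grid bin
#'   starts), `valid`.
#' @export
filter_velocity <- function(raw, track, grid, median_window = 1) {
  stopifnot(inherits(grid, "align_grid"), length(raw) == nrow(track))
  rate <- 1000 / stats::median(diff(track$ts_ms))
  k <- as.integer(round(median_window * rate))
  if (k %% 2L == 0L) k <- k + 1L
  vf <- median_filter(raw, k)
  v5 <- rep(NA_real_, grid$n_bins)
  keep <- !is.na(grid$track_bin)
  if (any(keep)) {
    mn <- tapply(vf[keep], grid$track_bin[keep], mean)
    v5[as.integer(names(mn))] <- as.numeric(mn)
  }
  fill <- is.na(v5) & !is.na(grid$track_nearest)
  v5[fill] <- vf[grid$track_nearest[fill]]
  valid <- grid$valid & !is.na(v5)
  structure(
    list(velocity = v5, raw_velocity = raw, filtered_velocity = vf,
         time = grid$time, valid = valid, dt = grid$dt),
    class = "locomotion_trace")
}

#' Classify rest and movement epochs and segment bouts
#'
#' Movement bins have velocity strictly above the threshold; bins at or
#' below it (including exactly 0.5 cm/s) are rest.  Contiguous runs of
#' valid movement bins are bouts.  Invalid bins are excluded and break
#' runs.
#'
#' @param loco a `locomotion_trace`.
#' @param v_thresh movement threshold (cm/s).
#' @return an `epoch_set`: list with `labels` (factor per bin, NA for
#'   invalid), `intervals` (label, start_s, end_s), `bouts`, `onset_bins`
#'   (rest-to-move transition bins), `n_bouts`, `mean_bout_length`,
#'   `fraction_rest`, `v_thresh`.
#' @export
classify_epochs <- function(loco, v_thresh = 0.5) {
  stopifnot(inherits(loco, "locomotion_trace"))
  v <- loco$velocity
  lab <- rep(NA_character_, length(v))
  ok <- loco$valid & !is.na(v)
  lab[ok] <- ifelse(v[ok] > v_thresh, "move", "rest")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  iv <- data.frame(
    label = r$values[keep],
    start_s = loco$time[starts[keep]],
    end_s = loco$time[ends[keep]] + loco$dt,
    n_bins = r$lengths[keep])
  bouts <- iv[iv$label == "move", , drop = FALSE]
  rownames(bouts) <- NULL
  structure(
    list(labels = factor(lab, levels = c("rest", "move")),
         intervals = iv, bouts = bouts,
         n_bouts = nrow(bouts),
         mean_bout_length = if (nrow(bouts))
           mean(bouts$end_s - bouts$start_s) else NA_real_,
         fraction_rest = sum(lab == "rest", na.rm = TRUE) / sum(ok),
         v_thresh = v_thresh, time = loco$time, dt = loco$dt),
    class = "epoch_set")
}

#' Movement-onset detection parameters
#'
#' @param displacement_min minimum net displacement (cm) within the
#'   lookahead window for a frame to count as moving.
#' @param lookahead displacement lookahead (s).
#' @param smooth_window moving-average window (s; 167 ms = 5 frames at
#'   30 fps).
#' @param v_thresh movement threshold (cm/s).
#' @param min_move minimum movement duration (s).
#' @param min_pre_rest required rest before onset (s).
#' @return list of class `onset_params`.
#' @export
onset_params <- function(displacement_min = 1, lookahead = 1,
                         smooth_window = 0.167, v_thresh = 0.5,
                         min_move = 2, min_pre_rest = 4) {
  p <- list(displacement_min = displacement_min, lookahead = lookahead,
            smooth_window = smooth_window, v_thresh = v_thresh,
            min_move = min_move, min_pre_rest = min_pre_rest)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, TRUE)))
  structure(p, class = "onset_params")
}

#' Detect movement onsets (forward ambulation) at the tracking rate
#'
#' Three rules: (1) a frame's velocity is zeroed unless the centroid moves
#' more than `displacement_min` cm from its current location at some point
#' within the next `lookahead` seconds (suppresses in-place dither);
#' (2) the resulting trace is smoothed with a centered `smooth_window`
#' moving average; (3) an onset is the first frame of every maximal run
#' with velocity above `v_thresh` lasting at least `min_move` seconds whose
#' preceding `min_pre_rest` seconds are entirely at or below `v_thresh` on
#' the filtered trace (the full pre-rest window must exist).
#'
#' @param track tracking data.frame.
#' @param p an [onset_params()].
#' @param cm_per_px calibration; defaults to the track attribute.
#' @return an `onset_set`: list with `onsets_s`, `velocity` (the filtered
#'   trace), `time_s`.
#' @export
detect_onsets <- function(track, p = onset_params(),
                          cm_per_px = attr(track, "cm_per_px")) {
  v <- compute_velocity(track, cm_per_px)
  t_s <- track$ts_ms / 1000
  n <- length(v)
  rate <- 1000 / stats::median(diff(track$ts_ms))
  need <- (p$min_pre_rest + p$min_move) * rate
  if (n < need) {
    warning("detect_onsets: trace shorter than min_pre_rest + min_move; ",
            "no onsets")
    return(structure(list(onsets_s = numeric(0), velocity = v,
                          time_s = t_s), class = "onset_set"))
  }

  ## rule 1: displacement filter over the next `lookahead` seconds
  K <- as.integer(round(p$lookahead * rate))
  x <- track$x_px * cm_per_px
  y <- track$y_px * cm_per_px
  maxdisp <- numeric(n)
  for (k in seq_len(K)) {
    idx <- pmin(seq_len(n) + k, n)
    d <- sqrt((x[idx] - x)^2 + (y[idx] - y)^2)
    maxdisp <- pmax(maxdisp, d)
  }
  v1 <- ifelse(maxdisp > p$displacement_min, v, 0)

  ## rule 2: centered moving average (truncated at the edges)
  w <- 2L * floor(p$smooth_window * rate / 2) + 1L
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v1))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  v2 <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  ## rule 3: sustained movement preceded by sustained rest
  moving <- v2 > p$v_thresh
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- as.integer(round(p$min_move * rate))
  pre <- as.integer(round(p$min_pre_rest * rate))
  onsets <- numeric(0)
  for (i in which(r$values & r$lengths >= min_run)) {
    s <- starts[i]
    if (s - pre < 1L) next
    if (all(v2[(s - pre):(s - 1L)] <= p$v_thresh))
      onsets <- c(onsets, t_s[s])
  }
  structure(list(onsets_s = onsets, velocity = v2, time_s = t_s),
            class = "onset_set")
}
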