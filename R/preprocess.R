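#' Scale a trace to its 99th percentile
#'
#' Divides the trace by its 99th percentile (linear-interpolation quantile),
#' so the scaled trace has a 99th percentile of 1.  Degenerate (constant or
#' non-positive-p99) traces are an error: such a cell carries no signal.
#'
#' @param x numeric trace.
#' @return scaled trace.
#' @export
scale_to_p99 <- function(x) {
  if (!is.numeric(x) || !length(x)) stop("scale_to_p99: empty trace")
  if (anyNA(x)) stop("scale_to_p99: trace contains missing values")
  if (max(x) == min(x))
    stop("scale_to_p99: constant trace (degenerate cell)", call. = FALSE)
  q <- unname(stats::quantile(x, 0.99, type = 7))
  if (!is.finite(q) || q == 0)
    stop("scale_to_p99: 99th percentile is zero (degenerate cell)",
         call. = FALSE)
  x / q
}

#' Z-score a trace over the whole session
#'
#' `(x - mean) / sd`, so positive values are fluorescence above the session
#' mean (events are positive excursions).
#'
#' @param x numeric trace.
#' @return z-scored trace (mean 0, SD 1).
#' @export
zscore_trace <- function(x) {
  if (anyNA(x)) stop("zscore_trace: trace contains missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zscore_trace: zero-variance trace", call. = FALSE)
  (x - mean(x)) / s
}

#' Max-downsample a trace onto the aligned 5 Hz grid
#'
#' Each grid bin takes the maximum over the acquisition-rate samples whose
#' timestamps fall in that bin; bins with no sample are `NA`.
#'
#' @param x numeric trace at the acquisition rate.
#' @param grid an `align_grid` from [align_streams()].
#' @return numeric vector of length `grid$n_bins`.
#' @export
downsample_max <- function(x, grid) {
  stopifnot(inherits(grid, "align_grid"))
  if (length(x) != length(grid$mini_bin))
    stop("downsample_max: trace length does not match the grid's miniscope",
         " frame count", call. = FALSE)
  keep <- !is.na(grid$mini_bin)
  out <- rep(NA_real_, grid$n_bins)
  if (!any(keep)) return(out)
  mx <- tapply(x[keep], grid$mini_bin[keep], max)
  out[as.integer(names(mx))] <- as.numeric(mx)
  out
}

#' Normalize a session into the 5 Hz z-scored raster
#'
#' The substrate for all event statistics: each cell's trace is scaled to
#' its 99th percentile, z-scored over the full session, then
#' max-downsampled to 5 Hz on the aligned grid (in that order; the two
#' linear steps cancel any per-cell gain, and the max preserves peaks).
#'
#' @param sess a `fluorescence_session`.
#' @param grid an `align_grid`.
#' @return a `normalized_raster`: list with `z` (cells x bins), `time`,
#'   `bin_duration`, `cell_ids`, `valid` (grid validity), and per-cell
#'   `scale` (p99), `mu`, `sd` (moments of the scaled trace).
#' @export
normalize_session <- function(sess, grid) {
  n <- nrow(sess$traces)
  z <- matrix(NA_real_, n, grid$n_bins)
  scale <- mu <- sdv <- numeric(n)
  for (c in seq_len(n)) {
    sc <- scale_to_p99(sess$traces[c, ])
    scale[c] <- unname(stats::quantile(sess$traces[c, ], 0.99, type = 7))
    mu[c] <- mean(sc)
    sdv[c] <- stats::sd(sc)
    z[c, ] <- downsample_max(zscore_trace(sc), grid)
  }
  structure(
    list(z = z, time = grid$time, bin_duration = grid$dt,
         cell_ids = sess$cell_ids, valid = grid$valid,
         scale = scale, mu = mu, sd = sdv),
    class = "normalized_raster")
}
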