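#' SCI parameters
#'
#' @param n_shuffles distance-shuffle draws per frame.
#' @param onset_window window after movement onset in which the normalized
#'   SCI peak is measured (s).
#' @param baseline_window pre-onset window whose mean SCI normalizes the
#'   onset-aligned curve (s); defaults to the 4 s pre-onset rest required
#'   by the onset definition.
#' @param method `"permutation"` (default): the per-direction p-value is
#'   the rank of the observed one-sided KS statistic among the statistics
#'   of the shuffle draws, which is calibrated under exchangeability of
#'   active-cell identity.  `"pooled_ks"`: the shuffle draws are pooled
#'   into one null sample and a single asymptotic two-sample KS p-value is
#'   computed per direction; simpler, but anticonservative for frames with
#'   many active cells because the observed pair distances share cells.
#' @return list of class `sci_params`.
#' @export
sci_params <- function(n_shuffles = 1000, onset_window = 2.5,
                       baseline_window = 4,
                       method = c("permutation", "pooled_ks")) {
  stopifnot(n_shuffles >= 1, onset_window > 0, baseline_window > 0)
  structure(list(n_shuffles = n_shuffles, onset_window = onset_window,
                 baseline_window = baseline_window,
                 method = match.arg(method)),
            class = "sci_params")
}

#' Distances between cells co-active in one frame
#'
#' @param active_frame logical vector (one raster column).
#' @param dist_matrix full inter-centroid distance matrix (um).
#' @return numeric vector of pairwise distances among active cells (empty
#'   for fewer than two active cells).
#' @export
active_pair_distances <- function(active_frame, dist_matrix) {
  idx <- which(active_frame)
  if (length(idx) < 2L) return(numeric(0))
  sub <- dist_matrix[idx, idx, drop = FALSE]
  sub[upper.tri(sub)]
}

## one-sided two-sample KS statistics: D_left = sup(F_a - F_b) measures how
## left-shifted (smaller-valued) `a` is relative to `b`; D_right the reverse.
ks_directional <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  w <- c(a, b)
  z <- cumsum(ifelse(order(w) <= n1, 1 / n1, -1 / n2))
  sw <- sort(w)
  keep <- c(diff(sw) != 0, TRUE)
  z <- z[keep]
  list(D_left = max(0, max(z)), D_right = max(0, -min(z)),
       n1 = n1, n2 = n2)
}

## one-sided asymptotic two-sample KS p-value
ks_p_one_sided <- function(D, n1, n2) {
  if (D <= 0) return(1)
  min(1, exp(-2 * D^2 * n1 * n2 / (n1 + n2)))
}

## one-sided KS statistics of a sample against a fixed sorted reference
## pool; O(m log N).  Equivalent to ks_directional(x, pool) up to ties.
ks_vs_pool <- function(x, pool_sorted) {
  m <- length(x)
  N <- length(pool_sorted)
  u <- sort(unique(x))
  n_le <- findInterval(u, sort(x))              # sample <= u
  n_lt <- c(0, n_le[-length(n_le)])             # sample <  u (unique vals)
  p_le <- findInterval(u, pool_sorted)          # pool <= u
  p_lt <- findInterval(u, pool_sorted, left.open = TRUE)  # pool < u
  D_left <- max(0, max(n_le / m - p_le / N))
  D_right <- max(0, max(p_lt / N - n_lt / m))
  list(D_left = D_left, D_right = D_right)
}

#' Spatial coordination index for one frame
#'
#' Asks whether the distances between the cells co-active in a frame are
#' left-shifted (clustered) or right-shifted (dispersed) relative to
#' chance, via a pair of one-sided Kolmogorov-Smirnov comparisons against
#' distance-shuffled surrogates; the index is `-log10` of the smaller of
#' the two p-values, signed positive when the clustered side wins.  Frames
#' with no active pair score exactly 0.
#'
#' With `method = "permutation"` each surrogate redraws the active-cell
#' identities (same count) and the p-value is the rank of the observed
#' one-sided KS statistic (computed against the full pair-distance pool)
#' among the surrogate statistics — a calibrated permutation test.  With
#' `method = "pooled_ks"` the surrogates instead resample frame-sized
#' distance sets from the pool (without replacement within a draw), all
#' draws are pooled into one null sample, and an asymptotic two-sample KS
#' p-value is computed per direction.
#'
#' @param frame_distances distances among co-active cells (um).
#' @param dist_matrix full inter-centroid distance matrix (um); for
#'   `"pooled_ks"` a plain pool vector of pairwise distances may be given
#'   instead.
#' @param p an [sci_params()].
#' @param n_active number of co-active cells in the frame (required for
#'   `"permutation"` unless it can be inferred from `frame_distances`).
#' @param exhaustive for `"permutation"`: enumerate all cell subsets
#'   instead of sampling (exact permutation p; only for small problems).
#' @return signed SCI (log10-p units).
#' @export
frame_sci <- function(frame_distances, dist_matrix, p = sci_params(),
                      n_active = NULL, exhaustive = FALSE) {
  m <- length(frame_distances)
  if (m == 0L) return(0)
  if (p$method == "pooled_ks")
    return(frame_sci_pooled(frame_distances,
                            as_pool(dist_matrix), p$n_shuffles))
  if (!is.matrix(dist_matrix))
    stop("frame_sci: permutation method needs the full distance matrix",
         call. = FALSE)
  if (is.null(n_active)) {
    n_active <- round((1 + sqrt(1 + 8 * m)) / 2)
    if (choose(n_active, 2) != m)
      stop("frame_sci: cannot infer n_active; pass it explicitly",
           call. = FALSE)
  }
  nc <- nrow(dist_matrix)
  pool <- sort(dist_matrix[upper.tri(dist_matrix)])
  obs <- ks_vs_pool(frame_distances, pool)
  if (exhaustive) {
    subsets <- utils::combn(nc, n_active, simplify = FALSE)
    draws <- lapply(subsets, function(idx) {
      sub <- dist_matrix[idx, idx]
      ks_vs_pool(sub[upper.tri(sub)], pool)
    })
    dl <- vapply(draws, `[[`, 0, "D_left")
    dr <- vapply(draws, `[[`, 0, "D_right")
  } else {
    ks <- ks_null_draws(dist_matrix, n_active, p$n_shuffles, pool)
    dl <- ks$D_left
    dr <- ks$D_right
  }
  n <- length(dl)
  p_clust <- (1 + sum(dl >= obs$D_left)) / (n + 1)
  p_disp <- (1 + sum(dr >= obs$D_right)) / (n + 1)
  signed_log_p(p_clust, p_disp, obs$D_left, obs$D_right)
}

## vectorized null: one-sided KS statistics (vs the pool) for `n_draws`
## random subsets of `k` cells.  All draws are processed at once: pairwise
## distances are gathered per pair slot, pool ranks come from two
## findInterval calls, and within-draw order statistics from a single
## order() over (draw, value).
ks_null_draws <- function(D, k, n_draws, pool_sorted) {
  nc <- nrow(D)
  N <- length(pool_sorted)
  m <- choose(k, 2)
  idx <- matrix(0L, k, n_draws)
  for (s in seq_len(n_draws)) idx[, s] <- sample.int(nc, k)
  pairs <- utils::combn(k, 2)
  vals <- matrix(0, m, n_draws)
  for (q in seq_len(m))
    vals[q, ] <- D[cbind(idx[pairs[1, q], ], idx[pairs[2, q], ])]
  o <- order(col(vals), vals)
  sv <- vals[o]                      # column-sorted values
  i_within <- rep(seq_len(m), n_draws)
  p_le <- findInterval(sv, pool_sorted)
  p_lt <- findInterval(sv, pool_sorted, left.open = TRUE)
  # ties within a draw: max over terms picks the right index automatically
  tl <- matrix(i_within / m - p_le / N, m, n_draws)
  tr <- matrix(p_lt / N - (i_within - 1) / m, m, n_draws)
  list(D_left = pmax(0, do.call(pmax, asplit(tl, 1))),
       D_right = pmax(0, do.call(pmax, asplit(tr, 1))))
}

as_pool <- function(dist_matrix) {
  if (is.matrix(dist_matrix)) dist_matrix[upper.tri(dist_matrix)]
  else dist_matrix
}

frame_sci_pooled <- function(frame_distances, pool, n_shuffles) {
  m <- length(frame_distances)
  N <- length(pool)
  if (m > N) stop("frame_sci: more frame distances than pool entries")
  null_sample <- if (m == N) {
    rep(pool, n_shuffles)
  } else {
    idx <- integer(n_shuffles * m)
    for (s in seq_len(n_shuffles))
      idx[((s - 1L) * m + 1L):(s * m)] <- sample.int(N, m)
    pool[idx]
  }
  ks <- ks_directional(frame_distances, null_sample)
  p_clust <- ks_p_one_sided(ks$D_left, ks$n1, ks$n2)
  p_disp <- ks_p_one_sided(ks$D_right, ks$n1, ks$n2)
  signed_log_p(p_clust, p_disp, ks$D_left, ks$D_right)
}

signed_log_p <- function(p_clust, p_disp, D_left, D_right) {
  if (p_clust == p_disp) {
    if (D_left == D_right) return(0)
    sgn <- if (D_left > D_right) 1 else -1
  } else sgn <- if (p_clust < p_disp) 1 else -1
  sgn * -log10(min(p_clust, p_disp))
}

#' Per-frame spatial coordination index series
#'
#' Runs [frame_sci()] over every frame of the forward-smoothed binary
#' raster ("active" means the same thing here as in the co-activity
#' analysis).  Deterministic under the seed.
#'
#' @param active logical matrix cells x bins (unsmoothed; smoothing applied
#'   internally, disable with `smooth_window = 0`).
#' @param cell_map a `cell_map`.
#' @param p an [sci_params()].
#' @param seed RNG seed.
#' @param time optional bin-start times (s).
#' @param smooth_window forward-smoothing window (s).
#' @param bin_duration raster bin length (s).
#' @return an `sci_series`: data.frame `frame`, `time_s`,
#'   `n_active_pairs`, `sci`.
#' @export
sci_series <- function(active, cell_map, p = sci_params(), seed = 1,
                       time = NULL, smooth_window = 1, bin_duration = 0.2) {
  xy <- cell_map$centroids
  D <- as.matrix(stats::dist(cbind(xy$x_um, xy$y_um)))
  sm <- if (smooth_window > 0)
    forward_smooth(active, smooth_window, bin_duration) else active
  n <- ncol(sm)
  if (is.null(time)) time <- (seq_len(n) - 1L) * bin_duration
  set.seed(seed)
  sci <- numeric(n)
  npair <- integer(n)
  for (f in seq_len(n)) {
    k <- sum(sm[, f])
    fd <- active_pair_distances(sm[, f], D)
    npair[f] <- length(fd)
    sci[f] <- if (length(fd)) frame_sci(fd, D, p, n_active = k) else 0
  }
  structure(data.frame(frame = seq_len(n), time_s = time,
                       n_active_pairs = npair, sci = sci),
            class = c("sci_series", "data.frame"),
            bin_duration = bin_duration)
}

#' Onset-aligned SCI and normalized peak
#'
#' Averages the SCI across movement onsets at each peri-onset offset,
#' normalizes the curve by the mean SCI over the pre-onset baseline
#' window, and reports the peak of the normalized curve within
#' `onset_window` seconds after onset.
#'
#' @param sci an `sci_series`.
#' @param onsets onset times (s); must be non-empty.
#' @param p an [sci_params()].
#' @return list with `offset_s`, `mean_sci`, `normalized`, `baseline`,
#'   `peak` (max normalized value in `[0, onset_window]`), `n_onsets`.
#' @export
onset_aligned_sci <- function(sci, onsets, p = sci_params()) {
  if (!length(onsets)) stop("onset_aligned_sci: no onsets", call. = FALSE)
  dt <- attr(sci, "bin_duration")
  offsets <- seq(-p$baseline_window, p$onset_window, by = dt)
  acc <- numeric(length(offsets))
  cnt <- integer(length(offsets))
  for (on in onsets) {
    b0 <- round((on - sci$time_s[1]) / dt) + 1
    idx <- b0 + round(offsets / dt)
    ok <- idx >= 1 & idx <= nrow(sci)
    acc[ok] <- acc[ok] + sci$sci[idx[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  mean_sci <- ifelse(cnt > 0, acc / cnt, NA_real_)
  base <- mean(mean_sci[offsets < 0], na.rm = TRUE)
  normalized <- mean_sci / base
  post <- offsets >= 0 & offsets <= p$onset_window
  list(offset_s = offsets, mean_sci = mean_sci, normalized = normalized,
       baseline = base, peak = max(normalized[post], na.rm = TRUE),
       n_onsets = length(onsets))
}
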