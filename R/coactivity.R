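#' Forward-smooth a binary raster
#'
#' Dilates activity forward in time: each active bin also activates the
#' following `window` seconds of bins (5 bins at 5 Hz), clipped at the
#' trace end.  Applied before pairwise co-activity so that near-coincident
#' events with small timing offsets still count as co-active.
#'
#' @param active logical matrix cells x bins.
#' @param window smoothing window (s).
#' @param bin_duration bin length (s).
#' @return logical matrix of the same shape.
#' @export
forward_smooth <- function(active, window = 1, bin_duration = 0.2) {
  k <- as.integer(round(window / bin_duration))
  n <- ncol(active)
  out <- active
  for (s in seq_len(min(k, n - 1L))) {
    cols <- (s + 1L):n
    out[, cols] <- out[, cols] | active[, cols - s, drop = FALSE]
  }
  out
}

#' Pairwise Jaccard co-activity matrix
#'
#' `J(a, b) = |frames both active| / |frames either active|`, restricted to
#' a frame subset.  Pairs whose union is empty on the subset are undefined
#' (`NA`).  `denominator = "frames"` gives the all-frames variant
#' (intersection divided by the number of frames in the subset).
#'
#' @param active logical matrix cells x bins (typically forward-smoothed).
#' @param frames integer vector of frame indices (default: all).
#' @param denominator `"union"` (Jaccard, default) or `"frames"`.
#' @return symmetric matrix of co-activity scores.
#' @export
jaccard_matrix <- function(active, frames = NULL,
                           denominator = c("union", "frames")) {
  denominator <- match.arg(denominator)
  if (nrow(active) < 2L)
    stop("jaccard_matrix: need at least 2 cells", call. = FALSE)
  A <- if (is.null(frames)) active else active[, frames, drop = FALSE]
  storage.mode(A) <- "double"
  inter <- tcrossprod(A)
  if (denominator == "frames") return(inter / ncol(A))
  ra <- rowSums(A)
  un <- outer(ra, ra, "+") - inter
  J <- inter / un
  J[un == 0] <- NA_real_
  J
}

## circularly rotate each row of a matrix by its own offset
rotate_rows <- function(active, offsets) {
  n <- ncol(active)
  out <- active
  for (r in seq_len(nrow(active))) {
    k <- offsets[r] %% n
    if (k > 0L) out[r, ] <- active[r, c((n - k + 1L):n, 1L:(n - k))]
  }
  out
}

## core shuffle engine: per-pair mean Jaccard over circular-shift surrogates,
## for one or more frame subsets, with offsets shared across subsets.
shuffle_jaccard_mean <- function(active, n_shuffles, seed = NULL,
                                 frame_sets = list(all = NULL),
                                 smooth_window = 1, bin_duration = 0.2,
                                 denominator = "union") {
  if (!is.null(seed)) set.seed(seed)
  n_cells <- nrow(active)
  nf <- ncol(active)
  acc <- lapply(frame_sets, function(f) matrix(0, n_cells, n_cells))
  cnt <- lapply(frame_sets, function(f) matrix(0, n_cells, n_cells))
  for (s in seq_len(n_shuffles)) {
    off <- sample.int(nf, n_cells, replace = TRUE) - 1L
    rot <- forward_smooth(rotate_rows(active, off),
                          smooth_window, bin_duration)
    for (g in seq_along(frame_sets)) {
      J <- jaccard_matrix(rot, frame_sets[[g]], denominator)
      ok <- !is.na(J)
      acc[[g]][ok] <- acc[[g]][ok] + J[ok]
      cnt[[g]] <- cnt[[g]] + ok
    }
  }
  out <- Map(function(a, k) {
    m <- a / k
    m[k == 0] <- NA_real_
    m
  }, acc, cnt)
  names(out) <- names(frame_sets)
  out
}

#' Shuffle null for pairwise co-activity
#'
#' Builds surrogate data by independently circularly rotating each cell's
#' unsmoothed binary trace by a uniform random offset (preserving event
#' counts and run lengths), re-applying the forward smoothing, and
#' recomputing the pairwise Jaccard matrix; returns the per-pair mean over
#' shuffles.
#'
#' @param active logical matrix cells x bins (unsmoothed).
#' @param n_shuffles number of independent shuffles.
#' @param seed RNG seed.
#' @param frames optional frame subset.
#' @inheritParams forward_smooth
#' @inheritParams jaccard_matrix
#' @return matrix of per-pair shuffle-mean Jaccard values.
#' @export
shuffle_null <- function(active, n_shuffles = 1000, seed = NULL,
                         frames = NULL, smooth_window = 1,
                         bin_duration = 0.2,
                         denominator = c("union", "frames")) {
  denominator <- match.arg(denominator)
  shuffle_jaccard_mean(active, n_shuffles, seed,
                       frame_sets = list(all = frames),
                       smooth_window, bin_duration, denominator)$all
}

#' Distance-binned shuffle-normalized co-activity profile
#'
#' The study's distance-resolved co-activity statistic: pairwise Jaccard
#' indices are computed on the forward-smoothed binary raster, pairs are
#' assigned to half-open inter-centroid distance bins `[k*w, (k+1)*w)`, and
#' each bin's mean observed Jaccard is divided by the mean over
#' circular-shift surrogates of the same pairs (bin-level normalization,
#' which stays defined for sparse cells).  Optionally restricted to rest or
#' movement frames using the 5 Hz epoch labels.
#'
#' @param active logical matrix cells x bins (unsmoothed event raster from
#'   [binary_raster()]).
#' @param cell_map a `cell_map` (centroids in um).
#' @param bin_width distance bin width (um), 50 or 250 in practice.
#' @param n_shuffles number of circular-shift surrogates.
#' @param state one or more of `"all"`, `"rest"`, `"move"`.
#' @param epochs an `epoch_set` (required for rest/move restriction).
#' @param seed RNG seed for the shuffle offsets (drawn once, reused across
#'   bins and states).
#' @param smooth_window forward-smoothing window (s).
#' @param bin_duration raster bin length (s).
#' @param denominator see [jaccard_matrix()].
#' @param min_pairs smallest pair count for a distance bin to be reported
#'   (default 1 = every non-empty bin; bin-level ratios from only a
#'   handful of pairs are dominated by sampling noise, so analyses in this
#'   package interpret bins with at least 10 pairs).
#' @return data.frame with `state`, `bin_lo`, `bin_hi`, `bin_center`,
#'   `n_pairs`, `observed`, `shuffle_mean`, `normalized`; empty distance
#'   bins are omitted.
#' @export
coactivity_profile <- function(active, cell_map, bin_width = 50,
                               n_shuffles = 1000, state = "all",
                               epochs = NULL, seed = 1,
                               smooth_window = 1, bin_duration = 0.2,
                               denominator = c("union", "frames"),
                               min_pairs = 1) {
  denominator <- match.arg(denominator)
  state <- match.arg(state, c("all", "rest", "move"), several.ok = TRUE)
  if (any(state != "all") && is.null(epochs))
    stop("coactivity_profile: epochs required for state restriction",
         call. = FALSE)
  n_cells <- nrow(active)
  if (n_cells < 2L) stop("coactivity_profile: need at least 2 cells",
                         call. = FALSE)

  frame_sets <- lapply(state, function(s) {
    if (s == "all") NULL
    else which(!is.na(epochs$labels) & epochs$labels == s)
  })
  names(frame_sets) <- state

  sm <- forward_smooth(active, smooth_window, bin_duration)
  J_obs <- lapply(frame_sets, function(f)
    jaccard_matrix(sm, f, denominator))
  J_null <- shuffle_jaccard_mean(active, n_shuffles, seed, frame_sets,
                                 smooth_window, bin_duration, denominator)

  xy <- cell_map$centroids
  D <- as.matrix(stats::dist(cbind(xy$x_um, xy$y_um)))
  ut <- upper.tri(D)
  d <- D[ut]
  bin <- floor(d / bin_width)

  out <- list()
  for (s in state) {
    jo <- J_obs[[s]][ut]
    jn <- J_null[[s]][ut]
    ok <- !is.na(jo) & !is.na(jn)
    for (b in sort(unique(bin[ok]))) {
      sel <- ok & bin == b
      if (sum(sel) < min_pairs) next
      mo <- mean(jo[sel])
      mn <- mean(jn[sel])
      out[[length(out) + 1L]] <- data.frame(
        state = s, bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
        bin_center = (b + 0.5) * bin_width, n_pairs = sum(sel),
        observed = mo, shuffle_mean = mn,
        normalized = if (mn > 0) mo / mn else NA_real_)
    }
  }
  do.call(rbind, out)
}
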