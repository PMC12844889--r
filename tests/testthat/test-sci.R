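test_that("active-pair distances enumerate C(k,2) pairs", {
  D <- as.matrix(stats::dist(cbind(c(0, 3, 0, 10), c(0, 4, 0, 0))))
  expect_equal(active_pair_distances(c(TRUE, FALSE, FALSE, FALSE), D),
               numeric(0))
  expect_equal(active_pair_distances(rep(FALSE, 4), D), numeric(0))
  d3 <- active_pair_distances(c(TRUE, TRUE, TRUE, FALSE), D)
  expect_equal(length(d3), choose(3, 2))
  expect_setequal(round(d3, 10), round(c(5, 0, 5), 10))
  # coincident cells give zero distances
  expect_equal(active_pair_distances(c(TRUE, FALSE, TRUE, FALSE), D), 0)
})

test_that("a frame with no active cell pair scores exactly zero", {
  D <- as.matrix(stats::dist(matrix(stats::runif(20), 10, 2)))
  expect_identical(frame_sci(numeric(0), D), 0)
})

test_that("directional KS statistics agree with stats::ks.test", {
  set.seed(20)
  for (i in 1:5) {
    a <- stats::rnorm(30)
    b <- stats::rnorm(50, mean = 0.3)
    ks <- minicoact:::ks_directional(a, b)
    expect_equal(max(ks$D_left, ks$D_right),
                 unname(suppressWarnings(
                   stats::ks.test(a, b)$statistic)))
    # the pool-rank path computes the same one-sided statistics
    kp <- minicoact:::ks_vs_pool(a, sort(b))
    expect_equal(kp$D_left, ks$D_left)
    expect_equal(kp$D_right, ks$D_right)
  }
})

test_that("exhaustive permutation SCI matches an independent brute force", {
  set.seed(21)
  nc <- 8
  xy <- matrix(stats::runif(2 * nc, 0, 100), nc, 2)
  D <- as.matrix(stats::dist(xy))
  pool <- sort(D[upper.tri(D)])
  k <- 3
  idx <- c(1, 2, 3)
  fd <- D[idx, idx][upper.tri(matrix(0, k, k))]
  p <- sci_params(method = "permutation")
  got <- frame_sci(fd, D, p, n_active = k, exhaustive = TRUE)

  # brute force: direct double-loop ECDF comparison over all k-subsets
  dstat <- function(x) {
    Fo <- function(t) mean(x <= t)
    Fp <- function(t) mean(pool <= t)
    Fpl <- function(t) mean(pool < t)
    Fol <- function(t) mean(x < t)
    pts <- sort(unique(x))
    list(L = max(0, max(vapply(pts, function(t) Fo(t) - Fp(t), 0))),
         R = max(0, max(vapply(pts, function(t) Fpl(t) - Fol(t), 0))))
  }
  obs <- dstat(fd)
  subs <- utils::combn(nc, k, simplify = FALSE)
  Ls <- Rs <- numeric(length(subs))
  for (s in seq_along(subs)) {
    ss <- D[subs[[s]], subs[[s]]]
    dd <- dstat(ss[upper.tri(ss)])
    Ls[s] <- dd$L; Rs[s] <- dd$R
  }
  n <- length(subs)
  pc <- (1 + sum(Ls >= obs$L)) / (n + 1)
  pd <- (1 + sum(Rs >= obs$R)) / (n + 1)
  want <- if (pc == pd) {
    if (obs$L == obs$R) 0
    else (if (obs$L > obs$R) 1 else -1) * -log10(pc)
  } else (if (pc < pd) 1 else -1) * -log10(min(pc, pd))
  expect_equal(got, want)
})

test_that("sampled permutation draws reproduce the vectorized statistics", {
  set.seed(22)
  D <- as.matrix(stats::dist(matrix(stats::runif(30, 0, 200), 15, 2)))
  pool <- sort(D[upper.tri(D)])
  set.seed(23)
  ks <- minicoact:::ks_null_draws(D, 4, 50, pool)
  set.seed(23)
  for (s in 1:50) {
    idx <- sample.int(15, 4)
    sub <- D[idx, idx]
    ref <- minicoact:::ks_vs_pool(sub[upper.tri(sub)], pool)
    expect_equal(ks$D_left[s], ref$D_left)
    expect_equal(ks$D_right[s], ref$D_right)
  }
})

test_that("sci sign follows proximal versus distal co-activation", {
  # tight cluster at the origin plus a ring of distant cells
  xy <- rbind(cbind(stats::runif(5, 0, 20), stats::runif(5, 0, 20)),
              cbind(300 * cos(1:15), 300 * sin(1:15)))
  cm <- structure(
    list(centroids = data.frame(cell = sprintf("c%02d", 1:20),
                                x_um = xy[, 1], y_um = xy[, 2])),
    class = "cell_map")
  D <- as.matrix(stats::dist(xy))
  p <- sci_params(n_shuffles = 500)
  set.seed(24)
  prox <- frame_sci(active_pair_distances(1:20 %in% 1:5, D), D, p,
                    n_active = 5)
  set.seed(24)
  # a nearly antipodal pair on the ring: distance close to the pool maximum
  dist_only <- frame_sci(active_pair_distances(1:20 %in% c(6, 9), D),
                         D, p, n_active = 2)
  expect_gt(prox, 0)
  expect_lt(dist_only, 0)
})

test_that("sci series is deterministic under a fixed seed", {
  set.seed(25)
  act <- matrix(stats::runif(10 * 40) < 0.2, 10, 40)
  cm <- structure(
    list(centroids = data.frame(cell = sprintf("c%02d", 1:10),
                                x_um = stats::runif(10, 0, 300),
                                y_um = stats::runif(10, 0, 300))),
    class = "cell_map")
  p <- sci_params(n_shuffles = 100)
  s1 <- sci_series(act, cm, p, seed = 26)
  s2 <- sci_series(act, cm, p, seed = 26)
  expect_identical(s1, s2)
  expect_true(all(s1$sci[s1$n_active_pairs == 0] == 0))
  expect_true(all(is.finite(s1$sci)))
})

test_that("onset alignment normalizes by the pre-onset baseline", {
  dt <- 0.2
  n <- 500
  sci_flat <- structure(
    data.frame(frame = 1:n, time_s = (1:n - 1) * dt,
               n_active_pairs = 1L, sci = 2),
    class = c("sci_series", "data.frame"), bin_duration = dt)
  al <- onset_aligned_sci(sci_flat, c(30, 60), sci_params())
  expect_true(all(abs(al$normalized - 1) < 1e-12))
  expect_equal(al$peak, 1)

  # single onset: the aligned curve is the raw segment around it
  set.seed(27)
  v <- stats::rnorm(n, mean = 3)
  sci_r <- structure(
    data.frame(frame = 1:n, time_s = (1:n - 1) * dt,
               n_active_pairs = 1L, sci = v),
    class = c("sci_series", "data.frame"), bin_duration = dt)
  al1 <- onset_aligned_sci(sci_r, 50, sci_params())
  idx <- (50 / dt + 1) + round(al1$offset_s / dt)
  expect_equal(al1$mean_sci, v[idx])

  # elevated sci after onsets pushes the normalized peak above 1
  v2 <- rep(1, n)
  for (on in c(20, 44, 70)) {
    b <- on / dt + 1
    v2[b:(b + 5)] <- 4
  }
  sci_e <- structure(
    data.frame(frame = 1:n, time_s = (1:n - 1) * dt,
               n_active_pairs = 1L, sci = v2),
    class = c("sci_series", "data.frame"), bin_duration = dt)
  al2 <- onset_aligned_sci(sci_e, c(20, 44, 70), sci_params())
  expect_gt(al2$peak, 1)
  expect_error(onset_aligned_sci(sci_e, numeric(0)), "onsets")
})
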