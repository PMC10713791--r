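test_that("GFP matches the hand formula with denominator C", {
  x <- matrix(c(1, 2, 3,
                4, 6, 8,
                0, 1, -1), 3, byrow = TRUE)  # channels x samples
  g <- compute_gfp(x)
  expect_equal(g$values, oracle_gfp(x), tolerance = 1e-12)
  # constant column across channels -> GFP 0
  x0 <- matrix(5, 4, 3)
  expect_equal(compute_gfp(x0)$values, rep(0, 3))
})

test_that("GFP peaks are strict local maxima with minimum spacing", {
  v <- c(0, 1, 0, 2, 0, 3, 0)
  # build a 2-channel signal whose GFP equals v (channels +v/-v around 0)
  x <- rbind(v, -v)
  g <- compute_gfp(x, sampling_rate = 1000, min_peak_distance_ms = 0)
  expect_identical(g$peak_indices, c(2L, 4L, 6L))
  # with spacing 3 samples at 1 kHz (3 ms), greedy-by-height keeps 6
  # first, then 4 and 2 are both >= 2 away? no: distance 2 < 3 drops 5
  g2 <- compute_gfp(x, sampling_rate = 1000, min_peak_distance_ms = 3)
  expect_true(6L %in% g2$peak_indices)
  expect_true(all(diff(g2$peak_indices) >= 3))
  # a plateau is not a strict local maximum
  p <- c(0, 1, 1, 0)
  gp <- compute_gfp(rbind(p, -p))
  expect_length(gp$peak_indices, 0)
})

test_that("clustering recovers planted prototypes", {
  fx <- fixture_recording()
  g <- compute_gfp(fx$recording)
  maps <- t(fx$recording$data[, g$peak_indices])
  cl <- cluster_microstates(maps, k = 4, seed = 1)
  expect_s3_class(cl, "prototype_set")
  expect_identical(dim(cl$maps), c(4L, 16L))
  # rows zero-mean unit-norm
  expect_lt(max(abs(rowMeans(cl$maps))), 1e-9)
  expect_equal(unname(sqrt(rowSums(cl$maps^2))), rep(1, 4),
               tolerance = 1e-9)
  expect_true(cl$gev_total > 0.8 && cl$gev_total <= 1)
  # each planted prototype matched by some cluster with high |corr|
  corr <- abs(msstm:::spatial_correlation(fx$prototypes, cl$maps))
  expect_true(all(apply(corr, 1, max) >= 0.95))
  expect_error(cluster_microstates(maps[1:2, ], k = 4), "at least k")
})

test_that("clustering is deterministic under a seed", {
  fx <- fixture_recording()
  maps <- t(fx$recording$data[, compute_gfp(fx$recording)$peak_indices])
  c1 <- cluster_microstates(maps, k = 3, n_init = 3, seed = 7)
  c2 <- cluster_microstates(maps, k = 3, n_init = 3, seed = 7)
  expect_identical(c1$maps, c2$maps)
  expect_identical(c1$labels, c2$labels)
})

test_that("GEV matches a brute-force recomputation and its bounds", {
  set.seed(20)
  data <- matrix(rnorm(30 * 8), 30)
  protos <- msstm:::normalize_maps(matrix(rnorm(3 * 8), 3))
  labels <- sample(1:3, 30, replace = TRUE)
  gev <- compute_gev(data, protos, labels)
  expect_equal(gev, oracle_gev(data, protos, labels), tolerance = 1e-10)
  expect_true(gev >= 0 && gev <= 1)
  # data exactly equal to assigned prototypes -> GEV = 1
  perfect <- protos[labels, ]
  expect_equal(compute_gev(perfect, protos, labels), 1, tolerance = 1e-12)
})

test_that("CV criterion matches its formula and edge cases", {
  set.seed(21)
  data <- matrix(rnorm(40 * 10), 40)
  protos <- matrix(rnorm(4 * 10), 4)
  labels <- sample(1:4, 40, replace = TRUE)
  expect_equal(compute_cv(data, protos, labels),
               oracle_cv(data, protos, labels), tolerance = 1e-10)
  # perfect fit: every sample is a multiple of its assigned prototype
  protos_n <- msstm:::normalize_maps(protos)
  perfect <- protos_n[labels, ] * runif(40, 0.5, 2)
  expect_equal(compute_cv(perfect, protos_n, labels), 0, tolerance = 1e-12)
  # C <= K + 1 is undefined
  expect_error(compute_cv(matrix(rnorm(20), 4, 5), matrix(rnorm(20), 4, 5),
                          c(1, 2, 3, 4)), "more channels")
})

test_that("select_k finds the planted number of states", {
  fx <- fixture_recording()
  maps <- t(fx$recording$data[, compute_gfp(fx$recording)$peak_indices])
  sel <- select_k(maps, k_range = 2:7, n_init = 5, seed = 2)
  expect_identical(sel$k, 4L)
  expect_identical(sel$table$k, 2:7)
  expect_true(all(diff(sel$table$gev) > -0.05))  # gev ~ monotone in k
  expect_error(select_k(maps, k_range = integer(0)))
})

test_that("backfit labels a noiseless recording perfectly", {
  fx <- fixture_recording()
  clean <- simulate_recording(fx$prototypes, fx$labels, 250, snr = Inf)
  seg <- backfit(clean, fx$prototypes)
  expect_s3_class(seg, "microstate_segmentation")
  expect_identical(seg$labels, fx$labels)
  expect_equal(unname(seg$correlations), rep(1, length(fx$labels)),
               tolerance = 1e-9)
  expect_identical(seg$sampling_rate, 250)
  expect_false(seg$smoothed)
})

test_that("backfit is polarity-invariant by default", {
  fx <- fixture_recording()
  clean <- simulate_recording(fx$prototypes, fx$labels, 250, snr = Inf)
  flipped <- eeg_recording(-clean$data, 250)
  expect_identical(backfit(flipped, fx$prototypes)$labels, fx$labels)
})

test_that("smoothing removes short segments and keeps long ones", {
  labels <- c(rep(1L, 40), 2L, 2L, rep(3L, 40), 1L, rep(2L, 40))
  seg <- structure(list(labels = labels,
                        correlations = rep(0.9, length(labels)),
                        k = 3L, sampling_rate = 250, smoothed = FALSE),
                   class = "microstate_segmentation")
  sm <- smooth_labels(seg, min_duration_ms = 30)  # >= 8 samples at 250 Hz
  expect_true(sm$smoothed)
  expect_length(sm$labels, length(labels))
  expect_true(all(rle(sm$labels)$lengths >= 8))
  # the three long runs survive
  expect_identical(unique(rle(sm$labels)$values), c(1L, 3L, 2L))
  # min_duration 0 is the identity
  expect_identical(smooth_labels(seg, 0)$labels, labels)
  # smoothing is idempotent
  expect_identical(smooth_labels(sm, 30)$labels, sm$labels)
})

test_that("short-segment merge follows the boundary correlation", {
  labels <- c(rep(1L, 20), 2L, 2L, rep(3L, 20))
  corr <- rep(0.5, length(labels))
  corr[21] <- 0.9  # left boundary of the short segment fits better
  seg <- structure(list(labels = labels, correlations = corr, k = 3L,
                        sampling_rate = 250, smoothed = FALSE),
                   class = "microstate_segmentation")
  sm <- smooth_labels(seg, 30)
  expect_identical(sm$labels[21:22], c(1L, 1L))
  corr2 <- corr; corr2[21] <- 0.1; corr2[22] <- 0.9  # right fits better
  seg$correlations <- corr2
  sm2 <- smooth_labels(seg, 30)
  expect_identical(sm2$labels[21:22], c(3L, 3L))
})

test_that("a lone segment is never wiped out", {
  seg <- structure(list(labels = rep(2L, 4), correlations = rep(1, 4),
                        k = 3L, sampling_rate = 250, smoothed = FALSE),
                   class = "microstate_segmentation")
  expect_identical(smooth_labels(seg, 100)$labels, rep(2L, 4))
})

test_that("microstate statistics match a hand-computed oracle", {
  # 10 samples at 100 Hz: 1 1 1 2 2 1 1 3 3 3
  labels <- c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 3L, 3L, 3L)
  st <- microstate_statistics(labels, k = 3, sampling_rate = 100)
  expect_equal(st$coverage, c(0.5, 0.2, 0.3))
  # durations: class 1 segments (3, 2) -> 2.5 samples = 25 ms at 100 Hz
  expect_equal(st$duration_ms, c(25, 20, 30))
  # occurrence: segments per second over 0.1 s total
  expect_equal(st$occurrence_per_s, c(20, 10, 10))
  # transitions: 1->2, 2->1, 1->3 -> row 1 splits 0.5/0.5
  expect_equal(st$transition,
               matrix(c(0, 0.5, 0.5,
                        1, 0, 0,
                        0, 0, 0), 3, byrow = TRUE))
})

test_that("occurrence x duration = 1000 x coverage for covered classes", {
  fx <- fixture_recording()
  st <- microstate_statistics(fx$labels, k = 4, sampling_rate = 250)
  nz <- st$coverage > 0
  expect_equal(st$occurrence_per_s[nz] * st$duration_ms[nz],
               1000 * st$coverage[nz], tolerance = 1e-9)
  # rows of the transition matrix are stochastic or all-zero
  rs <- rowSums(st$transition)
  expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
})

test_that("statistics recover the generating dynamics approximately", {
  trans <- matrix(c(0, 0.8, 0.2,
                    0.3, 0, 0.7,
                    0.5, 0.5, 0), 3, byrow = TRUE)
  s <- simulate_state_sequence(trans, c(80, 100, 120), 2e5, 250, seed = 33)
  st <- microstate_statistics(s, k = 3, sampling_rate = 250)
  expect_equal(st$duration_ms, c(80, 100, 120), tolerance = 0.05)
  expect_lt(max(abs(st$transition - trans)), 0.02)
})
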