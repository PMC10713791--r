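test_that("generator_config validates its arguments", {
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_identical(cfg$n_channels, 28L)
  expect_identical(cfg$sampling_rate, 250)
  expect_identical(cfg$n_states, 5L)
  expect_error(generator_config(n_subjects = 0))
  expect_error(generator_config(snr = 0))
  expect_error(generator_config(sampling_rate = -1))
})

test_that("K = 1 state sequence is constant", {
  s <- simulate_state_sequence(matrix(0, 1, 1), 100, 100, 250, seed = 1)
  expect_identical(s, rep(1L, 100))
})

test_that("empirical dwell mean matches the requested mean within 5%", {
  # K = 2, alternating transition, 100 ms at 250 Hz = 25 samples
  trans <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  s <- simulate_state_sequence(trans, c(100, 100), 1e5, 250, seed = 42)
  lens <- rle(s)$lengths
  expect_equal(mean(lens), 25, tolerance = 0.05)
})

test_that("empirical segment transitions converge to the input matrix", {
  trans <- matrix(c(0, 0.7, 0.3,
                    0.2, 0, 0.8,
                    0.5, 0.5, 0), 3, byrow = TRUE)
  s <- simulate_state_sequence(trans, c(60, 60, 60), 1e5, 250, seed = 7)
  seg <- rle(s)$values
  emp <- matrix(0, 3, 3)
  for (i in seq_len(length(seg) - 1)) {
    emp[seg[i], seg[i + 1]] <- emp[seg[i], seg[i + 1]] + 1
  }
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - trans)), 0.02)
})

test_that("state sequence rejects invalid transition matrices", {
  bad_diag <- matrix(c(0.5, 0.5, 1, 0), 2, byrow = TRUE)
  expect_error(simulate_state_sequence(bad_diag, c(100, 100), 100, 250),
               "zero diagonal")
  bad_rows <- matrix(c(0, 0.5, 1, 0), 2, byrow = TRUE)
  expect_error(simulate_state_sequence(bad_rows, c(100, 100), 100, 250),
               "sum to 1")
  expect_error(simulate_state_sequence(matrix(c(0, 1, 1, 0), 2),
                                       c(-5, 100), 100, 250))
})

test_that("simulate_recording honors the SNR and ground truth", {
  protos <- msstm:::make_prototypes(3, 10, seed = 2)
  labels <- rep(1:3, each = 200)
  rec <- simulate_recording(protos, labels, 250, snr = 5, seed = 3)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(dim(rec$data), c(10L, 600L))
  expect_identical(rec$state_sequence, labels)
  clean <- simulate_recording(protos, labels, 250, snr = Inf)
  noise <- rec$data - clean$data
  snr_hat <- sqrt(mean(clean$data^2)) / sqrt(mean(noise^2))
  expect_equal(snr_hat, 5, tolerance = 0.1)
  expect_error(simulate_recording(protos, labels, 250, snr = -1))
})

test_that("noiseless recording has a GFP maximum inside every segment", {
  protos <- msstm:::make_prototypes(3, 10, seed = 2)
  labels <- rep(c(1L, 2L, 3L, 1L), each = 25)
  rec <- simulate_recording(protos, labels, 250, snr = Inf)
  g <- compute_gfp(rec)
  seg <- rle(labels)
  ends <- cumsum(seg$lengths)
  starts <- ends - seg$lengths + 1L
  for (i in seq_along(starts)) {
    expect_true(any(g$peak_indices >= starts[i] &
                      g$peak_indices <= ends[i]))
  }
})

test_that("dataset ground truth satisfies its invariants", {
  ds <- tiny_dataset()
  gt <- ds$ground_truth
  # prototypes: zero-mean unit-norm rows
  expect_lt(max(abs(rowMeans(gt$prototypes))), 1e-12)
  expect_equal(unname(sqrt(rowSums(gt$prototypes^2))),
               rep(1, nrow(gt$prototypes)), tolerance = 1e-9)
  # transition rows sum to 1, zero diagonal
  for (Tm in gt$class_transition) {
    expect_equal(unname(rowSums(Tm)), rep(1, nrow(Tm)), tolerance = 1e-9)
    expect_equal(unname(diag(Tm)), rep(0, nrow(Tm)))
  }
  expect_true(all(gt$class_duration_means > 0))
  expect_length(gt$subject_styles, 2)
  expect_identical(dim(gt$subject_styles[[1]]$A), c(90L, 90L))
  # one recording per subject x class x trial with metadata set
  expect_length(ds$recordings, 2 * 2 * 1)
  subj <- vapply(ds$recordings, `[[`, numeric(1), "subject")
  labs <- vapply(ds$recordings, `[[`, numeric(1), "label")
  expect_false(any(is.na(subj)))
  expect_false(any(is.na(labs)))
  expect_setequal(unique(subj), 1:2)
  expect_setequal(unique(labs), 1:2)
})

test_that("identical seed gives a bit-identical dataset", {
  cfg <- generator_config(n_subjects = 2, n_classes = 2, n_channels = 10,
                          n_states = 3, trials_per_class = 1,
                          trial_duration = 2, feature_dim = 18, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  cfg2 <- generator_config(n_subjects = 2, n_classes = 2, n_channels = 10,
                           n_states = 3, trials_per_class = 1,
                           trial_duration = 2, feature_dim = 18, seed = 100)
  d3 <- simulate_dataset(cfg2)
  expect_false(identical(d1$recordings[[1]]$data, d3$recordings[[1]]$data))
})

test_that("style strength 0 yields identity styles", {
  styles <- msstm:::make_styles(2, 8, strength = 0, seed = 1)
  expect_equal(styles[[1]]$A, diag(8))
  expect_equal(styles[[1]]$b, numeric(8))
  X <- matrix(rnorm(40), 5)
  expect_equal(apply_subject_style(X, styles[[2]]), X)
})

test_that("apply_subject_style is the affine map it claims to be", {
  style <- list(A = matrix(c(2, 0, 1, 1), 2), b = c(1, -1))
  X <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(apply_subject_style(X, style),
               t(style$A %*% t(X) + style$b))
  expect_error(apply_subject_style(matrix(0, 2, 3), style))
})

test_that("lead field has unit-norm columns and full row rank", {
  lf <- make_lead_field(8, 20, seed = 3)
  expect_identical(dim(lf$gain), c(8L, 20L))
  expect_equal(unname(sqrt(colSums(lf$gain^2))), rep(1, 20),
               tolerance = 1e-12)
  sv <- svd(lf$gain, nu = 0, nv = 0)$d
  expect_gt(sv[8] / sv[1], 1e-8)
  expect_equal(unname(sqrt(rowSums(lf$source_positions^2))), rep(1, 20),
               tolerance = 1e-9)
  expect_error(make_lead_field(8, 4))
})

test_that("dataset round-trips through write/read", {
  skip_if_not_installed("jsonlite")
  ds <- tiny_dataset()
  dir <- tempfile("msstm-ds-")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back$recordings, length(ds$recordings))
  expect_equal(back$recordings[[3]]$data, ds$recordings[[3]]$data,
               tolerance = 1e-12)
  expect_identical(back$recordings[[3]]$subject, ds$recordings[[3]]$subject)
  expect_identical(back$recordings[[3]]$state_sequence,
                   ds$recordings[[3]]$state_sequence)
  expect_equal(back$ground_truth$prototypes, ds$ground_truth$prototypes,
               tolerance = 1e-12)
  expect_equal(back$ground_truth$subject_styles[[2]]$A,
               ds$ground_truth$subject_styles[[2]]$A, tolerance = 1e-12)
  expect_identical(back$ground_truth$config$seed, ds$ground_truth$config$seed)
})

test_that("seeded helpers do not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulate_state_sequence(matrix(c(0, 1, 1, 0), 2),
                                    c(100, 100), 50, 250, seed = 5))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
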