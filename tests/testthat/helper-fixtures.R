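# Shared fixtures, built once per test run. Everything here is small:
# the heavyweight scenarios live in test-acceptance.R only.

fixture_env <- new.env(parent = emptyenv())

# a tiny 2-subject, 2-class dataset for API-level tests
tiny_dataset <- function() {
  if (is.null(fixture_env$tiny)) {
    cfg <- generator_config(n_subjects = 2, n_classes = 2,
                            n_channels = 12, n_states = 3,
                            trials_per_class = 1, trial_duration = 4,
                            feature_dim = 90, seed = 11L)
    fixture_env$tiny <- simulate_dataset(cfg)
  }
  fixture_env$tiny
}

# one mid-sized single recording with known prototypes, reused across
# microstate tests
fixture_recording <- function() {
  if (is.null(fixture_env$rec)) {
    protos <- msstm:::make_prototypes(4, 16, seed = 5L)
    trans <- matrix(1 / 3, 4, 4); diag(trans) <- 0
    labels <- simulate_state_sequence(trans, rep(100, 4), 5000, 250,
                                      seed = 5L)
    rec <- simulate_recording(protos, labels, 250, snr = 10, seed = 6L)
    fixture_env$rec <- list(recording = rec, prototypes = protos,
                            labels = labels)
  }
  fixture_env$rec
}

# brute-force oracles, written independently of the package internals
oracle_gfp <- function(x) {
  vapply(seq_len(ncol(x)), function(t) {
    v <- x[, t]
    sqrt(sum((v - mean(v))^2) / length(v))
  }, numeric(1))
}

oracle_gev <- function(data, protos, labels) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(data))) {
    xi <- data[i, ]
    gfp_i <- sqrt(sum((xi - mean(xi))^2) / length(xi))
    r <- stats::cor(xi, protos[labels[i], ])
    num <- num + (r * gfp_i)^2
    den <- den + gfp_i^2
  }
  num / den
}

oracle_cv <- function(data, protos, labels) {
  C <- ncol(data); K <- nrow(protos); N <- nrow(data)
  protos <- t(apply(protos, 1, function(p) {
    p <- p - mean(p); p / sqrt(sum(p^2))
  }))
  s2 <- 0
  for (i in seq_len(N)) {
    xi <- data[i, ] - mean(data[i, ])
    a <- protos[labels[i], ]
    s2 <- s2 + sum(xi^2) - sum(a * xi)^2
  }
  s2 <- s2 / (N * (C - 1))
  s2 * ((C - 1) / (C - K - 1))^2
}

# numeric-gradient check helper: f increases in random directions
objective_is_local_min <- function(obj, A, b, pairs, beta, n_dir = 6,
                                   eps = 1e-4) {
  base <- obj(pairs, A, b, beta)
  M <- ncol(A)
  for (i in seq_len(n_dir)) {
    dA <- matrix(stats::rnorm(M * M), M)
    db <- stats::rnorm(M)
    pert <- obj(pairs, A + eps * dA, b + eps * db, beta)
    if (pert < base - 1e-10) return(FALSE)
  }
  TRUE
}
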