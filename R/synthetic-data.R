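#' Synthetic EEG with known microstate ground truth
#'
#' The generator emulates the structure of a multi-subject emotion EEG
#' study: K shared prototype topographies, a semi-Markov microstate
#' sequence whose dwell times and transition preferences differ by
#' emotion class, a GFP amplitude envelope with a local maximum inside
#' every microstate segment, additive Gaussian sensor noise at a
#' configured SNR, and per-subject affine "style" distortions applied to
#' extracted feature vectors. Every quantity the downstream analysis
#' estimates (prototypes, coverage, durations, transitions, styles) is
#' returned as ground truth.
#'
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_classes number of emotion classes (default 3:
#'   positive / neutral / negative).
#' @param n_channels scalp channels (default 28).
#' @param sampling_rate Hz (default 250).
#' @param n_states number of microstate prototypes K (default 5).
#' @param trials_per_class recordings per subject and class (default 5).
#' @param trial_duration seconds per recording (default 20; together
#'   with `trials_per_class` this keeps the window count per subject
#'   above the fused feature dimension, as in realistic recording
#'   sessions).
#' @param snr linear ratio of state-signal RMS to noise RMS (default 10).
#' @param style_strength scale of per-subject affine feature distortion
#'   (log-normal feature gains with sd `style_strength`, mild
#'   cross-feature mixing, scale-matched offsets); 0 disables styles.
#'   The default 1.5 is calibrated so the no-transfer cross-subject
#'   accuracy on the default benchmark drops to roughly 60%, the
#'   characteristic degradation of raw cross-subject emotion EEG
#'   features, recoverable by style transfer.
#' @param class_separation scales how far class-specific dwell/transition
#'   profiles deviate from the shared base (default 1).
#' @param trial_jitter lognormal sd of a per-trial multiplier on dwell
#'   means, modelling within-class variability across trials
#'   (default 0.05).
#' @param dwell_law `"truncnorm"` (truncated normal, sd = mean/4,
#'   minimum 2 samples — matches the ~80-120 ms quasi-stability of
#'   microstates better than a memoryless law) or `"geometric"`.
#' @param feature_dim dimension of the feature space the subject styles
#'   act on (default 200 = 5 bands x 40 microstate features at K = 5).
#' @param seed integer master seed; identical configs give bit-identical
#'   datasets.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 6, n_classes = 3, n_channels = 28,
                             sampling_rate = 250, n_states = 5,
                             trials_per_class = 5, trial_duration = 20,
                             snr = 10, style_strength = 1.5,
                             class_separation = 1, trial_jitter = 0.05,
                             dwell_law = c("truncnorm", "geometric"),
                             feature_dim = 200, seed = 1L) {
  dwell_law <- match.arg(dwell_law)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_classes = as.integer(n_classes),
              n_channels = as.integer(n_channels),
              sampling_rate = sampling_rate,
              n_states = as.integer(n_states),
              trials_per_class = as.integer(trials_per_class),
              trial_duration = trial_duration,
              snr = snr, style_strength = style_strength,
              class_separation = class_separation,
              trial_jitter = trial_jitter,
              dwell_law = dwell_law,
              feature_dim = as.integer(feature_dim),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects >= 1, n_classes >= 1, n_channels >= 2,
              n_states >= 1, trials_per_class >= 1,
              sampling_rate > 0, trial_duration > 0, snr > 0,
              style_strength >= 0, trial_jitter >= 0)
  })
  class(cfg) <- "generator_config"
  cfg
}

#' An EEG recording container
#'
#' @param data channels x samples numeric matrix.
#' @param sampling_rate Hz.
#' @param channel_labels character vector, one per channel.
#' @param subject subject identifier.
#' @param label class label (emotion), or NA.
#' @param state_sequence optional ground-truth per-sample state labels.
#' @return `eeg_recording` list.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          subject = NA, label = NA, state_sequence = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  stopifnot(length(channel_labels) == nrow(data), sampling_rate > 0)
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, subject = subject,
                 label = label, state_sequence = state_sequence),
            class = "eeg_recording")
}

#' Toy lead field on a spherical source grid
#'
#' Builds a sensors x sources gain matrix for testing the inverse
#' problem: sources sit on a Fibonacci grid over the unit sphere,
#' sensors on a slightly larger shell, and the gain falls off with the
#' squared sensor-source distance. Columns are scaled to unit norm so
#' the column-norm weighting of the standardized inverse reduces to the
#' identity. If the construction is rank-deficient the geometry is
#' perturbed and rebuilt (bounded retries).
#'
#' @param n_channels number of sensors (>= 2).
#' @param n_sources number of sources (>= n_channels).
#' @param seed integer seed.
#' @return `lead_field`: list with `gain` (channels x sources, full row
#'   rank, unit-norm columns), `source_positions` (n_sources x 3, on the
#'   unit sphere), `sensor_positions`, `channel_labels`.
#' @export
make_lead_field <- function(n_channels, n_sources, seed = 1L) {
  stopifnot(n_channels >= 2, n_sources >= n_channels)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  for (attempt in 1:10) {
    src <- fibonacci_sphere(n_sources)
    sens <- fibonacci_sphere(n_channels) * 1.2
    if (attempt > 1) {  # perturb geometry on retry
      sens <- sens + matrix(stats::rnorm(length(sens), sd = 0.05),
                            ncol = 3)
    }
    d2 <- outer(rowSums(sens^2), rowSums(src^2), `+`) -
      2 * sens %*% t(src)
    gain <- 1 / pmax(d2, 1e-6)
    # small fixed perturbation breaks symmetry-induced degeneracy
    gain <- gain * (1 + 0.05 * matrix(stats::rnorm(length(gain)),
                                      nrow = n_channels))
    cn <- sqrt(colSums(gain^2))
    if (any(cn == 0)) next
    gain <- sweep(gain, 2, cn, `/`)
    sv <- svd(gain, nu = 0, nv = 0)$d
    if (sv[n_channels] > max(sv) * 1e-8) {
      return(structure(list(gain = gain, source_positions = src,
                            sensor_positions = sens,
                            channel_labels = paste0("ch", seq_len(n_channels))),
                       class = "lead_field"))
    }
  }
  stop("could not build a full-row-rank lead field after 10 attempts")
}

# near-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Dwell times are drawn per segment from the configured law with the
#' requested per-state mean; successive segment labels follow the
#' (zero-diagonal, row-stochastic) transition matrix.
#'
#' @param transition K x K row-stochastic matrix with zero diagonal
#'   (ignored for K = 1).
#' @param dwell_means_ms K-vector of mean dwell times in ms (positive).
#' @param length number of samples to generate.
#' @param sampling_rate Hz.
#' @param dwell_law `"truncnorm"` (default; sd = mean/4, min 2 samples)
#'   or `"geometric"`.
#' @param seed integer seed.
#' @return integer vector of labels in 1..K, length `length`.
#' @export
simulate_state_sequence <- function(transition, dwell_means_ms, length,
                                    sampling_rate,
                                    dwell_law = c("truncnorm", "geometric"),
                                    seed = 1L) {
  dwell_law <- match.arg(dwell_law)
  transition <- as.matrix(transition)
  K <- length(dwell_means_ms)
  stopifnot(all(dwell_means_ms > 0), length >= 1)
  if (K > 1) {
    stopifnot(nrow(transition) == K, ncol(transition) == K)
    if (any(abs(diag(transition)) > 1e-12)) {
      stop("transition matrix must have zero diagonal (segment-level)")
    }
    if (any(abs(rowSums(transition) - 1) > 1e-9)) {
      stop("transition matrix rows must sum to 1")
    }
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  mean_samples <- dwell_means_ms / 1000 * sampling_rate
  labels <- integer(length)
  pos <- 1L
  state <- if (K == 1) 1L else sample.int(K, 1)
  while (pos <= length) {
    dwell <- draw_dwell(mean_samples[state], dwell_law)
    end <- min(pos + dwell - 1L, length)
    labels[pos:end] <- state
    pos <- end + 1L
    if (K > 1) state <- sample.int(K, 1, prob = transition[state, ])
  }
  labels
}

draw_dwell <- function(mean_samples, dwell_law) {
  if (dwell_law == "geometric") {
    # support starts at 1; mean = 1 + (1-p)/p
    p <- 1 / max(mean_samples, 1)
    1L + stats::rgeom(1, p)
  } else {
    max(2L, as.integer(round(stats::rnorm(1, mean_samples,
                                          mean_samples / 4))))
  }
}

#' Simulate a recording from prototypes and a state sequence
#'
#' At sample t the clean signal is the active prototype scaled by a
#' half-sine amplitude envelope over its segment (so GFP peaks near every
#' segment midpoint, exercising the GFP-peak pipeline), plus independent
#' Gaussian channel noise scaled so state-signal RMS / noise RMS equals
#' `snr`. Use `snr = Inf` for a noiseless recording.
#'
#' @param prototypes K x channels matrix (zero-mean unit-norm rows
#'   enforced internally).
#' @param labels integer state sequence in 1..K.
#' @param sampling_rate Hz.
#' @param snr positive linear SNR (RMS ratio); `Inf` allowed.
#' @param amplitude peak envelope amplitude in signal units (default 10,
#'   a typical microvolt-scale GFP).
#' @param seed integer seed (noise only).
#' @param subject,label optional metadata stored on the recording.
#' @return an [eeg_recording()] with `state_sequence` ground truth.
#' @export
simulate_recording <- function(prototypes, labels, sampling_rate, snr,
                               amplitude = 10, seed = 1L, subject = NA,
                               label = NA) {
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  prototypes <- normalize_maps(prototypes)
  n <- length(labels)
  seg <- label_segments(labels)
  envelope <- numeric(n)
  for (s in seq_len(nrow(seg))) {
    idx <- seg$start[s]:(seg$start[s] + seg$length[s] - 1L)
    # half-sine: 0 at segment edges, max at midpoint
    envelope[idx] <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
  }
  clean <- t(prototypes[labels, , drop = FALSE]) *
    rep(envelope * amplitude, each = ncol(prototypes))
  if (is.infinite(snr)) {
    noisy <- clean
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    sig_rms <- sqrt(mean(clean^2))
    noise <- matrix(stats::rnorm(length(clean), sd = sig_rms / snr),
                    nrow = nrow(clean))
    noisy <- clean + noise
  }
  eeg_recording(noisy, sampling_rate, subject = subject, label = label,
                state_sequence = labels)
}

# class-conditional microstate dynamics: dwell-mean profiles and
# cyclically-shifted transition preferences, scaled by `separation`
class_dynamics <- function(n_classes, K, separation) {
  base_ms <- seq(80, 120, length.out = n_classes)  # per-class dwell base
  dwell <- matrix(0, n_classes, K)
  trans <- vector("list", n_classes)
  for (c in seq_len(n_classes)) {
    prof <- 1 + separation * 0.35 *
      sin(2 * pi * (seq_len(K) + c - 1) / K)
    dwell[c, ] <- base_ms[c] * prof
    if (K == 1) {
      trans[[c]] <- matrix(0, 1, 1)
    } else {
      Tm <- matrix(1, K, K)
      diag(Tm) <- 0
      # each class prefers a different cyclic successor
      for (j in seq_len(K)) {
        Tm[j, (j + c - 1) %% K + 1] <- Tm[j, (j + c - 1) %% K + 1] +
          3 * separation
      }
      diag(Tm) <- 0
      trans[[c]] <- Tm / rowSums(Tm)
    }
  }
  list(dwell_means = dwell, transition = trans)
}

# random zero-mean unit-norm prototype maps with pairwise |cos| bounded
make_prototypes <- function(K, n_channels, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  raw <- matrix(stats::rnorm(K * n_channels), K)
  # Gram-Schmidt after centering: orthogonal zero-mean maps, well apart
  raw <- raw - rowMeans(raw)
  for (j in seq_len(K)) {
    if (j > 1) {
      prev <- raw[1:(j - 1), , drop = FALSE]
      raw[j, ] <- raw[j, ] - as.vector(t(prev) %*%
                                         (prev %*% raw[j, ]))
    }
    raw[j, ] <- raw[j, ] - mean(raw[j, ])
    raw[j, ] <- raw[j, ] / sqrt(sum(raw[j, ]^2))
  }
  raw
}

# nominal per-dimension scales of the fused microstate feature vector,
# used to make style distortions unit-aware (coverage ~1/K, duration in
# ms ~ dwell mean, occurrence ~1000/(K*dwell) per s, transition ~1/(K-1))
style_scales <- function(M, K, dwell_ms = 100) {
  per_band <- K * (K + 3)
  if (M %% per_band != 0) return(rep(1, M))
  occ <- 1000 / (K * dwell_ms)
  tr <- if (K > 1) 1 / (K - 1) else 1
  rep(c(rep(1 / K, K), rep(dwell_ms, K), rep(occ, K), rep(tr, K * K)),
      M / per_band)
}

# per-subject affine style in feature space: per-dimension gains plus
# mild cross-feature mixing and an offset, all expressed relative to the
# nominal scale of each feature (S): A = S D (I + m G/sqrt(M)) S^-1,
# b = s * S g.  Gain/offset dominated, as cross-subject EEG feature
# shifts are; `strength` 0 gives the identity.
make_styles <- function(n_subjects, M, strength, seed, K = 5,
                        dwell_ms = 100) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  S <- style_scales(M, K, dwell_ms)
  lapply(seq_len(n_subjects), function(i) {
    if (strength == 0) {
      return(list(A = diag(M), b = numeric(M)))
    }
    gains <- exp(strength * stats::rnorm(M))
    mix <- diag(M) + 0.25 * strength *
      matrix(stats::rnorm(M * M), M) / sqrt(M)
    A <- (gains * mix) * outer(S, 1 / S)
    list(A = A, b = strength * S * stats::rnorm(M))
  })
}

#' Simulate a full multi-subject dataset
#'
#' One recording per subject x class x trial. All subjects share the
#' prototype maps; classes differ only through their microstate dynamics
#' (dwell-time profiles and transition preferences), mirroring the
#' premise that prototypes are shared across conditions and the
#' statistics discriminate. Per-subject style maps (affine distortions
#' of the extracted feature vectors) are returned in the ground truth
#' and applied downstream by [apply_subject_style()].
#'
#' @param config a [generator_config()].
#' @return list with `recordings` (list of [eeg_recording()]) and
#'   `ground_truth`: `prototypes`, `class_transition` (list),
#'   `class_duration_means` (n_classes x K, ms), `subject_styles`
#'   (list of `(A, b)`), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  protos <- make_prototypes(cfg$n_states, cfg$n_channels, cfg$seed)
  dyn <- class_dynamics(cfg$n_classes, cfg$n_states, cfg$class_separation)
  styles <- make_styles(cfg$n_subjects, cfg$feature_dim,
                        cfg$style_strength, cfg$seed + 777L,
                        K = cfg$n_states,
                        dwell_ms = mean(dyn$dwell_means))
  n_samp <- round(cfg$trial_duration * cfg$sampling_rate)
  recordings <- list()
  idx <- 0L
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  for (subj in seq_len(cfg$n_subjects)) {
    for (cls in seq_len(cfg$n_classes)) {
      for (trial in seq_len(cfg$trials_per_class)) {
        idx <- idx + 1L
        # fixed fan-out: one derived stream per (subject, class, trial)
        s <- cfg$seed + 1000L * subj + 100L * cls + trial
        dwell <- dyn$dwell_means[cls, ]
        if (cfg$trial_jitter > 0) {
          set.seed(s + 50000L)
          dwell <- dwell * stats::rlnorm(1, 0, cfg$trial_jitter)
        }
        labels <- simulate_state_sequence(dyn$transition[[cls]], dwell,
                                          n_samp, cfg$sampling_rate,
                                          cfg$dwell_law, seed = s)
        rec <- simulate_recording(protos, labels, cfg$sampling_rate,
                                  cfg$snr, seed = s + 25000L)
        rec$subject <- subj
        rec$label <- cls
        recordings[[idx]] <- rec
      }
    }
  }
  list(recordings = recordings,
       ground_truth = list(prototypes = protos,
                           class_transition = dyn$transition,
                           class_duration_means = dyn$dwell_means,
                           subject_styles = styles,
                           config = cfg))
}

#' Apply a subject's style distortion to feature rows
#'
#' @param features matrix, windows x M.
#' @param style list with `A` (M x M) and `b` (M-vector).
#' @return distorted feature matrix, same shape.
#' @export
apply_subject_style <- function(features, style) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == nrow(style$A))
  t(style$A %*% t(features) + style$b)
}

#' Write a simulated dataset to a directory
#'
#' One CSV per recording (channels x samples, one row per channel), a
#' `metadata.json` sidecar describing each file (subject, class,
#' sampling rate, channel labels), and `ground_truth.json` with the
#' generating prototypes, dynamics, and style maps.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing datasets requires the jsonlite package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    fname <- sprintf("recording_%03d.csv", i)
    utils::write.table(rec$data, file.path(dir, fname), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    meta[[i]] <- list(file = fname, subject = rec$subject,
                      label = rec$label,
                      sampling_rate = rec$sampling_rate,
                      channel_labels = rec$channel_labels,
                      state_sequence = rec$state_sequence)
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- dataset$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `recordings` and `ground_truth` (as in
#'   [simulate_dataset()]; matrices restored from JSON arrays).
#' @export
read_dataset <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading datasets requires the jsonlite package")
  }
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  recordings <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    data <- as.matrix(utils::read.table(file.path(dir, m$file),
                                        sep = ",", header = FALSE))
    dimnames(data) <- NULL
    eeg_recording(data, m$sampling_rate,
                  channel_labels = m$channel_labels[[1]],
                  subject = m$subject, label = m$label,
                  state_sequence = m$state_sequence[[1]])
  })
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  to_mat <- function(x) do.call(rbind, lapply(x, unlist))
  gt$prototypes <- to_mat(gt$prototypes)
  gt$class_transition <- lapply(gt$class_transition, to_mat)
  gt$class_duration_means <- to_mat(gt$class_duration_means)
  gt$subject_styles <- lapply(gt$subject_styles, function(s) {
    list(A = to_mat(s$A), b = unlist(s$b))
  })
  gt$config <- do.call(generator_config, lapply(gt$config, unlist))
  list(recordings = recordings, ground_truth = gt)
}
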