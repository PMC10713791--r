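#' Global field power
#'
#' GFP at each time point is the spatial standard deviation of the
#' (average-referenced) potential across channels,
#' \eqn{GFP(t) = \sqrt{\sum_i (V_i(t) - \bar V(t))^2 / C}},
#' with `C` the channel count. Local maxima of the GFP curve mark the
#' high signal-to-noise samples used as input to microstate clustering.
#'
#' @param x numeric matrix, channels x samples (an [eeg_recording()] is
#'   also accepted).
#' @param sampling_rate sampling rate in Hz, used to convert the minimum
#'   peak distance to samples. Taken from the recording if one is given.
#' @param min_peak_distance_ms minimum spacing between reported GFP peaks
#'   in milliseconds (default 10 ms). Peaks are strict local maxima;
#'   when two candidates fall closer than this, the larger one wins.
#' @return an object of class `gfp_series`: list with `values`
#'   (nonnegative, one per sample) and `peak_indices`.
#' @export
compute_gfp <- function(x, sampling_rate = NULL, min_peak_distance_ms = 10) {
  if (inherits(x, "eeg_recording")) {
    if (is.null(sampling_rate)) sampling_rate <- x$sampling_rate
    x <- x$data
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("GFP requires at least 2 channels")
  centered <- sweep(x, 2, colMeans(x))
  values <- sqrt(colSums(centered^2) / nrow(x))
  peaks <- find_gfp_peaks(values, sampling_rate, min_peak_distance_ms)
  structure(list(values = values, peak_indices = peaks), class = "gfp_series")
}

# strict local maxima with optional minimum spacing (greedy by height)
find_gfp_peaks <- function(values, sampling_rate = NULL, min_peak_distance_ms = 0) {
  n <- length(values)
  if (n < 3) return(integer(0))
  inner <- 2:(n - 1)
  is_peak <- values[inner] > values[inner - 1] & values[inner] > values[inner + 1]
  peaks <- inner[is_peak]
  min_dist <- 0
  if (!is.null(sampling_rate) && min_peak_distance_ms > 0) {
    min_dist <- min_peak_distance_ms / 1000 * sampling_rate
  }
  if (min_dist > 1 && length(peaks) > 1) {
    keep <- logical(length(peaks))
    taken <- integer(0)
    for (i in order(values[peaks], decreasing = TRUE)) {
      if (!length(taken) || all(abs(peaks[i] - taken) >= min_dist)) {
        keep[i] <- TRUE
        taken <- c(taken, peaks[i])
      }
    }
    peaks <- sort(peaks[keep])
  }
  peaks
}

# zero-mean, unit-norm rows; rows with zero norm raise an error
normalize_maps <- function(maps) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < .Machine$double.eps * ncol(maps))) {
    stop("cannot normalize a spatially constant map")
  }
  maps / nrm
}

# Pearson spatial correlation of each row of `maps` (samples x channels)
# against each row of `protos` (K x channels); returns samples x K
spatial_correlation <- function(maps, protos) {
  maps <- as.matrix(maps) - rowMeans(as.matrix(maps))
  protos <- as.matrix(protos) - rowMeans(as.matrix(protos))
  mn <- sqrt(rowSums(maps^2))
  pn <- sqrt(rowSums(protos^2))
  mn[mn == 0] <- Inf  # constant map correlates 0 with everything
  pn[pn == 0] <- Inf
  (maps %*% t(protos)) / outer(mn, pn)
}

#' Cluster GFP-peak topographies into microstate prototypes
#'
#' Modified k-means on topography vectors. Assignment minimizes the
#' squared Euclidean distance to the prototype (or, with
#' `polarity_invariant = TRUE`, maximizes the absolute spatial
#' correlation); the update step averages the assigned maps (sign-aligned
#' in the polarity-invariant case) and renormalizes. The best of
#' `n_init` restarts by total global explained variance (GEV) is kept.
#' Empty clusters are re-seeded from the worst-fit map.
#'
#' @param peak_maps matrix, n_maps x channels: topographies at GFP peaks.
#' @param k number of microstate classes.
#' @param n_init number of random restarts (default 20).
#' @param max_iter iteration cap per restart (default 300).
#' @param polarity_invariant if TRUE, assignment ignores map polarity.
#'   Default FALSE: plain Euclidean assignment on normalized maps.
#' @param seed integer seed for restart initialization.
#' @return `prototype_set`: list with `maps` (k x channels, zero-mean
#'   unit-norm rows), `k`, `labels` (per input map), `gev_total`,
#'   `cv_value` (residual-noise criterion, needs C > k + 1 else NA),
#'   `polarity_invariant`.
#' @export
cluster_microstates <- function(peak_maps, k, n_init = 20, max_iter = 300,
                                polarity_invariant = FALSE, seed = 1L) {
  peak_maps <- as.matrix(peak_maps)
  if (k < 1) stop("k must be >= 1")
  n <- nrow(peak_maps)
  if (n < k) stop("need at least k peak maps (", n, " < ", k, ")")
  X <- normalize_maps(peak_maps)
  gfp_w <- sqrt(rowSums((peak_maps - rowMeans(peak_maps))^2) / ncol(peak_maps))

  best <- NULL
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  for (init in seq_len(n_init)) {
    centers <- X[sample.int(n, k), , drop = FALSE]
    labels <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      new_labels <- assign_maps(X, centers, polarity_invariant)
      centers <- update_centers(X, new_labels, centers, k, polarity_invariant)
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    gev <- gev_from_parts(X, centers, labels, gfp_w)
    if (is.null(best) || gev > best$gev) {
      best <- list(centers = centers, labels = labels, gev = gev)
    }
  }

  C <- ncol(X)
  cv <- if (C > k + 1) {
    compute_cv(peak_maps, best$centers, best$labels)
  } else NA_real_
  structure(list(maps = best$centers, k = k, labels = best$labels,
                 gev_total = best$gev, cv_value = cv,
                 polarity_invariant = polarity_invariant),
            class = "prototype_set")
}

assign_maps <- function(X, centers, polarity_invariant) {
  if (polarity_invariant) {
    max.col(abs(spatial_correlation(X, centers)), ties.method = "first")
  } else {
    # ||x - mu||^2 = ||x||^2 + ||mu||^2 - 2 x.mu ; rows unit-norm
    max.col(X %*% t(centers), ties.method = "first")
  }
}

update_centers <- function(X, labels, centers, k, polarity_invariant) {
  for (j in seq_len(k)) {
    idx <- which(labels == j)
    if (!length(idx)) {
      # re-seed an empty cluster from the worst-fit map
      fit <- apply(abs(spatial_correlation(X, centers)), 1, max)
      centers[j, ] <- X[which.min(fit), ]
      next
    }
    member <- X[idx, , drop = FALSE]
    if (polarity_invariant) {
      sgn <- sign(member %*% centers[j, ])
      sgn[sgn == 0] <- 1
      member <- member * as.vector(sgn)
    }
    m <- colMeans(member)
    if (sqrt(sum(m^2)) < 1e-12) m <- X[idx[1], ]
    centers[j, ] <- m
  }
  normalize_maps(centers)
}

gev_from_parts <- function(X, centers, labels, gfp_w) {
  corr <- spatial_correlation(X, centers)
  fit <- corr[cbind(seq_len(nrow(X)), labels)]
  sum((fit * gfp_w)^2) / sum(gfp_w^2)
}

#' Global explained variance of a microstate segmentation
#'
#' \eqn{GEV = \sum_i (Corr(x_i, p_{l_i}) \cdot GFP_i)^2 / \sum_i GFP_i^2}:
#' the GFP-weighted squared spatial correlation between each sample and
#' its assigned prototype, normalized to lie in \[0, 1\].
#'
#' @param data matrix, samples x channels.
#' @param prototypes matrix, K x channels.
#' @param labels integer vector in 1..K, one per sample.
#' @param gfp optional precomputed GFP values (one per sample).
#' @return scalar GEV in \[0, 1\].
#' @export
compute_gev <- function(data, prototypes, labels, gfp = NULL) {
  data <- as.matrix(data)
  if (is.null(gfp)) {
    gfp <- sqrt(rowSums((data - rowMeans(data))^2) / ncol(data))
  }
  if (sum(gfp^2) == 0) stop("total GFP is zero; GEV undefined")
  corr <- spatial_correlation(data, as.matrix(prototypes))
  fit <- corr[cbind(seq_along(labels), labels)]
  sum((fit * gfp)^2) / sum(gfp^2)
}

#' Cross-validation criterion for microstate model selection
#'
#' Residual-noise criterion
#' \eqn{CV = \hat\sigma^2 \cdot ((C-1)/(C-K-1))^2} with
#' \eqn{\hat\sigma^2 = \sum_i (x_i^T x_i - (a_{l_i}^T x_i)^2) / (N(C-1))},
#' where `a_l` are the unit-norm prototypes, `C` the channel count and
#' `K` the number of microstate classes. Lower is better; the
#' degrees-of-freedom factor penalizes larger K.
#'
#' @inheritParams compute_gev
#' @return scalar CV value (nonnegative).
#' @export
compute_cv <- function(data, prototypes, labels) {
  data <- as.matrix(data)
  prototypes <- normalize_maps(prototypes)
  C <- ncol(data)
  K <- nrow(prototypes)
  if (C <= K + 1) stop("CV criterion needs more channels than K + 1 (C=",
                       C, ", K=", K, ")")
  N <- nrow(data)
  data <- data - rowMeans(data)  # average reference per sample
  proj <- rowSums(data * prototypes[labels, , drop = FALSE])
  sigma2 <- sum(rowSums(data^2) - proj^2) / (N * (C - 1))
  sigma2 * ((C - 1) / (C - K - 1))^2
}

#' Select the number of microstate classes by GEV and CV
#'
#' Clusters the peak maps for each candidate `k` and tabulates total GEV
#' and the CV criterion. The default rule returns the smallest `k`
#' whose GEV exceeds `gev_threshold` and that is a local minimum of CV
#' over the candidate grid; if no k satisfies both, the smallest k
#' passing the GEV threshold; failing that, the CV-minimizing k.
#' Ties go to the smaller k.
#'
#' @param peak_maps matrix, n_maps x channels.
#' @param k_range integer vector of candidate class counts.
#' @param gev_threshold minimum acceptable explained variance
#'   (default 0.85; a dataset-level convention — roughly the fraction a
#'   5-class model explains on typical emotion EEG; 0.70 is a common
#'   per-subject choice).
#' @param ... passed to [cluster_microstates()].
#' @param seed seed forwarded to the clusterings.
#' @return list with `k` (chosen), `table` (data.frame k/gev/cv), and
#'   `models` (the per-k `prototype_set`s).
#' @export
select_k <- function(peak_maps, k_range = 2:10, gev_threshold = 0.85,
                     seed = 1L, ...) {
  peak_maps <- as.matrix(peak_maps)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k_range")
  C <- ncol(peak_maps)
  k_range <- k_range[k_range >= 1 & k_range < C - 1 & k_range <= nrow(peak_maps)]
  if (!length(k_range)) stop("no admissible k in range (need 1 <= k < C-1)")
  models <- lapply(k_range, function(k) {
    cluster_microstates(peak_maps, k, seed = seed, ...)
  })
  gev <- vapply(models, `[[`, numeric(1), "gev_total")
  cv <- vapply(models, `[[`, numeric(1), "cv_value")
  tab <- data.frame(k = k_range, gev = gev, cv = cv)

  pass <- gev >= gev_threshold
  local_min <- vapply(seq_along(cv), function(i) {
    left_ok <- i == 1 || cv[i] <= cv[i - 1]
    right_ok <- i == length(cv) || cv[i] <= cv[i + 1]
    left_ok && right_ok
  }, logical(1))
  cand <- which(pass & local_min)
  if (!length(cand)) cand <- which(pass)
  if (!length(cand)) cand <- which.min(cv)
  chosen <- k_range[min(cand)]
  list(k = chosen, table = tab, models = models)
}

#' Backfit microstate prototypes to a recording
#'
#' Assigns every sample to the prototype with the highest spatial
#' correlation. Polarity-invariant by default (the explained-variance
#' measure is sign-blind), so a map and its negation get the same label.
#'
#' @param data matrix samples x channels, or an `eeg_recording` /
#'   `source_activity` (transposed internally).
#' @param prototypes `prototype_set` or K x channels matrix.
#' @param sampling_rate Hz; needed later for statistics in physical
#'   units. Taken from the recording when available.
#' @param polarity_invariant use absolute correlation (default TRUE).
#' @return `microstate_segmentation`: list with `labels` (1..K per
#'   sample), `correlations` (winning |r| per sample), `k`,
#'   `sampling_rate`, `smoothed` flag.
#' @export
backfit <- function(data, prototypes, sampling_rate = NULL,
                    polarity_invariant = TRUE) {
  if (inherits(data, "eeg_recording")) {
    if (is.null(sampling_rate)) sampling_rate <- data$sampling_rate
    data <- t(data$data)
  } else if (inherits(data, "source_activity")) {
    if (is.null(sampling_rate)) sampling_rate <- data$sampling_rate
    data <- t(data$values)
  }
  maps <- if (inherits(prototypes, "prototype_set")) prototypes$maps else
    normalize_maps(prototypes)
  corr <- spatial_correlation(as.matrix(data), maps)
  score <- if (polarity_invariant) abs(corr) else corr
  labels <- max.col(score, ties.method = "first")
  structure(list(labels = labels,
                 correlations = score[cbind(seq_len(nrow(score)), labels)],
                 k = nrow(maps), sampling_rate = sampling_rate,
                 smoothed = FALSE),
            class = "microstate_segmentation")
}

# run-length segments of a label vector: data.frame(label, start, length)
label_segments <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L,
             length = r$lengths)
}

#' Temporally smooth a microstate segmentation
#'
#' Segments shorter than `min_duration_ms` are merged into the adjacent
#' segment whose prototype fits better at the boundary samples (higher
#' stored correlation), iterating until no short segment remains or a
#' fixed point is reached. `min_duration_ms = 0` is the identity.
#'
#' @param segmentation a `microstate_segmentation`.
#' @param min_duration_ms minimum segment duration in milliseconds
#'   (default 30 ms).
#' @return smoothed `microstate_segmentation` (`smoothed = TRUE`).
#' @export
smooth_labels <- function(segmentation, min_duration_ms = 30) {
  stopifnot(inherits(segmentation, "microstate_segmentation"))
  if (min_duration_ms < 0) stop("min_duration_ms must be >= 0")
  out <- segmentation
  out$smoothed <- TRUE
  if (min_duration_ms == 0) return(out)
  if (is.null(out$sampling_rate)) stop("sampling_rate needed to smooth")
  min_len <- ceiling(min_duration_ms / 1000 * out$sampling_rate)
  corr <- out$correlations
  seg <- label_segments(out$labels)
  st <- seg$start
  ln <- seg$length
  lb <- seg$label
  # merge the shortest sub-threshold segment into the neighbor with the
  # better fit at the shared boundary, coalesce equal-label neighbors,
  # and repeat; a lone full-length segment is never wiped out
  while (length(ln) > 1) {
    short <- which(ln < min_len)
    if (!length(short)) break
    s <- short[which.min(ln[short])]
    if (s == 1L) tgt <- 2L
    else if (s == length(ln)) tgt <- s - 1L
    else {
      lfit <- corr[st[s]]
      rfit <- corr[st[s] + ln[s] - 1L]
      tgt <- if (lfit >= rfit) s - 1L else s + 1L
    }
    lo <- min(s, tgt)
    hi <- max(s, tgt)
    ln[lo] <- ln[lo] + ln[hi]
    lb[lo] <- lb[tgt]
    st <- st[-hi]; ln <- ln[-hi]; lb <- lb[-hi]
    repeat {
      if (lo > 1L && lb[lo - 1L] == lb[lo]) {
        ln[lo - 1L] <- ln[lo - 1L] + ln[lo]
        st <- st[-lo]; ln <- ln[-lo]; lb <- lb[-lo]
        lo <- lo - 1L
      } else if (lo < length(lb) && lb[lo + 1L] == lb[lo]) {
        ln[lo] <- ln[lo] + ln[lo + 1L]
        st <- st[-(lo + 1L)]; ln <- ln[-(lo + 1L)]; lb <- lb[-(lo + 1L)]
      } else break
    }
  }
  out$labels <- rep.int(lb, ln)
  out
}

#' Microstate statistics: coverage, duration, occurrence, transitions
#'
#' Coverage is the fraction of samples assigned to each class. Duration
#' is the mean segment length per class in milliseconds. Occurrence is
#' the number of segments per class divided by total recording time in
#' seconds. Transitions are segment-level counts row-normalized to a
#' stochastic matrix (self-transitions are impossible at segment level;
#' a class that is never left keeps an all-zero row). For every class
#' with nonzero coverage, occurrence * duration = 1000 * coverage.
#'
#' @param segmentation `microstate_segmentation` (or integer label
#'   vector, with `k` and `sampling_rate` supplied).
#' @param k number of classes (taken from the segmentation if present).
#' @param sampling_rate Hz.
#' @return `microstate_stats`: list with `coverage`, `duration_ms`,
#'   `occurrence_per_s` (K-vectors) and `transition` (K x K matrix).
#' @export
microstate_statistics <- function(segmentation, k = NULL,
                                  sampling_rate = NULL) {
  if (inherits(segmentation, "microstate_segmentation")) {
    labels <- segmentation$labels
    if (is.null(k)) k <- segmentation$k
    if (is.null(sampling_rate)) sampling_rate <- segmentation$sampling_rate
  } else {
    labels <- as.integer(segmentation)
  }
  if (!length(labels)) stop("empty segmentation")
  if (is.null(k)) k <- max(labels)
  if (is.null(sampling_rate)) stop("sampling_rate required")
  n <- length(labels)
  total_s <- n / sampling_rate

  coverage <- tabulate(labels, nbins = k) / n
  seg <- label_segments(labels)
  n_seg <- tabulate(seg$label, nbins = k)
  mean_len <- vapply(seq_len(k), function(j) {
    lens <- seg$length[seg$label == j]
    if (length(lens)) mean(lens) else 0
  }, numeric(1))
  duration_ms <- mean_len / sampling_rate * 1000
  occurrence <- n_seg / total_s

  transition <- matrix(0, k, k)
  if (nrow(seg) > 1) {
    from <- seg$label[-nrow(seg)]
    to <- seg$label[-1]
    for (i in seq_along(from)) {
      transition[from[i], to[i]] <- transition[from[i], to[i]] + 1
    }
    rs <- rowSums(transition)
    nz <- rs > 0
    transition[nz, ] <- transition[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(coverage = coverage, duration_ms = duration_ms,
                 occurrence_per_s = occurrence, transition = transition),
            class = "microstate_stats")
}

# save/restore .Random.seed so seeded helpers do not disturb the caller
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
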