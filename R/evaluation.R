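#' Leave-one-subject-out evaluation
#'
#' Each subject in turn is held out as the unseen target domain; the
#' remaining subjects form the source domain. Prototype clustering, STM
#' pairing and classifier fitting see only source-domain data and the
#' unlabeled target features; target labels are reachable only by the
#' scorer.
#'
#' @name evaluation
NULL

#' Enumerate LOSO folds
#'
#' @param subjects vector of subject ids (one entry per recording or
#'   sample; duplicates fine).
#' @return list of folds, each `list(target = id, source = ids)`, one
#'   per distinct subject, in sorted order.
#' @export
loso_folds <- function(subjects) {
  ids <- sort(unique(subjects))
  if (length(ids) < 2) stop("LOSO needs at least 2 subjects")
  lapply(ids, function(t) list(target = t, source = setdiff(ids, t)))
}

#' The 27-value SVM hyperparameter pool
#'
#' `{0.01k, 0.1k, k | k = 1..9}`, used for grid search over the SVM cost
#' (and, for non-linear kernels, gamma).
#'
#' @return sorted numeric vector of 27 values.
#' @export
svm_param_grid <- function() {
  k <- 1:9
  sort(c(0.01 * k, 0.1 * k, k))
}

#' Train a linear-kernel SVM with grid-searched cost
#'
#' The cost parameter is selected from [svm_param_grid()] by accuracy on
#' an internal stratified validation split of the training data
#' (default 20% held out), then the model is refit on all training data
#' with the winning cost. Deterministic under `seed`.
#'
#' @param features matrix, samples x M.
#' @param labels class labels (>= 2 classes).
#' @param grid candidate cost values (default [svm_param_grid()]).
#' @param validation_fraction internal held-out fraction (default 0.2).
#' @param selection_cap ceiling on the number of training rows used
#'   while scoring grid candidates (stratified subsample, default 600);
#'   the winning cost is refit on all rows. Keeps the 27-fit grid cheap
#'   on large window sets without changing the final model class.
#' @param seed integer seed controlling the split.
#' @return fitted `e1071::svm` object with attribute `cost`.
#' @export
train_svm <- function(features, labels, grid = svm_param_grid(),
                      validation_fraction = 0.2, selection_cap = 600,
                      seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes to train")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(features)
  val <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(length(idx) * validation_fraction)))
  }))
  train <- setdiff(seq_len(n), val)
  if (nlevels(droplevels(labels[train])) < 2) {
    train <- seq_len(n); val <- seq_len(n)  # tiny data: select in-sample
  }
  if (length(train) > selection_cap) {
    sel <- unlist(lapply(levels(labels), function(cl) {
      idx <- intersect(train, which(labels == cl))
      sample(idx, round(selection_cap * length(idx) / length(train)))
    }))
  } else sel <- train
  acc <- vapply(grid, function(C) {
    fit <- e1071::svm(features[sel, , drop = FALSE],
                      droplevels(labels[sel]),
                      kernel = "linear", cost = C, scale = FALSE,
                      tolerance = 0.01)
    mean(stats::predict(fit, features[val, , drop = FALSE]) == labels[val])
  }, numeric(1))
  best <- grid[which.max(acc)]  # ties -> smallest cost
  fit <- e1071::svm(features, labels, kernel = "linear", cost = best,
                    scale = FALSE)
  attr(fit, "cost") <- best
  fit
}

#' Mean and sample standard deviation of per-subject accuracies
#'
#' @param accuracies numeric vector (percent).
#' @param digits rounding for the returned values (default 2, matching
#'   the convention of published accuracy tables).
#' @return list with `mean` and `sd` (n-1 denominator).
#' @export
summarize_accuracies <- function(accuracies, digits = 2) {
  stopifnot(length(accuracies) >= 1)
  list(mean = round(mean(accuracies), digits),
       sd = round(stats::sd(accuracies), digits))
}

#' Published per-subject benchmark accuracies
#'
#' Reference per-subject cross-subject recognition accuracies (percent)
#' for a 13-participant odor/video emotion EEG benchmark, per feature
#' kind (source microstate, differential entropy, PSD) and classifier
#' (SVM, CNN) after style transfer under video stimuli. Used to validate
#' the summary arithmetic of [summarize_accuracies()].
#'
#' @return data.frame with columns `participant`, `svm_microstate`,
#'   `svm_de`, `svm_psd`, `cnn_microstate`, `cnn_de`, `cnn_psd`.
#' @export
benchmark_accuracies <- function() {
  utils::read.csv(system.file("extdata", "benchmark_accuracies_video.csv",
                              package = "msstm"))
}

#' Extract fused band features for a set of recordings
#'
#' For every recording: band-filter into the given bands, backfit the
#' per-band microstate prototypes, smooth, cut into windows, and compute
#' per-window feature vectors, fused across bands (microstate kind;
#' `"de"` and `"psd"` kinds skip the prototype machinery). Prototypes
#' must come from source-domain data only — this function only consumes
#' them.
#'
#' @param recordings list of [eeg_recording()].
#' @param prototypes named list (per band) of `prototype_set`s; required
#'   for `kind = "microstate"`.
#' @param bands band list from [eeg_bands()], or `NULL` for broadband.
#' @param kind `"microstate"`, `"de"` or `"psd"`.
#' @param window_s window length in seconds (default 1).
#' @param smooth_ms minimum microstate segment duration (default 30 ms).
#' @return list with `features` (windows x M matrix), `subjects`,
#'   `labels` (per window).
#' @export
extract_features <- function(recordings, prototypes = NULL, bands = eeg_bands(),
                             kind = c("microstate", "de", "psd"),
                             window_s = 1, smooth_ms = 30) {
  kind <- match.arg(kind)
  rows <- list(); subj <- list(); labs <- list()
  for (rec in recordings) {
    fs <- rec$sampling_rate
    band_list <- if (is.null(bands)) list(broadband = NULL) else bands
    per_band_windows <- list()
    for (bn in names(band_list)) {
      filtered <- if (is.null(band_list[[bn]])) rec else
        bandpass_filter(rec, band_list[[bn]][1], band_list[[bn]][2])
      if (kind == "microstate") {
        seg <- backfit(filtered, prototypes[[bn]], sampling_rate = fs)
        seg <- smooth_labels(seg, smooth_ms)
        wins <- window_segments(
          eeg_recording(filtered$data, fs, state_sequence = seg$labels),
          window_s = window_s)
        k <- prototypes[[bn]]$k
        per_band_windows[[bn]] <- lapply(wins, function(w) {
          microstate_features_per_window(w$state_sequence, k, fs)
        })
      } else {
        wins <- window_segments(filtered, window_s = window_s)
        per_band_windows[[bn]] <- lapply(wins, function(w) {
          if (kind == "de") differential_entropy(w$data)
          else band_psd(w$data, band_list[[bn]] %||% c(0, fs / 2 - 1e-9), fs)
        })
      }
    }
    n_win <- length(per_band_windows[[1]])
    for (w in seq_len(n_win)) {
      vecs <- lapply(per_band_windows, `[[`, w)
      rows[[length(rows) + 1]] <- fuse_bands(vecs)
      subj[[length(subj) + 1]] <- rec$subject
      labs[[length(labs) + 1]] <- rec$label
    }
  }
  list(features = do.call(rbind, rows), subjects = unlist(subj),
       labels = unlist(labs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GFP-peak maps pooled over a set of recordings for one band
collect_peak_maps <- function(recordings, band = NULL) {
  maps <- list()
  for (rec in recordings) {
    filtered <- if (is.null(band)) rec else
      bandpass_filter(rec, band[1], band[2])
    g <- compute_gfp(filtered)
    if (length(g$peak_indices)) {
      maps[[length(maps) + 1]] <- t(filtered$data[, g$peak_indices,
                                                  drop = FALSE])
    }
  }
  do.call(rbind, maps)
}

#' Run the full cross-subject pipeline
#'
#' For every LOSO fold: cluster per-band microstate prototypes on the
#' source recordings' GFP peaks; extract per-window fused features for
#' source and target; optionally apply the dataset's ground-truth
#' subject styles (the synthetic stand-in for inter-subject variability);
#' train a linear SVM on the source windows; score the raw target
#' windows (no-transfer baseline) and the STM-transformed target windows.
#' Features are z-scored with source-domain statistics before
#' classification. Window-level accuracy is reported per fold.
#'
#' @param dataset output of [simulate_dataset()] (or a list with
#'   `recordings` and optionally `ground_truth$subject_styles`).
#' @param k number of microstate classes (default 5).
#' @param bands band list (default [eeg_bands()]); `NULL` = broadband.
#' @param kind feature kind (default `"microstate"`).
#' @param n_per_class STM prototypes per class (default 3).
#' @param confidence STM pair confidence (default 0.8).
#' @param beta fixed STM ridge; `NULL` (default) uses the data-scaled
#'   heuristic via [compute_beta()]. A fixed value like 0.2 is only
#'   meaningful when the window count per subject is large relative to
#'   the feature dimension; the heuristic scales with the data energy
#'   and is the robust default for moderate-sized runs.
#' @param beta_tilde heuristic multiplier (default 2, mid-range of the
#'   useful \[1, 3\] interval); ignored when `beta` is given.
#' @param apply_styles distort each subject's features with its
#'   ground-truth style map when available (default TRUE).
#' @param smooth_ms,window_s see [extract_features()].
#' @param use_source_space if TRUE, recordings are mapped through
#'   [sloreta_solve()] with `leadfield` before microstate analysis.
#' @param leadfield required when `use_source_space = TRUE`.
#' @param max_peak_maps cap on pooled GFP-peak maps entering the per-fold
#'   clustering (deterministic thinning above the cap; default 3000).
#' @param seed integer seed (clustering restarts, SVM splits).
#' @return `result_table`: data.frame with one row per fold — `target`,
#'   `accuracy_no_stm`, `accuracy_stm` (percent) — plus attributes
#'   `summary` (means/sds) and `chance` (percent).
#' @export
run_pipeline <- function(dataset, k = 5, bands = eeg_bands(),
                         kind = "microstate", n_per_class = 3,
                         confidence = 0.8, beta = NULL, beta_tilde = 2,
                         apply_styles = TRUE, smooth_ms = 30, window_s = 1,
                         use_source_space = FALSE, leadfield = NULL,
                         max_peak_maps = 3000, seed = 1L) {
  recordings <- dataset$recordings
  styles <- dataset$ground_truth$subject_styles
  subjects <- vapply(recordings, `[[`, numeric(1), "subject")
  rec_labels <- vapply(recordings, `[[`, numeric(1), "label")
  if (length(unique(rec_labels)) < 2) stop("need >= 2 classes")

  if (use_source_space) {
    if (is.null(leadfield)) stop("use_source_space needs a leadfield")
    recordings <- lapply(recordings, function(rec) {
      src <- sloreta_solve(rec, leadfield)
      eeg_recording(src$values, rec$sampling_rate, subject = rec$subject,
                    label = rec$label, state_sequence = rec$state_sequence)
    })
  }

  # band filtering and GFP peaks do not depend on the fold: do them once
  band_list <- if (is.null(bands)) list(broadband = NULL) else bands
  filtered <- lapply(band_list, function(b) {
    lapply(recordings, function(rec) {
      if (is.null(b)) rec else bandpass_filter(rec, b[1], b[2])
    })
  })
  peak_maps <- NULL
  if (kind == "microstate") {
    peak_maps <- lapply(filtered, function(recs) {
      lapply(recs, function(rec) {
        g <- compute_gfp(rec)
        t(rec$data[, g$peak_indices, drop = FALSE])
      })
    })
  }

  fold_features <- function(idx, protos) {
    rows <- list(); subj <- list(); labs <- list()
    for (i in idx) {
      fs <- recordings[[i]]$sampling_rate
      wlen <- round(window_s * fs)
      per_band <- lapply(names(band_list), function(bn) {
        rec <- filtered[[bn]][[i]]
        if (kind == "microstate") {
          seg <- smooth_labels(backfit(rec, protos[[bn]]), smooth_ms)
          kk <- protos[[bn]]$k
          n_win <- floor(length(seg$labels) / wlen)
          lapply(seq_len(n_win), function(w) {
            sl <- seg$labels[((w - 1) * wlen + 1):(w * wlen)]
            microstate_features_per_window(sl, kk, fs)
          })
        } else {
          wins <- window_segments(rec, window_s = window_s)
          lapply(wins, function(w) {
            if (kind == "de") differential_entropy(w$data)
            else band_psd(w$data, band_list[[bn]] %||%
                            c(0, fs / 2 - 1e-9), fs)
          })
        }
      })
      names(per_band) <- names(band_list)
      for (w in seq_along(per_band[[1]])) {
        rows[[length(rows) + 1]] <- fuse_bands(lapply(per_band, `[[`, w))
        subj[[length(subj) + 1]] <- recordings[[i]]$subject
        labs[[length(labs) + 1]] <- recordings[[i]]$label
      }
    }
    list(features = do.call(rbind, rows), subjects = unlist(subj),
         labels = unlist(labs))
  }

  folds <- loso_folds(subjects)
  out <- data.frame(target = vapply(folds, `[[`, numeric(1), "target"),
                    accuracy_no_stm = NA_real_, accuracy_stm = NA_real_)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    src_idx <- which(subjects %in% fold$source)
    tgt_idx <- which(subjects == fold$target)

    protos <- NULL
    if (kind == "microstate") {
      protos <- lapply(names(band_list), function(bn) {
        pm <- do.call(rbind, peak_maps[[bn]][src_idx])
        if (nrow(pm) > max_peak_maps) {  # deterministic thinning
          pm <- pm[round(seq(1, nrow(pm), length.out = max_peak_maps)), ]
        }
        cluster_microstates(pm, k = k, n_init = 5, max_iter = 100,
                            seed = seed + fi)
      })
      names(protos) <- names(band_list)
    }
    src <- fold_features(src_idx, protos)
    tgt <- fold_features(tgt_idx, protos)
    if (apply_styles && !is.null(styles)) {
      for (s in unique(src$subjects)) {
        rows <- src$subjects == s
        src$features[rows, ] <-
          apply_subject_style(src$features[rows, , drop = FALSE],
                              styles[[s]])
      }
      tgt$features <- apply_subject_style(tgt$features,
                                          styles[[fold$target]])
    }
    # z-score with source statistics (target labels never touched)
    mu <- colMeans(src$features)
    sdv <- apply(src$features, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    zs <- function(x) sweep(sweep(x, 2, mu), 2, sdv, `/`)
    Xs <- zs(src$features); Xt <- zs(tgt$features)

    clf <- train_svm(Xs, src$labels, seed = seed + fi)
    pred_raw <- stats::predict(clf, Xt)
    out$accuracy_no_stm[fi] <-
      100 * mean(pred_raw == factor(tgt$labels, levels = levels(pred_raw)))

    pm <- learn_prototypes(Xs, src$labels, n_per_class, seed = seed + fi)
    pairs <- pair_targets(Xt, pm, confidence)
    b_use <- if (is.null(beta)) compute_beta(beta_tilde, pairs) else beta
    map <- solve_stm(pairs, b_use)
    pred_stm <- stats::predict(clf, apply_map(map, Xt))
    out$accuracy_stm[fi] <-
      100 * mean(pred_stm == factor(tgt$labels, levels = levels(pred_stm)))
  }
  attr(out, "summary") <- list(
    no_stm = summarize_accuracies(out$accuracy_no_stm),
    stm = summarize_accuracies(out$accuracy_stm))
  attr(out, "chance") <- 100 / length(unique(rec_labels))
  class(out) <- c("result_table", "data.frame")
  out
}

#' @export
print.result_table <- function(x, ...) {
  cat("Leave-one-subject-out cross-subject accuracy (%)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  s <- attr(x, "summary")
  cat(sprintf("mean without STM: %.2f (sd %.2f)\n",
              s$no_stm$mean, s$no_stm$sd))
  cat(sprintf("mean with STM:    %.2f (sd %.2f)\n", s$stm$mean, s$stm$sd))
  cat(sprintf("chance level:     %.2f\n", attr(x, "chance")))
  invisible(x)
}
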