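#' Style transfer mapping (STM)
#'
#' Cross-subject feature distributions differ by an approximately affine
#' "style". STM learns a square matrix A and offset b minimizing the
#' confidence-weighted squared error between transformed target-domain
#' features and their paired source-domain anchors, with a ridge pull of
#' A toward the identity:
#' \deqn{\min_{A,b} \sum_i f_i \|A y_i + b - x_i\|^2 + \beta \|A - I\|_F^2}
#' Anchors come from a nearest-prototype model: per-class k-means
#' centers of the source features. Target samples are transformed toward
#' the source domain so a source-trained classifier applies unchanged.
#'
#' @name style-transfer
NULL

#' Learn per-class source-domain prototypes
#'
#' K-means centers within each class of the source features (k = 1
#' reduces to class means). Classes with fewer samples than requested
#' prototypes get one prototype per sample, with a warning.
#'
#' @param features matrix, samples x M (source domain).
#' @param labels class label per row.
#' @param n_per_class prototypes per class (default 3).
#' @param seed integer seed for the k-means initialization.
#' @return `prototype_model`: list with `prototypes` (total x M matrix),
#'   `classes` (class of each prototype row), `n_per_class`.
#' @export
learn_prototypes <- function(features, labels, n_per_class = 3, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), n_per_class >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  lv <- sort(unique(labels))
  protos <- list(); classes <- list()
  for (cl in lv) {
    X <- features[labels == cl, , drop = FALSE]
    k <- n_per_class
    if (nrow(X) < k) {
      warning("class ", cl, " has ", nrow(X), " samples < ", k,
              " prototypes; reducing")
      k <- nrow(X)
    }
    centers <- if (k == 1) {
      matrix(colMeans(X), 1)
    } else if (nrow(unique(X)) <= k) {
      unique(X)[seq_len(k), , drop = FALSE]
    } else {
      stats::kmeans(X, centers = k, nstart = 5, iter.max = 100)$centers
    }
    protos[[length(protos) + 1]] <- centers
    classes[[length(classes) + 1]] <- rep(cl, nrow(centers))
  }
  structure(list(prototypes = do.call(rbind, protos),
                 classes = unlist(classes), n_per_class = n_per_class),
            class = "prototype_model")
}

#' Pair target samples with their nearest source prototypes
#'
#' Label-blind Euclidean nearest-prototype assignment (target labels are
#' unknown in the cross-subject setting), with a constant confidence per
#' pair (0.8 by default).
#'
#' @param features matrix, samples x M (target domain).
#' @param model a `prototype_model`.
#' @param confidence scalar in \[0, 1\] applied to every pair
#'   (default 0.8), or a function of the distance vector returning
#'   per-pair confidences.
#' @return list of pairs: `y` (target features), `x` (matched
#'   prototypes, same shape), `f` (confidences), `distance`,
#'   `prototype_index`.
#' @export
pair_targets <- function(features, model, confidence = 0.8) {
  features <- as.matrix(features)
  P <- model$prototypes
  if (!nrow(P)) stop("empty prototype model")
  stopifnot(ncol(features) == ncol(P))
  # squared distances via the expansion trick
  d2 <- outer(rowSums(features^2), rowSums(P^2), `+`) -
    2 * features %*% t(P)
  idx <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(features)), idx)], 0))
  f <- if (is.function(confidence)) confidence(dist) else
    rep(confidence, nrow(features))
  stopifnot(all(f >= 0 & f <= 1))
  list(y = features, x = P[idx, , drop = FALSE], f = f,
       distance = dist, prototype_index = idx)
}

#' Regularization strength from the data second moment
#'
#' Heuristic `beta = beta_tilde * tr(sum_i f_i y_i y_i') / M`: the ridge
#' strength scales with the confidence-weighted energy of the target
#' features so the identity pull is commensurate with the data term.
#' `beta_tilde` in \[1, 3\] is the useful range; the division by the
#' feature dimension M is this package's normalization convention.
#'
#' @param beta_tilde nonnegative scalar.
#' @param pairs output of [pair_targets()] (or a list with `y`, `f`).
#' @return scalar beta >= 0.
#' @export
compute_beta <- function(beta_tilde, pairs) {
  stopifnot(beta_tilde >= 0)
  y <- as.matrix(pairs$y)
  beta_tilde * sum(pairs$f * rowSums(y^2)) / ncol(y)
}

#' Closed-form solution of the STM objective
#'
#' Eliminating b via the weighted means (`b = x_bar - A y_bar`) and
#' setting the gradient in A to zero gives
#' `A = (Sxy + beta I) (Syy + beta I)^-1` with Sxy, Syy the
#' confidence-weighted centered cross- and auto-scatter matrices. A
#' singular system falls back to the pseudo-inverse with a warning.
#'
#' @param pairs output of [pair_targets()]: `y` target features, `x`
#'   anchors, `f` confidences.
#' @param beta ridge strength >= 0 (default 0.2, a cross-validated
#'   operating point for z-scored emotion-EEG features; see also
#'   [compute_beta()] for the data-scaled heuristic).
#' @return `style_map`: list with `A` (M x M), `b` (M-vector), `beta`,
#'   `confidence` (the per-pair weights).
#' @export
solve_stm <- function(pairs, beta = 0.2) {
  y <- as.matrix(pairs$y); x <- as.matrix(pairs$x); f <- pairs$f
  stopifnot(nrow(y) >= 1, nrow(y) == nrow(x), length(f) == nrow(y),
            beta >= 0)
  M <- ncol(y)
  fs <- sum(f)
  if (fs <= 0) stop("all confidences are zero")
  ybar <- colSums(y * f) / fs
  xbar <- colSums(x * f) / fs
  yc <- sweep(y, 2, ybar); xc <- sweep(x, 2, xbar)
  Syy <- crossprod(yc * f, yc)       # sum f_i yc yc'
  Sxy <- crossprod(xc * f, yc)       # sum f_i xc yc'
  lhs <- Syy + beta * diag(M)
  rhs <- Sxy + beta * diag(M)
  ok <- tryCatch(rcond(lhs) > 1e-14, error = function(e) FALSE)
  A <- if (ok) {
    t(solve(lhs, t(rhs)))
  } else {
    warning("singular STM system; using pseudo-inverse")
    rhs %*% MASS::ginv(lhs)
  }
  b <- xbar - as.vector(A %*% ybar)
  structure(list(A = A, b = b, beta = beta, confidence = f),
            class = "style_map")
}

#' STM objective value for a candidate (A, b)
#'
#' `sum_i f_i ||A y_i + b - x_i||^2 + beta ||A - I||_F^2`; used in tests
#' to verify optimality of the closed form.
#'
#' @inheritParams solve_stm
#' @param A M x M matrix.
#' @param b M-vector.
#' @return scalar objective value.
#' @export
stm_objective <- function(pairs, A, b, beta) {
  y <- as.matrix(pairs$y); x <- as.matrix(pairs$x)
  resid <- t(A %*% t(y) + b) - x
  sum(pairs$f * rowSums(resid^2)) + beta * sum((A - diag(ncol(y)))^2)
}

#' Apply a style map to feature rows
#'
#' @param map a `style_map` (or list with `A`, `b`).
#' @param features matrix, samples x M.
#' @return transformed features `A x + b`, row-wise.
#' @export
apply_map <- function(map, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(map$A)) {
    stop("feature dimension ", ncol(features),
         " does not match map dimension ", ncol(map$A))
  }
  t(map$A %*% t(features) + map$b)
}
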