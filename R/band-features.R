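#' Frequency-band definitions
#'
#' The canonical five EEG bands used throughout: delta 1-4, theta 4-8,
#' alpha 8-13, beta 13-30, gamma 30-47 Hz (the gamma upper edge matches
#' the 47 Hz anti-alias low-pass of the preprocessing chain). All edges
#' are configurable.
#'
#' @param delta,theta,alpha,beta,gamma length-2 numeric `c(low, high)`
#'   in Hz.
#' @return named list of band definitions in delta-to-gamma order.
#' @export
eeg_bands <- function(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                      beta = c(13, 30), gamma = c(30, 47)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha,
                beta = beta, gamma = gamma)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] < 0 || b[1] >= b[2]) {
      stop("invalid band definition for ", nm)
    }
  }
  bands
}

check_band <- function(low, high, sampling_rate) {
  nyq <- sampling_rate / 2
  if (low < 0 || low >= high || high > nyq) {
    stop("band [", low, ", ", high, "] Hz invalid for Nyquist ", nyq, " Hz")
  }
}

# Forward extrapolation of every row of `x` by `p` samples using
# channel-wise Yule-Walker AR models fitted on the trailing `fitlen`
# samples. Autocovariances come from one multi-channel FFT; the
# Levinson-Durbin recursion and the prediction loop are vectorized
# across channels. The biased autocovariance estimate makes the fitted
# models stable by construction; degenerate channels fall back to a
# constant continuation.
ar_extrapolate_rows <- function(x, p, ord = 12L, fitlen = 750L) {
  nc <- nrow(x)
  n <- ncol(x)
  seg <- x[, max(1L, n - fitlen + 1L):n, drop = FALSE]
  ns <- ncol(seg)
  m <- min(ord, ns %/% 3)
  mu <- rowMeans(seg)
  if (m < 1) return(matrix(rep(x[, n], p), nc, p))
  segc <- seg - mu
  # biased autocovariances r_0..r_m for all channels via FFT
  nfft <- stats::nextn(ns + m, 2)
  padded <- cbind(segc, matrix(0, nc, nfft - ns))
  spec <- Mod(stats::mvfft(t(padded)))^2
  acov <- Re(stats::mvfft(spec, inverse = TRUE)) / (nfft * ns)
  r <- t(acov[seq_len(m + 1L), , drop = FALSE])  # nc x (m+1), lag 0..m
  r0 <- r[, 1]
  ok <- is.finite(r0) & r0 > 0
  a <- matrix(0, nc, m)
  e <- pmax(r0, .Machine$double.eps)
  for (k in seq_len(m)) {
    acc <- r[, k + 1L]
    if (k > 1) {
      acc <- acc - rowSums(a[, 1:(k - 1), drop = FALSE] *
                             r[, k:2, drop = FALSE])
    }
    kref <- ifelse(ok, acc / e, 0)
    kref[!is.finite(kref)] <- 0
    kref <- pmin(pmax(kref, -0.9999), 0.9999)
    if (k > 1) {
      prev <- a[, 1:(k - 1), drop = FALSE]
      a[, 1:(k - 1)] <- prev - kref * prev[, (k - 1):1, drop = FALSE]
    }
    a[, k] <- kref
    e <- pmax(e * (1 - kref^2), .Machine$double.eps)
  }
  # predict p steps ahead from the last m samples of each channel
  buf <- matrix(0, nc, m + p)
  buf[, seq_len(m)] <- x[, (n - m + 1L):n, drop = FALSE] - mu
  for (i in seq_len(p)) {
    buf[, m + i] <- rowSums(a * buf[, (m + i - 1L):i, drop = FALSE])
  }
  out <- buf[, (m + 1L):(m + p), drop = FALSE] + mu
  bad <- !ok | !is.finite(rowSums(out))
  if (any(bad)) out[bad, ] <- matrix(rep(x[bad, n], p), sum(bad), p)
  out
}

# Zero-phase application of an IIR design to every channel at once:
# multiply the spectrum of the padded signal by the squared magnitude
# response |H|^2 (the forward-backward response of the same filter,
# phase cancelled exactly). AR extrapolation pads at both ends continue
# each channel's oscillations coherently, suppressing the edge
# transients that step or reflection padding would ring into the data,
# and push the circular-wrap discontinuity away from it; one
# multi-channel FFT replaces per-channel time-domain recursions.
apply_filter_rows <- function(x, filt, pad = 250L) {
  n <- ncol(x)
  p <- min(pad, n - 1L)
  rpad <- ar_extrapolate_rows(x, p)
  lpad <- ar_extrapolate_rows(x[, n:1, drop = FALSE], p)[, p:1, drop = FALSE]
  xe <- cbind(lpad, x, rpad)
  N <- ncol(xe)
  w <- 2 * pi * (seq_len(N) - 1) / N
  polyval_ejw <- function(coef) {
    exp(-1i * outer(w, seq_along(coef) - 1)) %*% coef
  }
  mag2 <- as.vector(Mod(polyval_ejw(filt$b) / polyval_ejw(filt$a))^2)
  spec <- stats::mvfft(t(xe)) * mag2
  out <- Re(t(stats::mvfft(spec, inverse = TRUE))) / N
  out[, (p + 1):(p + n), drop = FALSE]
}

#' Zero-phase notch (band-stop) filter
#'
#' Forward-backward 4th-order Butterworth band-stop; the default 49-51 Hz
#' band removes 50 Hz mains interference with > 20 dB attenuation on a
#' pure 50 Hz tone while leaving in-band rhythms untouched.
#'
#' @param recording [eeg_recording()] or channels x samples matrix.
#' @param low,high stop-band edges in Hz.
#' @param sampling_rate Hz (taken from the recording if given).
#' @param order filter order (default 4).
#' @return same type as the input, filtered.
#' @export
notch_filter <- function(recording, low = 49, high = 51,
                         sampling_rate = NULL, order = 4) {
  x <- recording
  if (inherits(recording, "eeg_recording")) {
    sampling_rate <- recording$sampling_rate
    x <- recording$data
  }
  check_band(low, high, sampling_rate)
  filt <- signal::butter(order, c(low, high) / (sampling_rate / 2),
                         type = "stop")
  out <- apply_filter_rows(as.matrix(x), filt)
  if (inherits(recording, "eeg_recording")) {
    recording$data <- out
    recording
  } else out
}

#' Zero-phase band-pass filter
#'
#' Implemented as a cascade of a 2nd-order Butterworth high-pass and an
#' `order`-order low-pass, each applied forward-backward. The cascade is
#' numerically robust for very low high-pass edges (e.g. the 0.05 Hz
#' edge of the broadband preprocessing filter), where a single
#' narrow-relative-bandwidth band-pass design is fragile. A `low` of 0
#' skips the high-pass.
#'
#' @inheritParams notch_filter
#' @param low,high pass-band edges in Hz.
#' @export
bandpass_filter <- function(recording, low, high, sampling_rate = NULL,
                            order = 4) {
  x <- recording
  if (inherits(recording, "eeg_recording")) {
    sampling_rate <- recording$sampling_rate
    x <- recording$data
  }
  check_band(low, high, sampling_rate)
  x <- as.matrix(x)
  nyq <- sampling_rate / 2
  if (low > 0) {
    hp <- signal::butter(2, low / nyq, type = "high")
    x <- apply_filter_rows(x, hp)
  }
  if (high < nyq) {
    lp <- signal::butter(order, high / nyq, type = "low")
    x <- apply_filter_rows(x, lp)
  }
  if (inherits(recording, "eeg_recording")) {
    recording$data <- x
    recording
  } else x
}

#' Split a recording into non-overlapping (or overlapping) windows
#'
#' @param recording [eeg_recording()] or channels x samples matrix.
#' @param window_s window length in seconds (default 1).
#' @param overlap fraction of overlap between consecutive windows in
#'   \[0, 1) (default 0: non-overlapping).
#' @param sampling_rate Hz (from the recording if given).
#' @return list of windows; each is a list with `data` (channels x
#'   window samples), `start` (sample index), and, when the recording
#'   carries a ground-truth `state_sequence`, the matching slice. A
#'   trailing partial window is dropped; a window longer than the
#'   recording yields an empty list.
#' @export
window_segments <- function(recording, window_s = 1, overlap = 0,
                            sampling_rate = NULL) {
  x <- recording
  states <- NULL
  if (inherits(recording, "eeg_recording")) {
    sampling_rate <- recording$sampling_rate
    states <- recording$state_sequence
    x <- recording$data
  }
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  x <- as.matrix(x)
  wlen <- round(window_s * sampling_rate)
  stride <- max(1L, round(wlen * (1 - overlap)))
  n <- ncol(x)
  if (wlen > n) return(list())
  starts <- seq(1L, n - wlen + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    list(data = x[, idx, drop = FALSE], start = s,
         state_sequence = if (!is.null(states)) states[idx])
  })
}

#' Differential entropy of each channel in a window
#'
#' Under a Gaussian model the differential entropy of a channel is
#' `0.5 * ln(2 * pi * e * sigma^2)` (nats), with `sigma^2` the sample
#' variance of the window. A configurable variance floor guards the
#' degenerate zero-variance case.
#'
#' @param window channels x samples matrix (>= 2 samples), or a window
#'   from [window_segments()].
#' @param var_floor minimum variance substituted for (near-)constant
#'   channels (default 1e-12).
#' @return numeric vector of per-channel entropies in nats.
#' @export
differential_entropy <- function(window, var_floor = 1e-12) {
  if (is.list(window) && !is.null(window$data)) window <- window$data
  window <- as.matrix(window)
  if (ncol(window) < 2) stop("differential entropy needs >= 2 samples")
  v <- apply(window, 1, stats::var)
  v <- pmax(v, var_floor)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Band power of each channel in a window
#'
#' One-sided periodogram power summed over frequency bins inside
#' `[low, high]` Hz, after removing each channel's mean. Normalized so a
#' pure in-band sinusoid of amplitude `a` has band power `a^2 / 2` and
#' the powers over a partition of the spectrum sum to the signal
#' variance (Parseval).
#'
#' @inheritParams differential_entropy
#' @param band `c(low, high)` in Hz (one entry of [eeg_bands()]).
#' @param sampling_rate Hz.
#' @return numeric vector of per-channel band powers.
#' @export
band_psd <- function(window, band, sampling_rate) {
  if (is.list(window) && !is.null(window$data)) window <- window$data
  window <- as.matrix(window)
  check_band(band[1], band[2], sampling_rate)
  n <- ncol(window)
  freqs <- (0:(n - 1)) * sampling_rate / n
  half <- freqs <= sampling_rate / 2
  sel <- half & freqs >= band[1] & freqs <= band[2]
  apply(window, 1, function(ch) {
    ch <- ch - mean(ch)
    p <- (Mod(stats::fft(ch)) / n)^2
    # one-sided: double everything except DC and (even n) Nyquist
    scale <- ifelse(freqs > 0 & freqs < sampling_rate / 2, 2, 1)
    sum((p * scale)[sel])
  })
}

#' Microstate feature vector for one window
#'
#' Concatenates the four microstate statistics of a window's label slice
#' in a fixed, documented order: coverage (K), mean duration in ms (K),
#' occurrence per second (K), then the transition matrix flattened row
#' by row (K^2) — `K * (K + 3)` values in total, i.e. 40 for K = 5.
#'
#' @param labels integer label slice for the window (1..K).
#' @param k number of microstate classes.
#' @param sampling_rate Hz.
#' @return numeric vector of length `k * (k + 3)`, with names.
#' @export
microstate_features_per_window <- function(labels, k, sampling_rate) {
  st <- microstate_statistics(labels, k = k, sampling_rate = sampling_rate)
  v <- c(st$coverage, st$duration_ms, st$occurrence_per_s,
         as.vector(t(st$transition)))
  names(v) <- c(paste0("cov", seq_len(k)), paste0("dur", seq_len(k)),
                paste0("occ", seq_len(k)),
                paste0("tr", rep(seq_len(k), each = k), "_",
                       rep(seq_len(k), k)))
  v
}

#' Fuse per-band feature vectors into one sample
#'
#' Concatenates the per-band vectors in canonical delta-to-gamma order
#' (input order does not matter when the list is named). Five 40-length
#' microstate vectors fuse to the standard 200-length sample.
#'
#' @param band_vectors named list (names from [eeg_bands()]) of numeric
#'   vectors of identical length and kind.
#' @return single concatenated numeric vector, names prefixed by band.
#' @export
fuse_bands <- function(band_vectors) {
  stopifnot(length(band_vectors) >= 1)
  len <- unique(vapply(band_vectors, length, integer(1)))
  if (length(len) != 1) stop("band vectors have mixed lengths: ",
                             paste(len, collapse = ", "))
  canonical <- names(eeg_bands())
  nms <- names(band_vectors)
  if (!is.null(nms) && all(nms %in% canonical)) {
    band_vectors <- band_vectors[intersect(canonical, nms)]
  }
  out <- unlist(lapply(names(band_vectors), function(nm) {
    v <- band_vectors[[nm]]
    names(v) <- paste0(nm, ".", if (is.null(names(v)))
      seq_along(v) else names(v))
    v
  }))
  out
}
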