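#' Sine-cosine reference templates
#'
#' Builds the reference matrix for one stimulation frequency: column 2h-1 is
#' sin(2*pi*h*f*t_n) and column 2h is cos(2*pi*h*f*t_n) for harmonics
#' h = 1..n_harmonics, with t_n = n/fs, n = 0..N-1. The time origin is per
#' window; canonical correlation against sin/cos pairs is phase-invariant, so
#' the origin has no measurable effect.
#'
#' @param f_hz stimulation frequency (Hz).
#' @param fs_hz sampling rate (Hz).
#' @param n_samples window length N in samples.
#' @param n_harmonics number of harmonics (default 1: the plain sine-cosine
#'   pair).
#' @return an N x (2 * n_harmonics) numeric matrix.
#' @export
reference_matrix <- function(f_hz, fs_hz, n_samples, n_harmonics = 1) {
  stopifnot(n_harmonics >= 1, n_samples >= 2 * (2 * n_harmonics))
  if (f_hz * n_harmonics >= fs_hz / 2) {
    stop("harmonic ", n_harmonics, " of ", f_hz,
         " Hz is at or above Nyquist (", fs_hz / 2, " Hz)")
  }
  t_n <- (seq_len(n_samples) - 1) / fs_hz
  Y <- matrix(0, n_samples, 2 * n_harmonics)
  for (h in seq_len(n_harmonics)) {
    w <- 2 * pi * h * f_hz * t_n
    Y[, 2 * h - 1] <- sin(w)
    Y[, 2 * h] <- cos(w)
  }
  Y
}

#' Per-frequency reference set
#'
#' Templates for all stimulation frequencies at a fixed window length, with
#' precomputed orthonormal bases of the column-centered templates (used by
#' the vectorized stream decoder).
#'
#' @param frequencies_hz stimulation frequencies (default the speller's
#'   five).
#' @param fs_hz sampling rate (Hz).
#' @param n_samples window length in samples.
#' @param n_harmonics harmonics per template.
#' @return a list of class `reference_set`.
#' @export
reference_set <- function(frequencies_hz = stimulus_frequencies(),
                          fs_hz = 200, n_samples = 300, n_harmonics = 1) {
  templates <- lapply(frequencies_hz, reference_matrix, fs_hz = fs_hz,
                      n_samples = n_samples, n_harmonics = n_harmonics)
  bases <- lapply(templates, function(Y) {
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    qr.Q(qr(Yc))
  })
  structure(list(frequencies_hz = frequencies_hz, fs_hz = fs_hz,
                 n_samples = n_samples, n_harmonics = n_harmonics,
                 templates = templates, bases = bases),
            class = "reference_set")
}

#' Leading canonical correlation between two signal blocks
#'
#' Finds projection weights `w_x`, `w_y` maximizing the correlation between
#' `X w_x` and `Y w_y`; returns the leading canonical correlation (absolute
#' value). Columns are centered internally. Covariances are regularized by
#' adding `1e-12 * trace` to the diagonal, so rank-deficient inputs do not
#' crash.
#'
#' @param X numeric matrix N x C (e.g. an EEG window).
#' @param Y numeric matrix N x M (e.g. a reference template).
#' @return a list of class `canonical_result` with elements `rho` (in
#'   \[0, 1\]), `w_x` and `w_y`.
#' @export
canonical_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n > ncol(X) + ncol(Y))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  ridge <- function(S) S + diag(1e-12 * max(sum(diag(S)), .Machine$double.xmin),
                                nrow(S))
  Sxx <- ridge(Sxx); Syy <- ridge(Syy)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  e <- eigen(M)
  vals <- Re(e$values)
  i <- which.max(vals)
  rho <- sqrt(max(0, min(1, vals[i])))
  w_x <- Re(e$vectors[, i])
  w_y <- drop(solve(Syy, crossprod(Sxy, w_x)))
  ny <- sqrt(sum(w_y^2))
  if (ny > 0) w_y <- w_y / ny
  structure(list(rho = rho, w_x = w_x, w_y = w_y),
            class = "canonical_result")
}

#' Correlation profile of one analysis window
#'
#' Computes the canonical correlation between the window and every
#' frequency's template. In the default `per_channel_max` mode the CCA is
#' run per channel and the maximum across channels is retained as the
#' representative value for each frequency (the decoder's channel-wise
#' maximum strategy); `joint` mode runs a single multichannel CCA per
#' frequency.
#'
#' @param window a [signal_window()] (already filtered).
#' @param refs a [reference_set()] built for the window length.
#' @param mode `"per_channel_max"` (default) or `"joint"`.
#' @return a list of class `correlation_profile` with `t_s` (timestamp of
#'   the window end, i.e. the decoding update time) and `rho_by_freq`
#'   (named numeric, one value in \[0, 1\] per frequency).
#' @export
correlation_profile <- function(window, refs,
                                mode = c("per_channel_max", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "signal_window"), inherits(refs, "reference_set"))
  X <- window$samples
  if (nrow(X) != refs$n_samples) {
    stop("window has ", nrow(X), " samples but references were built for ",
         refs$n_samples)
  }
  rho <- vapply(seq_along(refs$frequencies_hz), function(k) {
    Y <- refs$templates[[k]]
    if (mode == "joint" || ncol(X) == 1L) {
      canonical_correlation(X, Y)$rho
    } else {
      max(vapply(seq_len(ncol(X)), function(ch) {
        canonical_correlation(X[, ch, drop = FALSE], Y)$rho
      }, numeric(1)))
    }
  }, numeric(1))
  names(rho) <- as.character(refs$frequencies_hz)
  structure(list(t_s = window$t_start_s + refs$n_samples / refs$fs_hz,
                 rho_by_freq = rho),
            class = "correlation_profile")
}

#' Pick the stimulation frequency with maximal correlation
#'
#' Ties are broken toward the lowest frequency index.
#'
#' @param profile a [correlation_profile()] or named numeric vector of
#'   per-frequency correlations.
#' @return the selected frequency (Hz).
#' @export
classify_frequency <- function(profile) {
  rho <- if (inherits(profile, "correlation_profile")) profile$rho_by_freq
         else profile
  stopifnot(length(rho) >= 1)
  as.numeric(names(rho)[which.max(rho)])
}

#' Correlation profiles for every sliding window of a stream (vectorized)
#'
#' Equivalent to running [correlation_profile()] in `per_channel_max` mode on
#' every window from [sliding_windows()], but computed in bulk. For a single
#' channel x against a template Y the leading canonical correlation equals
#' the norm of the projection of the centered x onto the orthonormalized
#' centered template columns, divided by the norm of the centered x; this is
#' evaluated for all windows with blocked matrix products.
#'
#' @param samples filtered stream matrix (N x C) or `session_stream`.
#' @param refs a [reference_set()].
#' @param hop_s hop between windows (s).
#' @param fs_hz sampling rate (required for bare matrices).
#' @param t0_s time of the first stream sample.
#' @param block number of windows per computation block.
#' @return a list of class `profile_stream`: `t_s` (update times = window
#'   ends) and `rho` (n_windows x n_frequencies matrix of channel-max
#'   correlations).
#' @export
stream_correlation_profiles <- function(samples, refs, hop_s = 0.05,
                                        fs_hz = NULL, t0_s = 0,
                                        block = 4096L) {
  if (inherits(samples, "session_stream")) {
    fs_hz <- samples$fs_hz; t0_s <- samples$t_s[1]; samples <- samples$samples
  }
  samples <- as.matrix(samples)
  if (is.null(fs_hz)) stop("fs_hz required for bare matrices")
  stopifnot(abs(fs_hz - refs$fs_hz) < 1e-9)
  N <- refs$n_samples
  idx <- window_index(nrow(samples), fs_hz, N / fs_hz, hop_s)
  n_win <- length(idx$starts)
  nf <- length(refs$frequencies_hz)
  rho <- matrix(0, n_win, nf,
                dimnames = list(NULL, as.character(refs$frequencies_hz)))
  if (n_win == 0) {
    return(structure(list(t_s = numeric(0), rho = rho,
                          frequencies_hz = refs$frequencies_hz),
                     class = "profile_stream"))
  }
  Qall <- do.call(cbind, refs$bases)          # N x sum(2H)
  qcols <- vapply(refs$bases, ncol, integer(1))
  qoff <- cumsum(c(0L, qcols))
  qsum1 <- colSums(Qall)                      # t(Q) %*% 1
  off <- seq_len(N) - 1L
  for (lo in seq(1L, n_win, by = block)) {
    hi <- min(lo + block - 1L, n_win)
    starts <- idx$starts[lo:hi]
    gather <- outer(off, starts, "+")         # N x nb index matrix
    best <- matrix(0, hi - lo + 1L, nf)
    for (ch in seq_len(ncol(samples))) {
      Xw <- matrix(samples[gather, ch], nrow = N)
      mu <- colMeans(Xw)
      ss <- colSums(Xw^2) - N * mu^2          # ||x - mean||^2 per window
      P <- crossprod(Qall, Xw) - outer(qsum1, mu)
      for (k in seq_len(nf)) {
        cols <- (qoff[k] + 1L):qoff[k + 1L]
        num <- colSums(P[cols, , drop = FALSE]^2)
        r <- sqrt(pmin(1, num / pmax(ss, .Machine$double.xmin)))
        best[, k] <- pmax(best[, k], r)
      }
    }
    rho[lo:hi, ] <- best
  }
  structure(list(t_s = t0_s + (idx$starts - 1L + N) / fs_hz, rho = rho,
                 frequencies_hz = refs$frequencies_hz),
            class = "profile_stream")
}
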