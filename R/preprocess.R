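#' Online filter chain
#'
#' The fixed preprocessing chain applied to each channel before decoding:
#' linear detrend, order-2 Butterworth band-pass 5-45 Hz, then band-stop
#' filters at 48-52 Hz and 58-62 Hz, applied in that order. The online path
#' is causal (forward-only IIR); a zero-phase variant (`filtfilt`) is
#' available for offline spectral analysis.
#'
#' @param fs_hz sampling rate the chain is designed for.
#' @param band_pass length-2 numeric, band-pass edges in Hz.
#' @param band_stops list of length-2 numeric vectors, stop-band edges in Hz.
#' @param order Butterworth design order for every section.
#' @param causal logical; `TRUE` (default) for the forward-only online path,
#'   `FALSE` for zero-phase offline filtering.
#' @return a list of class `filter_chain` holding the designed second-order
#'   sections' transfer-function coefficients.
#' @export
filter_chain <- function(fs_hz = 200, band_pass = c(5, 45),
                         band_stops = list(c(48, 52), c(58, 62)),
                         order = 2, causal = TRUE) {
  nyq <- fs_hz / 2
  edges <- c(band_pass, unlist(band_stops))
  if (any(edges >= nyq)) {
    stop("filter band edge at or above Nyquist (", nyq, " Hz)")
  }
  stopifnot(band_pass[1] < band_pass[2],
            all(vapply(band_stops, function(b) b[1] < b[2], logical(1))))
  sections <- c(
    list(signal::butter(order, band_pass / nyq, type = "pass")),
    lapply(band_stops, function(b) signal::butter(order, b / nyq, type = "stop"))
  )
  structure(list(fs_hz = fs_hz, band_pass = band_pass,
                 band_stops = band_stops, order = order, causal = causal,
                 sections = sections),
            class = "filter_chain")
}

#' Remove per-channel linear trend
#'
#' Subtracts the per-channel least-squares line, removing DC offset and slow
#' linear drift within the window.
#'
#' @param window a [signal_window()] or numeric matrix/vector.
#' @return same type as the input, detrended per channel.
#' @export
detrend_window <- function(window) {
  x <- if (inherits(window, "signal_window")) window$samples else
    as.matrix(window)
  n <- nrow(x)
  if (n < 2) stop("detrend requires at least 2 samples")
  tt <- seq_len(n)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  mu <- colMeans(x)
  slope <- as.numeric(crossprod(tc, x)) / denom
  out <- x - outer(rep(1, n), mu) - outer(tc, slope)
  if (inherits(window, "signal_window")) {
    window$samples <- out
    window
  } else if (is.matrix(window)) out else drop(out)
}

# Direct-form II transposed single-section IIR with explicit state, so that
# chunked causal filtering is sample-identical to whole-stream filtering.
iir_apply <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (is.null(zi)) zi <- rep(0, nfilt - 1)
  n <- length(x)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(nfilt - 2)) {
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
    z[nfilt - 1] <- b[nfilt] * x[i] - a[nfilt] * y[i]
  }
  list(y = y, zi = z)
}

# Fast whole-stream causal IIR (zero initial state) via stats::filter:
# FIR numerator as a one-sided convolution, then the recursive denominator.
iir_apply_fast <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  } else v
}

#' Apply the filter chain to a stream or window
#'
#' In causal mode the IIR filter state can be carried across successive
#' chunks (`state` argument), so chunked and whole-stream filtering agree
#' sample for sample. In zero-phase mode (`causal = FALSE` in the chain)
#' `signal::filtfilt` is used and no state is kept.
#'
#' @param x a [signal_window()], numeric matrix (samples x channels) or
#'   vector.
#' @param chain a [filter_chain()].
#' @param state optional state object returned by a previous call, to
#'   continue filtering the next chunk of the same stream.
#' @param return_state if `TRUE`, return `list(samples, state)` instead of
#'   the filtered samples only.
#' @return filtered samples (same shape as input), or a list with updated
#'   state when `return_state = TRUE`.
#' @export
apply_filter_chain <- function(x, chain, state = NULL, return_state = FALSE) {
  win <- NULL
  if (inherits(x, "signal_window")) { win <- x; x <- x$samples }
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  nsec <- length(chain$sections)
  ncH <- ncol(x)
  if (!chain$causal) {
    y <- x
    for (s in seq_len(nsec)) {
      f <- chain$sections[[s]]
      for (ch in seq_len(ncH)) y[, ch] <- signal::filtfilt(f, y[, ch])
    }
    st <- NULL
  } else if (is.null(state) && !return_state) {
    y <- x
    for (s in seq_len(nsec)) {
      f <- chain$sections[[s]]
      for (ch in seq_len(ncH)) y[, ch] <- iir_apply_fast(f$b, f$a, y[, ch])
    }
    st <- NULL
  } else {
    if (is.null(state)) {
      state <- lapply(seq_len(nsec), function(s) vector("list", ncH))
    }
    y <- x
    for (s in seq_len(nsec)) {
      f <- chain$sections[[s]]
      for (ch in seq_len(ncH)) {
        r <- iir_apply(f$b, f$a, y[, ch], state[[s]][[ch]])
        y[, ch] <- r$y
        state[[s]][[ch]] <- r$zi
      }
    }
    st <- state
  }
  out <- if (!is.null(win)) { win$samples <- y; win } else
    if (vec) drop(y) else y
  if (return_state) list(samples = out, state = st) else out
}

#' Cut a continuous stream into sliding analysis windows
#'
#' Windows of `window_s` seconds starting at t = 0, `hop_s`, `2*hop_s`, ...
#' (defaults: 1.5 s window, 50 ms hop, i.e. 300 samples / 10-sample hop at
#' 200 Hz). Window and hop must map to whole sample counts.
#'
#' @param stream a `session_stream`, [signal_window()] or numeric matrix.
#' @param window_s window length (s).
#' @param hop_s hop between window starts (s).
#' @param fs_hz sampling rate; taken from the stream object when available.
#' @return a list of [signal_window()]s (possibly empty).
#' @export
sliding_windows <- function(stream, window_s = 1.5, hop_s = 0.05,
                            fs_hz = NULL) {
  if (inherits(stream, "session_stream")) {
    x <- stream$samples; fs <- stream$fs_hz; t0 <- stream$t_s[1]
  } else if (inherits(stream, "signal_window")) {
    x <- stream$samples; fs <- stream$fs_hz; t0 <- stream$t_start_s
  } else {
    x <- as.matrix(stream); fs <- fs_hz; t0 <- 0
  }
  if (is.null(fs)) stop("fs_hz required for bare matrices")
  idx <- window_index(nrow(x), fs, window_s, hop_s)
  lapply(idx$starts, function(s0) {
    signal_window(x[s0 + seq_len(idx$n_win) - 1L, , drop = FALSE], fs,
                  t_start_s = t0 + (s0 - 1L) / fs)
  })
}

# shared window bookkeeping: start indices (1-based) and window sample count
window_index <- function(n_samples, fs, window_s, hop_s) {
  n_win <- window_s * fs
  n_hop <- hop_s * fs
  if (abs(n_win - round(n_win)) > 1e-9 || abs(n_hop - round(n_hop)) > 1e-9) {
    stop("window_s and hop_s must map to integer sample counts at fs = ",
         fs, " Hz")
  }
  n_win <- as.integer(round(n_win)); n_hop <- as.integer(round(n_hop))
  if (n_samples < n_win) {
    return(list(starts = integer(0), n_win = n_win, n_hop = n_hop))
  }
  k <- (n_samples - n_win) %/% n_hop
  list(starts = 1L + n_hop * (0:k), n_win = n_win, n_hop = n_hop)
}
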