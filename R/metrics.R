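#' Confusion matrix over the command set
#'
#' Rows are ground truth, columns predictions. Labels outside `labels` are
#' rejected.
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @param labels the label set (default the five commands; add `"NONE"`
#'   explicitly when scoring non-emissions).
#' @return a `confusion_matrix`: an integer matrix with class attribute.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             labels = speller_commands()) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), labels)
  if (length(bad)) stop("labels outside the label set: ",
                        paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = labels)
  pf <- factor(predicted_labels, levels = labels)
  cm <- table(true = tf, predicted = pf)
  structure(unclass(as.matrix(cm)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Write a confusion matrix as CSV with label header row/column
#'
#' @param cm a `confusion_matrix`.
#' @param path output file.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy is trace/total x 100. Precision and recall are computed per
#' class by one-vs-rest reduction and macro-averaged; F1 is the harmonic
#' mean of per-class precision and recall, macro-averaged. A class with no
#' predicted positives gets precision 0 (with a warning); a class absent
#' from the truth gets recall 0.
#'
#' @param cm a `confusion_matrix` (or plain square count matrix).
#' @return a list of class `classification_metrics` with `accuracy`,
#'   `precision`, `recall`, `f1` (all in percent), the `per_class` table
#'   and `averaging = "macro"`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- numeric(k); rec <- numeric(k)
  for (i in seq_len(k)) {
    if (tp[i] + fp[i] == 0) {
      warning("class '", rownames(cm)[i],
              "' has no predicted positives; precision set to 0")
      prec[i] <- 0
    } else prec[i] <- tp[i] / (tp[i] + fp[i])
    rec[i] <- if (tp[i] + fn[i] == 0) 0 else tp[i] / (tp[i] + fn[i])
  }
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = rownames(cm), precision = 100 * prec,
                          recall = 100 * rec, f1 = 100 * f1)
  structure(list(accuracy = 100 * sum(tp) / total,
                 precision = 100 * mean(prec),
                 recall = 100 * mean(rec),
                 f1 = 100 * mean(f1),
                 per_class = per_class,
                 averaging = "macro"),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%% | precision %.2f%% | recall %.2f%% | F1 %.2f%% (%s)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$averaging))
  invisible(x)
}

#' Information transfer rate (bits per minute)
#'
#' The standard discrete-selection ITR:
#' `ITR = [log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1))] * 60 / T`,
#' with `N` the number of available commands, `P` the classification
#' accuracy and `T` the mean seconds per selection. The limits `P -> 0` and
#' `P -> 1` are handled analytically (`0 * log 0 := 0`). For the speller's
#' decision rule the default selection time is the 1.5 s collection window
#' plus the 1.0 s ignore interval, `T = 2.5 s`.
#'
#' @param p accuracy in `[0, 1]`.
#' @param n_commands number of available commands (default 5).
#' @param t_s mean time per selection in seconds (default 2.5).
#' @return ITR in bits per minute.
#' @export
itr_bits_per_min <- function(p, n_commands = 5, t_s = 2.5) {
  stopifnot(n_commands >= 2, p >= 0, p <= 1, t_s > 0)
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_commands) + xlogx(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_commands - 1)), 0)
  max(0, bits) * 60 / t_s
}

#' One-sided amplitude spectrum
#'
#' Magnitude of the DFT, amplitude-normalized: bins are scaled by 2/N except
#' DC and (for even N) Nyquist, so a unit sinusoid at a bin frequency has
#' amplitude 1.
#'
#' @param x a [signal_window()], numeric vector or matrix (samples x
#'   channels).
#' @param fs_hz sampling rate; taken from the window when available.
#' @return a list of class `spectrum_report` with `freqs_hz` and `amplitude`
#'   (bins x channels).
#' @export
amplitude_spectrum <- function(x, fs_hz = NULL) {
  if (inherits(x, "signal_window")) { fs_hz <- x$fs_hz; x <- x$samples }
  x <- as.matrix(x)
  if (is.null(fs_hz)) stop("fs_hz required")
  n <- nrow(x)
  stopifnot(n >= 64)
  nk <- n %/% 2 + 1
  amp <- matrix(0, nk, ncol(x))
  for (ch in seq_len(ncol(x))) {
    X <- stats::fft(x[, ch])[seq_len(nk)]
    a <- Mod(X) / n
    scale2 <- rep(2, nk); scale2[1] <- 1
    if (n %% 2 == 0) scale2[nk] <- 1
    amp[, ch] <- a * scale2
  }
  structure(list(freqs_hz = (seq_len(nk) - 1) * fs_hz / n,
                 amplitude = amp, fs_hz = fs_hz, n = n),
            class = "spectrum_report")
}

#' Spectral SNR at a stimulus frequency
#'
#' 20 log10 of the amplitude at the bin nearest `f_hz` over the mean
#' amplitude of `k_neighbors` bins on each side, excluding the +/-1 bins
#' around `f_hz` and around any listed stimulus harmonics. A zero noise
#' floor is capped at +100 dB.
#'
#' @param spectrum a `spectrum_report` (single channel, or `channel`
#'   selects one).
#' @param f_hz frequency of interest (Hz).
#' @param k_neighbors neighbor bins per side used as the noise floor.
#' @param exclude_hz additional frequencies whose +/-1 bins are masked
#'   (e.g. harmonics).
#' @param channel channel index.
#' @return SNR in dB.
#' @export
snr_at <- function(spectrum, f_hz, k_neighbors = 10, exclude_hz = numeric(0),
                   channel = 1) {
  stopifnot(inherits(spectrum, "spectrum_report"))
  freqs <- spectrum$freqs_hz
  amp <- spectrum$amplitude[, channel]
  if (f_hz < min(freqs) || f_hz > max(freqs)) {
    stop("frequency outside spectrum range")
  }
  i0 <- which.min(abs(freqs - f_hz))
  masked <- unique(unlist(lapply(c(f_hz, exclude_hz), function(f) {
    j <- which.min(abs(freqs - f)); (j - 1):(j + 1)
  })))
  usable <- setdiff(seq_along(freqs), masked)
  lower <- rev(usable[usable < i0]); upper <- usable[usable > i0]
  if (length(lower) < k_neighbors && length(upper) < k_neighbors) {
    stop("insufficient neighbor bins for the noise floor")
  }
  nb <- c(utils::head(lower, k_neighbors), utils::head(upper, k_neighbors))
  floor_amp <- mean(amp[nb])
  if (floor_amp <= 0) return(100)
  min(100, 20 * log10(amp[i0] / floor_amp))
}

# Hann-windowed short-time power spectrogram of one channel
stft_power <- function(x, fs, seg_s = 0.5, overlap = 0.9) {
  nseg <- round(seg_s * fs)
  hop <- max(1L, round(nseg * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  nk <- nseg %/% 2 + 1
  P <- matrix(0, nk, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + seq_len(nseg) - 1L] * w
    P[, j] <- (Mod(stats::fft(seg))[seq_len(nk)])^2
  }
  list(P = P, freqs = (seq_len(nk) - 1) * fs / nseg,
       t_centers = (starts - 1 + nseg / 2) / fs)
}

#' Event-related spectral perturbation (ERSP)
#'
#' Hann-windowed short-time power spectrogram (0.5 s segments, 90% overlap)
#' per epoch, power averaged over epochs, converted to dB relative to the
#' mean baseline power of each frequency row.
#'
#' @param epochs list of [signal_window()]s with a common time base (epoch
#'   time = `t_start_s` + sample index / fs; baselines are given in epoch
#'   time).
#' @param baseline_s length-2 numeric, baseline interval in epoch time (s).
#' @param channel channel index to analyze.
#' @param seg_s,overlap short-time transform parameters.
#' @return a list of class `ersp_map` with `t_s`, `freqs_hz` and `db`
#'   (frequency x time matrix).
#' @export
ersp <- function(epochs, baseline_s, channel = 1, seg_s = 0.5,
                 overlap = 0.9) {
  stopifnot(length(epochs) >= 1, length(baseline_s) == 2)
  fs <- epochs[[1]]$fs_hz
  t0 <- epochs[[1]]$t_start_s
  n <- nrow(epochs[[1]]$samples)
  epoch_span <- c(t0, t0 + n / fs)
  if (baseline_s[1] < epoch_span[1] - 1e-9 ||
      baseline_s[2] > epoch_span[2] + 1e-9) {
    stop("baseline interval lies outside the epoch span")
  }
  acc <- NULL; s1 <- NULL
  for (ep in epochs) {
    s <- stft_power(ep$samples[, channel], fs, seg_s, overlap)
    if (is.null(acc)) { acc <- s$P; s1 <- s } else acc <- acc + s$P
  }
  P <- acc / length(epochs)
  t_s <- t0 + s1$t_centers
  base_cols <- which(t_s >= baseline_s[1] & t_s <= baseline_s[2])
  if (!length(base_cols)) stop("no spectrogram columns inside the baseline")
  base <- rowMeans(P[, base_cols, drop = FALSE])
  db <- 10 * log10(sweep(P, 1, pmax(base, .Machine$double.xmin), "/"))
  structure(list(t_s = t_s, freqs_hz = s1$freqs, db = db),
            class = "ersp_map")
}
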