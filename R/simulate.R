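#' Simulator configuration
#'
#' Parameters of the synthetic two-channel occipital EEG generator. The
#' generated signal is the sum of a stimulus-locked SSVEP component
#' (phase-locked sinusoidal harmonics, shared across channels up to a
#' per-channel gain and phase offset), 1/f^alpha background noise, a
#' narrow-band alpha rhythm around 10 Hz (band-filtered noise, deliberately
#' colliding with the 10 Hz stimulus), and power-line interference.
#'
#' @param fs_hz sampling rate (Hz).
#' @param n_channels number of EEG channels.
#' @param ssvep_amp_uV per-harmonic SSVEP amplitudes (uV), harmonics 1..H.
#' @param noise_exponent alpha of the 1/f^alpha background spectrum.
#' @param noise_rms_uV RMS of the broadband background noise (uV).
#' @param alpha_band_amp_uV RMS of the ~10 Hz alpha rhythm (uV).
#' @param line_noise_hz,line_noise_amp_uV power-line frequency and amplitude.
#' @param channel_gain per-channel multiplicative gain on the SSVEP source.
#' @param channel_phase_jitter_rad per-channel phase offset of the SSVEP.
#' @param response_latency_s delay from stimulus onset to entrained response.
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 200, n_channels = 2,
                       ssvep_amp_uV = c(1.0, 0.4, 0.15),
                       noise_exponent = 1, noise_rms_uV = 1.0,
                       alpha_band_amp_uV = 0.4,
                       line_noise_hz = 60, line_noise_amp_uV = 0.3,
                       channel_gain = NULL,
                       channel_phase_jitter_rad = NULL,
                       response_latency_s = 0.14, seed = 1L) {
  if (is.null(channel_gain)) {
    channel_gain <- seq(1, by = -0.1, length.out = n_channels)
  }
  if (is.null(channel_phase_jitter_rad)) {
    channel_phase_jitter_rad <- seq(0, by = 0.2, length.out = n_channels)
  }
  stopifnot(fs_hz > 0, n_channels >= 1,
            all(ssvep_amp_uV >= 0), noise_rms_uV >= 0,
            alpha_band_amp_uV >= 0, line_noise_amp_uV >= 0,
            length(channel_gain) == n_channels,
            length(channel_phase_jitter_rad) == n_channels)
  structure(list(fs_hz = fs_hz, n_channels = n_channels,
                 ssvep_amp_uV = ssvep_amp_uV,
                 noise_exponent = noise_exponent,
                 noise_rms_uV = noise_rms_uV,
                 alpha_band_amp_uV = alpha_band_amp_uV,
                 line_noise_hz = line_noise_hz,
                 line_noise_amp_uV = line_noise_amp_uV,
                 channel_gain = channel_gain,
                 channel_phase_jitter_rad = channel_phase_jitter_rad,
                 response_latency_s = response_latency_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Spectrally shaped Gaussian noise via FFT filtering: white noise whose
# rFFT amplitudes are multiplied by shape(f), then rescaled to target RMS.
shaped_noise <- function(n, fs, shape, rms) {
  if (rms <= 0 || n < 2) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)            # two-sided spectrum, mirrored
  g <- shape(f_fold)
  g[1] <- 0                            # kill DC
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

background_noise <- function(n, cfg) {
  pink <- shaped_noise(n, cfg$fs_hz,
                       function(f) ifelse(f > 0, f^(-cfg$noise_exponent / 2), 0),
                       cfg$noise_rms_uV)
  alpha <- shaped_noise(n, cfg$fs_hz,
                        function(f) exp(-(f - 10)^2 / (2 * 1^2)),
                        cfg$alpha_band_amp_uV)
  pink + alpha
}

line_noise <- function(t, cfg, phase) {
  if (cfg$line_noise_amp_uV <= 0) return(numeric(length(t)))
  cfg$line_noise_amp_uV * sin(2 * pi * cfg$line_noise_hz * t + phase)
}

# Stimulus-locked harmonic SSVEP source evaluated at times t, active on the
# (already latency-shifted) logical mask. Phase is locked to stimulus onset.
ssvep_source <- function(t, f_hz, active, cfg, onset_s, phase_offset = 0) {
  s <- numeric(length(t))
  if (!any(active)) return(s)
  for (h in seq_along(cfg$ssvep_amp_uV)) {
    a <- cfg$ssvep_amp_uV[h]
    if (a > 0) {
      s <- s + a * sin(2 * pi * h * f_hz * (t - onset_s) + phase_offset)
    }
  }
  s * active
}

#' Construct a signal window
#'
#' A fixed-duration multi-channel EEG segment with sampling metadata; the
#' unit of decoding.
#'
#' @param samples numeric matrix, N samples x C channels, in uV.
#' @param fs_hz sampling rate in Hz.
#' @param t_start_s time of the first sample (s).
#' @return an object of class `signal_window`.
#' @export
signal_window <- function(samples, fs_hz, t_start_s = 0) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), all(is.finite(samples)),
            fs_hz > 0, ncol(samples) >= 1)
  structure(list(samples = samples, fs_hz = fs_hz, t_start_s = t_start_s),
            class = "signal_window")
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("signal_window: %d samples x %d channels @ %g Hz (t0 = %g s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz, x$t_start_s))
  invisible(x)
}

#' Simulate one SSVEP epoch
#'
#' Generates a multi-channel EEG segment in which every channel contains the
#' attended stimulation frequency's harmonic response (after the configured
#' response latency), on top of 1/f background, alpha rhythm and line noise.
#' With `attended_freq_hz = NULL` only background is produced (rest).
#'
#' @param config a [sim_config()].
#' @param attended_freq_hz attended stimulation frequency (Hz) or `NULL`.
#' @param duration_s epoch length in seconds (> 0).
#' @param seed RNG seed; defaults to `config$seed`.
#' @param t_start_s epoch start time stamp.
#' @param on_intervals optional n x 2 matrix of (start, stop) times in epoch
#'   coordinates during which the stimulus is on; default: on for the whole
#'   epoch. Used to emulate intermittent flicker protocols.
#' @return a [signal_window()].
#' @export
simulate_ssvep_epoch <- function(config, attended_freq_hz = NULL, duration_s,
                                 seed = config$seed, t_start_s = 0,
                                 on_intervals = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  set.seed(seed)
  n <- round(duration_s * config$fs_hz)
  t <- t_start_s + (seq_len(n) - 1) / config$fs_hz
  x <- matrix(0, n, config$n_channels)
  if (is.null(on_intervals)) {
    on_intervals <- matrix(c(t_start_s, t_start_s + duration_s), 1)
  }
  for (ch in seq_len(config$n_channels)) {
    xi <- background_noise(n, config) +
      line_noise(t, config, phase = stats::runif(1, 0, 2 * pi))
    if (!is.null(attended_freq_hz)) {
      for (k in seq_len(nrow(on_intervals))) {
        onset <- on_intervals[k, 1]
        active <- t >= onset + config$response_latency_s &
          t < on_intervals[k, 2]
        xi <- xi + config$channel_gain[ch] *
          ssvep_source(t, attended_freq_hz, active, config, onset,
                       config$channel_phase_jitter_rad[ch])
      }
    }
    x[, ch] <- xi
  }
  signal_window(x, config$fs_hz, t_start_s)
}

#' Protocol script for a simulated session
#'
#' An ordered list of attended commands (or `"REST"`) with dwell durations,
#' separated by an inter-command gap.
#'
#' @param commands character vector over the five commands plus `"REST"`.
#' @param dwell_s attended dwell per entry, seconds (recycled).
#' @param gap_s inter-command gap in seconds (rest), default 2 s.
#' @return a list of class `protocol_script`.
#' @export
protocol_script <- function(commands, dwell_s = 4, gap_s = 2) {
  stopifnot(length(commands) >= 0,
            all(commands %in% c(speller_commands(), "REST")),
            all(dwell_s > 0), gap_s >= 0)
  entries <- data.frame(command = commands,
                        dwell_s = rep_len(dwell_s, length(commands)),
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, gap_s = gap_s),
            class = "protocol_script")
}

#' Single-command-recognition protocol script (one set)
#'
#' Each of the five commands twice per set (10 selections), in a
#' seed-shuffled order, with a 2 s inter-command gap.
#'
#' @param n_sets number of sets.
#' @param dwell_s dwell per selection (s).
#' @param gap_s inter-command gap (s).
#' @param seed RNG seed for the per-set command order.
#' @return a [protocol_script()].
#' @export
exp1_script <- function(n_sets = 1, dwell_s = 4, gap_s = 2, seed = 1L) {
  set.seed(seed)
  cmds <- unlist(lapply(seq_len(n_sets), function(i) {
    sample(rep(speller_commands(), 2))
  }))
  protocol_script(cmds, dwell_s = dwell_s, gap_s = gap_s)
}

#' Simulate a labeled continuous session
#'
#' Renders a protocol script into a continuous two-channel stream with a
#' sample-aligned ground-truth label track (`"NONE"` during gaps and rest).
#'
#' @param script a [protocol_script()].
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a list of class `session_stream`: `samples` (N x C matrix, uV),
#'   `fs_hz`, `t_s` (time stamps), `labels` (character per sample), and
#'   `segments` (data.frame with command, t_on, t_off per attended segment).
#' @export
simulate_session <- function(script, config, seed = config$seed) {
  stopifnot(inherits(script, "protocol_script"), inherits(config, "sim_config"))
  set.seed(seed)
  fs <- config$fs_hz
  ents <- script$entries
  if (nrow(ents) == 0) {
    return(structure(list(samples = matrix(0, 0, config$n_channels),
                          fs_hz = fs, t_s = numeric(0),
                          labels = character(0),
                          segments = data.frame(command = character(0),
                                                t_on = numeric(0),
                                                t_off = numeric(0))),
                     class = "session_stream"))
  }
  total_s <- sum(ents$dwell_s) + nrow(ents) * script$gap_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  labels <- rep("NONE", n)
  seg <- data.frame(command = ents$command, t_on = NA_real_, t_off = NA_real_)
  cursor <- 0
  for (i in seq_len(nrow(ents))) {
    seg$t_on[i] <- cursor
    seg$t_off[i] <- cursor + ents$dwell_s[i]
    cursor <- seg$t_off[i] + script$gap_s
    if (ents$command[i] != "REST") {
      labels[t >= seg$t_on[i] & t < seg$t_off[i]] <- ents$command[i]
    }
  }
  x <- matrix(0, n, config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    xi <- background_noise(n, config) +
      line_noise(t, config, phase = stats::runif(1, 0, 2 * pi))
    for (i in seq_len(nrow(ents))) {
      if (ents$command[i] == "REST") next
      f <- map_command_to_frequency(ents$command[i])
      active <- t >= seg$t_on[i] + config$response_latency_s & t < seg$t_off[i]
      xi <- xi + config$channel_gain[ch] *
        ssvep_source(t, f, active, config, seg$t_on[i],
                     config$channel_phase_jitter_rad[ch])
    }
    x[, ch] <- xi
  }
  seg <- seg[ents$command != "REST", , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(samples = x, fs_hz = fs, t_s = t, labels = labels,
                 segments = seg),
            class = "session_stream")
}

#' @export
print.session_stream <- function(x, ...) {
  cat(sprintf(
    "session_stream: %.1f s @ %g Hz, %d channels, %d attended segments\n",
    length(x$t_s) / x$fs_hz, x$fs_hz, ncol(x$samples), nrow(x$segments)))
  invisible(x)
}

#' Read/write continuous streams as CSV
#'
#' The stream format is a plain CSV with header
#' `time_s,ch1_uV,ch2_uV[,label]`; the label column carries command names or
#' `NONE`.
#'
#' @param stream a `session_stream`.
#' @param path file path.
#' @export
write_stream_csv <- function(stream, path) {
  df <- data.frame(time_s = stream$t_s)
  for (ch in seq_len(ncol(stream$samples))) {
    df[[paste0("ch", ch, "_uV")]] <- stream$samples[, ch]
  }
  if (!is.null(stream$labels)) df$label <- stream$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @return `read_stream_csv()` returns a `session_stream` (without segment
#'   metadata; segments are recovered from the label track).
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chcols <- grep("^ch[0-9]+_uV$", names(df), value = TRUE)
  if (length(chcols) == 0) stop("no channel columns (chN_uV) found in ", path)
  labels <- if ("label" %in% names(df)) df$label else NULL
  t_s <- df$time_s
  fs <- if (length(t_s) > 1) 1 / stats::median(diff(t_s)) else NA_real_
  segments <- data.frame(command = character(0), t_on = numeric(0),
                         t_off = numeric(0))
  if (!is.null(labels) && length(labels)) {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "NONE"
    if (any(keep)) {
      segments <- data.frame(command = r$values[keep],
                             t_on = t_s[starts[keep]],
                             t_off = t_s[ends[keep]] + 1 / fs)
    }
  }
  structure(list(samples = as.matrix(df[chcols]), fs_hz = fs, t_s = t_s,
                 labels = labels, segments = segments),
            class = "session_stream")
}
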