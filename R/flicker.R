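#' Command set and frequency map
#'
#' The speller uses five visual stimulation frequencies, each an integer
#' division of the 60 Hz display refresh, mapped one-to-one onto control
#' commands: 6.67 Hz -> UP, 7.5 Hz -> RIGHT, 8.57 Hz -> DOWN, 10 Hz -> LEFT,
#' 12 Hz -> SELECT.
#'
#' @return `speller_commands()` returns the five command names in frequency
#'   order; `stimulus_frequencies()` returns the nominal frequencies in Hz.
#' @export
speller_commands <- function() c("UP", "RIGHT", "DOWN", "LEFT", "SELECT")

#' @rdname speller_commands
#' @export
stimulus_frequencies <- function() c(6.67, 7.5, 8.57, 10, 12)

#' Map a stimulation frequency to its control command (and back)
#'
#' The bijection is fixed: 6.67 -> UP, 7.5 -> RIGHT, 8.57 -> DOWN,
#' 10 -> LEFT, 12 -> SELECT. Frequencies are matched to the nominal set
#' within 0.01 Hz so realized frame-locked values (e.g. 60/7 = 8.5714 Hz)
#' resolve to the right command.
#'
#' @param f_hz stimulation frequency in Hz.
#' @param command one of `"UP"`, `"RIGHT"`, `"DOWN"`, `"LEFT"`, `"SELECT"`.
#' @return the mapped command name, or the nominal frequency in Hz.
#' @export
map_frequency_to_command <- function(f_hz) {
  stopifnot(is.numeric(f_hz), length(f_hz) == 1L)
  i <- which(abs(stimulus_frequencies() - f_hz) < 0.01)
  if (length(i) != 1L) {
    stop("frequency ", f_hz, " Hz is not in the stimulus set")
  }
  speller_commands()[i]
}

#' @rdname map_frequency_to_command
#' @export
map_command_to_frequency <- function(command) {
  i <- match(match.arg(command, speller_commands()), speller_commands())
  stimulus_frequencies()[i]
}

#' Build a frame-locked flicker schedule
#'
#' Each stimulation frequency must divide the display refresh rate so that a
#' full on/off cycle spans an integer number of frames (at 60 Hz the five
#' speller frequencies use periods of 9, 8, 7, 6 and 5 frames). The realized
#' frequency is `refresh_hz / frame_period`; duty cycle is 50%, with the "on"
#' phase taking the extra frame for odd periods (configurable via
#' `on_frames_fun`).
#'
#' @param frequencies numeric vector of nominal frequencies (Hz).
#' @param refresh_hz display refresh rate (Hz), default 60.
#' @param duration_s length of the per-frame on/off timeline to generate;
#'   `0` returns specs with empty timelines.
#' @param commands optional character vector naming the command driven by each
#'   frequency; defaults to the speller map when the frequencies match the
#'   stimulus set, `NA` otherwise.
#' @param tol_hz tolerance for treating a nominal frequency as frame-locked.
#' @return an object of class `flicker_schedule`: a list with `specs` (a
#'   data.frame with columns command, nominal_freq_hz, frame_period,
#'   realized_freq_hz) and `timelines` (a logical matrix, frames x
#'   frequencies, TRUE = stimulus on).
#' @export
make_flicker_schedule <- function(frequencies, refresh_hz = 60,
                                  duration_s = 0, commands = NULL,
                                  tol_hz = 0.01,
                                  on_frames_fun = function(k) ceiling(k / 2)) {
  stopifnot(refresh_hz > 0, duration_s >= 0, length(frequencies) >= 1L)
  periods <- integer(length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    k <- round(refresh_hz / f)
    if (k < 2 || abs(refresh_hz / k - f) >= tol_hz) {
      stop("frequency ", f, " Hz is not frame-locked: no integer frame ",
           "period realizes it within ", tol_hz, " Hz of a ", refresh_hz,
           " Hz refresh")
    }
    periods[i] <- k
  }
  if (is.null(commands)) {
    commands <- vapply(frequencies, function(f) {
      j <- which(abs(stimulus_frequencies() - f) < 0.01)
      if (length(j) == 1L) speller_commands()[j] else NA_character_
    }, character(1))
  }
  realized <- refresh_hz / periods
  n_frames <- round(duration_s * refresh_hz)
  timelines <- matrix(FALSE, nrow = n_frames, ncol = length(frequencies))
  for (i in seq_along(frequencies)) {
    k <- periods[i]
    on <- on_frames_fun(k)
    cycle <- c(rep(TRUE, on), rep(FALSE, k - on))
    if (n_frames > 0) {
      timelines[, i] <- cycle[((seq_len(n_frames) - 1L) %% k) + 1L]
    }
  }
  colnames(timelines) <- as.character(frequencies)
  specs <- data.frame(
    command = commands,
    nominal_freq_hz = frequencies,
    frame_period = periods,
    realized_freq_hz = realized,
    stringsAsFactors = FALSE
  )
  structure(list(specs = specs, timelines = timelines,
                 refresh_hz = refresh_hz),
            class = "flicker_schedule")
}

#' @export
print.flicker_schedule <- function(x, ...) {
  cat("Frame-locked flicker schedule (refresh ", x$refresh_hz, " Hz, ",
      nrow(x$timelines), " frames)\n", sep = "")
  print(x$specs, row.names = FALSE)
  invisible(x)
}
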