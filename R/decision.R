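#' Decision-rule configuration
#'
#' The temporal accumulation rule that turns per-update correlation profiles
#' into discrete commands: profiles are collected for `collection_s` seconds
#' (30 updates at the 50 ms hop); a frequency is a valid candidate iff its
#' correlation reaches `threshold` in at least `consistency` of the updates
#' in the collection window (ceiling(0.30 * 30) = 9 of 30 at defaults);
#' among valid candidates the one with the highest mean accumulated
#' correlation (mean over its qualifying updates) is emitted; if none
#' qualifies, no command is issued. After each emission, updates within
#' `ignore_s` seconds are discarded (refractory interval).
#'
#' @param threshold correlation threshold r (default 0.25).
#' @param consistency required fraction of updates at or above threshold
#'   (default 0.30).
#' @param collection_s collection duration (default 1.5 s).
#' @param hop_s decoding update interval (default 0.05 s).
#' @param ignore_s post-emission refractory interval (default 1 s).
#' @param collection `"block"` (default): consecutive non-overlapping
#'   collection windows that reset after every decision; `"sliding"`: the
#'   rule is evaluated at every update over the trailing collection window.
#' @param consistency_mode `"fraction"` (default): count of qualifying
#'   updates anywhere in the collection window; `"run"`: longest strictly
#'   consecutive run of qualifying updates.
#' @return a list of class `decision_config`.
#' @export
decision_config <- function(threshold = 0.25, consistency = 0.30,
                            collection_s = 1.5, hop_s = 0.05, ignore_s = 1.0,
                            collection = c("block", "sliding"),
                            consistency_mode = c("fraction", "run")) {
  collection <- match.arg(collection)
  consistency_mode <- match.arg(consistency_mode)
  n_collect <- round(collection_s / hop_s)
  stopifnot(threshold >= 0, consistency > 0, consistency <= 1,
            n_collect >= 1, ignore_s >= 0)
  structure(list(threshold = threshold, consistency = consistency,
                 collection_s = collection_s, hop_s = hop_s,
                 ignore_s = ignore_s, collection = collection,
                 consistency_mode = consistency_mode,
                 n_collect = n_collect,
                 n_required = ceiling(consistency * n_collect)),
            class = "decision_config")
}

#' Fresh decision state
#'
#' @param config a [decision_config()].
#' @param frequencies_hz the stimulation frequencies being decoded.
#' @return a list of class `decision_state`.
#' @export
decision_state <- function(config = decision_config(),
                           frequencies_hz = stimulus_frequencies()) {
  structure(list(config = config, frequencies_hz = frequencies_hz,
                 buf = matrix(NA_real_, 0, length(frequencies_hz)),
                 buf_t = numeric(0), ignore_until = -Inf, last_t = -Inf,
                 last_command = NA_character_),
            class = "decision_state")
}

longest_run <- function(hits) {
  if (!any(hits)) return(0L)
  r <- rle(hits)
  max(r$lengths[r$values])
}

# evaluate the accumulation rule on a full collection buffer; returns NULL or
# a list(freq, command, mean_rho, n_hits)
evaluate_collection <- function(buf, cfg, frequencies) {
  hits <- buf >= cfg$threshold
  n_hits <- colSums(hits)
  qualifies <- if (cfg$consistency_mode == "fraction") {
    n_hits >= cfg$n_required
  } else {
    vapply(seq_len(ncol(buf)), function(k) longest_run(hits[, k]),
           integer(1)) >= cfg$n_required
  }
  if (!any(qualifies)) return(NULL)
  mean_rho <- rep(-Inf, ncol(buf))
  for (k in which(qualifies)) mean_rho[k] <- mean(buf[hits[, k], k])
  k_star <- which(mean_rho == max(mean_rho))[1]   # tie -> lowest freq index
  f <- frequencies[k_star]
  list(freq = f, command = map_frequency_to_command(f),
       mean_rho = mean_rho[k_star], n_hits = n_hits[k_star])
}

#' Advance the decision state by one correlation profile
#'
#' Profiles must arrive in time order at hop intervals. Returns the emitted
#' command (or `NULL`) together with the updated state.
#'
#' @param state a [decision_state()].
#' @param profile a [correlation_profile()] or numeric vector of
#'   per-frequency correlations.
#' @param t_s update timestamp; defaults to the profile's.
#' @return `list(command, event, state)`; `command` is a command name or
#'   `NULL`, `event` carries `t_s`, `freq`, `mean_rho` when a command was
#'   emitted.
#' @export
decision_update <- function(state, profile, t_s = NULL) {
  stopifnot(inherits(state, "decision_state"))
  if (inherits(profile, "correlation_profile")) {
    if (is.null(t_s)) t_s <- profile$t_s
    rho <- profile$rho_by_freq
  } else rho <- profile
  if (is.null(t_s)) stop("t_s required")
  if (t_s <= state$last_t) {
    stop("profiles must arrive in strictly increasing time order")
  }
  state$last_t <- t_s
  cfg <- state$config
  command <- NULL; event <- NULL
  if (t_s >= state$ignore_until) {
    state$buf <- rbind(state$buf, rho)
    state$buf_t <- c(state$buf_t, t_s)
    full <- nrow(state$buf) >= cfg$n_collect
    if (full) {
      if (cfg$collection == "sliding" && nrow(state$buf) > cfg$n_collect) {
        keep <- seq(nrow(state$buf) - cfg$n_collect + 1, nrow(state$buf))
        state$buf <- state$buf[keep, , drop = FALSE]
        state$buf_t <- state$buf_t[keep]
      }
      res <- evaluate_collection(state$buf, cfg, state$frequencies_hz)
      if (!is.null(res)) {
        command <- res$command
        event <- list(t_s = t_s, command = res$command, freq = res$freq,
                      mean_rho = res$mean_rho, n_hits = res$n_hits)
        state$ignore_until <- t_s + cfg$ignore_s
        state$last_command <- res$command
        state$buf <- state$buf[0, , drop = FALSE]
        state$buf_t <- numeric(0)
      } else if (cfg$collection == "block") {
        state$buf <- state$buf[0, , drop = FALSE]
        state$buf_t <- numeric(0)
      }
    }
  }
  list(command = command, event = event, state = state)
}

#' Decode a whole profile stream into command events
#'
#' Runs [decision_update()] over every row of a `profile_stream` (or a
#' matrix of per-update correlations) and collects the emitted commands.
#'
#' @param profiles a `profile_stream` from [stream_correlation_profiles()],
#'   or a numeric matrix (updates x frequencies) with `t_s` supplied.
#' @param config a [decision_config()].
#' @param t_s update timestamps when `profiles` is a bare matrix.
#' @param frequencies_hz frequencies for bare matrices.
#' @return a data.frame of events with columns `t_s`, `command`, `freq`,
#'   `mean_rho`, `n_hits` (zero rows if nothing was emitted).
#' @export
decode_profiles <- function(profiles, config = decision_config(),
                            t_s = NULL, frequencies_hz = NULL) {
  if (inherits(profiles, "profile_stream")) {
    t_s <- profiles$t_s
    frequencies_hz <- profiles$frequencies_hz
    profiles <- profiles$rho
  }
  if (is.null(frequencies_hz)) frequencies_hz <- stimulus_frequencies()
  st <- decision_state(config, frequencies_hz)
  cfg <- config
  n <- nrow(profiles)
  ev_t <- numeric(0); ev_cmd <- character(0); ev_f <- numeric(0)
  ev_rho <- numeric(0); ev_hits <- integer(0)
  # inlined update loop (avoids per-call list overhead on long streams)
  buf <- matrix(NA_real_, 0, ncol(profiles))
  ignore_until <- -Inf
  for (i in seq_len(n)) {
    ti <- t_s[i]
    if (ti < ignore_until) next
    buf <- rbind(buf, profiles[i, ])
    if (nrow(buf) >= cfg$n_collect) {
      if (cfg$collection == "sliding" && nrow(buf) > cfg$n_collect) {
        buf <- buf[-1, , drop = FALSE]
      }
      res <- evaluate_collection(buf, cfg, frequencies_hz)
      if (!is.null(res)) {
        ev_t <- c(ev_t, ti); ev_cmd <- c(ev_cmd, res$command)
        ev_f <- c(ev_f, res$freq); ev_rho <- c(ev_rho, res$mean_rho)
        ev_hits <- c(ev_hits, res$n_hits)
        ignore_until <- ti + cfg$ignore_s
        buf <- buf[0, , drop = FALSE]
      } else if (cfg$collection == "block") {
        buf <- buf[0, , drop = FALSE]
      }
    }
  }
  data.frame(t_s = ev_t, command = ev_cmd, freq = ev_f, mean_rho = ev_rho,
             n_hits = ev_hits, stringsAsFactors = FALSE)
}

#' Full streaming decode: filter, window, correlate, decide
#'
#' Applies the causal filter chain, computes channel-max correlation
#' profiles for every sliding window, and runs the accumulation decision
#' rule.
#'
#' @param stream a `session_stream`.
#' @param window_s analysis window length (s).
#' @param n_harmonics harmonics in the reference templates.
#' @param config a [decision_config()].
#' @param chain a [filter_chain()]; defaults to the standard chain at the
#'   stream's sampling rate.
#' @return a list with `events` (see [decode_profiles()]) and `profiles`
#'   (the `profile_stream`).
#' @export
decode_stream <- function(stream, window_s = 1.5, n_harmonics = 1,
                          config = decision_config(), chain = NULL) {
  stopifnot(inherits(stream, "session_stream"))
  if (is.null(chain)) chain <- filter_chain(fs_hz = stream$fs_hz)
  filt <- apply_filter_chain(stream$samples, chain)
  refs <- reference_set(fs_hz = stream$fs_hz,
                        n_samples = round(window_s * stream$fs_hz),
                        n_harmonics = n_harmonics)
  profiles <- stream_correlation_profiles(filt, refs, hop_s = config$hop_s,
                                          fs_hz = stream$fs_hz,
                                          t0_s = stream$t_s[1])
  events <- decode_profiles(profiles, config)
  list(events = events, profiles = profiles)
}

#' Write decoder events as a JSON-lines log
#'
#' One JSON object per emitted command: `{t, command, freq, mean_rho}`.
#'
#' @param events event data.frame from [decode_profiles()].
#' @param path output file.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(list(t = events$t_s[i],
                                     command = events$command[i],
                                     freq = events$freq[i],
                                     mean_rho = events$mean_rho[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
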