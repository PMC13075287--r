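#' Keyboard layouts
#'
#' `default_layout()` loads the bundled 4 x 4 Cheonjiin grid: 14 keys (two
#' empty cells), top row = the vowel elements ㅣ, ㆍ, ㅡ plus DELETE; the
#' remaining rows carry the seven multi-tap consonant keys (ㄱㅋㄲ, ㄴㄹ,
#' ㄷㅌㄸ, ㅂㅍㅃ, ㅅㅎㅆ, ㅈㅊㅉ, ㅇㅁ) and SPACE / ENTER / PERIOD.
#' `qwerty_layout()` loads a flat one-jamo-per-key two-set (dubeolsik) grid
#' used only as the comparison fixture for keystroke-economy analyses. Both
#' are plain JSON files under `inst/extdata/` and can be swapped for edited
#' copies via `path`.
#'
#' @param path optional path to a layout JSON file.
#' @return a list of class `keyboard_layout`.
#' @export
default_layout <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cheonjiin_layout.json",
                        package = "ssvepspeller")
  }
  load_layout(path)
}

#' @rdname default_layout
#' @export
qwerty_layout <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "qwerty_layout.json",
                        package = "ssvepspeller")
  }
  load_layout(path)
}

#' @rdname default_layout
#' @export
load_layout <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  grid <- raw$grid
  stopifnot(length(grid) == raw$rows,
            all(vapply(grid, length, integer(1)) == raw$cols))
  for (r in seq_len(raw$rows)) {
    for (c in seq_len(raw$cols)) {
      if (!is.null(grid[[r]][[c]])) {
        grid[[r]][[c]]$taps <- unlist(grid[[r]][[c]]$taps)
        grid[[r]][[c]]$row <- r
        grid[[r]][[c]]$col <- c
        grid[[r]][[c]]$id <- paste0(r, ",", c)
      }
    }
  }
  structure(list(name = raw$name, style = raw$style,
                 nrow = raw$rows, ncol = raw$cols,
                 home = c(raw$home[[1]] + 1L, raw$home[[2]] + 1L),
                 grid = grid),
            class = "keyboard_layout")
}

#' @export
print.keyboard_layout <- function(x, ...) {
  cat("keyboard_layout '", x$name, "' (", x$nrow, " x ", x$ncol, ", ",
      layout_key_count(x), " keys)\n", sep = "")
  for (r in seq_len(x$nrow)) {
    labs <- vapply(seq_len(x$ncol), function(c) {
      k <- x$grid[[r]][[c]]
      if (is.null(k)) "." else k$label
    }, character(1))
    cat(" ", formatC(labs, width = 5), "\n")
  }
  invisible(x)
}

layout_key_count <- function(layout) {
  sum(vapply(layout$grid, function(row) {
    sum(!vapply(row, is.null, logical(1)))
  }, numeric(1)))
}

layout_key_at <- function(layout, pos) layout$grid[[pos[1]]][[pos[2]]]

layout_positions <- function(layout) {
  out <- list()
  for (r in seq_len(layout$nrow)) {
    for (c in seq_len(layout$ncol)) {
      if (!is.null(layout$grid[[r]][[c]])) out[[length(out) + 1L]] <- c(r, c)
    }
  }
  out
}

#' Move the selection cursor
#'
#' One directional command moves the cursor one cell; empty cells are
#' skipped through (the cursor continues in the same direction to the next
#' occupied cell) and edges clamp (the cursor stays put when no occupied
#' cell lies further in that direction). With `wrap = TRUE` the grid is
#' toroidal instead of clamped.
#'
#' @param layout a `keyboard_layout`.
#' @param pos current cursor position `c(row, col)` (must be an occupied
#'   cell).
#' @param direction one of `"UP"`, `"DOWN"`, `"LEFT"`, `"RIGHT"`.
#' @param wrap toroidal wrapping instead of edge clamping.
#' @return the new position `c(row, col)`.
#' @export
move_cursor <- function(layout, pos, direction, wrap = FALSE) {
  d <- switch(match.arg(direction, c("UP", "DOWN", "LEFT", "RIGHT")),
              UP = c(-1L, 0L), DOWN = c(1L, 0L),
              LEFT = c(0L, -1L), RIGHT = c(0L, 1L))
  cur <- as.integer(pos)
  steps <- max(layout$nrow, layout$ncol)
  for (i in seq_len(steps)) {
    nxt <- cur + i * d
    if (wrap) {
      nxt <- c((nxt[1] - 1L) %% layout$nrow + 1L,
               (nxt[2] - 1L) %% layout$ncol + 1L)
    } else if (nxt[1] < 1 || nxt[1] > layout$nrow ||
               nxt[2] < 1 || nxt[2] > layout$ncol) {
      return(as.integer(pos))                     # clamp: nothing out there
    }
    if (!is.null(layout_key_at(layout, nxt))) return(nxt)
  }
  as.integer(pos)
}

# ---------------------------------------------------------------------------
# Composition automaton.
#
# The pending syllable is (L, elems, T1, T2): initial consonant, the ordered
# vowel-element sequence (resolved through the Cheonjiin table), and up to
# two final-consonant components (T1,T2 forming a compound final). `hold`
# keeps a completed-but-uncommitted previous syllable alive while a fresh
# consonant is being multi-tapped, because a later tap may turn that
# consonant into a jamo that merges back into the held syllable's final
# (e.g. ㅎㅏ + ㄹ + [ㄷ -> ㅌ] must resyllabify to 핥, not 할ㅌ).

#' Hangul composition state
#'
#' The state of the Cheonjiin input automaton: committed text, the pending
#' syllable (initial consonant, vowel-element sequence, final consonant
#' components) and the multi-tap state.
#'
#' @return an empty `composer_state`.
#' @export
composer_state <- function() {
  structure(list(committed = "", L = NA_character_,
                 elems = character(0),
                 T1 = NA_character_, T2 = NA_character_,
                 hold = NULL, multitap = NULL),
            class = "composer_state")
}

resolved_V <- function(state) {
  if (length(state$elems) == 0) return(NA_character_)
  resolve_vowel(state$elems)$vowel
}

pending_final <- function(state) {
  if (is.na(state$T1)) return(NA_character_)
  if (is.na(state$T2)) return(state$T1)
  unname(.compound_finals[paste0(state$T1, state$T2)])
}

# text form of a (possibly partial) syllable record
render_syllable <- function(rec) {
  V <- if (length(rec$elems) == 0) NA_character_ else
    resolve_vowel(rec$elems)$vowel
  Tf <- if (is.na(rec$T1)) NA_character_ else if (is.na(rec$T2)) rec$T1 else
    unname(.compound_finals[paste0(rec$T1, rec$T2)])
  if (!is.na(rec$L) && !is.na(V)) {
    return(compose_syllable(rec$L, V, Tf))
  }
  parts <- character(0)
  if (!is.na(rec$L)) parts <- c(parts, rec$L)
  if (length(rec$elems)) {
    parts <- c(parts, if (!is.na(V)) V else paste0(rec$elems, collapse = ""))
  }
  paste0(parts, collapse = "")
}

render_pending <- function(state) {
  paste0(if (!is.null(state$hold)) render_syllable(state$hold) else "",
         render_syllable(state))
}

#' Rendered text of a composer state
#'
#' Committed text plus the preview of the pending (uncommitted) syllable.
#'
#' @param state a `composer_state`.
#' @return a character scalar (UTF-8, NFC).
#' @export
composer_text <- function(state) paste0(state$committed, render_pending(state))

#' @export
print.composer_state <- function(x, ...) {
  cat("composer_state: \"", composer_text(x), "\"",
      if (!is.null(x$multitap)) " [multitap armed]", "\n", sep = "")
  invisible(x)
}

pending_record <- function(state) {
  list(L = state$L, elems = state$elems, T1 = state$T1, T2 = state$T2)
}

clear_pending <- function(state) {
  state$L <- NA_character_
  state$elems <- character(0)
  state$T1 <- NA_character_; state$T2 <- NA_character_
  state
}

restore_pending <- function(state, rec) {
  state$L <- rec$L; state$elems <- rec$elems
  state$T1 <- rec$T1; state$T2 <- rec$T2
  state
}

flush_hold <- function(state) {
  if (!is.null(state$hold)) {
    state$committed <- paste0(state$committed, render_syllable(state$hold))
    state$hold <- NULL
  }
  state
}

commit_pending <- function(state) {
  state <- flush_hold(state)
  state$committed <- paste0(state$committed, render_syllable(state))
  state <- clear_pending(state)
  state$multitap <- NULL
  state
}

#' Disarm the multi-tap cycle
#'
#' Moving the cursor commits the current multi-tap cycle in place: a
#' subsequent press of the same key starts a fresh cycle rather than
#' advancing the old one. (The BCI has no dwell clock, so there is no
#' timeout-based commit.)
#'
#' @param state a `composer_state`.
#' @return the updated state.
#' @export
composer_disarm <- function(state) {
  state$multitap <- NULL
  flush_hold(state)
}

place_new_consonant <- function(state, ch, key_id) {
  state <- flush_hold(state)
  V <- resolved_V(state)
  if (!is.na(state$L) && !is.na(V)) {
    if (is.na(state$T1) && ch %in% .jongseong) {
      state$T1 <- ch; target <- "T1"
    } else if (!is.na(state$T1) && is.na(state$T2) &&
               paste0(state$T1, ch) %in% names(.compound_finals)) {
      state$T2 <- ch; target <- "T2"
    } else {
      # cannot extend this syllable: hold it (a later multi-tap advance may
      # still merge back) and open a new one
      state$hold <- pending_record(state)
      state <- clear_pending(state)
      state$L <- ch; target <- "L"
    }
  } else if (!is.na(state$L) || length(state$elems) > 0) {
    state <- commit_pending(state)                 # bare jamo commits
    state$L <- ch; target <- "L"
  } else {
    state$L <- ch; target <- "L"
  }
  state$multitap <- list(key_id = key_id, pos = 1L, target = target)
  state
}

advance_multitap <- function(state, key) {
  mt <- state$multitap
  pos <- (mt$pos %% length(key$taps)) + 1L
  ch <- key$taps[pos]
  if (mt$target == "L") {
    # the advanced jamo may merge back into the held syllable's final
    if (!is.null(state$hold)) {
      h <- state$hold
      if (!is.na(h$T1) && is.na(h$T2) &&
          paste0(h$T1, ch) %in% names(.compound_finals)) {
        h$T2 <- ch
        state$hold <- NULL
        state <- restore_pending(clear_pending(state), h)
        state$multitap <- list(key_id = key$id, pos = pos, target = "T2")
        return(state)
      }
      if (is.na(h$T1) && ch %in% .jongseong) {
        h$T1 <- ch
        state$hold <- NULL
        state <- restore_pending(clear_pending(state), h)
        state$multitap <- list(key_id = key$id, pos = pos, target = "T1")
        return(state)
      }
    }
    state$L <- ch
    state$multitap$pos <- pos
  } else if (mt$target == "T1") {
    if (ch %in% .jongseong) {
      state$T1 <- ch
      state$multitap$pos <- pos
    } else {
      # advanced jamo cannot be a final (e.g. ㄸ): hold the open syllable
      # and let the jamo start the next one
      state$T1 <- NA_character_
      state$hold <- pending_record(state)
      state <- clear_pending(state)
      state$L <- ch
      state$multitap <- list(key_id = key$id, pos = pos, target = "L")
    }
  } else {                                         # T2 of a compound final
    if (paste0(state$T1, ch) %in% names(.compound_finals)) {
      state$T2 <- ch
      state$multitap$pos <- pos
    } else {
      state$T2 <- NA_character_
      state$hold <- pending_record(state)
      state <- clear_pending(state)
      state$L <- ch
      state$multitap <- list(key_id = key$id, pos = pos, target = "L")
    }
  }
  state
}

press_vowel_element <- function(state, elem) {
  state$multitap <- NULL
  state <- flush_hold(state)
  if (!is.na(state$T1)) {
    # a vowel after a final steals the last final component as the next
    # syllable's initial (standard automaton backtrack)
    steal <- if (!is.na(state$T2)) state$T2 else state$T1
    if (!is.na(state$T2)) state$T2 <- NA_character_ else
      state$T1 <- NA_character_
    state <- commit_pending(state)
    state$L <- steal
    state$elems <- elem
    return(state)
  }
  cand <- c(state$elems, elem)
  if (resolve_vowel(cand)$valid) {
    state$elems <- cand
  } else {
    state <- commit_pending(state)
    state$elems <- elem
  }
  state
}

press_delete <- function(state) {
  state$multitap <- NULL
  if (!is.na(state$T2)) {
    state$T2 <- NA_character_
  } else if (!is.na(state$T1)) {
    state$T1 <- NA_character_
  } else if (length(state$elems) > 0) {
    state$elems <- state$elems[-length(state$elems)]
  } else if (!is.na(state$L)) {
    state$L <- NA_character_
    if (!is.null(state$hold)) {                    # un-split: restore held
      state <- restore_pending(state, state$hold)
      state$hold <- NULL
    }
  } else if (nzchar(state$committed)) {
    state$committed <- substring(state$committed, 1,
                                 nchar(state$committed) - 1)
  }
  state
}

#' Press a key of the active layout
#'
#' Applies the Cheonjiin composition rules: a consonant key inserts the
#' first jamo of its tap cycle and an immediate re-press advances the cycle
#' in place; any other key (or a cursor move, see [composer_disarm()])
#' commits the cycle. Vowel-element keys append ㅣ/ㆍ/ㅡ and resolve through
#' the vowel table. A consonant after a medial attaches as the final when
#' legal; a following vowel steals it back as the next syllable's initial.
#' DELETE removes the last jamo/element; SPACE, ENTER and PERIOD commit the
#' pending syllable and append their character (ENTER appends nothing).
#'
#' @param state a `composer_state`.
#' @param key a key object from a `keyboard_layout` (see
#'   [default_layout()]).
#' @return the updated `composer_state`.
#' @export
press_key <- function(state, key) {
  stopifnot(inherits(state, "composer_state"), !is.null(key))
  if (key$kind == "consonant") {
    mt <- state$multitap
    if (!is.null(mt) && identical(mt$key_id, key$id)) {
      advance_multitap(state, key)
    } else {
      place_new_consonant(state, key$taps[1], key$id)
    }
  } else if (key$kind == "vowel") {
    press_vowel_element(state, key$taps[1])
  } else if (key$kind == "jamo") {
    # plain (non-Cheonjiin) layouts are planner-only fixtures
    stop("plain jamo keys are only supported by the typing planner")
  } else {
    switch(key$action,
           DELETE = press_delete(state),
           SPACE = { s <- commit_pending(state)
                     s$committed <- paste0(s$committed, " "); s },
           ENTER = commit_pending(state),
           PERIOD = { s <- commit_pending(state)
                      s$committed <- paste0(s$committed, "."); s },
           stop("unknown function key: ", key$action))
  }
}

#' Replay a command sequence through cursor and composer
#'
#' Deterministic replay of the five-command alphabet: directional commands
#' move the cursor (committing any armed multi-tap); SELECT presses the key
#' under the cursor.
#'
#' @param layout a `keyboard_layout` (Cheonjiin style).
#' @param commands character vector over
#'   `c("UP","DOWN","LEFT","RIGHT","SELECT")`.
#' @param start starting cursor position; defaults to the layout home.
#' @param wrap toroidal cursor wrapping (see [move_cursor()]).
#' @return a list with `text` (the rendered text, committed + pending),
#'   `cursor` (final position) and `state` (the final `composer_state`).
#' @export
execute_commands <- function(layout, commands, start = layout$home,
                             wrap = FALSE) {
  stopifnot(all(commands %in% c(speller_commands())))
  pos <- as.integer(start)
  st <- composer_state()
  for (cmd in commands) {
    if (cmd == "SELECT") {
      st <- press_key(st, layout_key_at(layout, pos))
    } else {
      newpos <- move_cursor(layout, pos, cmd, wrap = wrap)
      if (!identical(newpos, pos)) st <- composer_disarm(st)
      pos <- newpos
    }
  }
  list(text = composer_text(st), cursor = pos, state = st)
}
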