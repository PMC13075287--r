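# Breadth-first shortest paths on the key graph induced by move_cursor
# (clamp/skip or wrap semantics). Nodes are occupied cells; one edge per
# directional command. Directions are explored in a fixed order so paths
# are deterministic.

.plan_dirs <- c("UP", "RIGHT", "DOWN", "LEFT")

key_graph <- function(layout, wrap = FALSE) {
  nodes <- layout_positions(layout)
  ids <- vapply(nodes, function(p) paste0(p[1], ",", p[2]), character(1))
  edges <- lapply(nodes, function(p) {
    vapply(.plan_dirs, function(d) {
      q <- move_cursor(layout, p, d, wrap = wrap)
      paste0(q[1], ",", q[2])
    }, character(1))
  })
  names(edges) <- ids
  list(nodes = nodes, ids = ids, edges = edges)
}

# shortest command path between two cells; returns character vector of
# directional commands (possibly empty)
bfs_path <- function(graph, from, to) {
  src <- paste0(from[1], ",", from[2])
  dst <- paste0(to[1], ",", to[2])
  if (src == dst) return(character(0))
  prev <- stats::setNames(rep(NA_character_, length(graph$ids)), graph$ids)
  prev_dir <- prev
  visited <- stats::setNames(logical(length(graph$ids)), graph$ids)
  visited[src] <- TRUE
  queue <- src
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (d in .plan_dirs) {
      nb <- graph$edges[[cur]][d]
      if (!visited[nb]) {
        visited[nb] <- TRUE
        prev[nb] <- cur
        prev_dir[nb] <- d
        if (nb == dst) {
          path <- character(0)
          at <- dst
          while (at != src) {
            path <- c(prev_dir[at], path)
            at <- prev[at]
          }
          return(unname(path))
        }
        queue <- c(queue, nb)
      }
    }
  }
  stop("no path between keys ", src, " and ", dst)
}

# Decompose a text into an ordered list of key presses:
# list(pos = c(row, col), taps = n) groups. One group = one jamo (or
# function character); `taps` > 1 means repeated SELECTs of a multi-tap key.
text_to_presses <- function(text, layout) {
  # index: jamo -> (position, tap count); function actions -> position
  jamo_map <- list(); fn_map <- list()
  for (p in layout_positions(layout)) {
    k <- layout_key_at(layout, p)
    if (k$kind %in% c("consonant", "vowel", "jamo")) {
      for (i in seq_along(k$taps)) {
        if (is.null(jamo_map[[k$taps[i]]])) {
          jamo_map[[k$taps[i]]] <- list(pos = p, taps = i)
        }
      }
    } else {
      fn_map[[k$action]] <- list(pos = p, taps = 1L)
    }
  }
  cheonjiin <- identical(layout$style, "cheonjiin")
  jamo_group <- function(j) {
    g <- jamo_map[[j]]
    if (!is.null(g)) return(list(g))
    if (!cheonjiin && j %in% .choseong) {
      # doubled consonant with no key of its own: two presses of the base
      base <- switch(j, "ㄲ" = "ㄱ", "ㄸ" = "ㄷ",
                     "ㅃ" = "ㅂ", "ㅆ" = "ㅅ", "ㅉ" = "ㅈ",
                     NULL)
      if (!is.null(base) && !is.null(jamo_map[[base]])) {
        return(list(jamo_map[[base]], jamo_map[[base]]))
      }
    }
    stop("jamo not reachable on layout '", layout$name, "': ", j)
  }
  vowel_groups <- function(v) {
    if (cheonjiin) {
      lapply(vowel_elements_of(v), function(e) jamo_group(e)[[1]])
    } else if (!is.null(jamo_map[[v]])) {
      list(jamo_map[[v]])
    } else if (v %in% names(.compound_vowels)) {
      unlist(lapply(.compound_vowels[[v]], vowel_groups), recursive = FALSE)
    } else {
      stop("vowel not reachable on layout '", layout$name, "': ", v)
    }
  }
  final_groups <- function(f) {
    parts <- split_compound_final(f)
    unlist(lapply(parts, jamo_group), recursive = FALSE)
  }
  groups <- list()
  for (ch in strsplit(text, "")[[1]]) {
    cp <- utf8ToInt(ch)
    if (cp >= 0xAC00 && cp <= 0xD7A3) {
      s <- decompose_syllable(ch)
      groups <- c(groups, jamo_group(s$L), vowel_groups(s$V))
      if (!is.na(s$T)) groups <- c(groups, final_groups(s$T))
    } else if (ch == " ") {
      if (is.null(fn_map$SPACE)) stop("no SPACE key on layout")
      groups <- c(groups, list(fn_map$SPACE))
    } else if (ch == ".") {
      if (is.null(fn_map$PERIOD)) stop("no PERIOD key on layout")
      groups <- c(groups, list(fn_map$PERIOD))
    } else if (!is.na(match(ch, c(.choseong)))) {
      groups <- c(groups, jamo_group(ch))
    } else if (!is.na(match(ch, .jungseong))) {
      groups <- c(groups, vowel_groups(ch))
    } else {
      stop("unsupported character in text: '", ch, "'")
    }
  }
  groups
}

#' Plan the command sequence that types a text
#'
#' Greedy shortest-path planner: the text is decomposed into jamo, mapped to
#' key presses (multi-tap counts on Cheonjiin consonant keys, vowel-element
#' sequences for medials), and each key-to-key transition is routed over the
#' BFS-shortest directional path under the layout's clamp/skip (or wrap)
#' movement semantics, with one SELECT per press. When two consecutive jamo
#' would merge on the same multi-tap key, a minimal two-move detour (away
#' and back) is inserted to commit the cycle. Movement and SELECT counts are
#' returned separately so either keystroke-counting convention can be
#' reported.
#'
#' @param text UTF-8 Hangul text (precomposed syllables, spaces, periods,
#'   bare compatibility jamo).
#' @param layout a `keyboard_layout`; default the bundled Cheonjiin grid.
#' @param start starting cursor position; defaults to the layout home.
#' @param wrap toroidal movement (see [move_cursor()]).
#' @return a list of class `typing_plan`: `commands` (character vector over
#'   the five-command alphabet), `movements`, `selects`, `total`
#'   (= movements + selects), and `start`.
#' @export
type_text_plan <- function(text, layout = default_layout(),
                           start = layout$home, wrap = FALSE) {
  graph <- key_graph(layout, wrap = wrap)
  groups <- if (nzchar(text)) text_to_presses(text, layout) else list()
  commands <- character(0)
  pos <- as.integer(start)
  cheonjiin <- identical(layout$style, "cheonjiin")
  prev_multitap_id <- NULL
  for (g in groups) {
    target <- as.integer(g$pos)
    path <- bfs_path(graph, pos, target)
    key <- layout_key_at(layout, target)
    is_mt <- cheonjiin && identical(key$kind, "consonant")
    if (length(path) == 0 && is_mt &&
        identical(prev_multitap_id, key$id)) {
      # same consonant key twice in a row for distinct jamo: detour to
      # commit the armed cycle, then come back
      for (d in .plan_dirs) {
        q <- move_cursor(layout, pos, d, wrap = wrap)
        if (!identical(q, pos)) {
          back <- bfs_path(graph, q, pos)
          path <- c(d, back)
          break
        }
      }
    }
    commands <- c(commands, path, rep("SELECT", g$taps))
    pos <- target
    prev_multitap_id <- if (is_mt) key$id else NULL
  }
  structure(list(commands = commands,
                 movements = sum(commands != "SELECT"),
                 selects = sum(commands == "SELECT"),
                 total = length(commands),
                 start = as.integer(start),
                 layout = layout$name),
            class = "typing_plan")
}

#' @export
print.typing_plan <- function(x, ...) {
  cat(sprintf(
    "typing_plan on '%s': %d movements + %d selects = %d commands\n",
    x$layout, x$movements, x$selects, x$total))
  invisible(x)
}

#' Keystroke-economy comparison between layouts
#'
#' Plans the same text on two layouts (by default the bundled Cheonjiin
#' grid and the QWERTY-style fixture) and reports movement-only and
#' movement+select totals for each, from the same home-position convention.
#'
#' @param text Hangul text.
#' @param layout_a,layout_b the two layouts to compare.
#' @return a data.frame with one row per layout.
#' @export
movement_cost_comparison <- function(text, layout_a = default_layout(),
                                     layout_b = qwerty_layout()) {
  pa <- type_text_plan(text, layout_a)
  pb <- type_text_plan(text, layout_b)
  data.frame(layout = c(layout_a$name, layout_b$name),
             movements = c(pa$movements, pb$movements),
             selects = c(pa$selects, pb$selects),
             total = c(pa$total, pb$total),
             stringsAsFactors = FALSE)
}
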