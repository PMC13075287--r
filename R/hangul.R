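# Hangul jamo inventories in canonical (Unicode block) order. Compatibility
# jamo (U+3131..U+3163, U+318D for the Cheonjiin "heaven" dot) are used for
# user-facing single letters; precomposed syllables via the U+AC00 formula.

.choseong <- c("ㄱ", "ㄲ", "ㄴ", "ㄷ", "ㄸ", "ㄹ",
               "ㅁ", "ㅂ", "ㅃ", "ㅅ", "ㅆ", "ㅇ",
               "ㅈ", "ㅉ", "ㅊ", "ㅋ", "ㅌ", "ㅍ",
               "ㅎ")

.jungseong <- c("ㅏ", "ㅐ", "ㅑ", "ㅒ", "ㅓ", "ㅔ",
                "ㅕ", "ㅖ", "ㅗ", "ㅘ", "ㅙ", "ㅚ",
                "ㅛ", "ㅜ", "ㅝ", "ㅞ", "ㅟ", "ㅠ",
                "ㅡ", "ㅢ", "ㅣ")

.jongseong <- c("ㄱ", "ㄲ", "ㄳ", "ㄴ", "ㄵ", "ㄶ",
                "ㄷ", "ㄹ", "ㄺ", "ㄻ", "ㄼ", "ㄽ",
                "ㄾ", "ㄿ", "ㅀ", "ㅁ", "ㅂ", "ㅄ",
                "ㅅ", "ㅆ", "ㅇ", "ㅈ", "ㅊ", "ㅋ",
                "ㅌ", "ㅍ", "ㅎ")

# compound finals: first+second component -> compound jamo
.compound_finals <- c(
  "ㄱㅅ" = "ㄳ", "ㄴㅈ" = "ㄵ",
  "ㄴㅎ" = "ㄶ", "ㄹㄱ" = "ㄺ",
  "ㄹㅁ" = "ㄻ", "ㄹㅂ" = "ㄼ",
  "ㄹㅅ" = "ㄽ", "ㄹㅌ" = "ㄾ",
  "ㄹㅍ" = "ㄿ", "ㄹㅎ" = "ㅀ",
  "ㅂㅅ" = "ㅄ")

# compound vowels -> constituent simple vowels (plain-keyboard splitting)
.compound_vowels <- list(
  "ㅘ" = c("ㅗ", "ㅏ"), "ㅙ" = c("ㅗ", "ㅐ"),
  "ㅚ" = c("ㅗ", "ㅣ"), "ㅝ" = c("ㅜ", "ㅓ"),
  "ㅞ" = c("ㅜ", "ㅔ"), "ㅟ" = c("ㅜ", "ㅣ"),
  "ㅢ" = c("ㅡ", "ㅣ"))

# Cheonjiin vowel-element table: sequences over {human I, heaven dot,
# earth EU} -> resolved medial vowel. Compounds concatenate their
# constituents' sequences.
.vowel_table <- local({
  I <- "ㅣ"; D <- "ㆍ"; E <- "ㅡ"
  p <- function(...) paste0(...)
  seqs <- c(I, E,
            p(I, D), p(I, D, D), p(D, I), p(D, D, I),
            p(D, E), p(D, D, E), p(E, D), p(E, D, D),
            p(I, D, I), p(I, D, D, I), p(D, I, I), p(D, D, I, I),
            p(E, I),
            p(D, E, I), p(E, D, I),
            p(D, E, I, D), p(D, E, I, D, I),
            p(E, D, D, I), p(E, D, D, I, I))
  vowels <- c("ㅣ", "ㅡ",
              "ㅏ", "ㅑ", "ㅓ", "ㅕ",
              "ㅗ", "ㅛ", "ㅜ", "ㅠ",
              "ㅐ", "ㅒ", "ㅔ", "ㅖ",
              "ㅢ",
              "ㅚ", "ㅟ",
              "ㅘ", "ㅙ",
              "ㅝ", "ㅞ")
  stats::setNames(vowels, seqs)
})

#' Compose a precomposed Hangul syllable from jamo
#'
#' Applies the Unicode Hangul composition formula: code point =
#' 0xAC00 + (L_index * 21 + V_index) * 28 + T_index, where L is one of the
#' 19 initial consonants, V one of the 21 medial vowels and T one of the 27
#' final consonants (or absent).
#'
#' @param L initial consonant (compatibility jamo character).
#' @param V medial vowel.
#' @param T_ optional final consonant (`NULL` or `NA` for none).
#' @return a single precomposed Hangul character.
#' @export
compose_syllable <- function(L, V, T_ = NULL) {
  li <- match(L, .choseong)
  vi <- match(V, .jungseong)
  if (is.na(li)) stop("not a valid initial consonant: ", L)
  if (is.na(vi)) stop("not a valid medial vowel: ", V)
  ti <- 0L
  if (!is.null(T_) && !is.na(T_) && nzchar(T_)) {
    ti <- match(T_, .jongseong)
    if (is.na(ti)) stop("not a valid final consonant: ", T_)
  }
  intToUtf8(0xAC00 + ((li - 1L) * 21L + (vi - 1L)) * 28L + ti)
}

#' Decompose a precomposed Hangul syllable into jamo
#'
#' Inverse of [compose_syllable()].
#'
#' @param ch a single Hangul syllable character (U+AC00..U+D7A3).
#' @return a list with `L`, `V` and `T` (`NA` when no final).
#' @export
decompose_syllable <- function(ch) {
  cp <- utf8ToInt(ch)
  if (length(cp) != 1L || cp < 0xAC00 || cp > 0xD7A3) {
    stop("not a precomposed Hangul syllable: ", ch)
  }
  s <- cp - 0xAC00
  ti <- s %% 28L
  vi <- (s %/% 28L) %% 21L
  li <- s %/% (28L * 21L)
  list(L = .choseong[li + 1L], V = .jungseong[vi + 1L],
       T = if (ti > 0) .jongseong[ti] else NA_character_)
}

#' Resolve a Cheonjiin vowel-element sequence
#'
#' Table-driven resolution of an ordered sequence over the three vowel
#' elements (human ㅣ, heaven ㆍ, earth ㅡ) into a medial vowel.
#' Compound vowels concatenate their constituents' sequences. A sequence
#' that is a proper prefix of a table entry is returned as a partial.
#'
#' @param elements character vector of elements, each one of `"ㅣ"`,
#'   `"ㆍ"`, `"ㅡ"`.
#' @return a list with `vowel` (resolved medial, or `NA`), `partial`
#'   (`TRUE` if the sequence can still be extended to a longer vowel) and
#'   `valid` (`FALSE` if the sequence matches no table prefix at all).
#' @export
resolve_vowel <- function(elements) {
  stopifnot(length(elements) >= 1,
            all(elements %in% c("ㅣ", "ㆍ", "ㅡ")))
  s <- paste0(elements, collapse = "")
  keys <- names(.vowel_table)
  exact <- match(s, keys)
  extendable <- any(startsWith(keys, s) & nchar(keys) > nchar(s))
  list(vowel = if (!is.na(exact)) unname(.vowel_table[exact]) else
         NA_character_,
       partial = extendable,
       valid = !is.na(exact) || extendable)
}

# vowel -> element sequence (character vector), for the typing planner
vowel_elements_of <- function(vowel) {
  i <- match(vowel, .vowel_table)
  if (is.na(i)) stop("vowel has no Cheonjiin element sequence: ", vowel)
  strsplit(names(.vowel_table)[i], "")[[1]]
}

split_compound_final <- function(jamo) {
  i <- match(jamo, .compound_finals)
  if (is.na(i)) jamo else strsplit(names(.compound_finals)[i], "")[[1]]
}
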