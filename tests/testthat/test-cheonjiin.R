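lay <- default_layout()

test_that("the default grid has 14 keys with the vowel-element top row", {
  expect_equal(layout_key_count(lay), 14)
  expect_equal(lay$grid[[1]][[1]]$taps, "ㅣ")
  expect_equal(lay$grid[[1]][[2]]$taps, "ㆍ")
  expect_equal(lay$grid[[1]][[3]]$taps, "ㅡ")
  expect_equal(lay$grid[[1]][[4]]$action, "DELETE")
  # every plain consonant is reachable through some tap cycle
  cycle_jamo <- unlist(lapply(ssvepspeller:::layout_positions(lay),
                              function(p) lay$grid[[p[1]]][[p[2]]]$taps))
  need <- c("ㄱ", "ㄴ", "ㄷ", "ㅂ", "ㅅ", "ㅈ", "ㅇ", "ㅁ", "ㄹ",
            "ㅋ", "ㅌ", "ㅍ", "ㅎ", "ㅊ")
  expect_true(all(need %in% cycle_jamo))
})

test_that("cursor movement clamps at edges and skips empty cells", {
  expect_equal(move_cursor(lay, c(1, 1), "LEFT"), c(1L, 1L))
  expect_equal(move_cursor(lay, c(1, 1), "UP"), c(1L, 1L))
  expect_equal(move_cursor(lay, c(1, 1), "DOWN"), c(2L, 1L))
  # (4,2) is the ㅇㅁ key flanked by empty cells: LEFT clamps (nothing
  # occupied further left), RIGHT skips the empty cell to the period key
  expect_equal(move_cursor(lay, c(4, 2), "LEFT"), c(4L, 2L))
  expect_equal(move_cursor(lay, c(4, 2), "RIGHT"), c(4L, 4L))
  # moving down column 1 skips the empty (4,1) cell and clamps at row 3
  expect_equal(move_cursor(lay, c(3, 1), "DOWN"), c(3L, 1L))
})

test_that("random walks never land on an empty cell", {
  set.seed(30)
  pos <- lay$home
  for (i in 1:1000) {
    pos <- move_cursor(lay, pos, sample(c("UP", "DOWN", "LEFT", "RIGHT"), 1))
    expect_false(is.null(ssvepspeller:::layout_key_at(lay, pos)))
  }
})

test_that("syllable assembly matches the Unicode composition formula and NFC", {
  expect_equal(compose_syllable("ㄱ", "ㅏ"), "가")
  expect_equal(utf8ToInt(compose_syllable("ㄱ", "ㅏ")), 0xAC00)
  expect_equal(compose_syllable("ㅁ", "ㅓ"), "머")
  expect_equal(compose_syllable("ㅇ", "ㅏ", "ㄴ"), "안")
  skip_if_not_installed("stringi")
  expect_equal(compose_syllable("ㅁ", "ㅓ"),
               stringi::stri_trans_nfc(conjoining_sequence("ㅁ", "ㅓ")))
  expect_equal(compose_syllable("ㅇ", "ㅏ", "ㄴ"),
               stringi::stri_trans_nfc(conjoining_sequence("ㅇ", "ㅏ", "ㄴ")))
  expect_error(compose_syllable("ㅏ", "ㄱ"), "initial")
})

test_that("vowel-element sequences resolve through the Cheonjiin table", {
  expect_equal(resolve_vowel(c("ㆍ", "ㅣ"))$vowel, "ㅓ")
  expect_equal(resolve_vowel("ㅣ")$vowel, "ㅣ")
  expect_equal(resolve_vowel(c("ㆍ", "ㅣ", "ㅣ"))$vowel, "ㅔ")
  expect_equal(resolve_vowel(c("ㆍ", "ㅡ", "ㅣ", "ㆍ"))$vowel, "ㅘ")
  # lone heaven dot is a partial, extendable sequence
  p <- resolve_vowel("ㆍ")
  expect_true(is.na(p$vowel) && p$partial && p$valid)
  # every medial vowel has an element sequence that resolves back to it
  for (v in ssvepspeller:::.jungseong) {
    expect_equal(resolve_vowel(ssvepspeller:::vowel_elements_of(v))$vowel, v)
  }
})

press_at <- function(state, r, c) press_key(state, lay$grid[[r]][[c]])

test_that("multi-tap consonants cycle in place and commit on other input", {
  st <- composer_state()
  st <- press_at(st, 4, 2)                     # ㅇ
  expect_equal(composer_text(st), "ㅇ")
  st <- press_at(st, 4, 2)                     # -> ㅁ
  expect_equal(composer_text(st), "ㅁ")
  st <- press_at(st, 1, 2)                     # ㆍ
  st <- press_at(st, 1, 1)                     # ㅣ => ㅓ
  expect_equal(composer_text(st), "머")
  # SELECT twice on the ㄴㄹ key with no intervening move shows ㄹ
  st2 <- composer_state()
  st2 <- press_at(st2, 2, 2); st2 <- press_at(st2, 2, 2)
  expect_equal(composer_text(st2), "ㄹ")
  # a cursor move commits the cycle: the next press restarts it
  st3 <- composer_disarm(press_at(composer_state(), 2, 1))   # ㄱ, disarmed
  st3 <- press_at(st3, 2, 1)
  expect_equal(composer_text(st3), "ㄱㄱ")
})

test_that("the worked word presses compose and ENTER commits", {
  st <- composer_state()
  st <- press_at(st, 4, 2); st <- press_at(st, 4, 2)   # ㅁ
  st <- press_at(st, 1, 2); st <- press_at(st, 1, 1)   # ㅓ
  st <- press_at(st, 2, 2); st <- press_at(st, 2, 2)   # ㄹ
  st <- press_at(st, 1, 1)                             # ㅣ (steals ㄹ)
  expect_equal(composer_text(st), "머리")
  st <- press_key(st, lay$grid[[3]][[4]])              # ENTER commits
  expect_equal(st$committed, "머리")
  expect_equal(composer_text(composer_state()), "")
})

test_that("DELETE undoes the last jamo or element insertion", {
  seqs <- list(
    list(c(2, 1)),                        # lone consonant
    list(c(1, 2)),                        # lone element
    list(c(2, 1), c(1, 1), c(1, 2)),      # ㄱ + ㅏ
    list(c(2, 1), c(1, 1), c(1, 2), c(2, 2)),          # 간
    list(c(2, 1), c(1, 1), c(1, 2), c(2, 2), c(3, 2))  # 갅
  )
  for (s in seqs) {
    st <- composer_state()
    for (p in s[-length(s)]) st <- press_key(st, lay$grid[[p[1]]][[p[2]]])
    before <- composer_text(st)
    p <- s[[length(s)]]
    st <- press_key(st, lay$grid[[p[1]]][[p[2]]])
    st <- press_key(st, lay$grid[[1]][[4]])            # DELETE
    expect_equal(composer_text(st), before)
  }
})

test_that("resyllabification keeps hard words intact", {
  # 핥: the ㅌ of the ㄾ final needs a multi-tap through ㄷ, which
  # transiently opens a new syllable and must merge back
  p <- type_text_plan("핥", lay)
  expect_equal(execute_commands(lay, p$commands)$text, "핥")
  for (w in c("닭", "값", "없다", "있었다", "안녕하세요", "바빠요",
              "각각", "머리")) {
    p <- type_text_plan(w, lay)
    expect_equal(execute_commands(lay, p$commands)$text, w)
  }
})
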