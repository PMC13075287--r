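test_that("a frequency above threshold in enough updates is emitted once, then suppressed", {
  # 12 Hz at rho 0.4 in 12 of every 30 updates, everything else below 0.25
  m <- constructed_profiles(120, list(list(rows = rep(1:12, 4) +
                                             rep(c(0, 30, 60, 90), each = 12),
                                           col = 5, rho = 0.4)))
  t_s <- seq(0.05, by = 0.05, length.out = 120)
  ev <- decode_profiles(m, decision_config(), t_s = t_s)
  expect_true(all(ev$command == "SELECT"))
  expect_gte(nrow(ev), 2)
  # never closer than the 1 s ignore interval even though 12 Hz persists
  expect_true(all(diff(ev$t_s) >= 1.0 - 1e-9))
})

test_that("no command is issued when nothing reaches threshold consistently", {
  m <- constructed_profiles(30, base = 0.2)
  ev <- decode_profiles(m, t_s = seq(0.05, by = 0.05, length.out = 30))
  expect_equal(nrow(ev), 0)
  # 8 of 30 hits is one short of ceiling(0.30 * 30) = 9
  m8 <- constructed_profiles(30, list(list(rows = 1:8, col = 5, rho = 0.9)))
  expect_equal(nrow(decode_profiles(
    m8, t_s = seq(0.05, by = 0.05, length.out = 30))), 0)
  # 9 of 30 is exactly enough
  m9 <- constructed_profiles(30, list(list(rows = 1:9, col = 5, rho = 0.9)))
  expect_equal(decode_profiles(
    m9, t_s = seq(0.05, by = 0.05, length.out = 30))$command, "SELECT")
})

test_that("among valid candidates the highest mean accumulated correlation wins", {
  # 10 Hz: mean 0.35 over 10 hits; 12 Hz: mean 0.30 over 11 hits -> LEFT
  m <- constructed_profiles(30, list(
    list(rows = 1:10, col = 4, rho = 0.35),
    list(rows = 1:11, col = 5, rho = 0.30)))
  ev <- decode_profiles(m, t_s = seq(0.05, by = 0.05, length.out = 30))
  expect_equal(ev$command, "LEFT")
  # exact mean tie -> lowest frequency index
  mt <- constructed_profiles(30, list(
    list(rows = 1:10, col = 1, rho = 0.4),
    list(rows = 1:10, col = 5, rho = 0.4)))
  expect_equal(decode_profiles(
    mt, t_s = seq(0.05, by = 0.05, length.out = 30))$command, "UP")
})

test_that("decision_update enforces time order and matches decode_profiles", {
  cfg <- decision_config()
  st <- decision_state(cfg)
  p <- stats::setNames(rep(0.1, 5), stimulus_frequencies())
  r <- decision_update(st, p, t_s = 0.05)
  expect_null(r$command)
  expect_error(decision_update(r$state, p, t_s = 0.05), "increasing")
  # stepwise updates agree with the bulk decoder
  m <- constructed_profiles(60, list(list(rows = 5:20, col = 3, rho = 0.5)))
  t_s <- seq(0.05, by = 0.05, length.out = 60)
  bulk <- decode_profiles(m, cfg, t_s = t_s)
  st <- decision_state(cfg)
  got <- character(0)
  for (i in 1:60) {
    r <- decision_update(st, m[i, ], t_s = t_s[i])
    st <- r$state
    if (!is.null(r$command)) got <- c(got, r$command)
  }
  expect_equal(got, bulk$command)
})

test_that("emissions are rate-limited on arbitrary correlation streams", {
  set.seed(20)
  for (rep in 1:5) {
    m <- matrix(runif(400 * 5, 0, 0.6), 400, 5)
    colnames(m) <- as.character(stimulus_frequencies())
    ev <- decode_profiles(m, t_s = seq(0.05, by = 0.05, length.out = 400))
    if (nrow(ev) > 1) expect_true(all(diff(ev$t_s) >= 1.0 - 1e-9))
  }
})

test_that("run-length consistency mode requires consecutive hits", {
  # 9 scattered hits qualify under the fraction reading but the longest
  # run is 5, so the run reading stays silent
  rows <- c(1, 4, 7, 10, 13, 16, 19, 22, 25)
  m <- constructed_profiles(30, list(list(rows = rows, col = 2, rho = 0.5)))
  t_s <- seq(0.05, by = 0.05, length.out = 30)
  expect_equal(decode_profiles(m, decision_config(), t_s = t_s)$command,
               "RIGHT")
  expect_equal(nrow(decode_profiles(
    m, decision_config(consistency_mode = "run"), t_s = t_s)), 0)
  # 9 consecutive hits satisfy both
  m9 <- constructed_profiles(30, list(list(rows = 11:19, col = 2,
                                           rho = 0.5)))
  expect_equal(decode_profiles(
    m9, decision_config(consistency_mode = "run"), t_s = t_s)$command,
    "RIGHT")
})

test_that("sliding collection mode can emit between block boundaries", {
  # hits straddle a block boundary: the first block sees only 6 of the 16
  # hits, so the block decoder waits for the second block, while sliding
  # evaluation reaches 9-in-window much earlier
  m <- constructed_profiles(60, list(list(rows = 25:40, col = 1, rho = 0.5)))
  t_s <- seq(0.05, by = 0.05, length.out = 60)
  ev_block <- decode_profiles(m, decision_config(), t_s = t_s)
  ev_slide <- decode_profiles(m, decision_config(collection = "sliding"),
                              t_s = t_s)
  expect_equal(ev_block$command, "UP")
  expect_equal(ev_slide$command[1], "UP")
  expect_lt(ev_slide$t_s[1], ev_block$t_s[1])
})
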