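test_that("reference matrices are sine-cosine pairs from t = 0", {
  Y <- reference_matrix(12, 200, 300)
  expect_equal(dim(Y), c(300, 2))
  expect_equal(Y[1, ], c(0, 1))
  # integer number of cycles in the window -> orthogonal columns
  for (f in c(10, 12, 8)) {
    Yk <- reference_matrix(f, 200, 300)
    expect_lt(abs(sum(Yk[, 1] * Yk[, 2])) / 300, 1e-10)
  }
  # second harmonic of 6.67 Hz oscillates at ~13.33 Hz
  Y2 <- reference_matrix(6.67, 200, 300, n_harmonics = 2)
  zc <- sum(diff(sign(Y2[, 3])) != 0)
  expect_equal(zc, 2 * floor(2 * 6.67 * 1.5), tolerance = 1)
  expect_error(reference_matrix(60, 200, 300, n_harmonics = 2), "Nyquist")
})

test_that("canonical correlation is exact on constructed cases", {
  set.seed(10)
  Y <- matrix(rnorm(150), 50, 3)
  # X equal to one reference column -> perfect correlation
  r <- canonical_correlation(Y[, 1, drop = FALSE] + 2, Y)
  expect_equal(r$rho, 1, tolerance = 1e-9)
  # invariance under invertible channel mixing
  X <- matrix(rnorm(100), 50, 2)
  A <- matrix(c(2, 1, -1, 0.5), 2, 2)
  expect_equal(canonical_correlation(X %*% A, Y)$rho,
               canonical_correlation(X, Y)$rho, tolerance = 1e-9)
  # rho = |corr(X w_x, Y w_y)| at the returned weights
  r2 <- canonical_correlation(X, Y)
  u <- scale(X, scale = FALSE) %*% r2$w_x
  v <- scale(Y, scale = FALSE) %*% r2$w_y
  expect_equal(abs(stats::cor(u, v))[1, 1], r2$rho, tolerance = 1e-9)
  # rank-deficient input must not crash
  Xd <- cbind(X[, 1], X[, 1])
  expect_no_error(canonical_correlation(Xd, Y))
})

test_that("canonical correlation matches independent eigen and optimization oracles", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:50, 1)
    C <- sample(1:3, 1); M <- sample(1:3, 1)
    X <- matrix(rnorm(n * C), n, C)
    Y <- matrix(rnorm(n * M), n, M)
    expect_equal(canonical_correlation(X, Y)$rho,
                 stats::cancor(X, Y)$cor[1], tolerance = 1e-6)
  }
  # a handful of direct-optimization cross-checks
  set.seed(12)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 2), 40, 2)
    Y <- matrix(rnorm(40 * 2), 40, 2)
    expect_equal(canonical_correlation(X, Y)$rho,
                 oracle_cca_optim(X, Y, seed = i), tolerance = 1e-5)
  }
})

test_that("correlation profiles pick the attended frequency at high SNR", {
  ch <- filter_chain()
  refs <- reference_set()
  for (s in 1:20) {
    ep <- simulate_ssvep_epoch(high_snr_sim_config(), 10, 1.5, seed = s)
    pr <- correlation_profile(apply_filter_chain(ep, ch), refs)
    expect_equal(classify_frequency(pr), 10)
  }
})

test_that("single-channel windows make per-channel-max and joint modes agree", {
  refs <- reference_set()
  ep <- simulate_ssvep_epoch(sim_config(n_channels = 1), 12, 1.5, seed = 3)
  a <- correlation_profile(ep, refs, mode = "per_channel_max")
  b <- correlation_profile(ep, refs, mode = "joint")
  expect_equal(a$rho_by_freq, b$rho_by_freq, tolerance = 1e-9)
})

test_that("classify_frequency takes the argmax with lowest-frequency ties", {
  f <- stimulus_frequencies()
  p <- stats::setNames(c(0.1, 0.2, 0.6, 0.2, 0.1), f)
  expect_equal(classify_frequency(p), 8.57)
  tie <- stats::setNames(c(0.5, 0.5, 0.1, 0.1, 0.1), f)
  expect_equal(classify_frequency(tie), 6.67)
  # exhaustive argmax agreement on a fixed synthetic profile set
  set.seed(4)
  for (i in 1:20) {
    p <- stats::setNames(runif(5), f)
    expect_equal(classify_frequency(p), f[which.max(p)])
  }
})

test_that("the vectorized stream decoder equals the per-window path", {
  cfg <- sim_config(seed = 9)
  st <- simulate_session(protocol_script(c("LEFT", "SELECT"), dwell_s = 2),
                         cfg)
  filt <- apply_filter_chain(st$samples, filter_chain())
  refs <- reference_set()
  fast <- stream_correlation_profiles(filt, refs, fs_hz = 200)
  wins <- sliding_windows(filt, fs_hz = 200)
  for (i in c(1, 17, 53, length(wins))) {
    slow <- correlation_profile(
      signal_window(wins[[i]]$samples, 200, wins[[i]]$t_start_s), refs)
    expect_equal(unname(fast$rho[i, ]), unname(slow$rho_by_freq),
                 tolerance = 1e-9)
    expect_equal(fast$t_s[i], slow$t_s, tolerance = 1e-9)
  }
})
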