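test_that("confusion matrices count pairs with matching marginals", {
  cm <- confusion_matrix(rep(speller_commands(), 2),
                         rep(speller_commands(), 2))
  expect_equal(sum(diag(cm)), 10)
  cm2 <- confusion_matrix(c("UP", "UP", "DOWN"), c("UP", "DOWN", "DOWN"))
  expect_equal(cm2["UP", "DOWN"], 1L, ignore_attr = TRUE)
  set.seed(50)
  tr <- sample(speller_commands(), 500, replace = TRUE)
  pr <- sample(speller_commands(), 500, replace = TRUE)
  cm3 <- confusion_matrix(tr, pr)
  expect_equal(sum(cm3), 500)
  expect_equal(unname(rowSums(cm3)), unname(table(factor(
    tr, levels = speller_commands()))), ignore_attr = TRUE)
  expect_error(confusion_matrix("UP", c("UP", "DOWN")), "length")
  expect_error(confusion_matrix("UP", "JUMP"), "JUMP")
})

test_that("classification metrics evaluate the standard formulas", {
  perfect <- confusion_matrix(rep(speller_commands(), 3),
                              rep(speller_commands(), 3))
  m <- classification_metrics(perfect)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1),
               rep(100, 4))
  # binary toy: TP=8, FN=2, FP=1, TN=9
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  mb <- classification_metrics(cm)
  pos <- mb$per_class[mb$per_class$class == "pos", ]
  expect_equal(pos$precision, 100 * 8 / 9, tolerance = 1e-6)   # 88.89%
  expect_equal(pos$recall, 80, tolerance = 1e-6)
  expect_equal(pos$f1, 2 * (800 / 9) * 80 / (800 / 9 + 80),
               tolerance = 1e-4)                               # 84.21%
  # permutation symmetry of the macro averages
  set.seed(51)
  cmr <- matrix(rpois(25, 10), 5, 5,
                dimnames = list(speller_commands(), speller_commands()))
  perm <- c(3, 1, 5, 2, 4)
  mp <- classification_metrics(cmr[perm, perm])
  mo <- classification_metrics(cmr)
  expect_equal(mp$accuracy, mo$accuracy)
  expect_equal(mp$precision, mo$precision)
  expect_equal(mp$f1, mo$f1)
  # accuracy equals micro-recall (pooled TP over total)
  expect_equal(mo$accuracy, 100 * sum(diag(cmr)) / sum(cmr))
  # a class never predicted warns and gets precision 0
  cz <- matrix(c(2, 3, 0, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(mz <- classification_metrics(cz), "precision")
  expect_equal(mz$per_class$precision[mz$per_class$class == "b"], 0)
})

test_that("the ITR formula reproduces its closed-form anchors", {
  expect_equal(itr_bits_per_min(0.83, 5, 2.5), 31.8, tolerance = 0.05)
  expect_equal(itr_bits_per_min(0.2, 5, 1.7), 0)
  expect_equal(itr_bits_per_min(1, 5, 2.5), log2(5) * 24, tolerance = 1e-9)
  # P = 0 is handled analytically (0 log 0 := 0); closed form remains
  expect_equal(itr_bits_per_min(0, 5, 2.5),
               (log2(5) + log2(1 / 4)) * 24, tolerance = 1e-9)
})

test_that("ITR is increasing in accuracy above chance and scales as 1/T", {
  p_grid <- seq(0.25, 1, by = 0.05)
  v <- vapply(p_grid, itr_bits_per_min, numeric(1), n_commands = 5,
              t_s = 2.5)
  expect_true(all(diff(v) > 0))
  for (p in c(0.4, 0.83)) {
    expect_equal(itr_bits_per_min(p, 5, 1.25),
                 2 * itr_bits_per_min(p, 5, 2.5), tolerance = 1e-12)
  }
})

test_that("amplitude spectra are amplitude-true and satisfy Parseval", {
  t <- (0:399) / 200
  sp <- amplitude_spectrum(sin(2 * pi * 10 * t), fs_hz = 200)
  i10 <- which(sp$freqs_hz == 10)
  expect_equal(sp$amplitude[i10, 1], 1, tolerance = 1e-6)
  expect_lt(max(sp$amplitude[-i10, 1]), 1e-6)
  mix <- 0.5 * sin(2 * pi * 10 * t) + 0.25 * sin(2 * pi * 20 * t)
  spm <- amplitude_spectrum(mix, fs_hz = 200)
  expect_equal(spm$amplitude[spm$freqs_hz == 10, 1], 0.5, tolerance = 1e-6)
  expect_equal(spm$amplitude[spm$freqs_hz == 20, 1], 0.25, tolerance = 1e-6)
  expect_equal(max(amplitude_spectrum(rep(0, 400), fs_hz = 200)$amplitude),
               0)
  # Parseval: mean square power from the one-sided amplitude spectrum
  set.seed(52)
  x <- rnorm(400)
  spx <- amplitude_spectrum(x, fs_hz = 200)
  a <- spx$amplitude[, 1]
  n <- length(a)
  pw <- a[1]^2 + a[n]^2 + sum(a[2:(n - 1)]^2 / 2)
  expect_equal(pw, mean(x^2), tolerance = 1e-6)
})

test_that("SNR compares the peak to masked neighbor bins", {
  t <- (0:799) / 200
  sp <- amplitude_spectrum(sin(2 * pi * 12 * t), fs_hz = 200)
  expect_equal(snr_at(sp, 12), 100)                     # zero floor, capped
  # synthetic flat floor at 0.1 around a unit tone -> 20 dB
  flat <- sp
  flat$amplitude[] <- 0.1
  flat$amplitude[which.min(abs(flat$freqs_hz - 12)), 1] <- 1
  expect_equal(snr_at(flat, 12), 20, tolerance = 1e-9)
  # white noise: SNR distribution centered near 0 dB
  set.seed(53)
  v <- vapply(1:100, function(i) {
    snr_at(amplitude_spectrum(rnorm(800), fs_hz = 200), 12)
  }, numeric(1))
  expect_lt(abs(mean(v)), 3)
  expect_error(snr_at(sp, 150), "range")
})

test_that("ERSP shows time-locked enhancement for intermittent flicker", {
  # the representative 12 Hz protocol: baseline -2..0 s, stimulation on at
  # 0-1, 2-3, 4-6 and 7-10 s
  on <- matrix(c(0, 1, 2, 3, 4, 6, 7, 10), ncol = 2, byrow = TRUE)
  make_epochs <- function(gain, seeds) {
    lapply(seeds, function(s) {
      simulate_ssvep_epoch(high_snr_sim_config(gain = gain), 12,
                           duration_s = 12, seed = s, t_start_s = -2,
                           on_intervals = on)
    })
  }
  ep <- make_epochs(3, 1:10)
  m <- ersp(ep, baseline_s = c(-2, 0))
  row12 <- which.min(abs(m$freqs_hz - 12))
  # interior masks avoid smearing across on/off transitions
  on_cols <- m$t_s > 0.4 & m$t_s < 0.8
  on_cols <- on_cols | (m$t_s > 4.4 & m$t_s < 5.6) |
    (m$t_s > 7.4 & m$t_s < 9.6)
  off_cols <- (m$t_s > 1.4 & m$t_s < 1.6) | (m$t_s > 3.4 & m$t_s < 3.6) |
    (m$t_s > 6.4 & m$t_s < 6.6)
  expect_gt(mean(m$db[row12, on_cols]), 3)
  expect_lt(abs(mean(m$db[row12, off_cols])), 1.5)
  # doubling the signal power (amplitude x sqrt(2)) raises the on-interval
  # enhancement by about 3 dB
  m2 <- ersp(make_epochs(3 * sqrt(2), 1:10), baseline_s = c(-2, 0))
  expect_equal(mean(m2$db[row12, on_cols]) - mean(m$db[row12, on_cols]),
               3, tolerance = 1.2)
  expect_error(ersp(ep, baseline_s = c(-5, 0)), "outside")
})

test_that("stationary noise yields a flat ERSP map", {
  eps <- lapply(1:20, function(s) {
    simulate_ssvep_epoch(sim_config(ssvep_amp_uV = c(0, 0, 0)), NULL,
                         duration_s = 6, seed = s, t_start_s = -2)
  })
  m <- ersp(eps, baseline_s = c(-2, 0))
  # no systematic structure: the map is flat up to averaging noise
  expect_lt(stats::median(abs(m$db)), 1)
  expect_lt(stats::quantile(abs(m$db), 0.95), 3)
})
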