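# Independent oracles and fixture builders used across the suite.

# Direct numerical maximization of |corr(X w_x, Y w_y)| over unit-sphere
# weights (multi-start Nelder-Mead), independent of the package's eigen
# solver. Only sensible for small C, M.
oracle_cca_optim <- function(X, Y, n_starts = 8, seed = 1) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  obj <- function(par) {
    wx <- par[seq_len(ncol(Xc))]
    wy <- par[ncol(Xc) + seq_len(ncol(Yc))]
    if (sum(wx^2) < 1e-12 || sum(wy^2) < 1e-12) return(0)
    u <- Xc %*% wx; v <- Yc %*% wy
    su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
    if (su < 1e-12 || sv < 1e-12) return(0)
    -abs(sum(u * v) / (su * sv))
  }
  set.seed(seed)
  best <- 0
  for (s in seq_len(n_starts)) {
    p0 <- stats::rnorm(ncol(Xc) + ncol(Yc))
    r <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- max(best, -r$value)
  }
  best
}

# conjoining-jamo (U+1100 block) sequence for a syllable, for the NFC oracle
conjoining_sequence <- function(L, V, T_ = NA) {
  li <- match(L, ssvepspeller:::.choseong) - 1L
  vi <- match(V, ssvepspeller:::.jungseong) - 1L
  s <- intToUtf8(c(0x1100 + li, 0x1161 + vi))
  if (!is.na(T_)) {
    ti <- match(T_, ssvepspeller:::.jongseong)
    s <- paste0(s, intToUtf8(0x11A7 + ti))
  }
  s
}

# random Hangul string over the full supported jamo inventory
rand_hangul_string <- function(n_syllables, p_final = 0.4) {
  syl <- vapply(seq_len(n_syllables), function(i) {
    L <- sample(ssvepspeller:::.choseong, 1)
    V <- sample(ssvepspeller:::.jungseong, 1)
    T_ <- if (stats::runif(1) < p_final) sample(ssvepspeller:::.jongseong, 1)
          else NA
    compose_syllable(L, V, T_)
  }, character(1))
  paste0(syl, collapse = "")
}

# per-update correlation-profile matrix with given per-frequency hit
# patterns; rows = updates, cols = the five stimulus frequencies
constructed_profiles <- function(n_updates, hits = list(), base = 0.1) {
  m <- matrix(base, n_updates, 5,
              dimnames = list(NULL, as.character(stimulus_frequencies())))
  for (h in hits) m[h$rows, h$col] <- h$rho
  m
}
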