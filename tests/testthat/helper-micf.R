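# shared helpers for the micf test suite

# band power of a single series via a padded periodogram
band_power <- function(x, rate, band) {
  m <- stats::nextn(length(x))
  P <- Mod(stats::fft(c(x, rep(0, m - length(x)))))^2 / m
  f <- (seq_len(m) - 1) * rate / m
  sum(P[f >= band[1] & f <= band[2]])
}

# construct a trial set directly from a list of epochs
mk_trials <- function(epochs, condition, rate = 250,
                      labels = paste0("ch", seq_len(nrow(epochs[[1]])))) {
  micf:::trialset(epochs, condition, labels, rate,
                  subject_id = "T00", group_tag = "test")
}

# independent straight-line Welch msc oracle (8 Hamming segments, 50%
# overlap, 256-point transforms) used to cross-check coherence_binned
oracle_msc <- function(x, y, rate) {
  n <- length(x)
  seg <- floor(2 * n / 9); hop <- floor(seg / 2)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  nfft <- 256
  sxx <- syy <- numeric(nfft / 2 + 1)
  sxy <- complex(real = numeric(nfft / 2 + 1))
  for (s in seq(1, n - seg + 1, by = hop)[1:8]) {
    a <- (x[s:(s + seg - 1)] - mean(x[s:(s + seg - 1)])) * w
    b <- (y[s:(s + seg - 1)] - mean(y[s:(s + seg - 1)])) * w
    A <- stats::fft(c(a, rep(0, nfft - seg)))[1:(nfft / 2 + 1)]
    B <- stats::fft(c(b, rep(0, nfft - seg)))[1:(nfft / 2 + 1)]
    sxx <- sxx + Mod(A)^2; syy <- syy + Mod(B)^2; sxy <- sxy + A * Conj(B)
  }
  list(freq = (0:(nfft / 2)) * rate / nfft,
       msc = Mod(sxy)^2 / (sxx * syy))
}

# simulate a bivariate VAR with known coefficient matrices (list of
# 2 x 2 lags), unit innovations
sim_var <- function(A, n, burn = 50) {
  p <- length(A)
  x <- matrix(0, 2, n + burn)
  e <- matrix(stats::rnorm(2 * (n + burn)), 2)
  for (t in (p + 1):(n + burn)) {
    acc <- e[, t]
    for (m in seq_len(p)) acc <- acc + A[[m]] %*% x[, t - m]
    x[, t] <- acc
  }
  x[, (burn + 1):(burn + n), drop = FALSE]
}
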