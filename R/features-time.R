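#' Hjorth parameters per channel
#'
#' Activity is the signal variance; mobility the ratio
#' `sqrt(var(dx)/var(x))` with `dx` the first difference; complexity the
#' mobility of `dx` divided by the mobility of `x`. Zero-variance
#' channels yield activity 0 with mobility/complexity undefined (`NA`).
#'
#' @param epoch Channels x samples numeric matrix (>= 3 samples).
#' @return Matrix with rows `activity`, `mobility`, `complexity` and one
#'   column per channel.
#' @export
hjorth <- function(epoch) {
  epoch <- as.matrix(epoch)
  stopifnot(ncol(epoch) >= 3)
  out <- matrix(NA_real_, 3, nrow(epoch),
                dimnames = list(c("activity", "mobility", "complexity"),
                                rownames(epoch)))
  for (i in seq_len(nrow(epoch))) {
    x <- epoch[i, ]
    v0 <- stats::var(x)
    if (v0 == 0) { out[1, i] <- 0; next }
    d1 <- diff(x); d2 <- diff(d1)
    v1 <- stats::var(d1); v2 <- stats::var(d2)
    mob <- sqrt(v1 / v0)
    out[, i] <- c(v0, mob, sqrt(v2 / v1) / mob)
  }
  out
}

# midpoints of the five classical EEG bands used by the brainrate
brainrate_bands <- cbind(lower = c(1, 4, 8, 13, 20),
                         upper = c(4, 8, 13, 20, 30),
                         mid = c(2.5, 6, 10.5, 16.5, 25))

#' Brainrate (spectrally weighted mean frequency) per channel
#'
#' Weighted mean of the five band midpoints (delta, theta, alpha, beta1,
#' beta2; midpoints 2.5, 6, 10.5, 16.5, 25 Hz), weighted by the relative
#' spectral power of each band over the whole segment.
#'
#' @param epoch Channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector, one value per channel; `NA` for
#'   constant channels.
#' @export
brainrate <- function(epoch, rate) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  nfft <- 2^ceiling(log2(n))
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * rate / nfft
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (i in seq_len(nrow(epoch))) {
    x <- epoch[i, ]
    if (stats::var(x) == 0) next
    X <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
    p <- Mod(X[seq_along(freqs)])^2
    bp <- apply(brainrate_bands, 1, function(b)
      sum(p[freqs >= b["lower"] & freqs < b["upper"]]))
    if (sum(bp) == 0) next
    out[i] <- sum(brainrate_bands[, "mid"] * bp) / sum(bp)
  }
  out
}

#' Wackermann global descriptors
#'
#' Global field strength `sigma` (RMS over channels and time), global
#' frequency `phi = sqrt(m2/m0)/(2*pi)` with `m0`/`m2` the total signal
#' and derivative power summed over channels, and spatial complexity
#' `omega = exp(-sum(l * log(l)))` with `l` the eigenvalues of the
#' channel covariance normalized to unit sum. Omega ranges from 1
#' (rank-one topography) to the channel count (spatially white data).
#' Intended for average-referenced multichannel epochs.
#'
#' @param epoch Channels x samples matrix (>= 2 channels).
#' @param rate Sampling rate in Hz (scales the derivative).
#' @return Named vector `c(sigma, phi, omega)`; `phi`/`omega` are `NA`
#'   on zero data.
#' @export
wackermann <- function(epoch, rate) {
  epoch <- as.matrix(epoch)
  stopifnot(nrow(epoch) >= 2)
  m0 <- sum(rowMeans(epoch^2))
  sigma <- sqrt(m0 / nrow(epoch))
  if (m0 == 0)
    return(c(sigma = 0, phi = NA_real_, omega = NA_real_))
  d <- t(diff(t(epoch))) * rate
  m2 <- sum(rowMeans(d^2))
  phi <- sqrt(m2 / m0) / (2 * pi)
  ev <- eigen(stats::cov(t(epoch)), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0)
    return(c(sigma = sigma, phi = phi, omega = NA_real_))
  l <- ev / sum(ev)
  l <- l[l > 0]
  c(sigma = sigma, phi = phi, omega = exp(-sum(l * log(l))))
}

#' Hurst exponent by rescaled-range analysis, per channel
#'
#' Slope of the least-squares fit of `log(R/S)` against `log(window)`
#' over a dyadic ladder of window lengths (16, 32, ... up to a quarter
#' of the epoch). Around 0.5 for white noise (with the usual small-n
#' upward bias), near 1 for integrated noise.
#'
#' @param epoch Channels x samples matrix (>= 64 samples).
#' @return Named numeric vector of exponents; `NA` for constant
#'   channels.
#' @export
hurst_rs <- function(epoch) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n >= 64)
  sizes <- 2^(4:floor(log2(n / 4)))
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (i in seq_len(nrow(epoch))) {
    x <- epoch[i, ]
    if (stats::var(x) == 0) next
    rs <- vapply(sizes, function(w) {
      nb <- n %/% w
      vals <- vapply(seq_len(nb), function(b) {
        seg <- x[((b - 1) * w + 1):(b * w)]
        s <- stats::sd(seg)
        if (s == 0) return(NA_real_)
        y <- cumsum(seg - mean(seg))
        (max(y) - min(y)) / s
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    ok <- is.finite(rs) & rs > 0
    if (sum(ok) < 2) next
    out[i] <- stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2]
  }
  out
}
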