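#' Bin-averaged FFT magnitude spectrum per channel
#'
#' Magnitude spectrum of a zero-padded 1024-point transform (frequency
#' resolution `rate/1024`, about 0.244 Hz at 250 Hz) averaged within each
#' frequency bin; for the default 12-bin grid and 21 channels this gives
#' the 252-dimensional power-spectrum feature.
#'
#' @param epoch Channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param binning A [frequency_binning()].
#' @param nfft Transform length (zero-padded).
#' @return Channels x bins matrix of bin-averaged magnitudes.
#' @export
fft_binned_power <- function(epoch, rate, binning = frequency_binning(),
                             nfft = 1024) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n <= nfft)
  nfreq <- nfft %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * rate / nfft
  padded <- matrix(0, nfft, nrow(epoch))
  padded[seq_len(n), ] <- t(epoch)
  mag <- Mod(stats::mvfft(padded)[seq_len(nfreq), , drop = FALSE])
  t(bin_average(mag, freqs, binning))
}

#' Bin-averaged magnitude-squared coherence per channel pair
#'
#' Welch estimate (8 Hamming segments, 50% overlap) of the
#' magnitude-squared coherence for every unordered channel pair,
#' averaged within each frequency bin. For 21 channels and 12 bins this
#' is the 2520-dimensional coherence feature. Values lie in \[0, 1\];
#' pairs involving a zero-variance channel are `NA`.
#'
#' @inheritParams fft_binned_power
#' @param n_segments Number of Welch segments.
#' @return Pairs x bins matrix; row names `"A-B"` name the pair.
#' @export
coherence_binned <- function(epoch, rate, binning = frequency_binning(),
                             n_segments = 8) {
  epoch <- as.matrix(epoch)
  acc <- welch_accumulate(epoch, rate, n_segments = n_segments)
  msc <- msc_from_welch(acc)
  out <- t(bin_average(msc, acc$freq, binning))
  labs <- rownames(epoch)
  if (!is.null(labs))
    rownames(out) <- paste(labs[acc$pairs[, 1]], labs[acc$pairs[, 2]],
                           sep = "-")
  out
}
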