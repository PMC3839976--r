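#' Frequency binning grid
#'
#' Twelve bins with centers `1 + 2.44 * j` Hz for `j = 0..11` (last
#' center 27.84 Hz) and half-open edges `[center - 1.22, center + 1.22)`.
#' Spectral features are averaged within these bins to compress the raw
#' frequency resolution.
#'
#' @param n_bins Number of bins.
#' @param start First bin center in Hz.
#' @param step Bin spacing in Hz.
#' @return An object of class `micf_binning` with elements `centers`,
#'   `lower`, `upper`.
#' @export
frequency_binning <- function(n_bins = 12, start = 1, step = 2.44) {
  centers <- start + step * (seq_len(n_bins) - 1)
  structure(list(centers = centers,
                 lower = centers - step / 2,
                 upper = centers + step / 2),
            class = "micf_binning")
}

# average rows of `values` (freq x k) into bins; freqs in Hz
bin_average <- function(values, freqs, binning) {
  values <- as.matrix(values)
  out <- matrix(NA_real_, length(binning$centers), ncol(values))
  for (b in seq_along(binning$centers)) {
    sel <- freqs >= binning$lower[b] & freqs < binning$upper[b]
    if (any(sel))
      out[b, ] <- colMeans(values[sel, , drop = FALSE])
  }
  out
}

hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Welch auto- and cross-spectral accumulation for a channels x time epoch.
# Returns per-frequency auto-spectra (freq x ch) and cross-spectra
# (freq x npair, complex) summed over segments, plus the segment count.
# Segment length gives `n_segments` half-overlapping Hamming segments.
welch_accumulate <- function(x, rate, n_segments = 8, nfft = NULL) {
  x <- as.matrix(x)
  nch <- nrow(x); n <- ncol(x)
  seg <- floor(2 * n / (n_segments + 1))
  hop <- floor(seg / 2)
  starts <- seq(1L, n - seg + 1L, by = hop)[seq_len(n_segments)]
  if (is.null(nfft)) nfft <- max(256L, 2^ceiling(log2(seg)))
  w <- hamming(seg)
  nfreq <- nfft %/% 2L + 1L
  pr <- pair_index(nch)
  auto <- matrix(0, nfreq, nch)
  cross <- matrix(0 + 0i, nfreq, nrow(pr))
  for (s in starts) {
    segm <- x[, s:(s + seg - 1L), drop = FALSE]
    segm <- sweep(segm, 1, rowMeans(segm))      # remove per-segment mean
    segm <- sweep(segm, 2, w, `*`)
    padded <- matrix(0, nfft, nch)
    padded[seq_len(seg), ] <- t(segm)
    F <- stats::mvfft(padded)[seq_len(nfreq), , drop = FALSE]
    auto <- auto + Mod(F)^2
    cross <- cross + F[, pr[, 1L], drop = FALSE] *
      Conj(F[, pr[, 2L], drop = FALSE])
  }
  list(freq = (seq_len(nfreq) - 1L) * rate / nfft,
       auto = auto, cross = cross, pairs = pr,
       n_segments = length(starts))
}

pair_index <- function(nch) {
  idx <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# magnitude-squared coherence (freq x pair) from accumulated spectra
msc_from_welch <- function(acc) {
  denom <- acc$auto[, acc$pairs[, 1L], drop = FALSE] *
    acc$auto[, acc$pairs[, 2L], drop = FALSE]
  msc <- Mod(acc$cross)^2 / denom
  msc[!is.finite(msc)] <- NA_real_
  pmin(pmax(msc, 0), 1)
}
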