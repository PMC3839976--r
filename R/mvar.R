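#' Fit a multivariate autoregressive (MVAR) model by least squares
#'
#' Ordinary least squares with an intercept, with the model order chosen
#' by the Schwarz (Bayesian information) criterion over `1..max_order`.
#'
#' @param epoch Channels x samples matrix.
#' @param max_order Largest candidate order (default 20).
#' @return An object of class `micf_mvar` with elements `A` (array
#'   `order x K x K`; `A[m, i, j]` is the influence of channel `j` at lag
#'   `m` on channel `i`), `Sigma` (residual covariance), `order`, `sbc`
#'   (criterion values) and `rate`-free coefficients.
#' @export
fit_mvar <- function(epoch, max_order = 20) {
  x <- t(as.matrix(epoch))                     # time x channels
  n <- nrow(x); K <- ncol(x)
  max_order <- min(max_order, (n - 1) %/% (2 * K))
  if (max_order < 1) stop("fit error: too few samples for an MVAR fit")
  sbc <- rep(NA_real_, max_order)
  fits <- vector("list", max_order)
  for (p in seq_len(max_order)) {
    E <- stats::embed(x, p + 1)
    Y <- E[, seq_len(K), drop = FALSE]
    Z <- cbind(1, E[, -seq_len(K), drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      kap <- kappa(Z)
      stop(sprintf(
        "fit error: ill-conditioned MVAR regression at order %d (condition number %.3g)",
        p, kap))
    }
    B <- qr.coef(qz, Y)
    res <- Y - Z %*% B
    neff <- nrow(Y)
    Sigma <- crossprod(res) / (neff - ncol(Z))
    detS <- det(crossprod(res) / neff)
    sbc[p] <- log(max(detS, .Machine$double.xmin)) +
      log(neff) * p * K^2 / neff
    fits[[p]] <- list(B = B, Sigma = Sigma)
  }
  p <- which.min(sbc)
  B <- fits[[p]]$B
  A <- array(0, dim = c(p, K, K))
  for (m in seq_len(p))
    A[m, , ] <- t(B[1 + ((m - 1) * K + 1):(m * K), , drop = FALSE])
  Sigma <- fits[[p]]$Sigma
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(A = A, Sigma = Sigma, order = p, sbc = sbc,
                 channels = rownames(epoch)),
            class = "micf_mvar")
}

#' @export
print.micf_mvar <- function(x, ...) {
  cat(sprintf("<micf_mvar> %d channels, order %d (Schwarz criterion)\n",
              dim(x$A)[2], x$order))
  invisible(x)
}

# A(f) = I - sum_m A_m exp(-2i pi f m / fs), complex K x K
mvar_afreq <- function(model, f, rate) {
  K <- dim(model$A)[2]
  Af <- diag(K) + 0i
  for (m in seq_len(dim(model$A)[1]))
    Af <- Af - model$A[m, , ] * exp(-2i * pi * f * m / rate)
  Af
}

#' Partial directed coherence / directed transfer function
#'
#' PDC normalizes the Fourier-transformed coefficient matrix `A(f)` by
#' column (outflows from each source sum to one in squared magnitude);
#' DTF normalizes the transfer matrix `H(f) = A(f)^-1` by row. Both are
#' evaluated on the raw frequency grid (`rate/1024` steps over the bin
#' range) and then bin-averaged; only the off-diagonal directed pairs
#' are returned.
#'
#' @param model A fitted [fit_mvar()] model.
#' @param binning A [frequency_binning()].
#' @param method `"pdc"` or `"dtf"`.
#' @param rate Sampling rate in Hz.
#' @return Directed-pairs x bins matrix (row names `"src->dst"` for the
#'   influence of `src` on `dst`); values in \[0, 1\].
#' @export
directed_spectral <- function(model, binning = frequency_binning(),
                              method = c("pdc", "dtf"), rate = 250) {
  method <- match.arg(method)
  K <- dim(model$A)[2]
  step <- rate / 1024
  freqs <- seq(min(binning$lower), max(binning$upper) - step / 2, by = step)
  off <- which(row(diag(K)) != col(diag(K)))
  vals <- matrix(NA_real_, length(freqs), length(off))
  for (fi in seq_along(freqs)) {
    Af <- mvar_afreq(model, freqs[fi], rate)
    M <- if (method == "pdc") {
      sweep(Mod(Af), 2, sqrt(colSums(Mod(Af)^2)), `/`)
    } else {
      H <- tryCatch(solve(Af), error = function(e) NULL)
      if (is.null(H)) next                     # singular: bin stays NA
      sweep(Mod(H), 1, sqrt(rowSums(Mod(H)^2)), `/`)
    }
    vals[fi, ] <- M[off]
  }
  out <- t(bin_average(vals, freqs, binning))
  labs <- model$channels
  if (is.null(labs)) labs <- paste0("ch", seq_len(K))
  src <- col(diag(K))[off]; dst <- row(diag(K))[off]
  rownames(out) <- paste0(labs[src], "->", labs[dst])
  out
}

# Geweke spectral Granger causality for a fitted bivariate model,
# evaluated at frequencies `freqs`; returns cbind(f_{1->2}, f_{2->1})
geweke_bivariate <- function(model, freqs, rate) {
  S <- model$Sigma
  out <- matrix(NA_real_, length(freqs), 2)
  s11 <- S[1, 1]; s22 <- S[2, 2]; s12 <- S[1, 2]
  for (fi in seq_along(freqs)) {
    Af <- mvar_afreq(model, freqs[fi], rate)
    H <- tryCatch(solve(Af), error = function(e) NULL)
    if (is.null(H)) next
    Sp <- H %*% S %*% Conj(t(H))
    # influence 1 -> 2: reduction of S22 spectrum
    num2 <- Re(Sp[2, 2])
    den2 <- num2 - (s11 - s12^2 / s22) * Mod(H[2, 1])^2
    # influence 2 -> 1
    num1 <- Re(Sp[1, 1])
    den1 <- num1 - (s22 - s12^2 / s11) * Mod(H[1, 2])^2
    out[fi, 1] <- log(num2 / max(den2, .Machine$double.xmin))
    out[fi, 2] <- log(num1 / max(den1, .Machine$double.xmin))
  }
  pmax(out, 0)
}

#' Pairwise spectral Granger causality and parametric power spectra
#'
#' For every directed channel pair, a bivariate MVAR model is fitted
#' (order by Schwarz criterion up to `max_order`) and the Geweke
#' spectral Granger causality is evaluated on the raw frequency grid,
#' then bin-averaged. `pp` is the parametric (autoregressive) power
#' spectrum of each channel from a univariate fit, bin-averaged.
#'
#' @inheritParams fft_binned_power
#' @param max_order Largest candidate MVAR order.
#' @return List with `gw` (directed-pairs x bins, `"src->dst"` rows,
#'   non-negative) and `pp` (channels x bins).
#' @export
granger_spectral <- function(epoch, rate, binning = frequency_binning(),
                             max_order = 20) {
  epoch <- as.matrix(epoch)
  K <- nrow(epoch)
  step <- rate / 1024
  freqs <- seq(min(binning$lower), max(binning$upper) - step / 2, by = step)
  labs <- rownames(epoch)
  if (is.null(labs)) labs <- paste0("ch", seq_len(K))
  pr <- pair_index(K)
  gw <- matrix(NA_real_, 2 * nrow(pr), length(binning$centers))
  rn <- character(2 * nrow(pr))
  for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1]; j <- pr[q, 2]
    model <- fit_mvar(epoch[c(i, j), , drop = FALSE], max_order)
    g <- geweke_bivariate(model, freqs, rate)
    gw[2 * q - 1, ] <- bin_average(g[, 1, drop = FALSE], freqs, binning)
    gw[2 * q, ] <- bin_average(g[, 2, drop = FALSE], freqs, binning)
    rn[2 * q - 1] <- paste0(labs[i], "->", labs[j])
    rn[2 * q] <- paste0(labs[j], "->", labs[i])
  }
  rownames(gw) <- rn
  pp <- matrix(NA_real_, K, length(binning$centers),
               dimnames = list(labs, NULL))
  for (i in seq_len(K)) {
    m <- fit_mvar(epoch[i, , drop = FALSE], max_order)
    s2 <- as.numeric(m$Sigma)
    spec <- vapply(freqs, function(f)
      s2 / Mod(mvar_afreq(m, f, rate)[1, 1])^2, numeric(1))
    pp[i, ] <- bin_average(matrix(spec, ncol = 1), freqs, binning)
  }
  list(gw = gw, pp = pp)
}
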