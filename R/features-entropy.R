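#' Approximate entropy per channel
#'
#' Pincus ApEn with template length `m` and tolerance `r` expressed as a
#' fraction of the channel SD. Regular signals score low, white noise
#' high. Constant channels return 0 (defined but degenerate).
#'
#' @param epoch Channels x samples matrix (>= 50 samples).
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of the channel SD (default 0.2).
#' @return Named numeric vector per channel.
#' @export
approximate_entropy <- function(epoch, m = 2, r_frac = 0.2) {
  epoch <- as.matrix(epoch)
  stopifnot(ncol(epoch) >= 50)
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (i in seq_len(nrow(epoch))) {
    x <- epoch[i, ]
    s <- stats::sd(x)
    if (s == 0) { out[i] <- 0; next }
    out[i] <- .apen_cpp(x, as.integer(m), r_frac * s)
  }
  out
}

# deterministic de-tie jitter: spread exact duplicates by a tiny ramp
break_ties <- function(xs) {
  eps <- max(abs(xs), 1) * 1e-10
  xs + eps * (seq_along(xs) - 1) / length(xs)
}

#' Spacing (Vasicek-type) entropy estimators per channel
#'
#' m-spacing estimators of differential entropy on the per-channel
#' sample distribution, `m = floor(sqrt(n))`. `kind = "shannon"` is the
#' Vasicek estimator with Ebrahimi boundary weights; `kind = "renyi"`
#' is the spacing form of the Renyi entropy of order `alpha`. Exact ties
#' are broken by a deterministic tiny jitter (logged via attribute
#' `"jittered"`).
#'
#' @param epoch Channels x samples matrix (>= 100 samples).
#' @param kind `"shannon"` or `"renyi"`.
#' @param alpha Renyi order (default 2; ignored for Shannon).
#' @return Named numeric vector of entropies in nats.
#' @export
spacing_entropy <- function(epoch, kind = c("shannon", "renyi"), alpha = 2) {
  kind <- match.arg(kind)
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n >= 100)
  m <- floor(sqrt(n))
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  jit <- logical(nrow(epoch))
  for (ch in seq_len(nrow(epoch))) {
    xs <- sort(epoch[ch, ])
    if (any(diff(xs) == 0)) { xs <- sort(break_ties(xs)); jit[ch] <- TRUE }
    i <- seq_len(n)
    hi <- pmin(i + m, n); lo <- pmax(i - m, 1)
    sp <- xs[hi] - xs[lo]
    if (kind == "shannon") {
      # Ebrahimi weights correct the clamped boundary spacings
      ci <- rep(2, n)
      ci[1:m] <- 1 + (i[1:m] - 1) / m
      ci[(n - m + 1):n] <- 1 + (n - i[(n - m + 1):n]) / m
      out[ch] <- mean(log(n * sp / (ci * m)))
    } else {
      fac <- n * sp / (2 * m)
      out[ch] <- log(mean(fac^(1 - alpha))) / (1 - alpha)
    }
  }
  attr(out, "jittered") <- jit
  out
}

# row-wise k-th smallest of a candidate matrix (Inf-padded)
kth_smallest_rows <- function(M, k) {
  n <- nrow(M)
  for (t in seq_len(k - 1)) {
    idx <- max.col(-M, ties.method = "first")
    M[cbind(seq_len(n), idx)] <- Inf
  }
  M[cbind(seq_len(n), max.col(-M, ties.method = "first"))]
}

# distance to the k-th nearest neighbour within a sorted 1-D sample,
# evaluated at the sorted points themselves (excluding self); the k-th
# neighbour is among the k sorted neighbours on each side
knn_dist_sorted <- function(xs, k) {
  n <- length(xs)
  cand <- matrix(Inf, n, 2 * k)
  for (j in seq_len(k)) {
    d <- xs[(j + 1):n] - xs[1:(n - j)]
    cand[(j + 1):n, j] <- d
    cand[1:(n - j), k + j] <- d
  }
  kth_smallest_rows(cand, k)
}

# k-th nearest-neighbour distance from each (sorted) point of `ps` to
# the sorted sample `qs`
knn_dist_cross <- function(ps, qs, k) {
  n <- length(ps); m <- length(qs)
  pos <- findInterval(ps, qs)
  cand <- matrix(Inf, n, 2 * k)
  for (j in seq_len(k)) {
    li <- pos - j + 1L
    ok <- li >= 1L
    cand[ok, j] <- ps[ok] - qs[li[ok]]
    ri <- pos + j
    ok <- ri <= m
    cand[ok, k + j] <- qs[ri[ok]] - ps[ok]
  }
  kth_smallest_rows(cand, k)
}

#' Tsallis entropy by k-nearest-neighbour estimation, per channel
#'
#' Leonenko-Pronzato-Savani estimator of the Tsallis entropy of order
#' `q`: the integral `I = int f^q` is estimated from k-NN distances and
#' `H_q = (1 - I)/(q - 1)`. Requires `k + 1 - q > 0`.
#'
#' @param epoch Channels x samples matrix (>= 100 samples).
#' @param q Tsallis order (default 1.5).
#' @param k Number of neighbours (default 4).
#' @return Named numeric vector.
#' @export
knn_entropy_tsallis <- function(epoch, q = 1.5, k = 4) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n >= 100, k + 1 - q > 0, q != 1)
  ck <- (gamma(k) / gamma(k + 1 - q))^(1 / (1 - q))
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (ch in seq_len(nrow(epoch))) {
    xs <- sort(epoch[ch, ])
    if (any(diff(xs) == 0)) xs <- sort(break_ties(xs))
    rho <- knn_dist_sorted(xs, k)
    iq <- mean(((n - 1) * ck * 2 * rho)^(1 - q))
    out[ch] <- (1 - iq) / (q - 1)
  }
  out
}

#' k-NN Bhattacharyya distance between two univariate samples
#'
#' Plug-in estimate of `-log int sqrt(p q)` using leave-one-out k-NN
#' density estimates, symmetrized over the two samples (so the result is
#' exactly symmetric in its arguments). The half-order moment bias of
#' the k-NN distance ratio is removed analytically with the Gamma-moment
#' factor `gamma(k + 1/2) * gamma(k - 1/2) / gamma(k)^2`. Within the
#' feature battery the two samples are the first and second halves of
#' each channel's epoch. Asymptotically 0 for identical distributions
#' (small negative values can occur at finite n).
#'
#' @param a,b Numeric vectors (>= 2 k + 2 points each).
#' @param k Number of neighbours (default 4, must be >= 2 for the bias
#'   factor to be finite).
#' @return Scalar distance estimate.
#' @export
bhattacharyya_knn <- function(a, b, k = 4) {
  stopifnot(k >= 2)
  bias <- gamma(k + 0.5) * gamma(k - 0.5) / gamma(k)^2
  half <- function(p, qq) {
    # E_{x~p}[ sqrt(q(x)/p(x)) ] via knn densities
    ps <- sort(p); qs <- sort(qq)
    if (any(diff(ps) == 0)) ps <- sort(break_ties(ps))
    if (any(diff(qs) == 0)) qs <- sort(break_ties(qs))
    np <- length(ps); nq <- length(qs)
    rho_p <- knn_dist_sorted(ps, k)
    rho_q <- knn_dist_cross(ps, qs, k)
    dens_p <- k / ((np - 1) * 2 * rho_p)
    dens_q <- k / (nq * 2 * rho_q)
    mean(sqrt(dens_q / dens_p))
  }
  bc <- (half(a, b) + half(b, a)) / 2 / bias
  -log(bc)
}

bhattacharyya_feature <- function(epoch, k = 4) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n >= 200)
  h <- n %/% 2
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (ch in seq_len(nrow(epoch)))
    out[ch] <- bhattacharyya_knn(epoch[ch, 1:h], epoch[ch, (h + 1):n], k)
  out
}

#' Correntropy (kernel correlation) per channel
#'
#' Mean Gaussian kernel evaluated on lag-1 sample differences:
#' `mean(exp(-(x[t] - x[t+1])^2 / (2 w^2)))`. The kernel maximum is 1,
#' attained by constant signals; the value is invariant to adding a
#' constant. The default width is `0.2 * sd(x)` (falling back to 1 on
#' constant channels).
#'
#' @param epoch Channels x samples matrix (>= 100 samples).
#' @param kernel_width Kernel width `w`; `NULL` for the adaptive
#'   default.
#' @return Named numeric vector in (0, 1\].
#' @export
correntropy_kde <- function(epoch, kernel_width = NULL) {
  epoch <- as.matrix(epoch)
  stopifnot(ncol(epoch) >= 100)
  out <- stats::setNames(rep(NA_real_, nrow(epoch)), rownames(epoch))
  for (ch in seq_len(nrow(epoch))) {
    x <- epoch[ch, ]
    w <- kernel_width
    if (is.null(w)) {
      s <- stats::sd(x)
      w <- if (s > 0) 0.2 * s else 1
    }
    d <- diff(x)
    out[ch] <- mean(exp(-d^2 / (2 * w^2)))
  }
  out
}
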