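#' Names of the 20-feature battery
#' @return Character vector of the registered feature names.
#' @export
feature_names <- function() {
  c("hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    "brainrate", "wackermann_sigma", "wackermann_phi", "wackermann_omega",
    "hurst", "fft", "coherence", "granger_gw", "granger_pp",
    "pdc", "dtf", "apen", "shannon_spacing", "renyi_spacing",
    "tsallis_knn", "bhattacharyya_knn", "correntropy")
}

#' Feature-vector dimensions for a given channel count
#'
#' For the standard 21-channel montage and 12 frequency bins: per-channel
#' features have 21 dimensions, the Wackermann descriptors 1, the binned
#' spectrum 252, coherence 2520, directed connectivity 5040, and the
#' pairwise Granger power spectrum 252.
#'
#' @param n_channels Number of analysis channels.
#' @param n_bins Number of frequency bins.
#' @return Named integer vector over [feature_names()].
#' @export
feature_dimensions <- function(n_channels = 21, n_bins = 12) {
  K <- n_channels
  pairs <- K * (K - 1) / 2
  dir <- K * (K - 1)
  c(hjorth_activity = K, hjorth_mobility = K, hjorth_complexity = K,
    brainrate = K, wackermann_sigma = 1L, wackermann_phi = 1L,
    wackermann_omega = 1L, hurst = K, fft = K * n_bins,
    coherence = pairs * n_bins, granger_gw = dir * n_bins,
    granger_pp = K * n_bins, pdc = dir * n_bins, dtf = dir * n_bins,
    apen = K, shannon_spacing = K, renyi_spacing = K, tsallis_knn = K,
    bhattacharyya_knn = K, correntropy = K)
}

# flatten a (unit x bin) matrix row-major with composed labels
flatten_bins <- function(m, binning) {
  labs <- as.vector(t(outer(rownames(m), binning$centers,
                            function(a, b) sprintf("%s@%.2fHz", a, b))))
  stats::setNames(as.vector(t(m)), labs)
}

# evaluate one named feature on a single epoch; returns a named vector
feature_vector <- function(name, epoch, rate, binning, opts = list()) {
  labs <- rownames(epoch)
  if (is.null(labs)) {
    labs <- paste0("ch", seq_len(nrow(epoch)))
    rownames(epoch) <- labs
  }
  switch(name,
    hjorth_activity = hjorth(epoch)["activity", ],
    hjorth_mobility = hjorth(epoch)["mobility", ],
    hjorth_complexity = hjorth(epoch)["complexity", ],
    brainrate = brainrate(epoch, rate),
    wackermann_sigma = wackermann(epoch, rate)["sigma"],
    wackermann_phi = wackermann(epoch, rate)["phi"],
    wackermann_omega = wackermann(epoch, rate)["omega"],
    hurst = hurst_rs(epoch),
    fft = flatten_bins(
      structure(fft_binned_power(epoch, rate, binning),
                dimnames = list(labs, NULL)), binning),
    coherence = flatten_bins(coherence_binned(epoch, rate, binning),
                             binning),
    granger_gw = flatten_bins(
      granger_spectral(epoch, rate, binning,
                       max_order = opts$max_order %||% 20)$gw, binning),
    granger_pp = flatten_bins(
      granger_spectral(epoch, rate, binning,
                       max_order = opts$max_order %||% 20)$pp, binning),
    pdc = flatten_bins(
      directed_spectral(fit_mvar(epoch, opts$max_order %||% 20),
                        binning, "pdc", rate), binning),
    dtf = flatten_bins(
      directed_spectral(fit_mvar(epoch, opts$max_order %||% 20),
                        binning, "dtf", rate), binning),
    apen = approximate_entropy(epoch, m = opts$apen_m %||% 2,
                               r_frac = opts$apen_r %||% 0.2),
    shannon_spacing = spacing_entropy(epoch, "shannon"),
    renyi_spacing = spacing_entropy(epoch, "renyi",
                                    alpha = opts$renyi_alpha %||% 2),
    tsallis_knn = knn_entropy_tsallis(epoch, q = opts$tsallis_q %||% 1.5,
                                      k = opts$knn_k %||% 4),
    bhattacharyya_knn = bhattacharyya_feature(epoch,
                                              k = opts$knn_k %||% 4),
    correntropy = correntropy_kde(epoch, opts$kernel_width),
    stop("registry error: unknown feature name: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute one feature's trial-by-dimension matrix
#'
#' Evaluates a registered feature on every retained trial. The matrix is
#' flagged degenerate (and should be excluded from classification) when
#' all rows are identical or any value is non-finite.
#'
#' @param trials A `micf_trialset`.
#' @param feature_name One of [feature_names()].
#' @param binning A [frequency_binning()].
#' @param opts Named list of estimator options (`max_order`, `apen_m`,
#'   `apen_r`, `renyi_alpha`, `tsallis_q`, `knn_k`, `kernel_width`).
#' @return An object of class `micf_features`: list with `values`
#'   (trials x d), `feature_name`, `dim_labels`, `condition`,
#'   `degenerate` flag.
#' @export
extract_feature_matrix <- function(trials, feature_name,
                                   binning = frequency_binning(),
                                   opts = list()) {
  stopifnot(inherits(trials, "micf_trialset"))
  if (!feature_name %in% feature_names())
    stop("registry error: unknown feature name: ", feature_name)
  if (!length(trials$epochs)) stop("no retained trials")
  rows <- lapply(trials$epochs, function(ep)
    feature_vector(feature_name, ep, trials$rate, binning, opts))
  values <- do.call(rbind, rows)
  feature_matrix(values, trials$condition, feature_name,
                 subject_id = trials$subject_id,
                 group_tag = trials$group_tag)
}

#' Construct a feature matrix object
#'
#' Unless overridden, the degenerate flag is set automatically when all
#' rows are identical or any value is non-finite; degenerate matrices
#' are excluded from classification by [loocv()].
#'
#' @param values Trials x dimensions numeric matrix.
#' @param condition Per-trial condition labels.
#' @param feature_name Feature name string.
#' @param subject_id,group_tag Metadata.
#' @param degenerate Logical override of the automatic flag.
#' @return An object of class `micf_features`.
#' @export
feature_matrix <- function(values, condition, feature_name,
                           subject_id = "S00", group_tag = "unknown",
                           degenerate = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(condition))
  if (is.null(degenerate))
    degenerate <- any(!is.finite(values)) ||
      (nrow(values) > 1 && all(apply(values, 2, function(cc)
        diff(range(cc)) == 0)))
  structure(
    list(values = values, feature_name = feature_name,
         dim_labels = colnames(values), condition = as.character(condition),
         subject_id = subject_id, group_tag = group_tag,
         degenerate = degenerate),
    class = "micf_features")
}

#' @export
print.micf_features <- function(x, ...) {
  cat(sprintf("<micf_features> %s: %d trials x %d dims%s\n",
              x$feature_name, nrow(x$values), ncol(x$values),
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}
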