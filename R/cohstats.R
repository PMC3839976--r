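#' Pooled magnitude-squared coherence over all trials of one condition
#'
#' Welch auto- and cross-spectra are accumulated over all segments of
#' all trials of the condition before forming the coherence, giving a
#' single low-bias estimate per channel pair (bias roughly one over the
#' number of pooled segments); the result is then bin-averaged.
#'
#' @param trials A `micf_trialset`.
#' @param condition `"imagery"` or `"rest"` (>= 2 trials present).
#' @param binning A [frequency_binning()].
#' @param n_segments Welch segments per trial.
#' @return Pairs x bins matrix of msc with attribute `"n_segments"`
#'   (total pooled segment count).
#' @export
pooled_coherence <- function(trials, condition,
                             binning = frequency_binning(),
                             n_segments = 8) {
  stopifnot(inherits(trials, "micf_trialset"))
  sel <- which(trials$condition == condition)
  if (length(sel) < 2)
    stop("need at least 2 trials of condition '", condition, "'")
  acc <- NULL
  for (e in sel) {
    a <- welch_accumulate(trials$epochs[[e]], trials$rate, n_segments)
    if (is.null(acc)) acc <- a
    else {
      acc$auto <- acc$auto + a$auto
      acc$cross <- acc$cross + a$cross
      acc$n_segments <- acc$n_segments + a$n_segments
    }
  }
  msc <- msc_from_welch(acc)
  out <- t(bin_average(msc, acc$freq, binning))
  labs <- trials$channel_labels
  rownames(out) <- paste(labs[acc$pairs[, 1]], labs[acc$pairs[, 2]],
                         sep = "-")
  attr(out, "n_segments") <- acc$n_segments
  out
}

#' Compare two pooled coherence maps via Fisher's r-to-z
#'
#' Each coherence magnitude `sqrt(msc)` (the correlation analog) is
#' Fisher-transformed, `z = atanh(r)`, and the two conditions compared
#' with `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` where `n1`,
#' `n2` are the effective pooled segment counts; p is the two-sided
#' normal tail. `fisher_on_msc = TRUE` transforms the msc itself
#' instead (compatibility switch).
#'
#' @param msc1,msc2 Pairs x bins msc matrices (imagery, rest).
#' @param n1,n2 Effective segment counts (> 3).
#' @param fisher_on_msc Apply atanh to msc instead of its square root.
#' @return List with matrices `Z` and `p` (same shape as the inputs).
#' @export
compare_coherence <- function(msc1, msc2, n1, n2, fisher_on_msc = FALSE) {
  if (n1 <= 3 || n2 <= 3) stop("effective counts must exceed 3")
  tr <- function(m) {
    r <- if (fisher_on_msc) m else sqrt(m)
    atanh(pmin(r, 1 - 1e-12))
  }
  Z <- (tr(msc1) - tr(msc2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Per-subject coherence condition comparison
#'
#' Convenience wrapper: pooled coherence for each condition, Fisher
#' comparison, and a within-subject Benjamini-Hochberg correction over
#' the full pair x bin family.
#'
#' @inheritParams pooled_coherence
#' @param q FDR level for the within-subject family.
#' @param fisher_on_msc Passed to [compare_coherence()].
#' @return Object of class `micf_coh_comparison`: list with `msc_imagery`,
#'   `msc_rest`, `Z`, `p`, `significant` (BH mask, same shape), `n1`,
#'   `n2`, `subject_id`.
#' @export
coherence_comparison <- function(trials, binning = frequency_binning(),
                                 n_segments = 8, q = 0.05,
                                 fisher_on_msc = FALSE) {
  m1 <- pooled_coherence(trials, "imagery", binning, n_segments)
  m2 <- pooled_coherence(trials, "rest", binning, n_segments)
  n1 <- attr(m1, "n_segments"); n2 <- attr(m2, "n_segments")
  cmp <- compare_coherence(m1, m2, n1, n2, fisher_on_msc)
  pv <- cmp$p
  mask <- matrix(fdr_bh(as.vector(pv), q)$rejected, nrow(pv), ncol(pv),
                 dimnames = dimnames(pv))
  structure(list(msc_imagery = m1, msc_rest = m2, Z = cmp$Z, p = pv,
                 significant = mask, n1 = n1, n2 = n2,
                 subject_id = trials$subject_id,
                 group_tag = trials$group_tag),
            class = "micf_coh_comparison")
}

#' @export
print.micf_coh_comparison <- function(x, ...) {
  cat(sprintf(
    "<micf_coh_comparison> %s: %d pairs x %d bins, %d significant after FDR (n1=%d, n2=%d)\n",
    x$subject_id, nrow(x$Z), ncol(x$Z), sum(x$significant), x$n1, x$n2))
  invisible(x)
}

# restrict a pair x bin matrix to pairs within a channel subset
restrict_pairs <- function(m, subset) {
  if (is.null(subset)) return(m)
  parts <- strsplit(rownames(m), "-", fixed = TRUE)
  keep <- vapply(parts, function(p) all(p %in% subset), logical(1))
  m[keep, , drop = FALSE]
}

#' Count subjects with significantly different coherence
#'
#' Per channel pair and frequency bin, the number of subjects whose
#' within-subject BH-corrected comparison is significant, reported on a
#' display subset of electrodes (13 by default).
#'
#' @param comparisons List of [coherence_comparison()] results.
#' @param subset Channel labels to display (`NULL` for all).
#' @return Pairs x bins integer matrix of counts.
#' @export
subject_significance_counts <- function(comparisons,
                                        subset = micf_display_subset()) {
  stopifnot(length(comparisons) >= 1)
  acc <- NULL
  for (cmp in comparisons) {
    m <- restrict_pairs(cmp$significant, subset)
    acc <- if (is.null(acc)) m + 0L else acc + m
  }
  acc
}

#' Power-spectrum condition-difference summary
#'
#' Per subject and channel, the mean over rest trials of the binned
#' magnitude spectra minus the mean over imagery trials (positive where
#' rest power exceeds imagery power, as under mu-rhythm ERD). At cohort
#' level, the across-subject mean and SD are reported, optionally on a
#' display channel subset.
#'
#' @param trialsets List of `micf_trialset` objects (one per subject),
#'   or a single trialset.
#' @param binning A [frequency_binning()].
#' @param subset Channel labels to report (`NULL` for all).
#' @return List with `mean` and `sd` (channels x bins matrices across
#'   subjects) and `per_subject` (list of channels x bins difference
#'   matrices).
#' @export
power_difference_summary <- function(trialsets,
                                     binning = frequency_binning(),
                                     subset = NULL) {
  if (inherits(trialsets, "micf_trialset")) trialsets <- list(trialsets)
  per_subject <- lapply(trialsets, function(tr) {
    stopifnot(all(c("imagery", "rest") %in% tr$condition))
    spec_of <- function(cond) {
      sel <- which(tr$condition == cond)
      mats <- lapply(sel, function(e)
        fft_binned_power(tr$epochs[[e]], tr$rate, binning))
      Reduce(`+`, mats) / length(mats)
    }
    d <- spec_of("rest") - spec_of("imagery")
    rownames(d) <- tr$channel_labels
    if (!is.null(subset)) d <- d[rownames(d) %in% subset, , drop = FALSE]
    d
  })
  arr <- simplify2array(per_subject)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(s) <- dimnames(per_subject[[1]])
  list(mean = m, sd = s, per_subject = per_subject)
}
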