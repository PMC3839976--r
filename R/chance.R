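#' Proportional chance criterion
#'
#' Chance-level accuracy accounting for class imbalance: the sum of the
#' squared proportions that each condition's trial count represents in
#' the whole trial set, `(n1/N)^2 + (n2/N)^2`. Minimal (0.5) for
#' balanced classes, 1 when one class is absent.
#'
#' @param n1,n2 Retained trial counts per condition (non-negative,
#'   `n1 + n2 > 0`).
#' @return Scalar in \[0.5, 1\].
#' @export
cpro <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stop("trial counts must be non-negative")
  N <- n1 + n2
  if (N <= 0) stop("n1 + n2 must be positive")
  (n1 / N)^2 + (n2 / N)^2
}

#' z-statistic for improvement over the proportional chance criterion
#'
#' `z = (n_correct - N * cpro) / sqrt(N * cpro * (1 - cpro))`. The
#' default p-value is the two-sided standard-normal tail probability;
#' significantly below-chance accuracies therefore give a negative z
#' with a small p. `compat_pdf = TRUE` instead evaluates the standard
#' normal density at z — the literal convention of some legacy analyses,
#' kept as a comparability switch only.
#'
#' @param n_correct Correctly classified trials, `0 <= n_correct <= N`.
#' @param N Total trial count.
#' @param cpro Proportional chance criterion in (0, 1).
#' @param compat_pdf Use the normal-density convention for p.
#' @return List with elements `z` and `p`.
#' @export
improvement_z <- function(n_correct, N, cpro, compat_pdf = FALSE) {
  if (any(cpro <= 0 | cpro >= 1))
    stop("cpro must lie strictly between 0 and 1")
  if (any(n_correct < 0 | n_correct > N))
    stop("n_correct must be in [0, N]")
  z <- (n_correct - N * cpro) / sqrt(N * cpro * (1 - cpro))
  p <- if (compat_pdf) stats::dnorm(z) else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Improvement-over-chance criterion (effect size)
#'
#' `(accuracy - cpro) / (1 - cpro)`: 0 at chance, 1 at perfect
#' classification, negative for below-chance accuracy.
#'
#' @param accuracy Classification accuracy in \[0, 1\].
#' @param cpro Proportional chance criterion (< 1).
#' @return Scalar in \[-1, 1\].
#' @export
iocc <- function(accuracy, cpro) {
  if (any(cpro >= 1)) stop("iocc undefined at cpro = 1")
  (accuracy - cpro) / (1 - cpro)
}

#' All chance statistics for one classification outcome
#'
#' @inheritParams improvement_z
#' @param n1,n2 Per-condition retained trial counts.
#' @return List with `cpro`, `z`, `p`, `iocc`, `n1`, `n2`, `N`,
#'   `n_correct`.
#' @export
chance_stats <- function(n_correct, n1, n2, compat_pdf = FALSE) {
  cp <- cpro(n1, n2)
  N <- n1 + n2
  zp <- improvement_z(n_correct, N, cp, compat_pdf)
  list(cpro = cp, z = zp$z, p = zp$p, iocc = iocc(n_correct / N, cp),
       n1 = n1, n2 = n2, N = N, n_correct = n_correct)
}

#' Benjamini-Hochberg false-discovery-rate step-up
#'
#' @param p Vector of p-values in \[0, 1\] (non-empty).
#' @param q Target FDR level (default 0.05).
#' @return List with `rejected` (logical mask) and `threshold` (largest
#'   rejected p, 0 when none).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value family")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  rejected <- stats::p.adjust(p, method = "BH") <= q
  rejected[is.na(rejected)] <- FALSE
  threshold <- if (any(rejected)) max(p[rejected]) else 0
  list(rejected = rejected, threshold = threshold)
}

#' Count subjects classified above chance
#'
#' A result counts as above chance iff its p-value is below the
#' threshold (uncorrected `alpha`, or the Benjamini-Hochberg threshold
#' over the supplied family when `corrected`) AND its effect size is
#' positive (`iocc > 0`) — the two-sided p is small for significantly
#' below-chance results too. Failed results are excluded from the
#' family.
#'
#' @param results Data frame of classification results (columns `p`,
#'   `iocc`, `failed`, `feature`, `classifier`, `subject`).
#' @param alpha Uncorrected significance level.
#' @param q FDR level for the corrected mode.
#' @param corrected Use the BH-corrected family threshold.
#' @return The input with a logical column `above_chance`, restricted to
#'   non-failed rows; attribute `"threshold"` carries the applied
#'   p-threshold.
#' @export
count_above_chance <- function(results, alpha = 0.05, q = 0.05,
                               corrected = FALSE) {
  ok <- results[!results$failed & !is.na(results$p), , drop = FALSE]
  if (!nrow(ok)) {
    attr(ok, "threshold") <- 0
    ok$above_chance <- logical(0)
    return(ok)
  }
  if (corrected) {
    bh <- fdr_bh(ok$p, q)
    ok$above_chance <- bh$rejected & ok$iocc > 0
    attr(ok, "threshold") <- bh$threshold
  } else {
    ok$above_chance <- ok$p < alpha & ok$iocc > 0
    attr(ok, "threshold") <- alpha
  }
  ok
}

#' Wilcoxon signed-rank test (exact for small n, tie-aware)
#'
#' Paired (or one-sample) signed-rank test. Zero differences are
#' dropped; absolute differences are ranked with mid-ranks for ties.
#' For `n <= exact_limit` the two-sided p is computed by exact
#' enumeration of the null sign-assignment distribution (valid with
#' ties); otherwise a normal approximation with continuity and tie
#' correction is used.
#'
#' @param x Numeric vector.
#' @param y Optional paired vector; if missing, `x` is tested against
#'   `mu`.
#' @param mu Reference value for the one-sample test.
#' @param exact_limit Largest n for exact enumeration (default 25).
#' @return List with `statistic` (positive-rank sum `V`), `z` (`NA` in
#'   exact mode), `p`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, exact_limit = 25) {
  d <- if (is.null(y)) x - mu else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, z = NA_real_, p = 1, n = 0L,
                method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of V under random signs: convolve over 2*ranks so
    # mid-ranks (x.5) stay integral
    r2 <- as.integer(round(2 * r))
    f <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      g <- f
      g[(ri + 1):length(f)] <- g[(ri + 1):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    f <- f / sum(f)
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[1:(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = V, z = NA_real_, p = p, n = n,
                method = "exact"))
  }
  mu_v <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu_v - sign(V - mu_v) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = V, z = z, p = min(1, p), n = n, method = "normal")
}

#' Group summary of classification results
#'
#' Per feature x classifier x group: mean, SD and range
#' (maximum - minimum) of accuracies, mean p, mean IOCC, and the counts
#' of subjects above chance with and without FDR correction (the FDR
#' family being all non-failed results supplied). Failed results are
#' excluded from the summaries; their count is reported.
#'
#' @param results Data frame of per-subject classification results.
#' @param alpha,q Significance levels for the above-chance counts.
#' @return Data frame with one row per feature x classifier x group.
#' @export
summarize_group <- function(results, alpha = 0.05, q = 0.05) {
  if (!nrow(results) || all(results$failed))
    stop("no non-failed results to summarize")
  unc <- count_above_chance(results, alpha = alpha, corrected = FALSE)
  cor <- count_above_chance(results, q = q, corrected = TRUE)
  key <- function(d) paste(d$feature, d$classifier, d$group, sep = "\r")
  ok <- results[!results$failed, , drop = FALSE]
  groups <- split(ok, key(ok))
  out <- do.call(rbind, lapply(groups, function(g) {
    k <- key(g)[1]
    data.frame(
      feature = g$feature[1], classifier = g$classifier[1],
      group = g$group[1], n_subjects = nrow(g),
      mean_accuracy = mean(g$accuracy), sd_accuracy = stats::sd(g$accuracy),
      range_accuracy = diff(range(g$accuracy)),
      mean_p = mean(g$p), mean_iocc = mean(g$iocc),
      n_above_uncorrected = sum(unc$above_chance[key(unc) == k]),
      n_above_fdr = sum(cor$above_chance[key(cor) == k]),
      stringsAsFactors = FALSE)
  }))
  out$sd_accuracy[is.na(out$sd_accuracy)] <- 0
  nf <- results[results$failed, , drop = FALSE]
  attr(out, "n_failed") <- nrow(nf)
  attr(out, "fdr_threshold") <- attr(cor, "threshold")
  rownames(out) <- NULL
  out
}

#' Feature and classifier comparison tables
#'
#' (a) Classifier-vs-classifier Wilcoxon signed-rank tests on the
#' per-feature counts of above-chance subjects, separately for
#' uncorrected and FDR-corrected counts. (b) Per-feature one-sample
#' Wilcoxon tests of the other features' metric values (mean, SD and
#' range of accuracy; one family) and above-chance counts (second
#' family) against the target feature's value, restricted to
#' `best_classifier`. Both families are Benjamini-Hochberg corrected and
#' their sizes reported.
#'
#' @param summary A [summarize_group()] table covering >= 2 features and
#'   >= 2 classifiers.
#' @param q FDR level.
#' @param best_classifier Classifier used for the feature comparisons
#'   (default `"svm_linear"`).
#' @return List with data frames `classifiers`, `features_metrics`,
#'   `features_counts`; family sizes in attributes.
#' @export
compare_features_and_classifiers <- function(summary, q = 0.05,
                                             best_classifier = "svm_linear") {
  feats <- unique(summary$feature)
  clfs <- unique(summary$classifier)
  if (length(feats) < 2 || length(clfs) < 2)
    stop("need at least 2 features and 2 classifiers")

  counts_of <- function(clf, col) {
    sub <- summary[summary$classifier == clf, , drop = FALSE]
    agg <- tapply(sub[[col]], sub$feature, sum)
    as.numeric(agg[feats])
  }
  rows <- list()
  for (col in c("n_above_uncorrected", "n_above_fdr")) {
    for (a in seq_along(clfs)) for (b in seq_along(clfs)) {
      if (a >= b) next
      ca <- counts_of(clfs[a], col); cb <- counts_of(clfs[b], col)
      w <- wilcoxon_signed_rank(ca, cb)
      rows[[length(rows) + 1]] <- data.frame(
        family = if (col == "n_above_uncorrected") "uncorrected" else "fdr",
        classifier_a = clfs[a], classifier_b = clfs[b],
        statistic = w$statistic, p = w$p, stringsAsFactors = FALSE)
    }
  }
  classifiers <- do.call(rbind, rows)
  classifiers$significant_fdr <- fdr_bh(classifiers$p, q)$rejected

  best <- summary[summary$classifier == best_classifier, , drop = FALSE]
  if (!nrow(best))
    stop("best_classifier not present in the summary")
  groups <- unique(best$group)
  metric_cols <- c(mean = "mean_accuracy", sd = "sd_accuracy",
                   range = "range_accuracy")
  rows <- list()
  for (g in groups) for (mi in seq_along(metric_cols)) {
    sub <- best[best$group == g, , drop = FALSE]
    vals <- stats::setNames(sub[[metric_cols[mi]]], sub$feature)
    for (f in names(vals)) {
      w <- wilcoxon_signed_rank(vals[names(vals) != f], mu = vals[[f]])
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = names(metric_cols)[mi], feature = f,
        value = vals[[f]], p = w$p, stringsAsFactors = FALSE)
    }
  }
  features_metrics <- do.call(rbind, rows)
  features_metrics$significant_fdr <- fdr_bh(features_metrics$p, q)$rejected

  rows <- list()
  for (g in groups) for (col in c("n_above_uncorrected", "n_above_fdr")) {
    sub <- best[best$group == g, , drop = FALSE]
    vals <- stats::setNames(sub[[col]], sub$feature)
    for (f in names(vals)) {
      w <- wilcoxon_signed_rank(vals[names(vals) != f], mu = vals[[f]])
      rows[[length(rows) + 1]] <- data.frame(
        group = g,
        correction = if (col == "n_above_fdr") "fdr" else "uncorrected",
        feature = f, count = vals[[f]], p = w$p, stringsAsFactors = FALSE)
    }
  }
  features_counts <- do.call(rbind, rows)
  features_counts$significant_fdr <- fdr_bh(features_counts$p, q)$rejected

  structure(list(classifiers = classifiers,
                 features_metrics = features_metrics,
                 features_counts = features_counts),
            family_sizes = c(metrics = nrow(features_metrics),
                             counts = nrow(features_counts)))
}

#' Advisory normality checks
#'
#' Chi-square goodness-of-fit (Pearson) and Lilliefors tests of
#' normality. Advisory only: results never gate the pipeline.
#'
#' @param values Numeric vector, n >= 8.
#' @return List with `chisq_p`, `lilliefors_p`, `degenerate`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8) stop("need at least 8 values")
  if (stats::sd(values) == 0)
    return(list(chisq_p = NA_real_, lilliefors_p = NA_real_,
                degenerate = TRUE))
  list(chisq_p = nortest::pearson.test(values)$p.value,
       lilliefors_p = nortest::lillie.test(values)$p.value,
       degenerate = FALSE)
}
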