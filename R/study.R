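#' Study configuration
#'
#' Bundles everything a full study run needs: cohort composition and
#' effect specification, preprocessing parameters, the feature and
#' classifier selections, significance levels, compatibility switches,
#' and the mandatory seed.
#'
#' @param seed Integer seed (mandatory; every stochastic stage derives
#'   from it).
#' @param n_responsive,n_null Cohort sizes (paper-scale study: 22
#'   responsive-analog and 14 null-analog subjects).
#' @param spec An [effect_spec()].
#' @param montage Channel labels for generation.
#' @param band Band-pass `c(low, high)` in Hz.
#' @param target_rate Analysis sampling rate (Hz).
#' @param epoch_seconds Epoch length.
#' @param features Feature names (subset of [feature_names()]).
#' @param classifiers List of [classifier_spec()]s.
#' @param alpha,q Uncorrected and FDR significance levels.
#' @param compat_pdf Legacy normal-density p-value convention.
#' @param fisher_on_msc Fisher-transform msc instead of its square root.
#' @param subset_13 Restrict condition-difference maps to the
#'   13-electrode display subset.
#' @param feature_opts Estimator options passed to
#'   [extract_feature_matrix()].
#' @return An object of class `micf_config`.
#' @export
study_config <- function(seed,
                         n_responsive = 22, n_null = 14,
                         spec = effect_spec(),
                         montage = micf_montage(),
                         band = c(1, 48), target_rate = 250,
                         epoch_seconds = 4,
                         features = feature_names(),
                         classifiers = default_classifiers(),
                         alpha = 0.05, q = 0.05,
                         compat_pdf = FALSE, fisher_on_msc = FALSE,
                         subset_13 = TRUE, feature_opts = list()) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("configuration error: a seed is mandatory")
  bad <- setdiff(features, feature_names())
  if (length(bad))
    stop("configuration error: unknown feature(s): ",
         paste(bad, collapse = ", "))
  stopifnot(all(vapply(classifiers, inherits, TRUE, "micf_classifier")))
  structure(
    list(seed = as.integer(seed), n_responsive = n_responsive,
         n_null = n_null, spec = spec, montage = montage, band = band,
         target_rate = target_rate, epoch_seconds = epoch_seconds,
         features = features, classifiers = classifiers, alpha = alpha,
         q = q, compat_pdf = compat_pdf, fisher_on_msc = fisher_on_msc,
         subset_13 = subset_13, feature_opts = feature_opts),
    class = "micf_config")
}

#' Read a study configuration from YAML
#'
#' Recognized top-level keys mirror the [study_config()] arguments;
#' `spec` is a mapping of [effect_spec()] arguments and `classifiers` a
#' list of mappings with `method`, `k`, `C`.
#'
#' @param path YAML file path.
#' @return A `micf_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) y$spec <- do.call(effect_spec, y$spec)
  if (!is.null(y$classifiers))
    y$classifiers <- lapply(y$classifiers, function(cl)
      do.call(classifier_spec, cl))
  do.call(study_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(
    lapply(unclass(config), function(v)
      if (is.list(v) && !is.data.frame(v)) lapply(v, unclass) else v),
    auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full study pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses and epochs every
#' subject, applies artifact rejection and common average referencing,
#' extracts the configured features, classifies each feature with each
#' classifier under leave-one-out cross-validation, computes chance
#' statistics, group summaries and comparison tables, and builds the
#' coherence and power condition-difference maps. Per-feature classifier
#' failures are recorded as failed rows, never coerced to an accuracy.
#'
#' @param config A [study_config()].
#' @param recordings Optional list of [recording()]s to analyse instead
#'   of simulating (their `group_tag` is kept).
#' @param out_dir Optional directory to write result tables into (see
#'   [write_results()]).
#' @param verbose Print progress.
#' @return An object of class `micf_study`: list with `results` (one
#'   row per subject x feature x classifier), `summary`, `comparisons`,
#'   `coherence` (per-subject comparisons + significance counts),
#'   `power_diff`, `rejection_log`, `manifest`.
#' @export
run_study <- function(config, recordings = NULL, out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "micf_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(recordings)) {
    say("simulating %d + %d subjects",
        config$n_responsive, config$n_null)
    recordings <- generate_cohort(config$n_responsive, config$n_null,
                                  config$spec, config$seed)
  }
  binning <- frequency_binning()
  rows <- list(); rej <- list(); coh <- list(); pdiff <- list()
  for (rec in recordings) {
    say("subject %s", rec$subject_id)
    tr <- preprocess_recording(rec, config$band, config$target_rate)
    tr <- segment_trials(tr, config$epoch_seconds)
    tr <- reject_artifacts(tr)
    rej[[length(rej) + 1]] <- tr$rejected_log
    if (length(tr$epochs) < 4 ||
        min(table(factor(tr$condition,
                         levels = c("imagery", "rest")))) < 2) {
      warning("subject ", rec$subject_id,
              " has too few clean trials; skipped")
      next
    }
    tr <- common_average_reference(tr)
    for (fn in config$features) {
      fm <- extract_feature_matrix(tr, fn, binning, config$feature_opts)
      for (cl in config$classifiers) {
        r <- loocv(fm, cl, compat_pdf = config$compat_pdf)
        rows[[length(rows) + 1]] <- result_row(r)
      }
    }
    subset <- if (config$subset_13) micf_display_subset() else NULL
    coh[[length(coh) + 1]] <- coherence_comparison(
      tr, binning, q = config$q, fisher_on_msc = config$fisher_on_msc)
    pdiff[[length(pdiff) + 1]] <-
      power_difference_summary(tr, binning, subset)$per_subject[[1]]
  }
  if (!length(rows)) stop("stage error [classify]: no subjects survived")
  results <- do.call(rbind, rows)
  summary <- summarize_group(results, config$alpha, config$q)
  comparisons <- NULL
  if (length(config$features) >= 2 && length(config$classifiers) >= 2) {
    best <- if ("svm_linear" %in% results$classifier) "svm_linear"
            else results$classifier[1]
    comparisons <- compare_features_and_classifiers(summary, config$q,
                                                    best)
  }
  subset <- if (config$subset_13) micf_display_subset() else NULL
  counts <- subject_significance_counts(coh, subset)
  arr <- simplify2array(pdiff)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  pd_mean <- apply(arr, c(1, 2), mean)
  pd_sd <- apply(arr, c(1, 2), stats::sd)
  dimnames(pd_mean) <- dimnames(pd_sd) <- dimnames(pdiff[[1]])
  manifest <- list(package = "micf",
                   version = as.character(utils::packageVersion("micf")),
                   seed = config$seed, config_md5 = config_hash(config),
                   n_subjects = length(recordings),
                   n_results = nrow(results))
  bundle <- structure(
    list(results = results, summary = summary, comparisons = comparisons,
         coherence = list(per_subject = coh, counts = counts),
         power_diff = list(mean = pd_mean, sd = pd_sd),
         rejection_log = do.call(rbind, rej), manifest = manifest,
         config = config),
    class = "micf_study")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' @export
print.micf_study <- function(x, ...) {
  cat(sprintf(
    "<micf_study> %d results (%d failed) over %d subjects; seed %d\n",
    nrow(x$results), sum(x$results$failed), x$manifest$n_subjects,
    x$manifest$seed))
  invisible(x)
}

#' @export
summary.micf_study <- function(object, ...) object$summary

#' Write a study result bundle to disk
#'
#' Tab-separated tables (`results.tsv`, `summary.tsv`,
#' `rejection_log.tsv`, `coherence_counts.tsv`, `power_diff_mean.tsv`,
#' comparison tables) and a JSON `manifest.json`.
#'
#' @param bundle A `micf_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "micf_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(bundle$results, "results.tsv")
  tsv(bundle$summary, "summary.tsv")
  if (!is.null(bundle$rejection_log) && nrow(bundle$rejection_log))
    tsv(bundle$rejection_log, "rejection_log.tsv")
  if (!is.null(bundle$comparisons)) {
    tsv(bundle$comparisons$classifiers, "comparison_classifiers.tsv")
    tsv(bundle$comparisons$features_metrics, "comparison_features_metrics.tsv")
    tsv(bundle$comparisons$features_counts, "comparison_features_counts.tsv")
  }
  cm <- as.data.frame(bundle$coherence$counts)
  cm <- cbind(pair = rownames(bundle$coherence$counts), cm)
  tsv(cm, "coherence_counts.tsv")
  pm <- as.data.frame(bundle$power_diff$mean)
  pm <- cbind(channel = rownames(bundle$power_diff$mean), pm)
  tsv(pm, "power_diff_mean.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
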