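#' Re-reference, filter and downsample a recording
#'
#' Applies, in order: mastoid-average re-referencing (when mastoid
#' channels are present; otherwise the reference is left untouched and a
#' notice is logged), zero-phase Butterworth band-pass filtering, and
#' anti-aliased decimation to `target_rate`. The band-pass is realized as
#' an order-2 high-pass at `band[1]` plus an order-8 low-pass at
#' `band[2]`, each run forward-backward (zero net phase, 48 dB/oct
#' roll-off per pass at the upper edge).
#'
#' Mastoid channels are dropped from the output after re-referencing.
#'
#' @param rec A [recording()].
#' @param band Pass band `c(low, high)` in Hz; must lie inside
#'   `(0, rate/2)`.
#' @param target_rate Output sampling rate in Hz; `rate/target_rate` must
#'   be a whole number.
#' @return A filtered [recording()] at `target_rate`, with a character
#'   vector of log messages in attribute `"preprocess_log"`.
#' @export
preprocess_recording <- function(rec, band = c(1, 48), target_rate = 250) {
  stopifnot(inherits(rec, "micf_recording"))
  log <- character(0)
  if (band[1] <= 0 || band[2] >= rec$rate / 2 || band[1] >= band[2])
    stop("parameter error: band must lie inside (0, rate/2)")

  mast <- intersect(micf_mastoid_channels(), rec$channel_labels)
  x <- rec$samples
  if (length(mast) >= 1) {
    ref <- colMeans(x[mast, , drop = FALSE])
    x <- sweep(x, 2, ref)
    x <- x[setdiff(rec$channel_labels, mast), , drop = FALSE]
    log <- c(log, sprintf("re-referenced to mastoid average (%s)",
                          paste(mast, collapse = ", ")))
  } else {
    log <- c(log, "no mastoid channels found; reference left unchanged")
  }

  hp <- signal::butter(2, band[1] / (rec$rate / 2), type = "high")
  lp <- signal::butter(8, band[2] / (rec$rate / 2), type = "low")
  for (i in seq_len(nrow(x))) {
    x[i, ] <- signal::filtfilt(hp, x[i, ])
    x[i, ] <- signal::filtfilt(lp, x[i, ])
  }
  log <- c(log, sprintf("zero-phase Butterworth band-pass %g-%g Hz",
                        band[1], band[2]))

  events <- rec$events
  rate <- rec$rate
  if (rate != target_rate) {
    fac <- rate / target_rate
    if (abs(fac - round(fac)) > 1e-9 || fac < 1)
      stop("parameter error: rate must be an integer multiple of target_rate")
    fac <- as.integer(round(fac))
    aa <- signal::butter(8, 0.8 * (target_rate / 2) / (rate / 2),
                         type = "low")
    for (i in seq_len(nrow(x))) x[i, ] <- signal::filtfilt(aa, x[i, ])
    keep <- seq(1L, ncol(x), by = fac)
    x <- x[, keep, drop = FALSE]
    if (nrow(events)) events$sample <- (events$sample - 1L) %/% fac + 1L
    rate <- target_rate
    log <- c(log, sprintf("downsampled by %d to %g Hz", fac, target_rate))
  }

  out <- recording(x, rate, rownames(x), events,
                   subject_id = rec$subject_id, group_tag = rec$group_tag)
  attr(out, "preprocess_log") <- log
  out
}

#' Segment a recording into fixed-length labeled epochs
#'
#' One epoch per event, starting at the event sample (the end of the
#' acoustic instruction). Events whose epoch would overrun the recording
#' are skipped and logged.
#'
#' @param rec A [recording()] with events.
#' @param epoch_seconds Epoch length in seconds (default 4).
#' @return An object of class `micf_trialset`.
#' @export
segment_trials <- function(rec, epoch_seconds = 4) {
  stopifnot(inherits(rec, "micf_recording"))
  if (!nrow(rec$events)) stop("empty-trial error: recording has no events")
  len <- sec_to_samp(epoch_seconds, rec$rate)
  epochs <- list(); cond <- character(0)
  log <- data.frame(event = integer(0), condition = character(0),
                    rule = character(0), channel = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rec$events))) {
    from <- rec$events$sample[i]
    to <- from + len - 1L
    if (to > ncol(rec$samples)) {
      log <- rbind(log, data.frame(
        event = i, condition = rec$events$condition[i],
        rule = "overrun", channel = NA_character_))
      next
    }
    epochs[[length(epochs) + 1L]] <- rec$samples[, from:to, drop = FALSE]
    cond <- c(cond, rec$events$condition[i])
  }
  trialset(epochs, cond, rownames(rec$samples), rec$rate,
           rec$subject_id, rec$group_tag, rejected_log = log)
}

trialset <- function(epochs, condition, channel_labels, rate,
                     subject_id = "S00", group_tag = "unknown",
                     rejected_log = NULL) {
  if (length(epochs)) {
    dims <- vapply(epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all epochs must share the same shape")
  }
  structure(
    list(epochs = epochs, condition = as.character(condition),
         channel_labels = channel_labels, rate = rate,
         subject_id = subject_id, group_tag = group_tag,
         rejected_log = rejected_log),
    class = "micf_trialset")
}

#' @export
print.micf_trialset <- function(x, ...) {
  tab <- table(factor(x$condition, levels = c("imagery", "rest")))
  cat(sprintf(
    "<micf_trialset> %s [%s]: %d epochs (%s), %d channels @ %g Hz\n",
    x$subject_id, x$group_tag, length(x$epochs),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    length(x$channel_labels), x$rate))
  if (!is.null(x$rejected_log) && nrow(x$rejected_log))
    cat("  rejections logged:", nrow(x$rejected_log), "\n")
  invisible(x)
}

#' Per-condition retained trial counts
#' @param trials A `micf_trialset`.
#' @return Named integer vector with entries `imagery` and `rest`.
#' @export
trial_counts <- function(trials) {
  c(imagery = sum(trials$condition == "imagery"),
    rest = sum(trials$condition == "rest"))
}

# running max/min over a sliding window of `w` samples
run_max <- function(x, w) {
  n <- length(x) - w + 1L
  out <- x[seq_len(n)]
  for (k in seq_len(w - 1L)) out <- pmax(out, x[seq_len(n) + k])
  out
}
run_min <- function(x, w) {
  n <- length(x) - w + 1L
  out <- x[seq_len(n)]
  for (k in seq_len(w - 1L)) out <- pmin(out, x[seq_len(n) + k])
  out
}

#' Automatic artifact rejection
#'
#' An epoch is removed when any channel violates one of three rules:
#' (a) an absolute sample-to-sample voltage step above `step_uv`;
#' (b) a peak-to-peak range above `range_uv` within any 200-ms window;
#' (c) a peak-to-peak range below `min_range_uv` within any 100-ms window
#' (flat-line detector). Removal reasons are logged per epoch; surviving
#' per-condition counts feed the proportional chance criterion.
#'
#' @param trials A `micf_trialset` (250 Hz analysis rate assumed for the
#'   window lengths, which are computed from the actual rate).
#' @param step_uv,range_uv,min_range_uv Thresholds in microvolts.
#' @return The filtered `micf_trialset`; the rejection log gains one row
#'   per (epoch, rule) with the first offending channel.
#' @export
reject_artifacts <- function(trials, step_uv = 50, range_uv = 200,
                             min_range_uv = 0.5) {
  stopifnot(inherits(trials, "micf_trialset"))
  w200 <- max(2L, sec_to_samp(0.2, trials$rate))
  w100 <- max(2L, sec_to_samp(0.1, trials$rate))
  keep <- logical(length(trials$epochs))
  log <- trials$rejected_log
  if (is.null(log))
    log <- data.frame(event = integer(0), condition = character(0),
                      rule = character(0), channel = character(0),
                      stringsAsFactors = FALSE)
  for (e in seq_along(trials$epochs)) {
    ep <- trials$epochs[[e]]
    rules <- character(0); chans <- character(0)
    for (i in seq_len(nrow(ep))) {
      x <- ep[i, ]
      lab <- trials$channel_labels[i]
      if (any(abs(diff(x)) > step_uv)) {
        rules <- c(rules, "max_step"); chans <- c(chans, lab)
      }
      if (any(run_max(x, w200) - run_min(x, w200) > range_uv)) {
        rules <- c(rules, "max_range_200ms"); chans <- c(chans, lab)
      }
      if (any(run_max(x, w100) - run_min(x, w100) < min_range_uv)) {
        rules <- c(rules, "min_range_100ms"); chans <- c(chans, lab)
      }
    }
    keep[e] <- length(rules) == 0L
    if (length(rules)) {
      first <- !duplicated(rules)
      log <- rbind(log, data.frame(
        event = e, condition = trials$condition[e],
        rule = rules[first], channel = chans[first],
        stringsAsFactors = FALSE))
    }
  }
  out <- trialset(trials$epochs[keep], trials$condition[keep],
                  trials$channel_labels, trials$rate,
                  trials$subject_id, trials$group_tag, rejected_log = log)
  if (!length(out$epochs))
    attr(out, "empty_after_rejection") <- TRUE
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over channels from each channel.
#' Column sums of every epoch are exactly zero afterwards; the operation
#' is idempotent.
#'
#' @param trials A `micf_trialset` with at least 2 channels.
#' @return The re-referenced `micf_trialset`.
#' @export
common_average_reference <- function(trials) {
  stopifnot(inherits(trials, "micf_trialset"))
  if (length(trials$channel_labels) < 2)
    stop("common average reference needs at least 2 channels")
  trials$epochs <- lapply(trials$epochs, function(ep)
    sweep(ep, 2, colMeans(ep)))
  trials
}
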