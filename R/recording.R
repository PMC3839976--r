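#' Construct a continuous multichannel EEG recording
#'
#' A recording bundles a channels-by-time sample matrix (microvolts), its
#' sampling rate, channel labels, and the event markers that tag the onset
#' of each trial's response window with its condition.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param rate Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `samples`.
#' @param events Data frame with columns `sample` (1-based sample index,
#'   strictly increasing) and `condition` (`"imagery"` or `"rest"`).
#' @param subject_id Subject identifier string.
#' @param group_tag `"responsive"` or `"null"` for synthetic subjects;
#'   free-form for imported data.
#' @return An object of class `micf_recording`.
#' @export
recording <- function(samples, rate, channel_labels,
                      events = empty_events(),
                      subject_id = "S00", group_tag = "unknown") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per row of samples required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("sample", "condition") %in% names(events)))
      stop("events need columns 'sample' and 'condition'")
    if (any(diff(events$sample) <= 0))
      stop("event sample indices must be strictly increasing")
    if (any(events$sample < 1L) || any(events$sample > ncol(samples)))
      stop("event sample indices must lie within the recording")
    if (!all(events$condition %in% c("imagery", "rest")))
      stop("conditions restricted to 'imagery' and 'rest'")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, rate = rate,
         channel_labels = as.character(channel_labels),
         events = events, subject_id = subject_id, group_tag = group_tag),
    class = "micf_recording")
}

empty_events <- function() {
  data.frame(sample = integer(0), condition = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.micf_recording <- function(x, ...) {
  secs <- ncol(x$samples) / x$rate
  cat(sprintf(
    "<micf_recording> %s [%s]: %d channels x %d samples (%.1f s @ %g Hz), %d events\n",
    x$subject_id, x$group_tag, nrow(x$samples), ncol(x$samples),
    secs, x$rate, nrow(x$events)))
  if (nrow(x$events))
    cat("  conditions:",
        paste(sprintf("%s=%d", names(table(x$events$condition)),
                      table(x$events$condition)), collapse = ", "), "\n")
  invisible(x)
}

# seconds -> sample count at the recording's rate
sec_to_samp <- function(sec, rate) as.integer(round(sec * rate))
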