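#' Standard 10-20 montage used throughout the package
#'
#' The analysis montage consists of the 21 scalp electrodes retained for
#' feature extraction plus the two mastoid electrodes (`M1`, `M2`) used
#' only to rebuild the reference.
#'
#' @return Character vector of channel labels (23 entries).
#' @export
micf_montage <- function() {
  c(micf_analysis_channels(), micf_mastoid_channels())
}

#' The 21 scalp electrodes entering the analysis
#' @return Character vector of 21 channel labels.
#' @export
micf_analysis_channels <- function() {
  c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2", "F7", "F8",
    "Fz", "Cz", "Pz", "FC1", "FC2", "CP1", "CP2", "FC5", "FC6",
    "CP5", "CP6")
}

#' Mastoid electrode labels recognised for re-referencing
#' @return Character vector.
#' @export
micf_mastoid_channels <- function() c("M1", "M2")

#' The 13-electrode display subset used for condition-difference maps
#' @return Character vector of 13 channel labels.
#' @export
micf_display_subset <- function() {
  c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2", "F7", "F8",
    "Fz", "Cz", "Pz")
}

# unordered channel pairs (i < j) as a 2-column character matrix
channel_pairs <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(labels[idx[, 1L]], labels[idx[, 2L]])
}
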