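# --- EDF (16-bit) -----------------------------------------------------

pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

# render a number into <= 8 ASCII bytes, as EDF headers require
num8 <- function(x) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot render ", x, " in 8 bytes")
}

#' Write a recording to EDF
#'
#' Plain 16-bit EDF with one-second data records in physical microvolt
#' units. Samples beyond the last whole record are dropped. EDF itself
#' carries no event markers, so events and group metadata round-trip
#' through a JSON sidecar `<path>.events.json`.
#'
#' @param rec A [recording()]; `rate` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "micf_recording"))
  rate <- as.integer(round(rec$rate))
  x <- rec$samples
  nch <- nrow(x)
  n_rec <- ncol(x) %/% rate
  if (n_rec < 1) stop("recording shorter than one data record")
  x <- x[, seq_len(n_rec * rate), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad("0", 8))
  wr(pad(rec$subject_id, 80))
  wr(pad(paste0("group=", rec$group_tag), 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + nch), 8))
  wr(pad("", 44))
  wr(pad(n_rec, 8))
  wr(pad("1", 8))
  wr(pad(nch, 4))
  wr(paste(vapply(rec$channel_labels, pad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * nch))                     # transducer
  wr(paste(rep(pad("uV", 8), nch), collapse = ""))
  wr(paste(vapply(pmin_, function(v) pad(num8(v), 8), ""), collapse = ""))
  wr(paste(vapply(pmax_, function(v) pad(num8(v), 8), ""), collapse = ""))
  wr(paste(rep(pad(dmin, 8), nch), collapse = ""))
  wr(paste(rep(pad(dmax, 8), nch), collapse = ""))
  wr(strrep(" ", 80 * nch))                     # prefiltering
  wr(paste(rep(pad(rate, 8), nch), collapse = ""))
  wr(strrep(" ", 32 * nch))

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    for (i in seq_len(nch)) {
      d <- round((x[i, cols] - pmin_[i]) / scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  sidecar <- paste0(path, ".events.json")
  jsonlite::write_json(
    list(subject_id = rec$subject_id, group_tag = rec$group_tag,
         rate = rec$rate,
         events = rec$events),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads plain 16-bit EDF written by [write_edf()] (or compatible
#' single-rate EDF files) and the event sidecar when present.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("format error: truncated EDF header")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdnum <- function(n) as.numeric(trimws(rd(n)))
  version <- trimws(rd(8))
  if (!identical(version, "0")) stop("format error: not an EDF file")
  patient <- trimws(rd(80))
  recid <- trimws(rd(80))
  rd(16)                                        # date + time
  header_bytes <- rdnum(8)
  rd(44)
  n_rec <- rdnum(8)
  rec_dur <- rdnum(8)
  nch <- as.integer(rdnum(4))
  if (is.na(nch) || nch < 1 || is.na(n_rec) || n_rec < 1)
    stop("format error: malformed EDF header")
  if (sz < header_bytes) stop("format error: truncated EDF header")
  field <- function(w) vapply(seq_len(nch), function(i) trimws(rd(w)), "")
  labels <- field(16)
  field(80)
  field(8)                                      # physical dimension
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr)) != 1)
    stop("format error: mixed per-signal rates are not supported")
  rate <- spr[1] / rec_dur
  need <- header_bytes + 2 * sum(spr) * n_rec
  if (sz < need) stop("format error: truncated EDF data")
  x <- matrix(0, nch, spr[1] * n_rec)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      x[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (d - dmin[i]) * scale[i]
    }
  }
  events <- empty_events()
  subject_id <- if (nzchar(patient)) patient else "S00"
  group_tag <- sub("^group=", "", recid)
  if (!nzchar(group_tag)) group_tag <- "unknown"
  sidecar <- paste0(path, ".events.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$events) && nrow(as.data.frame(meta$events)))
      events <- data.frame(sample = as.integer(meta$events$sample),
                           condition = meta$events$condition,
                           stringsAsFactors = FALSE)
    if (!is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (!is.null(meta$group_tag)) group_tag <- meta$group_tag
  }
  recording(x, rate, labels, events, subject_id, group_tag)
}

# --- flat-binary array dialect ---------------------------------------

#' Write a recording as flat binary + JSON header
#'
#' Float64 little-endian samples in `<prefix>.bin` (column-major,
#' channels x samples) with a JSON header `<prefix>.json` documenting
#' `shape`, `dtype`, `byte_order`, `order`, `rate`, `channel_labels`,
#' `events`, `subject_id` and `group_tag`. Round trips bit-exactly.
#'
#' @param rec A [recording()].
#' @param prefix Output path prefix (without extension).
#' @return The header path, invisibly.
#' @export
write_recording_array <- function(rec, prefix) {
  stopifnot(inherits(rec, "micf_recording"))
  bin <- paste0(prefix, ".bin")
  hdr <- paste0(prefix, ".json")
  con <- file(bin, "wb")
  writeBin(as.vector(rec$samples), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "micf-array-v1", dtype = "float64",
         byte_order = "little", order = "column_major",
         shape = dim(rec$samples), rate = rec$rate,
         channel_labels = rec$channel_labels, events = rec$events,
         subject_id = rec$subject_id, group_tag = rec$group_tag),
    hdr, auto_unbox = TRUE, digits = NA)
  invisible(hdr)
}

read_recording_array <- function(hdr) {
  meta <- tryCatch(jsonlite::read_json(hdr, simplifyVector = TRUE),
                   error = function(e) stop("format error: bad JSON header"))
  if (!identical(meta$format, "micf-array-v1"))
    stop("format error: not a micf array header")
  bin <- sub("\\.json$", ".bin", hdr)
  if (!file.exists(bin)) stop("format error: missing .bin payload")
  n <- prod(meta$shape)
  con <- file(bin, "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n) stop("format error: truncated .bin payload")
  events <- if (length(meta$events) && length(meta$events$sample))
    data.frame(sample = as.integer(meta$events$sample),
               condition = meta$events$condition,
               stringsAsFactors = FALSE)
  else empty_events()
  recording(matrix(x, meta$shape[1], meta$shape[2]), meta$rate,
            meta$channel_labels, events, meta$subject_id, meta$group_tag)
}

#' Read a recording from EDF or the array dialect
#'
#' Dispatches on the file extension: `.edf` or a `.json` array header.
#'
#' @param path File path.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(read_recording_array(path))
  stop("format error: unknown recording format: ", path)
}
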