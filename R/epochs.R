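#' Epoched EEG container
#'
#' An `eeg_epochs` object holds epoched multichannel EEG as a numeric array
#' `[n_trials x n_channels x n_samples]` in microvolts, together with integer
#' class labels, 10-20 channel names, the sampling rate, and the epoch start
#' time relative to the first motor-imagery onset.
#'
#' @param data numeric array `[n_trials x n_channels x n_samples]`, microvolts.
#' @param labels integer vector, one label per trial, values in `0..n_classes-1`.
#' @param channel_names character vector of unique 10-20 electrode labels.
#' @param fs sampling rate in Hz.
#' @param t0 epoch start time in seconds relative to first-MI onset
#'   (e.g. `-2` when the epoch carries 2 s of pre-onset baseline).
#' @param subject_id subject identifier string.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, channel_names, fs, t0 = 0,
                       subject_id = "S01") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array [trials x channels x samples]")
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  x <- structure(
    list(data = data, labels = labels,
         channel_names = as.character(channel_names),
         fs = as.numeric(fs), t0 = as.numeric(t0),
         subject_id = as.character(subject_id)),
    class = "eeg_epochs")
  validate_epochs(x)
  x
}

#' @rdname eeg_epochs
#' @param x an `eeg_epochs` object.
#' @export
validate_epochs <- function(x) {
  d <- dim(x$data)
  if (any(!is.finite(x$data)))
    stop("epoch data contains non-finite values")
  if (length(x$labels) != d[1L])
    stop(sprintf("labels length (%d) != n_trials (%d)", length(x$labels), d[1L]))
  if (any(x$labels < 0L))
    stop("labels must be non-negative integers")
  if (anyDuplicated(x$channel_names))
    stop("channel_names contains duplicates: ",
         paste(unique(x$channel_names[duplicated(x$channel_names)]), collapse = ", "))
  if (length(x$channel_names) != d[2L])
    stop(sprintf("channel_names length (%d) != n_channels (%d)",
                 length(x$channel_names), d[2L]))
  if (!is.finite(x$fs) || x$fs <= 0) stop("fs must be a positive number")
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subject %s, t = [%g, %g) s, classes: %s\n", x$subject_id,
              x$t0, x$t0 + d[3] / x$fs,
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

#' @rdname eeg_epochs
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname eeg_epochs
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname eeg_epochs
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' Epoch time axis
#'
#' Sample `i` covers time `[t0 + (i-1)/fs, t0 + i/fs)`; the returned axis
#' gives the left edge of each sample.
#' @param x an `eeg_epochs` object.
#' @return numeric vector of length `n_samples(x)`.
#' @export
epoch_times <- function(x) x$t0 + (seq_len(n_samples(x)) - 1L) / x$fs

#' Channel index lookup
#' @param x an `eeg_epochs` object.
#' @param channel a channel name.
#' @keywords internal
channel_index <- function(x, channel) {
  i <- match(channel, x$channel_names)
  if (is.na(i)) stop("unknown channel: ", channel)
  i
}

#' Crop epochs to a time window
#'
#' @param x an `eeg_epochs` object.
#' @param tmin,tmax half-open window `[tmin, tmax)` in seconds relative to
#'   first-MI onset.
#' @return an `eeg_epochs` covering the window.
#' @export
crop_epochs <- function(x, tmin, tmax) {
  tt <- epoch_times(x)
  keep <- which(tt >= tmin - 1e-9 & tt < tmax - 1e-9)
  if (!length(keep)) stop("crop window [", tmin, ", ", tmax, ") is empty")
  eeg_epochs(x$data[, , keep, drop = FALSE], x$labels, x$channel_names,
             x$fs, t0 = tt[keep[1L]], subject_id = x$subject_id)
}

#' Subset trials
#' @param x an `eeg_epochs` object.
#' @param idx trial indices.
#' @export
subset_trials <- function(x, idx) {
  eeg_epochs(x$data[idx, , , drop = FALSE], x$labels[idx], x$channel_names,
             x$fs, x$t0, x$subject_id)
}

#' Select channels
#' @param x an `eeg_epochs` object.
#' @param channels channel names to keep (order preserved as given).
#' @export
select_channels <- function(x, channels) {
  idx <- vapply(channels, function(ch) channel_index(x, ch), integer(1))
  eeg_epochs(x$data[, idx, , drop = FALSE], x$labels, channels,
             x$fs, x$t0, x$subject_id)
}

#' Concatenate epoch sets across trials
#'
#' All sets must share channels, sampling rate and epoch window. Used for
#' pooling subjects, e.g. in leave-one-subject-out training.
#' @param sets a list of `eeg_epochs`.
#' @param subject_id subject tag for the combined set.
#' @export
combine_epochs <- function(sets, subject_id = "pooled") {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (!identical(s$channel_names, ref$channel_names))
      stop("channel sets differ between epoch sets")
    if (s$fs != ref$fs || abs(s$t0 - ref$t0) > 1e-9 ||
        n_samples(s) != n_samples(ref))
      stop("sampling rate or epoch window differs between epoch sets")
  }
  ntot <- sum(vapply(sets, n_trials, integer(1)))
  dat <- array(0, c(ntot, n_channels(ref), n_samples(ref)))
  lab <- integer(ntot)
  at <- 0L
  for (s in sets) {
    n <- n_trials(s)
    dat[at + seq_len(n), , ] <- s$data
    lab[at + seq_len(n)] <- s$labels
    at <- at + n
  }
  eeg_epochs(dat, lab, ref$channel_names, ref$fs, ref$t0, subject_id)
}

# ---------------------------------------------------------------------------
# On-disk container.
#
# Single self-describing binary file, documented byte-exactly:
#   bytes 0..7   : magic "EEGEPOC1" (ASCII)
#   bytes 8..11  : header length L, little-endian int32
#   bytes 12..11+L : JSON header (UTF-8) with fields
#       dims [n_trials, n_channels, n_samples], dtype "float32"|"float64",
#       fs, t0, channel_names, subject_id, labels (int array)
#   remaining    : raw sample data, little-endian, in R column-major order of
#                  the [trials x channels x samples] array (trial index
#                  fastest, then channel, then sample).
# ---------------------------------------------------------------------------

EPOCH_MAGIC <- "EEGEPOC1"

#' Write epochs to the on-disk container
#'
#' @param x an `eeg_epochs` object.
#' @param path output file path (conventionally `.eegepo`).
#' @param dtype on-disk sample type, `"float32"` (default) or `"float64"`.
#'   `"float32"` halves file size; writing quantises to 24-bit mantissa.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  validate_epochs(x)
  hdr <- list(dims = dim(x$data), dtype = dtype, fs = x$fs, t0 = x$t0,
              channel_names = x$channel_names, subject_id = x$subject_id,
              labels = x$labels)
  hj <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(EPOCH_MAGIC), con)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  writeBin(as.vector(x$data), con,
           size = if (dtype == "float32") 4L else 8L, endian = "little")
  invisible(path)
}

#' Read epochs from the on-disk container
#'
#' @param path file written by [write_epochs()].
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, EPOCH_MAGIC))
    stop("not an epoch container (bad magic): ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  for (f in c("dims", "dtype", "fs", "t0", "channel_names", "subject_id",
              "labels"))
    if (is.null(hdr[[f]])) stop("epoch container missing field: ", f)
  dims <- as.integer(hdr$dims)
  if (length(hdr$labels) != dims[1L])
    stop(sprintf("epoch container field mismatch: %d labels for %d trials",
                 length(hdr$labels), dims[1L]))
  n <- prod(dims)
  dat <- readBin(con, "double", n,
                 size = if (hdr$dtype == "float32") 4L else 8L,
                 endian = "little")
  if (length(dat) != n) stop("epoch container truncated: ", path)
  eeg_epochs(array(dat, dims), hdr$labels, hdr$channel_names, hdr$fs,
             hdr$t0, hdr$subject_id)
}
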