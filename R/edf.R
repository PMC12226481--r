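# Minimal EDF (European Data Format) reader for continuous recordings, plus
# an events-table loader, so real recordings can enter the pipeline. Only
# uniform sampling rates across channels are supported; annotations channels
# ("EDF Annotations") are dropped.

read_edf_str <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous EDF recording
#'
#' @param path EDF file.
#' @return list with `data` (matrix `[channels x samples]`, physical units),
#'   `fs` (Hz), `channel_names`, `n_records`, `record_s`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_str(con, 8L)
  if (!startsWith(version, "0"))
    stop("not an EDF file (bad version field): ", path)
  invisible(readBin(con, "raw", 80L + 80L + 8L + 8L))  # patient/rec/date/time
  invisible(read_edf_str(con, 8L))                     # header length
  invisible(readBin(con, "raw", 44L))
  n_rec <- as.integer(read_edf_str(con, 8L))
  rec_s <- as.numeric(read_edf_str(con, 8L))
  ns <- as.integer(read_edf_str(con, 4L))
  lab <- vapply(seq_len(ns), function(i) read_edf_str(con, 16L), character(1))
  invisible(readBin(con, "raw", ns * 80L))             # transducer
  invisible(readBin(con, "raw", ns * 8L))              # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_str(con, 8L)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_str(con, 8L)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_str(con, 8L)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i)
    as.numeric(read_edf_str(con, 8L)), numeric(1))
  invisible(readBin(con, "raw", ns * 80L))             # prefiltering
  spr <- vapply(seq_len(ns), function(i)
    as.integer(read_edf_str(con, 8L)), integer(1))
  invisible(readBin(con, "raw", ns * 32L))

  keep <- lab != "EDF Annotations"
  if (length(unique(spr[keep])) != 1L)
    stop("channels have differing sampling rates; not supported")
  fs <- spr[keep][1L] / rec_s
  dat <- matrix(0, sum(keep), n_rec * spr[keep][1L])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  row_at <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", spr[s], size = 2L, endian = "little")
      if (!keep[s]) next
      dat[row_at[s], (r - 1L) * spr[s] + seq_len(spr[s])] <-
        (v - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  list(data = dat, fs = fs, channel_names = lab[keep],
       n_records = n_rec, record_s = rec_s)
}

#' Read a trial events table
#'
#' CSV with columns `onset_sample` (1-based sample index of the first-MI
#' onset) and `label` (0-based class).
#'
#' @param path CSV file.
#' @return data.frame with `onset_sample`, `label`.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("onset_sample", "label") %in% names(ev)))
    stop("events CSV must have columns onset_sample,label")
  ev
}

#' Epochs from an EDF recording plus events table
#'
#' Runs the full preprocessing chain on the recording and extracts
#' baseline-corrected epochs at the listed onsets. Note: ocular-artifact
#' removal is not performed; recordings should be pre-cleaned.
#'
#' @param edf_path EDF file.
#' @param events_path events CSV (see [read_events_csv()]).
#' @param cfg a [preprocess_config()].
#' @param subject_id subject tag.
#' @return an [eeg_epochs()] object.
#' @export
epochs_from_edf <- function(edf_path, events_path,
                            cfg = preprocess_config(), subject_id = "S01") {
  rec <- read_edf(edf_path)
  ev <- read_events_csv(events_path)
  preprocess(rec$data, rec$fs, ev$onset_sample, ev$label,
             rec$channel_names, cfg, subject_id)
}
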