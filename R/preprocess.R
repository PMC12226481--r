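#' Preprocessing configuration
#'
#' Parameters of the standard preprocessing chain: zero-phase FIR bandpass,
#' common average reference, downsampling, epoch extraction with baseline
#' correction from the 1-s pre-onset window.
#'
#' @param band_lo,band_hi bandpass edges in Hz (defaults 0.1 and 30).
#' @param fir_order FIR order (number of taps minus one). `NULL` (default)
#'   chooses a Hamming-window design with transition width equal to
#'   `band_lo`, i.e. `order = ceil(3.3 * fs / band_lo)` rounded up to even.
#' @param target_fs sampling rate after downsampling, Hz (default 100).
#' @param epoch_window epoch extent `[start, end)` in seconds relative to the
#'   first-MI onset (default `c(0, 12)`: the 12-s segment spanning the first
#'   5-s MI phase, the 2-s preparation gap, and the second 5-s MI phase).
#' @param baseline_window window whose per-channel mean is subtracted from
#'   each epoch, seconds relative to onset (default `c(-1, 0)`).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_lo = 0.1, band_hi = 30, fir_order = NULL,
                              target_fs = 100, epoch_window = c(0, 12),
                              baseline_window = c(-1, 0)) {
  cfg <- structure(list(band_lo = band_lo, band_hi = band_hi,
                        fir_order = fir_order, target_fs = target_fs,
                        epoch_window = epoch_window,
                        baseline_window = baseline_window),
                   class = "preprocess_config")
  if (!(band_lo > 0 && band_lo < band_hi))
    stop("need 0 < band_lo < band_hi")
  if (band_hi >= target_fs / 2)
    stop("band_hi must lie below the post-downsampling Nyquist (target_fs/2)")
  if (epoch_window[1] >= epoch_window[2])
    stop("epoch_window start must precede end")
  cfg
}

# Zero-phase application of a symmetric (linear-phase) FIR: single FFT-domain
# pass on a reflection-padded signal, with the constant group delay removed.
# x: [channels x samples]; b: odd-length symmetric taps.
fir_apply <- function(x, b) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  L <- length(b)
  d <- (L - 1L) %/% 2L
  p <- min(L, n - 1L)                       # reflection pad length
  left  <- x[, seq(p + 1L, 2L), drop = FALSE]
  right <- x[, seq(n - 1L, n - p), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  nfft <- stats::nextn(np + L - 1L, 2)
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  B <- stats::fft(c(b, rep(0, nfft - L)))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  # full convolution index k corresponds to sum b[j] * xp[k - j + 1];
  # zero-phase output sample t of x sits at k = p + t + d
  t(y)[, p + d + seq_len(n), drop = FALSE]
}

# Hamming-window FIR design for the bandpass, delegated to signal::fir1.
design_bandpass <- function(fs, band_lo, band_hi, fir_order = NULL) {
  ny <- fs / 2
  if (band_hi >= ny) stop("band_hi (", band_hi, " Hz) is at/above Nyquist (",
                          ny, " Hz)")
  if (is.null(fir_order)) {
    tw <- band_lo                           # Hz; Hamming width ~ 3.3/N * fs
    fir_order <- ceiling(3.3 * fs / tw)
  }
  if (fir_order %% 2 == 1) fir_order <- fir_order + 1L  # even order, odd taps
  signal::fir1(fir_order, c(band_lo, band_hi) / ny, type = "pass")
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) bandpass applied per channel with exact zero
#' phase (linear-phase taps, group delay compensated). Output length equals
#' input length; edges are handled by reflection padding.
#'
#' @param x multichannel signal, matrix `[channels x samples]` (a vector is
#'   treated as one channel).
#' @param fs sampling rate in Hz.
#' @param cfg a [preprocess_config()].
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_fir <- function(x, fs, cfg = preprocess_config()) {
  b <- design_bandpass(fs, cfg$band_lo, cfg$band_hi, cfg$fir_order)
  fir_apply(x, b)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean of the output is zero at every sample.
#'
#' @param x matrix `[channels x samples]`, at least two channels.
#' @return re-referenced signal, same shape.
#' @export
common_average_reference <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L)
    stop("common average reference needs at least 2 channels")
  sweep(x, 2L, colMeans(x), "-")
}

#' Resample a multichannel signal
#'
#' Downsampling applies an anti-alias zero-phase FIR (cutoff at 80% of the
#' new Nyquist) before decimation. Output length is
#' `round(n * fs_out / fs_in)`.
#'
#' @param x matrix `[channels x samples]` or vector.
#' @param fs_in,fs_out input/output sampling rates in Hz.
#' @return resampled signal.
#' @export
resample_to <- function(x, fs_in, fs_out) {
  if (!is.finite(fs_out) || fs_out <= 0) stop("fs_out must be positive")
  if (fs_out > fs_in) stop("upsampling not supported (fs_out > fs_in)")
  if (fs_out == fs_in) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  n_out <- round(n * fs_out / fs_in)
  q <- fs_in / fs_out
  if (abs(q - round(q)) < 1e-9) {         # integer decimation
    q <- round(q)
    cutoff <- 0.8 * (fs_out / 2)
    ord <- ceiling(3.3 * fs_in / (0.4 * fs_out / 2))
    if (ord %% 2 == 1) ord <- ord + 1L
    b <- signal::fir1(ord, cutoff / (fs_in / 2), type = "low")
    y <- fir_apply(x, b)[, seq(1L, n, by = q), drop = FALSE]
  } else {                                # rational resampling via signal
    fr <- rational_approx(fs_out / fs_in)
    y <- t(apply(x, 1L, function(r) {
      out <- signal::resample(r, fr[1L], fr[2L])
      length(out) <- n_out
      out[is.na(out)] <- 0
      out
    }))
  }
  if (ncol(y) > n_out) y <- y[, seq_len(n_out), drop = FALSE]
  if (vec) y <- drop(y)
  y
}

rational_approx <- function(r, max_den = 1000L) {
  den <- seq_len(max_den)
  err <- abs(r * den - round(r * den))
  d <- den[which.min(err)]
  c(round(r * d), d)
}

#' Extract baseline-corrected epochs from a continuous recording
#'
#' One epoch per onset, covering `cfg$epoch_window` relative to the onset
#' sample. The per-channel mean of `cfg$baseline_window` (by default the
#' 1 s preceding the onset) is subtracted from each epoch.
#'
#' @param x continuous signal, matrix `[channels x samples]`.
#' @param fs sampling rate in Hz.
#' @param onsets integer sample indices (1-based) of the first-MI onset of
#'   each trial.
#' @param labels integer class label per onset.
#' @param channel_names channel names, one per row of `x`.
#' @param cfg a [preprocess_config()].
#' @param subject_id subject tag.
#' @return an [eeg_epochs()] object with `t0 = cfg$epoch_window[1]`.
#' @export
extract_epochs <- function(x, fs, onsets, labels, channel_names,
                           cfg = preprocess_config(), subject_id = "S01") {
  ep <- cfg$epoch_window
  bl <- cfg$baseline_window
  n_ep <- round((ep[2] - ep[1]) * fs)
  nch <- nrow(x)
  out <- array(0, c(length(onsets), nch, n_ep))
  for (i in seq_along(onsets)) {
    a <- onsets[i] + round(ep[1] * fs)
    b0 <- onsets[i] + round(bl[1] * fs)
    b1 <- onsets[i] + round(bl[2] * fs) - 1L
    lo <- min(a, b0); hi <- max(a + n_ep - 1L, b1)
    if (lo < 1L || hi > ncol(x))
      stop(sprintf(
        "trial %d: window [sample %d, %d] outside recording (1..%d)",
        i, lo, hi, ncol(x)))
    seg <- x[, a:(a + n_ep - 1L), drop = FALSE]
    base <- rowMeans(x[, b0:b1, drop = FALSE])
    out[i, , ] <- seg - base
  }
  eeg_epochs(out, labels, channel_names, fs, t0 = ep[1],
             subject_id = subject_id)
}

#' Full preprocessing chain
#'
#' Bandpass -> common average reference -> downsample -> epoch extraction
#' with baseline correction, in that order.
#'
#' @inheritParams extract_epochs
#' @return an [eeg_epochs()] object at `cfg$target_fs`.
#' @export
preprocess <- function(x, fs, onsets, labels, channel_names,
                       cfg = preprocess_config(), subject_id = "S01") {
  y <- bandpass_fir(x, fs, cfg)
  y <- common_average_reference(y)
  y <- resample_to(y, fs, cfg$target_fs)
  onsets <- round((onsets - 1L) * cfg$target_fs / fs) + 1L
  extract_epochs(y, cfg$target_fs, onsets, labels, channel_names, cfg,
                 subject_id)
}
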