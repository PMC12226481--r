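# Time-frequency analysis: Morlet instantaneous power, event-related
# spectral perturbation (ERSP) in dB relative to a pre-onset baseline,
# band curves, scalp topographies, and MRCP trial averaging.

#' Instantaneous spectral power via complex Morlet decomposition
#'
#' Convolves the signal with complex Morlet wavelets (implemented as
#' frequency-domain Gaussians of width `sigma_f = f / cycles`, unit gain at
#' the centre frequency, analytic). With the default
#' `cycles = max(3, f / 2)` the spectral bandwidth is a constant 2 Hz above
#' 6 Hz, so broadband noise yields a flat power profile across frequencies.
#' A unit-amplitude sinusoid at `f` yields power 1 at `f`.
#'
#' The signal is mirror-padded by `pad_s` seconds before the transform; the
#' first/last 0.5 s of the output remain the least reliable and are
#' annotated via the `"edge_s"` attribute.
#'
#' @param x single-channel signal: vector, or matrix `[n_trials x n_samples]`
#'   to transform several trials at once.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (all below Nyquist).
#' @param cycles wavelet cycles per frequency (recycled).
#' @param pad_s mirror padding, seconds.
#' @return for vector input a `[n_freqs x n_samples]` power matrix; for
#'   matrix input an `[n_trials x n_freqs x n_samples]` array.
#' @export
tf_power <- function(x, fs, freqs, cycles = pmax(3, freqs / 2), pad_s = 1) {
  if (any(freqs >= fs / 2))
    stop("analysis frequencies must lie below Nyquist (", fs / 2, " Hz)")
  if (any(freqs <= 0)) stop("analysis frequencies must be positive")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  B <- nrow(x); n <- ncol(x)
  cycles <- rep_len(cycles, length(freqs))
  p <- min(round(pad_s * fs), n - 1L)
  xp <- cbind(x[, seq(p + 1L, 2L), drop = FALSE], x,
              x[, seq(n - 1L, n - p), drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np, 2)
  X <- stats::mvfft(t(cbind(xp, matrix(0, B, nfft - np))))  # [nfft x B]
  fgrid <- (seq_len(nfft) - 1L) * fs / nfft
  out <- array(0, c(B, length(freqs), n))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sf <- f / cycles[k]
    H <- 2 * exp(-0.5 * ((fgrid - f) / sf)^2)   # analytic, unit gain at +f
    a <- stats::mvfft(X * H, inverse = TRUE) / nfft
    out[, k, ] <- t(abs(a[p + seq_len(n), , drop = FALSE])^2)
  }
  res <- if (vec) out[1L, , , drop = TRUE] else out
  if (vec) dim(res) <- c(length(freqs), n)
  attr(res, "edge_s") <- 0.5
  res
}

#' Event-related spectral perturbation
#'
#' Averages Morlet power across trials per (frequency, time) and converts to
#' dB relative to the mean baseline power of each frequency:
#' `10 * log10(P(f, t) / mean_{t in baseline} P(f, t))`. With `db = FALSE`
#' the raw trial-mean power is returned instead.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param channel electrode to analyse (e.g. `"C3"`, over the left motor
#'   cortex for right-limb imagery).
#' @param freqs analysis frequencies, Hz (default 8-30 Hz).
#' @param baseline_window baseline period `[start, end]` in seconds relative
#'   to the first-MI onset (default `c(-2, 0)`), must lie inside the epoch.
#' @param db return dB relative to baseline (default) or raw mean power.
#' @param cycles wavelet cycles, see [tf_power()].
#' @return object of class `ersp_map`: `values` `[n_freqs x n_times]`,
#'   `freqs`, `times`, `channel`, `baseline_window`.
#' @export
ersp <- function(epochs, channel, freqs = 8:30, baseline_window = c(-2, 0),
                 db = TRUE, cycles = pmax(3, freqs / 2)) {
  if (n_trials(epochs) < 1L) stop("no trials selected")
  ci <- channel_index(epochs, channel)
  tt <- epoch_times(epochs)
  x <- epochs$data[, ci, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  P <- tf_power(x, epochs$fs, freqs, cycles)
  Pm <- apply(P, c(2L, 3L), mean)                 # trial-mean power
  if (db) {
    bi <- tt >= baseline_window[1] & tt < baseline_window[2]
    if (!any(bi))
      stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
           ") lies outside the epoch")
    base <- rowMeans(Pm[, bi, drop = FALSE])
    Pm <- 10 * log10(sweep(Pm, 1L, base, "/"))
  }
  structure(list(values = Pm, freqs = freqs, times = tt, channel = channel,
                 baseline_window = baseline_window, db = db),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %s: %d freqs (%g-%g Hz) x %d times [%g, %g] s%s\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times),
              if (x$db) ", dB vs baseline" else ", raw power"))
  invisible(x)
}

#' Band-averaged ERSP curve
#'
#' Mean of the ERSP rows whose frequency falls inside `band`, at every time.
#'
#' @param map an [ersp()] result.
#' @param band `[lo, hi]` Hz, inclusive; must contain at least one analysis
#'   frequency.
#' @return numeric vector over `map$times` (attached as the `"times"`
#'   attribute), in the map's units.
#' @export
band_curve <- function(map, band) {
  rows <- which(map$freqs >= band[1] & map$freqs <= band[2])
  if (!length(rows))
    stop("band [", band[1], ", ", band[2], "] contains no analysis frequency")
  v <- colMeans(map$values[rows, , drop = FALSE])
  attr(v, "times") <- map$times
  v
}

#' Band-power scalp topography
#'
#' Per-channel mean ERSP (dB) over a frequency band and time window — the
#' numbers behind a scalp topographic map.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param band `[lo, hi]` Hz (alpha 8-13 or beta 13-30 by convention).
#' @param window `[start, end]` s, inside the epoch.
#' @param channels channels to map (default: all in `epochs`).
#' @param baseline_window see [ersp()].
#' @param freq_step spacing of analysis frequencies within the band, Hz.
#' @return object of class `band_summary` with `per_channel_db` (named
#'   vector), `band`, `window`.
#' @export
topography <- function(epochs, band = c(8, 13), window = c(0, 5),
                       channels = epochs$channel_names,
                       baseline_window = c(-2, 0), freq_step = 1) {
  tt <- epoch_times(epochs)
  if (window[1] < tt[1L] - 1e-9 || window[2] > tt[length(tt)] + 1 / epochs$fs + 1e-9)
    stop("window [", window[1], ", ", window[2], "] lies outside the epoch")
  miss <- setdiff(channels, epochs$channel_names)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  freqs <- seq(band[1], band[2], by = freq_step)
  wi <- tt >= window[1] & tt < window[2]
  vals <- vapply(channels, function(ch) {
    m <- ersp(epochs, ch, freqs = freqs, baseline_window = baseline_window)
    mean(m$values[, wi])
  }, numeric(1))
  structure(list(per_channel_db = vals, band = band, window = window,
                 baseline_window = baseline_window),
            class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("<band_summary> %g-%g Hz, window [%g, %g] s\n",
              x$band[1], x$band[2], x$window[1], x$window[2]))
  print(round(sort(x$per_channel_db), 2))
  invisible(x)
}

#' Trial-averaged MRCP waveform
#'
#' Low-pass filters one electrode (default <= 5 Hz, where the
#' movement-related cortical potential lives), averages trials per class,
#' and baseline-corrects to the pre-onset mean.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param channel electrode (frontocentral, e.g. `"FC3"`).
#' @param lowpass_hz low-pass cutoff, Hz.
#' @param by_class average separately per class (default) or over all trials.
#' @return object of class `mrcp_waveform`: `values` (`[n_classes x n_times]`
#'   matrix, rownames = class labels; single row when `by_class = FALSE`),
#'   `times`, `channel`.
#' @export
mrcp_average <- function(epochs, channel, lowpass_hz = 5, by_class = TRUE) {
  if (n_trials(epochs) < 1L) stop("no trials")
  ci <- channel_index(epochs, channel)
  x <- epochs$data[, ci, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ord <- ceiling(3.3 * epochs$fs / 2)          # 2 Hz transition
  if (ord %% 2 == 1) ord <- ord + 1L
  b <- signal::fir1(ord, lowpass_hz / (epochs$fs / 2), type = "low")
  xf <- fir_apply(x, b)
  tt <- epoch_times(epochs)
  groups <- if (by_class) sort(unique(epochs$labels)) else NA
  avg <- do.call(rbind, lapply(groups, function(g) {
    sel <- if (is.na(g)) rep(TRUE, nrow(xf)) else epochs$labels == g
    colMeans(xf[sel, , drop = FALSE])
  }))
  rownames(avg) <- if (by_class) as.character(groups) else "all"
  bw <- c(max(tt[1L], -1), 0)
  bi <- tt >= bw[1] & tt < bw[2]
  if (!any(bi)) bi <- tt < tt[1L] + 0.5        # epochs without pre-onset data
  avg <- avg - rowMeans(avg[, bi, drop = FALSE])
  structure(list(values = avg, times = tt, channel = channel,
                 lowpass_hz = lowpass_hz),
            class = "mrcp_waveform")
}

#' @export
print.mrcp_waveform <- function(x, ...) {
  mins <- apply(x$values, 1L, min)
  at <- x$times[apply(x$values, 1L, which.min)]
  cat(sprintf("<mrcp_waveform> %s (<= %g Hz): minima %s uV at %s s\n",
              x$channel, x$lowpass_hz,
              paste(round(mins, 2), collapse = "/"),
              paste(round(at, 2), collapse = "/")))
  invisible(x)
}
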