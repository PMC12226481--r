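# Turning epochs into network inputs: crop to the 12-s MI segment, optional
# anti-aliased decimation to the model's sampling rate, electrode-plane
# interpolation (standardised per trial), and the [0,1]-scaled electrode
# subset plus its low-pass denoising target for the auto-encoder.

#' Prepare network inputs from epochs
#'
#' @param epochs an [eeg_epochs()] object.
#' @param cfg a [model_config()].
#' @param grid optional [build_grid()] result (defaults to the epochs'
#'   montage on `cfg$grid_shape`).
#' @param lowpass_hz cutoff of the auto-encoder's denoising target (Hz).
#' @return an object of class `model_inputs`: `plane` (`[T, H, W, 1, B]`),
#'   `cae_x` and `cae_target` (`[T, 1, B * n_cae]`, rows channel-fastest),
#'   `labels`, `grid`, `cfg`.
#' @export
prepare_model_inputs <- function(epochs, cfg, grid = NULL, lowpass_hz = 5) {
  dur <- cfg$T_samples / cfg$input_fs
  ep <- crop_epochs(epochs, 0, dur)
  if (!is.null(cfg$grid_channels)) {
    want <- unique(c(cfg$grid_channels,
                     if (cfg$use_cae) cfg$cae_channels))
    miss <- setdiff(want, ep$channel_names)
    if (length(miss))
      stop("epochs missing channel(s): ", paste(miss, collapse = ", "))
    ep <- select_channels(ep, want)
  }
  if (cfg$input_fs > epochs$fs)
    stop("model input_fs exceeds the epochs' sampling rate")
  if (cfg$input_fs < epochs$fs) {
    B <- n_trials(ep); C <- n_channels(ep); S <- n_samples(ep)
    m <- matrix(aperm(ep$data, c(3L, 1L, 2L)), nrow = S)   # [S, B*C]
    r <- resample_to(t(m), epochs$fs, cfg$input_fs)        # [B*C, T]
    dat <- aperm(array(t(r), c(ncol(r), B, C)), c(2L, 3L, 1L))
    ep <- eeg_epochs(dat, ep$labels, ep$channel_names, cfg$input_fs,
                     t0 = ep$t0, subject_id = ep$subject_id)
  }
  if (n_samples(ep) != cfg$T_samples)
    stop(sprintf("epochs provide %d samples at %g Hz; model expects T = %d",
                 n_samples(ep), cfg$input_fs, cfg$T_samples))
  B <- n_trials(ep)

  plane <- NULL
  if (cfg$use_msstcn) {
    if (is.null(grid))
      grid <- build_grid(cfg$grid_channels %||% ep$channel_names,
                         cfg$grid_shape)
    pt <- to_plane(ep, grid)
    v <- pt$values                                   # [B, 1, H, W, T]
    mu <- apply(v, 1L, mean)
    sdv <- pmax(apply(v, 1L, stats::sd), 1e-9)
    v <- (v - mu) / sdv                              # recycles over trials
    plane <- aperm(v, c(5L, 3L, 4L, 2L, 1L))         # [T, H, W, 1, B]
  }

  cae_x <- cae_target <- NULL
  if (cfg$use_cae) {
    miss <- setdiff(cfg$cae_channels, ep$channel_names)
    if (length(miss))
      stop("epochs missing auto-encoder channel(s): ",
           paste(miss, collapse = ", "))
    sub <- select_channels(ep, cfg$cae_channels)
    nc <- n_channels(sub)
    x <- sub$data                                    # [B, nc, T]
    lo <- apply(x, c(1L, 2L), min)
    hi <- apply(x, c(1L, 2L), max)
    rng <- pmax(hi - lo, 1e-9)
    xs <- (x - as.vector(lo)) / as.vector(rng)       # per trial/channel [0,1]
    # denoising target: <= lowpass_hz content on the same scale
    m <- matrix(aperm(x, c(3L, 1L, 2L)), nrow = cfg$T_samples)
    ord <- ceiling(3.3 * cfg$input_fs / 2)
    if (ord %% 2 == 1) ord <- ord + 1L
    bl <- signal::fir1(ord, lowpass_hz / (cfg$input_fs / 2), type = "low")
    xf <- t(fir_apply(t(m), bl))                     # [T, B*nc]
    tgt <- array(xf, c(cfg$T_samples, B, nc))
    tgt <- sweep(tgt, c(2L, 3L), lo, "-")
    tgt <- sweep(tgt, c(2L, 3L), rng, "/")
    tgt <- pmin(pmax(tgt, 0), 1)
    # [T, B, nc] -> [T, 1, nc*B] rows channel-fastest
    cae_x <- aperm(xs, c(3L, 2L, 1L))                # [T, nc, B]
    dim(cae_x) <- c(cfg$T_samples, 1L, nc * B)
    cae_target <- aperm(tgt, c(1L, 3L, 2L))          # [T, nc, B]
    dim(cae_target) <- c(cfg$T_samples, 1L, nc * B)
  }

  structure(list(plane = plane, cae_x = cae_x, cae_target = cae_target,
                 labels = ep$labels, grid = grid, cfg = cfg,
                 n = B, n_cae = length(cfg$cae_channels)),
            class = "model_inputs")
}

#' Subset prepared inputs by trial index
#' @param inputs a [prepare_model_inputs()] result.
#' @param idx trial indices.
#' @export
subset_inputs <- function(inputs, idx) {
  out <- inputs
  if (!is.null(inputs$plane))
    out$plane <- inputs$plane[, , , , idx, drop = FALSE]
  if (!is.null(inputs$cae_x)) {
    nc <- inputs$n_cae
    cols <- as.vector(vapply(idx, function(b) (b - 1L) * nc + seq_len(nc),
                             integer(nc)))
    out$cae_x <- inputs$cae_x[, , cols, drop = FALSE]
    out$cae_target <- inputs$cae_target[, , cols, drop = FALSE]
  }
  out$labels <- inputs$labels[idx]
  out$n <- length(idx)
  out
}

#' Scaled-down decoding benchmark configuration
#'
#' A runtime-friendly variant of the architecture for the bundled synthetic
#' benchmark: 18-channel sensorimotor montage on a 6 x 6 plane, inputs
#' anti-alias decimated to 25 Hz (T = 300, which preserves the alpha-band
#' ERD and the MRCP while dropping the beta carrier), and per-branch filter
#' counts reduced to 2 and 4 (encoder 4/8). Kernels, pooling roles, branch
#' structure and the LSTM/attention stage are unchanged; pools become
#' (3,3,5)/(2,2,10) so the 6 x 6 x 300 plane again collapses to 1 x 1 with
#' 6 time steps.
#'
#' @param ... overrides passed to [model_config()].
#' @export
benchmark_model_config <- function(...) {
  args <- list(grid_shape = c(6, 6), T_samples = 300, input_fs = 25,
               msstcn_filters = c(2, 4),
               pools = list(c(3, 3, 5), c(2, 2, 10)),
               cae_filters = c(4, 8),
               grid_channels = montage_channels("sensorimotor_18"),
               precision = "single")
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

#' Montage used by the scaled-down benchmark
#' @export
benchmark_montage <- function() montage_channels("sensorimotor_18")
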