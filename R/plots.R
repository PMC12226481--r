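# Base-graphics displays for the analysis objects: time-frequency maps,
# scalp topographies on the electrode grid, and MRCP waveforms.

ersp_palette <- function(n = 64)
  grDevices::hcl.colors(n, "Blue-Red 3", rev = TRUE)

#' @export
plot.ersp_map <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) {
    r <- max(abs(range(x$values)))
    zlim <- c(-r, r)
  }
  graphics::image(x$times, x$freqs, t(x$values), col = ersp_palette(),
                  zlim = zlim, xlab = "time (s)", ylab = "frequency (Hz)",
                  main = sprintf("ERSP at %s (dB vs baseline)", x$channel),
                  ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Plot a band-power topography on the electrode grid
#'
#' Renders the per-channel values of a [topography()] result as the filled
#' electrode plane (grid cells coloured by interpolated dB, electrode
#' labels overlaid).
#'
#' @param x a `band_summary`.
#' @param grid a [build_grid()] for the mapped channels (default: built
#'   from the channel names on 9 x 9).
#' @param ... passed to [graphics::image()].
#' @export
plot.band_summary <- function(x, grid = NULL, ...) {
  chs <- names(x$per_channel_db)
  if (is.null(grid)) grid <- build_grid(chs, c(9, 9))
  H <- grid$shape[1L]; W <- grid$shape[2L]
  vals <- grid$wmat[, chs, drop = FALSE] %*% x$per_channel_db
  img <- matrix(vals, H, W)
  img[grid$outside_mask] <- NA
  r <- max(abs(vals), na.rm = TRUE)
  graphics::image(seq_len(W), seq_len(H), t(img[H:1, , drop = FALSE]),
                  col = ersp_palette(), zlim = c(-r, r), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%g-%g Hz, %g-%g s (dB)", x$band[1],
                                 x$band[2], x$window[1], x$window[2]), ...)
  graphics::text(grid$placed[, "col"], H + 1 - grid$placed[, "row"],
                 labels = grid$channels, cex = 0.7)
  invisible(x)
}

#' @export
plot.mrcp_waveform <- function(x, ...) {
  cls <- rownames(x$values)
  graphics::matplot(x$times, t(x$values), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "amplitude (uV)",
                    main = sprintf("MRCP at %s (<= %g Hz)", x$channel,
                                   x$lowpass_hz), ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  graphics::legend("bottomright", legend = paste("class", cls), lty = 1,
                   col = seq_along(cls), bty = "n")
  invisible(x)
}
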