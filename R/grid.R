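# Electrode plane: embed a 10-20 montage into an H x W grid and fill vacant
# in-hull cells by distance-based interpolation (inverse-distance weighting
# over the k nearest placed electrodes). The filled plane is the input of the
# multi-scale spatial-temporal convolution branch.

#' Build an electrode grid map
#'
#' Places each electrode in a cell of an `H x W` grid and computes
#' inverse-distance interpolation weights for every vacant cell inside the
#' convex hull of the montage; cells outside the hull are masked and carry
#' no weights (their plane values are zero).
#'
#' Two placement modes:
#' * default (no `positions`): schematic 10-20 placement — grid row from the
#'   anterior-posterior row letter (Fp..O), grid column from the lateral
#'   digit (odd = left, `z` = centre, even = right). With `shape = c(9, 9)`
#'   the canonical 9-row / 9-column layout is used directly; smaller shapes
#'   compact the rows/columns present in the montage.
#' * with `positions` (data.frame `channel,x,y`, e.g. from
#'   [montage_positions()] or [read_montage_csv()]): electrodes snap to the
#'   nearest cell of a regular grid spanning the montage's bounding box.
#'
#' @param channel_names electrode labels.
#' @param shape grid shape `c(H, W)`.
#' @param positions optional data.frame with columns `channel`, `x`, `y`.
#' @param k number of nearest placed electrodes used to interpolate a vacant
#'   cell (default 4).
#' @return an object of class `grid_map` with elements `shape`, `channels`,
#'   `placed` (matrix `[n_channels x 2]` of row/col), `wmat`
#'   (`[H*W x n_channels]` interpolation matrix, cells in column-major
#'   `(row, col)` order), `outside_mask` (`[H x W]` logical), and `coords`
#'   (electrode coordinates used for distances).
#' @export
build_grid <- function(channel_names, shape = c(9, 9), positions = NULL,
                       k = 4L) {
  H <- shape[1L]; W <- shape[2L]
  nch <- length(channel_names)
  if (anyDuplicated(channel_names)) stop("duplicate channel names")

  if (is.null(positions)) {
    p <- parse_1020(channel_names)
    rows <- p$row; cols <- p$col
    if (H < 9) {
      ur <- sort(unique(rows))
      if (length(ur) > H)
        stop("montage spans ", length(ur), " electrode rows; grid height ",
             H, " is too small - use a larger shape")
      rows <- match(rows, ur)
    }
    if (W < 9) {
      uc <- sort(unique(cols))
      if (length(uc) > W)
        stop("montage spans ", length(uc), " electrode columns; grid width ",
             W, " is too small - use a larger shape")
      cols <- match(cols, uc)
    }
    if (any(rows > H) || any(cols > W))
      stop("montage does not fit the requested grid shape - use at least c(9, 9)")
    cell_r <- rows; cell_c <- cols
    # electrode coordinates in grid units; cell centers likewise
    ex <- cols; ey <- rows
    ctr_x <- function(cc) cc
    ctr_y <- function(rr) rr
  } else {
    idx <- match(channel_names, positions$channel)
    if (anyNA(idx))
      stop("positions missing channel(s): ",
           paste(channel_names[is.na(idx)], collapse = ", "))
    ex <- positions$x[idx]; ey <- positions$y[idx]
    gx <- if (W > 1) seq(min(ex), max(ex), length.out = W) else mean(ex)
    gy <- if (H > 1) seq(max(ey), min(ey), length.out = H) else mean(ey)
    cell_c <- vapply(ex, function(v) which.min(abs(gx - v)), integer(1))
    cell_r <- vapply(ey, function(v) which.min(abs(gy - v)), integer(1))
    ctr_x <- function(cc) gx[cc]
    ctr_y <- function(rr) gy[rr]
  }

  cell_id <- cell_r + (cell_c - 1L) * H
  if (anyDuplicated(cell_id)) {
    d <- which(duplicated(cell_id) | duplicated(cell_id, fromLast = TRUE))
    stop("electrodes snap to the same grid cell: ",
         paste(channel_names[d], collapse = ", "),
         " - use a larger grid shape")
  }

  # convex hull of electrode coordinates (degenerate hulls fall back to the
  # bounding box so tiny montages remain interpolable)
  in_hull <- hull_test_fn(ex, ey)

  wmat <- matrix(0, H * W, nch,
                 dimnames = list(NULL, channel_names))
  outside <- matrix(FALSE, H, W)
  kk <- min(k, nch)
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    id <- rr + (cc - 1L) * H
    hit <- which(cell_id == id)
    if (length(hit) == 1L) { wmat[id, hit] <- 1; next }
    px <- ctr_x(cc); py <- ctr_y(rr)
    if (!in_hull(px, py)) { outside[rr, cc] <- TRUE; next }
    dist <- sqrt((ex - px)^2 + (ey - py)^2)
    near <- order(dist)[seq_len(kk)]
    w <- 1 / pmax(dist[near], 1e-12)
    wmat[id, near] <- w / sum(w)
  }

  structure(list(shape = c(H, W), channels = channel_names,
                 placed = cbind(row = cell_r, col = cell_c),
                 wmat = wmat, outside_mask = outside,
                 coords = cbind(x = ex, y = ey), k = kk),
            class = "grid_map")
}

# returns function(x, y) -> TRUE if inside/on the convex hull (with a small
# tolerance); bounding box if the hull is degenerate
hull_test_fn <- function(ex, ey) {
  pts <- unique(cbind(ex, ey))
  eps <- 1e-9 + 1e-9 * max(abs(pts))
  if (nrow(pts) < 3L) {
    rngx <- range(ex); rngy <- range(ey)
    return(function(x, y)
      x >= rngx[1] - eps & x <= rngx[2] + eps &
      y >= rngy[1] - eps & y <= rngy[2] + eps)
  }
  h <- grDevices::chull(pts[, 1L], pts[, 2L])   # clockwise order
  hx <- pts[h, 1L]; hy <- pts[h, 2L]
  n <- length(h)
  function(x, y) {
    j <- c(n, seq_len(n - 1L))
    cr <- (hx - hx[j]) * (y - hy[j]) - (hy - hy[j]) * (x - hx[j])
    all(cr <= eps) || all(cr >= -eps)
  }
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> %d x %d grid, %d electrodes, %d interpolated, %d outside\n",
              x$shape[1], x$shape[2], length(x$channels),
              sum(rowSums(x$wmat) > 0) - length(x$channels),
              sum(x$outside_mask)))
  invisible(x)
}

#' Export/import a grid map as JSON
#' @param grid a `grid_map`.
#' @param path output path.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(shape = grid$shape, channels = grid$channels,
         placed = unname(grid$placed), wmat = unname(grid$wmat),
         outside_mask = grid$outside_mask, coords = unname(grid$coords),
         k = grid$k),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Interpolate epochs onto the electrode plane
#'
#' Produces the network input tensor: each trial becomes a
#' `1 x H x W x T` volume in which placed cells copy their electrode's
#' signal exactly, vacant in-hull cells are inverse-distance weighted sums
#' of the `k` nearest electrodes, and cells outside the montage hull are 0.
#'
#' @param epochs an [eeg_epochs()] object containing every grid channel.
#' @param grid a [build_grid()] result.
#' @return object of class `plane_tensor` with `values`
#'   (`[n_trials x 1 x H x W x T]`), `grid`, and `fs`.
#' @export
to_plane <- function(epochs, grid) {
  idx <- match(grid$channels, epochs$channel_names)
  if (anyNA(idx))
    stop("epochs missing grid channel(s): ",
         paste(grid$channels[is.na(idx)], collapse = ", "))
  H <- grid$shape[1L]; W <- grid$shape[2L]
  B <- n_trials(epochs); S <- n_samples(epochs)
  dat <- epochs$data[, idx, , drop = FALSE]          # [B, C, S]
  M <- matrix(aperm(dat, c(2L, 1L, 3L)), nrow = length(idx))   # [C, B*S]
  P <- grid$wmat %*% M                               # [H*W, B*S]
  arr <- array(P, c(H, W, B, S))
  vals <- aperm(arr, c(3L, 1L, 2L, 4L))              # [B, H, W, S]
  dim(vals) <- c(B, 1L, H, W, S)
  structure(list(values = vals, grid = grid, fs = epochs$fs),
            class = "plane_tensor")
}
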