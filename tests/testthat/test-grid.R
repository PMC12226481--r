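# Electrode plane: schematic placement, distance-based interpolation
# weights, convexity, and equality with a brute-force interpolation loop.

test_that("the standard cap places symmetric electrodes symmetrically", {
  g <- build_grid(montage_channels("standard_1010"), c(9, 9))
  p <- g$placed
  rownames(p) <- g$channels
  expect_equal(unname(p["Cz", ]), c(5, 5))
  expect_equal(p["C3", "row"], p["C4", "row"])
  expect_equal(p["C3", "col"] - 1, 9 - p["C4", "col"])   # mirror about col 5
  expect_equal(unname(p["C3", "col"]), 3)
  expect_equal(p["FC3", "row"], 4)
})

test_that("a cell equidistant from two electrodes splits weights 0.5/0.5", {
  pos <- data.frame(channel = c("A", "B"), x = c(0, 2), y = c(0, 0))
  g <- build_grid(c("A", "B"), c(1, 3), positions = pos)
  mid <- g$wmat[1 + 1 * 1, ]                       # middle cell of 1 x 3
  expect_equal(unname(mid), c(0.5, 0.5))
})

test_that("interpolation weights are convex on random montages", {
  set.seed(12)
  full <- montage_channels("standard_1010")
  for (i in 1:50) {
    chs <- sample(full, sample(8:20, 1))
    g <- tryCatch(build_grid(chs, c(9, 9)), error = function(e) NULL)
    if (is.null(g)) next
    rs <- rowSums(g$wmat)
    expect_true(all(g$wmat >= 0))
    expect_true(all(abs(rs[rs > 1e-12] - 1) < 1e-12))
    expect_true(all(rs[as.vector(g$outside_mask)] == 0))
  }
  for (i in 1:50) {
    n <- sample(4:10, 1)
    pos <- data.frame(channel = paste0("E", 1:n),
                      x = runif(n), y = runif(n))
    g <- tryCatch(build_grid(pos$channel, c(6, 6), positions = pos),
                  error = function(e) NULL)
    if (is.null(g)) next
    rs <- rowSums(g$wmat)
    expect_true(all(g$wmat >= -1e-15))
    expect_true(all(abs(rs[rs > 1e-12] - 1) < 1e-12))
  }
})

test_that("to_plane equals a brute-force loop and copies placed cells", {
  g <- build_grid(montage_channels("sensorimotor_18"), c(6, 6))
  for (rep in 1:20) {
    ep <- random_epochs(n_trials = 2,
                        channels = montage_channels("sensorimotor_18"),
                        fs = 50, n_samples = 30, seed = rep)
    pt <- to_plane(ep, g)
    H <- 6; W <- 6
    for (tr in 1:2) {
      brute <- array(0, c(H, W, 30))
      for (r in seq_len(H)) for (cc in seq_len(W)) {
        wrow <- g$wmat[r + (cc - 1) * H, ]
        for (ch in which(wrow != 0))
          brute[r, cc, ] <- brute[r, cc, ] + wrow[ch] * ep$data[tr, ch, ]
      }
      expect_lt(max(abs(pt$values[tr, 1, , , ] - brute)), 1e-9)
    }
  }
  # placed cells reproduce channels bitwise; outside-hull cells are zero
  ep <- random_epochs(n_trials = 3,
                      channels = montage_channels("sensorimotor_18"),
                      fs = 50, n_samples = 40, seed = 77)
  pt <- to_plane(ep, g)
  for (ch in seq_along(g$channels)) {
    r <- g$placed[ch, "row"]; cc <- g$placed[ch, "col"]
    expect_identical(pt$values[, 1, r, cc, ], ep$data[, ch, ])
  }
  out_cells <- which(g$outside_mask, arr.ind = TRUE)
  if (nrow(out_cells))
    expect_equal(max(abs(pt$values[, 1, out_cells[1, 1], out_cells[1, 2], ])),
                 0)
  # convexity: interpolated values bounded by contributing electrode values
  # (use the 30-channel cap on 9 x 9, which has vacant in-hull cells)
  g9 <- build_grid(montage_channels("sensorimotor_30"), c(9, 9))
  ep9 <- random_epochs(n_trials = 1,
                       channels = montage_channels("sensorimotor_30"),
                       fs = 50, n_samples = 40, seed = 5)
  pt9 <- to_plane(ep9, g9)
  cells <- which(rowSums(g9$wmat) > 1e-12 &
                   apply(g9$wmat, 1, function(w) sum(w != 0)) > 1)
  expect_gt(length(cells), 5)                      # DBI actually used
  for (cell in cells) {
    r <- (cell - 1) %% 9 + 1; cc <- (cell - 1) %/% 9 + 1
    contrib <- which(g9$wmat[cell, ] != 0)
    vals <- pt9$values[1, 1, r, cc, ]
    lo <- apply(ep9$data[1, contrib, , drop = FALSE], 3, min)
    hi <- apply(ep9$data[1, contrib, , drop = FALSE], 3, max)
    expect_true(all(vals >= lo - 1e-12 & vals <= hi + 1e-12))
  }
})

test_that("identical signals everywhere interpolate to the same signal", {
  chs <- montage_channels("sensorimotor_18")
  s <- sin(seq(0, 4 * pi, length.out = 50))
  dat <- array(rep(s, each = length(chs)), c(1, length(chs), 50))
  ep <- eeg_epochs(dat, 0L, chs, 50)
  g <- build_grid(chs, c(6, 6))
  pt <- to_plane(ep, g)
  inhull <- rowSums(g$wmat) > 1e-12
  for (cell in which(inhull)) {
    r <- (cell - 1) %% 6 + 1; cc <- (cell - 1) %/% 6 + 1
    expect_equal(pt$values[1, 1, r, cc, ], s, tolerance = 1e-12)
  }
})

test_that("grid construction is deterministic and validates inputs", {
  g1 <- build_grid(montage_channels("bci_iv_2a"), c(6, 7))
  g2 <- build_grid(montage_channels("bci_iv_2a"), c(6, 7))
  expect_identical(g1$wmat, g2$wmat)
  expect_identical(g1$placed, g2$placed)
  # JSON export round-trips the essentials
  jf <- withr::local_tempfile(fileext = ".json")
  write_grid_json(g1, jf)
  gj <- jsonlite::fromJSON(jf)
  expect_equal(gj$shape, c(6, 7))
  expect_equal(gj$channels, g1$channels)
  expect_equal(matrix(unlist(gj$wmat), nrow = 42), unname(g1$wmat),
               tolerance = 1e-12)
  # unknown label
  expect_error(build_grid(c("C3", "XX9"), c(9, 9)), "XX9")
  # collision with custom positions
  pos <- data.frame(channel = c("A", "B", "C"),
                    x = c(0, 0.01, 1), y = c(0, 0, 1))
  expect_error(build_grid(c("A", "B", "C"), c(2, 2), positions = pos),
               "larger grid shape")
  # missing channel in epochs
  ep <- random_epochs()
  g <- build_grid(c("C3", "Cz", "C4", "P3"), c(9, 9))
  expect_error(to_plane(ep, g), "P3")
})
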