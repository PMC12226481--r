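# Shared fixtures. Everything is generated in code; the default benchmark
# dataset (42 trials/class) is cached per test run because several files
# reuse it.

.fixture_env <- new.env(parent = emptyenv())

benchmark_data_cached <- function() {
  if (is.null(.fixture_env$bench))
    .fixture_env$bench <- generate_dataset(synthetic_config())
  .fixture_env$bench
}

# small random epoch set with a valid montage
random_epochs <- function(n_trials = 6, channels = c("FC3", "FCz", "FC4",
                                                     "C3", "Cz", "C4"),
                          fs = 50, n_samples = 100, t0 = 0, seed = 1) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n_trials * length(channels) * n_samples),
                   c(n_trials, length(channels), n_samples)),
             labels = rep_len(0:2, n_trials), channel_names = channels,
             fs = fs, t0 = t0)
}

# tiny model configuration for structural/gradient tests
tiny_model_cfg <- function(...) {
  args <- list(grid_shape = c(3, 3), T_samples = 20,
               msstcn_kernels = list(c(1, 1, 3), c(3, 3, 3), c(3, 3, 5)),
               msstcn_filters = c(2, 2), pools = list(c(3, 3, 2), c(1, 1, 2)),
               dropout_p = 0, cae_channels = c("C3", "Cz"),
               cae_filters = c(2, 3), lstm_a_units = 4, lstm_b_units = 5,
               n_classes = 3, input_fs = 100)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

tiny_model_inputs <- function(cfg, B = 6, seed = 1) {
  set.seed(seed)
  list(plane = array(rnorm(cfg$T_samples * prod(cfg$grid_shape) * B),
                     c(cfg$T_samples, cfg$grid_shape, 1, B)),
       cae_x = array(runif(cfg$T_samples * length(cfg$cae_channels) * B),
                     c(cfg$T_samples, 1, length(cfg$cae_channels) * B)),
       labels = rep_len(0:(cfg$n_classes - 1), B))
}

# nudge all biases away from 0 so finite differences never sit exactly on a
# ReLU kink
randomize_biases <- function(model, seed = 99) {
  set.seed(seed)
  for (l in model$layers)
    for (nm in names(l$params))
      if (nm %in% c("b", "beta", "bq", "bk", "bv"))
        l$params[[nm]] <- l$params[[nm]] +
          rnorm(length(l$params[[nm]]), sd = 0.05)
  invisible(model)
}

expect_grad_match <- function(layer, x, dout, tol = 1e-5, eps = 1e-6,
                              n_checked = 6, extra_fwd = NULL) {
  fwd <- function() {
    y <- layer$fwd(x, training = FALSE)
    if (!is.null(extra_fwd)) y <- extra_fwd(y)
    sum(y * dout)
  }
  fnssir:::layer_zero_grads(layer)
  y <- layer$fwd(x, training = FALSE)
  g <- dout
  if (!is.null(extra_fwd)) stop("extra_fwd unsupported in backward here")
  dx <- layer$bwd(g)
  for (nm in names(layer$params)) {
    p <- layer$params[[nm]]
    idx <- sample(length(p), min(n_checked, length(p)))
    for (i in idx) {
      o <- p[i]
      layer$params[[nm]][i] <- o + eps
      lp <- fwd()
      layer$params[[nm]][i] <- o - eps
      lm <- fwd()
      layer$params[[nm]][i] <- o
      num <- (lp - lm) / (2 * eps)
      expect_equal(layer$grads[[nm]][i], num, tolerance = tol,
                   label = sprintf("d/d%s[%d]", nm, i))
    }
  }
  invisible(dx)
}

# write a minimal valid EDF file (int16, uniform rate) for import tests
write_test_edf <- function(path, x, fs, channel_names, record_s = 1) {
  nch <- nrow(x)
  spr <- fs * record_s
  nrec <- ncol(x) %/% spr
  dmin <- -32768; dmax <- 32767; pmin <- -200; pmax <- 200
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) writeChar(formatC(s, width = -n), con, n, eos = NULL)
  pad("0", 8); pad("patient", 80); pad("rec", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(as.character(256L * (1L + nch)), 8); pad("", 44)
  pad(as.character(nrec), 8); pad(as.character(record_s), 8)
  pad(as.character(nch), 4)
  for (ch in channel_names) pad(ch, 16)
  for (i in seq_len(nch)) pad("", 80)
  for (i in seq_len(nch)) pad("uV", 8)
  for (i in seq_len(nch)) pad(as.character(pmin), 8)
  for (i in seq_len(nch)) pad(as.character(pmax), 8)
  for (i in seq_len(nch)) pad(as.character(dmin), 8)
  for (i in seq_len(nch)) pad(as.character(dmax), 8)
  for (i in seq_len(nch)) pad("", 80)
  for (i in seq_len(nch)) pad(as.character(spr), 8)
  for (i in seq_len(nch)) pad("", 32)
  for (r in seq_len(nrec))
    for (ch in seq_len(nch))
      writeBin(as.integer(dig[ch, (r - 1) * spr + seq_len(spr)]), con,
               size = 2L, endian = "little")
  invisible(path)
}
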