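# Time-frequency analysis against analytic and Monte-Carlo oracles, plus
# recovery of the generator's injected ERD/MRCP signatures.

test_that("Morlet power matches the analytic envelope of a sinusoid", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * t)                        # unit amplitude
  P <- tf_power(x, fs, freqs = c(8, 10, 12))
  interior <- 200:800
  p10 <- P[2, interior]
  expect_lt(max(abs(p10 - 1)), 0.1)                # constant power 1 +- 10%
  expect_identical(tf_power(numeric(500), fs, 10) >= 0, matrix(TRUE, 1, 500))
  expect_equal(max(tf_power(numeric(500), fs, 10)), 0)
  expect_error(tf_power(x, fs, freqs = c(10, 60)), "Nyquist")
})

test_that("white-noise power is flat across 8-30 Hz in the trial average", {
  set.seed(4)
  fs <- 100
  x <- matrix(rnorm(400 * 300), 400)               # 400 trials of 3 s
  P <- tf_power(x, fs, freqs = seq(8, 30, by = 2))
  pm <- apply(P[, , 80:220], 2, mean)              # interior, trial-mean
  rng <- 10 * log10(max(pm) / min(pm))
  expect_lt(rng, 1)                                # flat within 1 dB
})

test_that("a doubling of amplitude during MI shows as +6.02 dB", {
  fs <- 100
  tt <- seq(-2, 6, by = 1 / fs)
  tt <- tt[-length(tt)]
  set.seed(8)
  n <- 20
  dat <- array(0, c(n, 1, length(tt)))
  for (k in seq_len(n)) {
    amp <- ifelse(tt >= 0, 2, 1)
    dat[k, 1, ] <- amp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
  }
  ep <- eeg_epochs(dat, rep(0L, n), "C3", fs, t0 = -2)
  m <- ersp(ep, "C3", freqs = 8:13, baseline_window = c(-2, 0))
  mi <- m$times >= 1 & m$times <= 5
  expect_equal(mean(m$values[m$freqs == 10, mi]), 20 * log10(2),
               tolerance = 0.5 / (20 * log10(2)))
  # stationary signal: ERSP ~ 0 dB everywhere away from the edges
  dat2 <- dat
  for (k in seq_len(n)) dat2[k, 1, ] <- sin(2 * pi * 10 * tt + k)
  m2 <- ersp(eeg_epochs(dat2, rep(0L, n), "C3", fs, t0 = -2), "C3",
             freqs = 8:13)
  inner <- m2$times >= -1.5 & m2$times <= 5.5
  expect_lt(max(abs(m2$values[m2$freqs == 10, inner])), 0.2)
})

test_that("ersp equals a direct per-trial loop and is rescale-invariant", {
  ep <- random_epochs(n_trials = 5, fs = 50, n_samples = 150, t0 = -1,
                      seed = 10)
  freqs <- c(9, 12, 15)
  m <- ersp(ep, "Cz", freqs = freqs, baseline_window = c(-1, 0))
  # independent loop: accumulate per-trial power, then the same dB transform
  acc <- 0
  for (k in seq_len(n_trials(ep)))
    acc <- acc + tf_power(ep$data[k, 5, ], ep$fs, freqs)
  Pm <- acc / n_trials(ep)
  tt <- epoch_times(ep)
  base <- rowMeans(Pm[, tt >= -1 & tt < 0])
  expect_equal(m$values, 10 * log10(Pm / base), tolerance = 1e-9,
               ignore_attr = TRUE)
  # global amplitude rescaling leaves the dB map unchanged
  ep2 <- ep; ep2$data <- ep2$data * 3.7
  m2 <- ersp(ep2, "Cz", freqs = freqs, baseline_window = c(-1, 0))
  expect_equal(m2$values, m$values, tolerance = 1e-9)
})

test_that("band curves average the requested rows", {
  m <- structure(list(values = matrix(-3, 5, 10), freqs = 8:12,
                      times = seq_len(10), channel = "C3",
                      baseline_window = c(-2, 0), db = TRUE),
                 class = "ersp_map")
  expect_equal(as.numeric(band_curve(m, c(8, 12))), rep(-3, 10))
  m$values[3, ] <- 7
  expect_equal(as.numeric(band_curve(m, c(10, 10))), rep(7, 10))
  expect_error(band_curve(m, c(40, 50)), "no analysis frequency")
})

test_that("generator ERD is recovered at C3 with force ordering", {
  ep <- benchmark_data_cached()
  gt <- effect_ground_truth(synthetic_config())
  rec <- matrix(NA_real_, 3, 2)
  for (cl in 0:2) {
    sub <- subset_trials(ep, which(ep$labels == cl))
    m <- ersp(sub, "C3", freqs = 8:13)
    cur <- band_curve(m, c(8, 13))
    for (sg in 1:2) {
      seg <- synthetic_config()$mi_segments[[sg]]
      dur <- gt$erd_dur_s[gt$class == cl & gt$segment == sg]
      w <- m$times >= seg[1] + 0.6 & m$times <= seg[1] + dur - 0.6
      rec[cl + 1, sg] <- mean(cur[w])
    }
  }
  inj <- matrix(gt$erd_depth_db, 3, 2, byrow = TRUE)
  expect_lt(max(abs(rec - inj)), 1)                # within +-1 dB
  # deeper injected ERD -> deeper recovered ERD (segment 1: L, L, M)
  expect_lt(mean(rec[1:2, 1]), rec[3, 1])
  # segment 2: M, S, S
  expect_lt(rec[1, 2], mean(rec[2:3, 2]))
})

test_that("alpha topography localises to C3 and shortens with ERD duration", {
  ep <- subset_trials(benchmark_data_cached(), 1:60)
  tp <- topography(ep, band = c(8, 13), window = c(0, 5))
  v <- tp$per_channel_db
  neighbours <- c("C3", "FC3", "CP3", "T7")
  expect_true(names(sort(v))[1] %in% neighbours)
  # class with short second-segment ERD: late window less negative than full
  msf <- subset_trials(benchmark_data_cached(),
                       which(benchmark_data_cached()$labels == 2))
  t1 <- topography(msf, band = c(8, 13), window = c(7, 12),
                   channels = "C3")$per_channel_db
  t2 <- topography(msf, band = c(8, 13), window = c(10, 12),
                   channels = "C3")$per_channel_db
  expect_gt(t2[["C3"]], t1[["C3"]])                # strictly less negative
})

test_that("null data yields a flat topography", {
  cfg <- synthetic_config(n_trials_per_class = 20,
                          erd_depth_db = c(0, 0, 0),
                          mrcp_peak_uv = c(0, 0, 0), seed = 21)
  ep <- generate_dataset(cfg)
  tp <- topography(ep, band = c(8, 13), window = c(0, 5),
                   channels = c("C3", "Cz", "C4", "FC3", "Pz"))
  expect_lt(max(abs(tp$per_channel_db)), 1)
})

test_that("MRCP averages peak at the injected latency with force ordering", {
  ep <- benchmark_data_cached()
  w <- mrcp_average(ep, "FC3")
  seg1 <- w$times >= 0 & w$times <= 2.5
  mins <- apply(w$values[, seg1], 1, min)
  at <- w$times[seg1][apply(w$values[, seg1], 1, which.min)]
  expect_true(all(at >= 0.5 & at <= 1.5))
  # larger force -> larger negativity: segment-1 forces are L, L, M
  expect_lt(mean(mins[1:2]), mins[3])
  # amplitude recovery: averaged minima within 30% of the injected peaks
  # (profile value at FC3 and onset jitter both shave the averaged peak)
  inj <- synthetic_config()$mrcp_peak_uv
  expect_lt(abs(mean(mins[1:2]) - inj[1]) / abs(inj[1]), 0.3)
  expect_lt(abs(mins[3] - inj[2]) / abs(inj[2]), 0.3)
  # null data: averaged minimum comparable to baseline noise
  cfg0 <- synthetic_config(n_trials_per_class = 40,
                           erd_depth_db = c(0, 0, 0),
                           mrcp_peak_uv = c(0, 0, 0), seed = 31)
  ep0 <- generate_dataset(cfg0)
  w0 <- mrcp_average(ep0, "FC3", by_class = FALSE)
  bl <- w0$values[1, w0$times < 0]
  se3 <- 3 * stats::sd(bl)
  expect_lt(abs(min(w0$values[1, w0$times >= 0 & w0$times <= 2])), se3 * 3)
})
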