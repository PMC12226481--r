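# Synthetic force-variation motor-imagery EEG.
#
# Forward model of the empirical signatures of force-intensity MI: alpha/beta
# oscillations over the contralateral sensorimotor cortex whose amplitude is
# multiplicatively suppressed (ERD) during each MI segment -- depth, duration
# and spatial extent scaling with the imagined force -- plus a frontocentral
# MRCP negative transient after each MI onset whose peak amplitude scales
# with force, on top of 1/f background noise, with per-trial onset/duration
# jitter. Every effect size is configurable, so the generator doubles as a
# ground-truth source for parameter-recovery tests.

FORCE_LEVELS <- c("large", "medium", "small")
# class -> force level of (segment 1, segment 2); classes 0/1/2 = LMF/LSF/MSF
CLASS_FORCES <- list(LMF = c(1L, 2L), LSF = c(1L, 3L), MSF = c(2L, 3L))

#' Synthetic force-MI generator configuration
#'
#' Defaults mirror the force-variation MI paradigm: 42 trials per class,
#' 100 Hz, two 5-s MI segments at 0-5 s and 7-12 s separated by a 2-s
#' preparation gap, with 2 s of pre-onset context (epochs cover
#' `[-pre_s, epoch_s)` so a -2..0 s spectral baseline exists inside the
#' epoch).
#'
#' @param n_trials_per_class trials per class (default 42; 3 classes).
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch length after the first-MI onset, seconds.
#' @param pre_s pre-onset context length, seconds.
#' @param mi_segments list of two `[start, end]` MI windows, seconds.
#' @param channel_names montage (default 30-channel sensorimotor cap).
#' @param erd_depth_db alpha/beta ERD depth at C3 per force level
#'   (large, medium, small), dB; more negative = deeper suppression.
#' @param erd_dur_frac fraction of the MI segment showing ERD per force level.
#' @param erd_topo_sigma spatial spread of the ERD (grid cells) per force
#'   level, centred at C3.
#' @param osc_topo_sigma spatial spread of the background alpha/beta
#'   oscillation amplitude (grid cells).
#' @param alpha_freq,beta_freq carrier frequencies, Hz.
#' @param alpha_amp_uv,beta_amp_uv oscillation RMS amplitude at C3, microvolts.
#' @param mrcp_peak_uv MRCP negative peak per force level, microvolts.
#' @param mrcp_onset_s,mrcp_peak_s MRCP onset and peak latency after each MI
#'   onset, seconds (the transient is a raised cosine ending at
#'   `mrcp_onset_s + 2 * (mrcp_peak_s - mrcp_onset_s)`).
#' @param mrcp_topo_sigma spatial spread of the MRCP (grid cells), centred
#'   between FCz and C3.
#' @param noise_exponent 1/f^a background noise exponent.
#' @param noise_scale_uv background noise RMS, microvolts.
#' @param subject_jitter SD of per-trial onset/duration jitter, seconds.
#' @param seed RNG seed; fully determines the output.
#' @param subject_id subject tag.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trials_per_class = 42L, fs = 100, epoch_s = 12,
                             pre_s = 2,
                             mi_segments = list(c(0, 5), c(7, 12)),
                             channel_names = montage_channels("sensorimotor_30"),
                             erd_depth_db = c(-6, -4, -2),
                             erd_dur_frac = c(1, 0.8, 0.6),
                             erd_topo_sigma = c(2.2, 1.8, 1.4),
                             osc_topo_sigma = 2.5,
                             alpha_freq = 10, beta_freq = 24,
                             alpha_amp_uv = 8, beta_amp_uv = 4,
                             mrcp_peak_uv = c(-8, -5, -3),
                             mrcp_onset_s = 0.5, mrcp_peak_s = 1,
                             mrcp_topo_sigma = 2.2,
                             noise_exponent = 1, noise_scale_uv = 5,
                             subject_jitter = 0.1,
                             seed = 42L, subject_id = "sim01") {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  if (!(all(diff(cfg$erd_depth_db) >= 0) &&
        (all(cfg$erd_depth_db == 0) || any(diff(cfg$erd_depth_db) > 0))))
    stop("erd_depth_db must be ordered large <= medium <= small ",
         "(more negative = deeper), e.g. c(-6, -4, -2)")
  if (!all(diff(cfg$mrcp_peak_uv) >= 0))
    stop("mrcp_peak_uv must be ordered large <= medium <= small, ",
         "e.g. c(-8, -5, -3)")
  if (length(cfg$mi_segments) != 2L)
    stop("exactly two MI segments are required")
  cfg
}

#' Injected effect sizes per class and segment
#'
#' Echoes the generator's ground truth for use as recovery targets.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame with one row per (class, segment): the force level and
#'   the injected ERD depth (dB), ERD duration (s) and MRCP peak (uV).
#' @export
effect_ground_truth <- function(cfg = synthetic_config()) {
  rows <- do.call(rbind, lapply(0:2, function(cl) {
    forces <- CLASS_FORCES[[cl + 1L]]
    do.call(rbind, lapply(1:2, function(sg) {
      v <- forces[sg]
      seg <- cfg$mi_segments[[sg]]
      data.frame(class = cl, class_name = names(CLASS_FORCES)[cl + 1L],
                 segment = sg, force = FORCE_LEVELS[v],
                 erd_depth_db = cfg$erd_depth_db[v],
                 erd_dur_s = cfg$erd_dur_frac[v] * (seg[2] - seg[1]),
                 mrcp_peak_uv = cfg$mrcp_peak_uv[v],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' 1/f background noise
#'
#' Gaussian noise spectrally shaped to `1/f^exponent` power (flat below
#' 0.5 Hz to keep the variance finite), normalised to the requested RMS.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param exponent spectral slope of power with frequency.
#' @param rms target RMS.
#' @return numeric vector of length `n`.
#' @export
onef_noise <- function(n, fs, exponent = 1, rms = 1) {
  nf <- stats::nextn(n, 2)
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided
  shape <- (pmax(f, 0.5))^(-exponent / 2)
  shape[1L] <- 0                               # no DC
  z <- stats::fft(stats::rnorm(nf))
  x <- Re(stats::fft(z * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x * rms / stats::sd(x)
}

# run expr under a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# raised-cosine on/off window over [on, off] with ramp length `ramp`
smooth_window <- function(t, on, off, ramp = 0.25) {
  w <- numeric(length(t))
  if (off <= on) return(w)
  ramp <- min(ramp, (off - on) / 2)
  w[t >= on + ramp & t <= off - ramp] <- 1
  ri <- t >= on & t < on + ramp
  w[ri] <- 0.5 * (1 - cos(pi * (t[ri] - on) / ramp))
  rf <- t > off - ramp & t <= off
  w[rf] <- 0.5 * (1 - cos(pi * (off - t[rf]) / ramp))
  w
}

#' Generate a synthetic force-MI epoch set
#'
#' @param cfg a [synthetic_config()].
#' @return an [eeg_epochs()] object with `3 * n_trials_per_class` trials in
#'   randomised order, `t0 = -cfg$pre_s`, labels 0 (LMF), 1 (LSF), 2 (MSF).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  n_cls <- 3L
  ntr <- n_cls * cfg$n_trials_per_class
  nch <- length(cfg$channel_names)
  ns <- round((cfg$pre_s + cfg$epoch_s) * cfg$fs)
  tt <- -cfg$pre_s + (seq_len(ns) - 1) / cfg$fs

  # spatial profiles in grid-cell units
  grid <- build_grid(cfg$channel_names, c(9, 9))
  pos <- grid$placed
  rownames(pos) <- cfg$channel_names
  need <- c("C3", "FCz")
  miss <- setdiff(need, cfg$channel_names)
  if (length(miss))
    stop("synthetic montage must include ", paste(miss, collapse = ", "))
  c3 <- pos["C3", ]
  mrcp_ctr <- (pos["FCz", ] + c3) / 2
  d_c3 <- sqrt((pos[, "row"] - c3["row"])^2 + (pos[, "col"] - c3["col"])^2)
  d_mrcp <- sqrt((pos[, "row"] - mrcp_ctr["row"])^2 +
                 (pos[, "col"] - mrcp_ctr["col"])^2)
  osc_prof <- exp(-d_c3^2 / (2 * cfg$osc_topo_sigma^2))
  mrcp_prof <- exp(-d_mrcp^2 / (2 * cfg$mrcp_topo_sigma^2))

  labels <- rep(0:2, each = cfg$n_trials_per_class)

  with_local_seed(cfg$seed, {
    ord <- sample.int(ntr)
    labels <- labels[ord]
    dat <- array(0, c(ntr, nch, ns))
    amp2 <- sqrt(2)   # RMS -> sine amplitude
    for (i in seq_len(ntr)) {
      forces <- CLASS_FORCES[[labels[i] + 1L]]
      # envelope of the oscillation amplitude: 1 at baseline, suppressed
      # during each segment's force-scaled ERD window
      ph_a <- stats::runif(1, 0, 2 * pi)
      ph_b <- stats::runif(1, 0, 2 * pi)
      trial <- matrix(0, nch, ns)
      # per-channel multiplicative log-amplitude suppression
      log_supp <- matrix(0, nch, ns)   # in dB (amplitude dB = depth/2... kept in power dB)
      mrcp <- numeric(ns)
      for (sg in 1:2) {
        v <- forces[sg]
        seg <- cfg$mi_segments[[sg]]
        j_on <- stats::rnorm(1, 0, cfg$subject_jitter)
        j_du <- stats::rnorm(1, 0, cfg$subject_jitter)
        on <- seg[1] + max(-0.3, min(0.3, j_on))
        dur <- max(0.5, cfg$erd_dur_frac[v] * (seg[2] - seg[1]) + j_du)
        w <- smooth_window(tt, on, min(on + dur, seg[2]))
        sig <- cfg$erd_topo_sigma[v]
        spat <- exp(-d_c3^2 / (2 * sig^2))
        log_supp <- log_supp + cfg$erd_depth_db[v] * (spat %o% w)
        # MRCP raised-cosine transient
        m_on <- seg[1] + cfg$mrcp_onset_s + max(-0.3, min(0.3, j_on))
        m_wid <- 2 * (cfg$mrcp_peak_s - cfg$mrcp_onset_s)
        mi <- tt >= m_on & tt <= m_on + m_wid
        bump <- numeric(ns)
        bump[mi] <- 0.5 * (1 - cos(2 * pi * (tt[mi] - m_on) / m_wid))
        mrcp <- mrcp + cfg$mrcp_peak_uv[v] * bump
      }
      gain <- 10^(log_supp / 20)        # power-dB depth -> amplitude factor
      carrier_a <- sin(2 * pi * cfg$alpha_freq * tt + ph_a)
      carrier_b <- sin(2 * pi * cfg$beta_freq * tt + ph_b)
      osc <- (cfg$alpha_amp_uv * amp2 * osc_prof) %o% carrier_a * gain +
             (cfg$beta_amp_uv * amp2 * osc_prof) %o% carrier_b * gain
      noise <- t(vapply(seq_len(nch), function(ch)
        onef_noise(ns, cfg$fs, cfg$noise_exponent, cfg$noise_scale_uv),
        numeric(ns)))
      trial <- osc + noise + mrcp_prof %o% mrcp
      # baseline correction from the 1-s pre-onset window
      bi <- tt >= -1 & tt < 0
      trial <- trial - rowMeans(trial[, bi, drop = FALSE])
      dat[i, , ] <- trial
    }
    eeg_epochs(dat, labels, cfg$channel_names, cfg$fs, t0 = -cfg$pre_s,
               subject_id = cfg$subject_id)
  })
}

#' Simulate a multi-subject cohort
#'
#' Each subject shares the paradigm but draws its own ERD onset/duration
#' idiosyncrasies: a subject-level onset shift (SD 0.2 s) and duration scale
#' (SD 10%), emulating the inter-subject variability of ERD timing.
#'
#' @param n_subjects number of subjects.
#' @param cfg base [synthetic_config()].
#' @param seed cohort seed (per-subject seeds are derived from it).
#' @return list of [eeg_epochs()], one per subject.
#' @export
simulate_subjects <- function(n_subjects, cfg = synthetic_config(),
                              seed = cfg$seed) {
  with_local_seed(seed, {
    shifts <- stats::rnorm(n_subjects, 0, 0.2)
    scales <- pmax(0.6, stats::rnorm(n_subjects, 1, 0.1))
    seeds <- sample.int(2^30, n_subjects)
    lapply(seq_len(n_subjects), function(s) {
      ci <- cfg
      ci$mi_segments <- lapply(cfg$mi_segments, function(sg) sg + 0)  # copy
      ci$erd_dur_frac <- pmin(1, cfg$erd_dur_frac * scales[s])
      ci$mrcp_onset_s <- cfg$mrcp_onset_s + shifts[s] * 0.5
      ci$mrcp_peak_s <- cfg$mrcp_peak_s + shifts[s] * 0.5
      ci$seed <- seeds[s]
      ci$subject_id <- sprintf("sim%02d", s)
      generate_dataset(ci)
    })
  })
}
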