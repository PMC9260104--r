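#' Simulation configuration
#'
#' Parameters of the synthetic two-channel LFP generator. Event amplitudes
#' are expressed in multiples of the corresponding band-limited background
#' SD measured over NREM sleep, so detector thresholds (which are SD-based)
#' are analytically predictable: an amplitude of 3 is a signal-to-noise
#' ratio of 3 in the detection band.
#'
#' Defaults emulate a juvenile-rat resting-period recording: a 30 min
#' session alternating 120 s NREM / 60 s awake-or-REM blocks, 1/f
#' background, a quasi-continuous slow-oscillation rhythm (48 per NREM
#' minute, cycle 0.55-0.75 s), spindle bursts at 5 per minute (10-16 Hz,
#' 0.9-1.15 s), ripples at 5 per minute (160-240 Hz, 60-95 ms), with half
#' of the spindles/SWRs coupled to the slow-oscillation up-state (90 deg)
#' and trough (270 deg) respectively. Event amplitudes sit well above the
#' SNR-3 floor because the SD-adaptive detectors include event samples in
#' their own threshold statistics: sigma-band and ripple-band variance
#' during real NREM is dominated by the events themselves, and the
#' thresholds only separate events from background when that holds here
#' too.
#'
#' @param duration_s total duration (s)
#' @param fs sampling rate (Hz)
#' @param nrem_block_s,other_block_s alternating state block lengths (s);
#'   multiples of the 5 s staging window keep windows state-pure
#' @param noise_exponent 1/f^a background exponent
#' @param noise_sd background SD (arbitrary units; the pipeline z-scores)
#' @param delta_boost extra NREM delta-band noise amplitude (x delta-band
#'   background SD); separates the staging clusters
#' @param theta_amp awake/REM hippocampal theta amplitude (x theta-band
#'   background SD)
#' @param theta_freq theta frequency (Hz)
#' @param so_rate slow oscillations per NREM minute. The default (28/min,
#'   cycle 0.75-0.95 s) makes the slow rhythm quasi-continuous, as in deep
#'   NREM: with a ~40\% duty cycle the SO rhythm dominates the 0.5-4 Hz
#'   variance, which is what places ground-truth troughs inside the
#'   detector's amplitude acceptance window (between -1.5 and -4 SD of the
#'   filtered trace) while background delta lobes stay above -1.5 SD
#' @param so_dur SO cycle duration range (s)
#' @param so_amp SO trough depth (x 0.5-4 Hz NREM background SD)
#' @param so_up_frac up-state peak amplitude as a fraction of trough depth
#'   (the SO is asymmetric: a broad positive up-state, then the deep
#'   down-state trough, so its detector peak-to-trough measure - taken
#'   after the trough - stays under the mean + 3 SD ceiling)
#' @param sp_rate,sp_freq,sp_dur,sp_amp spindle rate (/min), frequency
#'   range (Hz), burst duration range (s), peak amplitude (x 9-17 Hz SD)
#' @param swr_rate,swr_freq,swr_dur,swr_amp ripple rate (/min), frequency
#'   range (Hz), burst duration range (s), peak amplitude (x 150-250 Hz SD)
#' @param p_couple_so_sp,mu_sp,kappa_sp probability a spindle is anchored
#'   to a slow oscillation, and the von Mises phase law it is placed at
#'   (degrees; 90 = SO peak)
#' @param p_couple_so_swr,mu_swr,kappa_swr same for ripples (270 = trough)
#' @param seed RNG seed
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(duration_s = 1800, fs = 1000,
                       nrem_block_s = 120, other_block_s = 60,
                       noise_exponent = 1.0, noise_sd = 1.0,
                       delta_boost = 1.0, theta_amp = 1.5, theta_freq = 6,
                       so_rate = 48, so_dur = c(0.55, 0.75), so_amp = 12,
                       so_up_frac = 0.9,
                       sp_rate = 5, sp_freq = c(10, 16),
                       sp_dur = c(0.9, 1.15), sp_amp = 16,
                       swr_rate = 5, swr_freq = c(160, 240),
                       swr_dur = c(0.06, 0.095), swr_amp = 8,
                       p_couple_so_sp = 0.5, mu_sp = 90, kappa_sp = 4,
                       p_couple_so_swr = 0.5, mu_swr = 270, kappa_swr = 4,
                       seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, so_rate >= 0, sp_rate >= 0,
            swr_rate >= 0, p_couple_so_sp >= 0, p_couple_so_sp <= 1,
            p_couple_so_swr >= 0, p_couple_so_swr <= 1,
            kappa_sp >= 0, kappa_swr >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# 1/f^a noise by spectral shaping, scaled to unit-free sd
.pink_noise <- function(n, exponent, sd_target) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))  # avoid DC blow-up
  f <- pmin(f, n - f + 1)    # symmetric frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x * sd_target / stats::sd(x)
}

# alternating state schedule -> list(nrem interval_set, windows df)
.state_schedule <- function(duration_s, nrem_block_s, other_block_s,
                            window_s = 5) {
  t <- 0; ns <- ne <- numeric(0); state_nrem <- TRUE
  while (t < duration_s) {
    len <- if (state_nrem) nrem_block_s else other_block_s
    end <- min(t + len, duration_s)
    if (state_nrem) { ns <- c(ns, t); ne <- c(ne, end) }
    t <- end; state_nrem <- !state_nrem
  }
  nrem <- interval_set(ns, ne)
  n_win <- floor(duration_s / window_s)
  ws <- (seq_len(n_win) - 1) * window_s
  inside <- !is.na(iv_locate(nrem, ws)) &
    !is.na(iv_locate(nrem, ws + window_s - 1e-9)) &
    iv_locate(nrem, ws) == iv_locate(nrem, ws + window_s - 1e-9)
  windows <- data.frame(state = ifelse(inside, "NREM", "OTHER"),
                        start_s = ws, end_s = ws + window_s)
  list(nrem = nrem, windows = windows)
}

# renewal event times within [a, b]: cycle = dur + exponential gap with the
# mean chosen so the long-run rate matches rate_per_min
.renewal_times <- function(a, b, rate_per_min, mean_dur) {
  if (rate_per_min <= 0 || b <= a) return(numeric(0))
  gap_mean <- max(0.05, 60 / rate_per_min - mean_dur)
  out <- numeric(0)
  t <- a + stats::rexp(1, 1 / gap_mean)
  while (t < b) {
    out <- c(out, t)
    t <- t + mean_dur + stats::rexp(1, 1 / gap_mean)
  }
  out
}

#' Simulate a two-channel LFP recording with ground truth
#'
#' Generates a cortical channel (1/f background + NREM delta boost + slow
#' oscillations + spindle bursts) and a hippocampal channel (1/f background
#' + awake theta + ripple bursts), on an alternating NREM/other schedule,
#' fully determined by \code{cfg$seed}.
#'
#' The SO waveform is one period of an asymmetric raised cosine starting
#' on a rising zero crossing (positive lobe then trough), so its bounding
#' negative-to-positive crossings, trough depth and cycle duration realize
#' the detector's candidate geometry by construction. Spindle bursts are
#' Hann-windowed sinusoids; ripple bursts are Hann-windowed cosines with
#' the deepest trough at the burst center (the detection anchor). Coupled
#' spindles/SWRs are placed at a von Mises-distributed SO phase; uncoupled
#' ones uniformly within NREM. All events keep at least 1 s clearance from
#' epoch boundaries.
#'
#' @param cfg a \code{sim_config}
#' @return list: \code{recording} (an \code{lfp_recording}, channels MPtA
#'   cortical / CA1 hippocampal) and \code{truth} (list: \code{nrem}
#'   interval set, \code{epochs} ready-made \code{sleep_epochs},
#'   \code{windows} state table, \code{so}/\code{spindle}/\code{swr} event
#'   tables with anchors and coupling flags, \code{band_sd} the measured
#'   NREM background band SDs, \code{immobile} all-TRUE window mask)
#' @export
simulate_lfp <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  sched <- .state_schedule(cfg$duration_s, cfg$nrem_block_s,
                           cfg$other_block_s)
  nrem <- sched$nrem
  epochs <- .sleep_epochs(sched$windows)
  nrem_samp <- .nrem_mask(epochs, fs, n)

  ctx <- .pink_noise(n, cfg$noise_exponent, cfg$noise_sd)
  hpc <- .pink_noise(n, cfg$noise_exponent, cfg$noise_sd)

  # state-dependent background: NREM delta boost (cortex), awake theta (hpc)
  delta_bg_sd <- stats::sd(bandpass(ctx, 0.5, 4, fs))
  if (cfg$delta_boost > 0) {
    boost <- bandpass(.pink_noise(n, cfg$noise_exponent, cfg$noise_sd),
                      0.5, 4, fs)
    ctx <- ctx + ifelse(nrem_samp,
                        boost * cfg$delta_boost * delta_bg_sd /
                          stats::sd(boost), 0)
  }
  if (cfg$theta_amp > 0) {
    theta_bg_sd <- stats::sd(bandpass(hpc, 4, 8, fs))
    th <- sin(2 * pi * cfg$theta_freq * tt + stats::runif(1, 0, 2 * pi))
    hpc <- hpc + ifelse(nrem_samp, 0,
                        th * cfg$theta_amp * theta_bg_sd * sqrt(2))
  }

  # background SDs in the detection bands, NREM samples only
  band_sd <- c(so = stats::sd(bandpass(ctx, 0.5, 4, fs)[nrem_samp]),
               sp = stats::sd(bandpass(ctx, 9, 17, fs)[nrem_samp]),
               swr = stats::sd(bandpass(hpc, 150, 250, fs)[nrem_samp]))

  margin <- 1.8  # keeps coupled bursts > 1 s clear of epoch boundaries
  ## slow oscillations -------------------------------------------------
  so <- NULL
  for (i in seq_len(nrow(nrem))) {
    starts <- .renewal_times(nrem$start[i] + margin, nrem$end[i] - margin,
                             cfg$so_rate, mean(cfg$so_dur))
    if (!length(starts)) next
    dur <- stats::runif(length(starts), cfg$so_dur[1], cfg$so_dur[2])
    starts <- starts[starts + dur < nrem$end[i] - margin]
    dur <- dur[seq_along(starts)]
    so <- rbind(so, data.frame(start_s = starts, end_s = starts + dur,
                               dur_s = dur))
  }
  if (!is.null(so) && nrow(so)) {
    so$anchor_s <- so$start_s + 0.75 * so$dur_s  # trough at 3T/4
    A <- cfg$so_amp * band_sd["so"]
    soc <- numeric(n)
    for (i in seq_len(nrow(so))) {
      idx <- (round(so$start_s[i] * fs) + 1L):(round(so$end_s[i] * fs))
      u <- (seq_along(idx) - 1) / (length(idx) - 1)
      # asymmetric raised-cosine cycle: positive lobe (up-state), then the
      # deep trough; the full filtered cycle spans the waveform duration
      # plus the filter's undershoot lead-in, so durations are kept short
      # enough that the cycle stays inside the detector's 0.2-1.0 s window
      w <- ifelse(u < 0.5, cfg$so_up_frac * sin(2 * pi * u)^2,
                  -sin(2 * pi * (u - 0.5))^2)
      soc[idx] <- soc[idx] + A * w
    }
    # band-limit the SO component so its edges leak nothing into the
    # spindle band
    ctx <- ctx + bandpass(soc, 0.5, 4, fs)
  } else so <- data.frame(start_s = numeric(), end_s = numeric(),
                          dur_s = numeric(), anchor_s = numeric())

  ## bursty events (spindles on ctx, ripples on hpc) -------------------
  place_bursts <- function(rate, dur_rng, p_couple, mu, kappa, min_gap) {
    durs_all <- anchors <- coupled <- phase <- numeric(0)
    # coupled events ride on randomly chosen SOs
    if (nrow(so) && p_couple > 0 && rate > 0) {
      n_exp <- rate / 60 * iv_duration(nrem)
      n_cp <- stats::rbinom(1, round(n_exp), p_couple)
      n_cp <- min(n_cp, nrow(so))
      if (n_cp > 0) {
        pick <- sample(nrow(so), n_cp)
        ph <- rvonmises(n_cp, mu, kappa)
        anchors <- so$start_s[pick] + ph / 360 * so$dur_s[pick]
        coupled <- rep(1, n_cp); phase <- ph
        durs_all <- stats::runif(n_cp, dur_rng[1], dur_rng[2])
      }
      n_un <- round(n_exp) - n_cp
    } else n_un <- if (rate > 0) round(rate / 60 * iv_duration(nrem)) else 0
    if (n_un > 0) {
      for (i in seq_len(nrow(nrem))) {
        ni <- round(n_un * (nrem$end[i] - nrem$start[i]) /
                      iv_duration(nrem))
        if (ni < 1) next
        a <- stats::runif(ni, nrem$start[i] + margin, nrem$end[i] - margin)
        anchors <- c(anchors, a)
        coupled <- c(coupled, rep(0, ni))
        phase <- c(phase, rep(NA_real_, ni))
        durs_all <- c(durs_all, stats::runif(ni, dur_rng[1], dur_rng[2]))
      }
    }
    if (!length(anchors))
      return(data.frame(start_s = numeric(), end_s = numeric(),
                        anchor_s = numeric(), coupled = logical(),
                        phase = numeric()))
    o <- order(anchors)
    anchors <- anchors[o]; durs_all <- durs_all[o]
    coupled <- coupled[o]; phase <- phase[o]
    # thin overlapping bursts (would merge at detection)
    keep <- rep(TRUE, length(anchors)); last_end <- -Inf
    for (i in seq_along(anchors)) {
      st <- anchors[i] - durs_all[i] / 2
      if (st - last_end < min_gap) { keep[i] <- FALSE; next }
      last_end <- anchors[i] + durs_all[i] / 2
    }
    data.frame(start_s = (anchors - durs_all / 2)[keep],
               end_s = (anchors + durs_all / 2)[keep],
               anchor_s = anchors[keep], coupled = coupled[keep] > 0,
               phase = phase[keep])
  }

  spd <- place_bursts(cfg$sp_rate, cfg$sp_dur, cfg$p_couple_so_sp,
                      cfg$mu_sp, cfg$kappa_sp, min_gap = 0.45)
  if (nrow(spd)) {
    A <- cfg$sp_amp * band_sd["sp"]
    f <- stats::runif(nrow(spd), cfg$sp_freq[1], cfg$sp_freq[2])
    ph0 <- stats::runif(nrow(spd), 0, 2 * pi)
    for (i in seq_len(nrow(spd))) {
      idx <- (round(spd$start_s[i] * fs) + 1L):(round(spd$end_s[i] * fs))
      tloc <- (idx - 1) / fs - spd$start_s[i]
      u <- (seq_along(idx) - 1) / (length(idx) - 1)
      hann <- 0.5 * (1 - cos(2 * pi * u))
      ctx[idx] <- ctx[idx] + A * hann * sin(2 * pi * f[i] * tloc + ph0[i])
    }
  }

  swd <- place_bursts(cfg$swr_rate, cfg$swr_dur, cfg$p_couple_so_swr,
                      cfg$mu_swr, cfg$kappa_swr, min_gap = 0.3)
  if (nrow(swd)) {
    A <- cfg$swr_amp * band_sd["swr"]
    f <- stats::runif(nrow(swd), cfg$swr_freq[1], cfg$swr_freq[2])
    for (i in seq_len(nrow(swd))) {
      idx <- (round(swd$start_s[i] * fs) + 1L):(round(swd$end_s[i] * fs))
      tloc <- (idx - 1) / fs - swd$anchor_s[i]
      u <- (seq_along(idx) - 1) / (length(idx) - 1)
      # Hann envelope peaked at the burst center: the central carrier
      # trough is strictly the deepest, pinning the detection anchor (the
      # most negative band-passed sample) to the true anchor
      env <- 0.5 * (1 - cos(2 * pi * u))
      hpc[idx] <- hpc[idx] - A * env * cos(2 * pi * f[i] * tloc)
    }
  }

  rec <- lfp_recording(cbind(ctx, hpc), fs,
                       data.frame(label = c("MPtA", "CA1"),
                                  role = c("cortical", "hippocampal")))
  list(recording = rec,
       truth = list(nrem = nrem, epochs = epochs, windows = sched$windows,
                    so = so, spindle = spd, swr = swd, band_sd = band_sd,
                    immobile = rep(TRUE, nrow(sched$windows))))
}

#' Simulate object-place-recognition behavior tracks
#'
#' Generates per-trial nose/body tracking tables in a square arena with two
#' objects. Exploration bouts alternate with wandering; each bout targets
#' the displaced object with probability \code{preference_p} and lasts an
#' exponential time. During a bout the nose sits within the exploration
#' distance of the object boundary with the heading toward the object;
#' while wandering the animal stays near the arena center, away from both
#' objects.
#'
#' @param n_trials number of trials
#' @param preference_p probability each bout targets the displaced object
#' @param mean_bout_s,mean_gap_s exponential means of bout and gap
#'   durations (s)
#' @param total_s trial duration (s)
#' @param fs_track tracking rate (Hz)
#' @param arena_cm arena side (cm)
#' @param seed RNG seed
#' @return list: \code{tracks} (list of tracking data.frames),
#'   \code{objects} (object table, first object displaced), \code{truth}
#'   (per-trial data.frame with allocated \code{t_d}, \code{t_n} and the
#'   realized \code{index})
#' @export
simulate_behavior <- function(n_trials, preference_p, mean_bout_s = 2,
                              mean_gap_s = 5, total_s = 300, fs_track = 25,
                              arena_cm = 40, seed = 1L) {
  if (preference_p < 0 || preference_p > 1) stop("invalid preference_p")
  set.seed(seed)
  objects <- data.frame(label = c("displaced", "nondisplaced"),
                        x = c(0.3, 0.7) * arena_cm,
                        y = c(0.3, 0.7) * arena_cm,
                        radius = 3, displaced = c(TRUE, FALSE))
  dt <- 1 / fs_track
  tracks <- vector("list", n_trials)
  td <- tn <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    tgrid <- seq(0, total_s - dt, by = dt)
    nx <- ny <- bx <- by <- numeric(length(tgrid))
    # wandering default: noisy loop around the arena center
    cx <- arena_cm / 2
    wob <- 3 * sin(2 * pi * 0.05 * tgrid) + stats::rnorm(length(tgrid), 0, .3)
    nx[] <- cx + wob; ny[] <- cx - wob
    bx[] <- nx - 4; by[] <- ny + 4
    t <- stats::rexp(1, 1 / mean_gap_s)
    while (t < total_s) {
      dur <- stats::rexp(1, 1 / mean_bout_s)
      dur <- min(dur, total_s - t)
      obj <- if (stats::runif(1) < preference_p) 1L else 2L
      sel <- tgrid >= t & tgrid < t + dur
      if (any(sel)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d0 <- objects$radius[obj] + stats::runif(1, 0.5, 1.5)
        nxp <- objects$x[obj] + d0 * cos(ang)
        nyp <- objects$y[obj] + d0 * sin(ang)
        ux <- (objects$x[obj] - nxp); uy <- (objects$y[obj] - nyp)
        nrm <- sqrt(ux^2 + uy^2)
        nx[sel] <- nxp; ny[sel] <- nyp
        bx[sel] <- nxp - 6 * ux / nrm; by[sel] <- nyp - 6 * uy / nrm
        realized <- sum(sel) * dt
        if (obj == 1L) td[tr] <- td[tr] + realized
        else tn[tr] <- tn[tr] + realized
      }
      t <- t + dur + stats::rexp(1, 1 / mean_gap_s)
    }
    tracks[[tr]] <- data.frame(time_s = tgrid, nose_x = nx, nose_y = ny,
                               body_x = bx, body_y = by)
  }
  idx <- ifelse(td + tn > 0, (td - tn) / (td + tn), NA_real_)
  list(tracks = tracks, objects = objects,
       truth = data.frame(trial = seq_len(n_trials), t_d = td, t_n = tn,
                          index = idx))
}
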