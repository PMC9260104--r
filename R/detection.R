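#' Detection configuration
#'
#' All thresholds of the three event detectors, in the units the detectors
#' use: SD multiples of the relevant filtered signal or envelope over NREM
#' sleep, seconds for durations.
#'
#' @param so_band slow-oscillation band (Hz)
#' @param so_cycle admissible interval between the two bounding
#'   negative-to-positive zero crossings (s)
#' @param so_p2p_max peak-to-trough must be below mean + this many SD
#' @param so_p2p_min ... and above mean - this many SD (vacuous for a
#'   positive amplitude on a z-scored trace; retained for fidelity to the
#'   published rule)
#' @param so_trough_max trough must be below mean - this many SD
#' @param so_trough_min ... and above mean - this many SD
#' @param sp_band spindle band (Hz)
#' @param sp_lower,sp_upper envelope thresholds (SD above mean)
#' @param sp_min_dur minimum spindle duration (s)
#' @param sp_merge_gap spindles closer than this merge (s)
#' @param sp_kernel_alpha,sp_kernel_len Gaussian envelope smoother: width
#'   factor and kernel length (s)
#' @param swr_band ripple band (Hz)
#' @param swr_env_thresh squared-envelope span threshold (SD above mean)
#' @param swr_peak_thresh squared-envelope peak threshold (SD above mean)
#' @param swr_dur admissible ripple duration range (s)
#' @return list of class \code{detection_config}
#' @export
detection_config <- function(so_band = c(0.5, 4), so_cycle = c(0.2, 1.0),
                             so_p2p_max = 3, so_p2p_min = 6,
                             so_trough_max = 1.5, so_trough_min = 4,
                             sp_band = c(9, 17), sp_lower = 1, sp_upper = 2,
                             sp_min_dur = 0.5, sp_merge_gap = 0.3,
                             sp_kernel_alpha = 2.0, sp_kernel_len = 0.2,
                             swr_band = c(150, 250), swr_env_thresh = 2,
                             swr_peak_thresh = 5, swr_dur = c(0.03, 0.1)) {
  stopifnot(so_band[1] < so_band[2], sp_band[1] < sp_band[2],
            swr_band[1] < swr_band[2], so_cycle[1] > 0,
            so_cycle[1] < so_cycle[2], sp_min_dur > 0,
            swr_dur[1] > 0, swr_dur[1] < swr_dur[2])
  structure(as.list(environment()), class = "detection_config")
}

# sample indices (1-based) covered by retained NREM epochs, per epoch
.epoch_sample_ranges <- function(epochs, fs, n) {
  iv <- epochs$nrem
  if (nrow(iv) == 0L) return(list())
  out <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    a <- max(1L, floor(iv$start[i] * fs) + 1L)
    b <- min(n, ceiling(iv$end[i] * fs))
    out[[i]] <- if (b > a) c(a, b) else NULL
  }
  Filter(Negate(is.null), out)
}

.nrem_mask <- function(epochs, fs, n) {
  m <- logical(n)
  for (r in .epoch_sample_ranges(epochs, fs, n)) m[r[1]:r[2]] <- TRUE
  m
}

# maximal runs of TRUE in a logical vector -> matrix [start, end] (indices)
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# zero-crossing count of a vector (sign changes, either direction)
.n_zero_cross <- function(x) sum(diff(sign(x)) != 0)

#' Detect slow oscillations
#'
#' Candidates are pairs of consecutive negative-to-positive zero crossings of
#' the 0.5-4 Hz filtered cortical trace with inter-crossing interval within
#' \code{cfg$so_cycle}. A candidate is retained when its peak-to-trough
#' amplitude lies below mean + 3 SD (and above mean - 6 SD), and its trough
#' lies below mean - 1.5 SD and above mean - 4 SD, where mean/SD are taken
#' over the filtered trace restricted to NREM sleep. The event anchor is the
#' trough (down-state); the peak for peak-to-trough is the maximum between
#' trough and second crossing. Events are detected within each retained NREM
#' epoch separately, so none straddles an epoch boundary.
#'
#' @param x z-scored cortical signal (numeric vector)
#' @param fs sampling rate (Hz)
#' @param epochs a \code{sleep_epochs} object with non-empty retained NREM
#' @param cfg a \code{detection_config}
#' @param channel channel label recorded into the output (default "cortical")
#' @return an \code{event_set} of SO events
#' @export
detect_so <- function(x, fs, epochs, cfg = detection_config(),
                      channel = "cortical") {
  xf <- bandpass(x, cfg$so_band[1], cfg$so_band[2], fs)
  mask <- .nrem_mask(epochs, fs, length(x))
  mu <- mean(xf[mask]); sig <- stats::sd(xf[mask])
  out <- list()
  for (r in .epoch_sample_ranges(epochs, fs, length(x))) {
    seg <- xf[r[1]:r[2]]
    cross <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)  # neg-to-pos
    if (length(cross) < 2L) next
    for (k in seq_len(length(cross) - 1L)) {
      c1 <- cross[k]; c2 <- cross[k + 1L]
      dt <- (c2 - c1) / fs
      if (dt < cfg$so_cycle[1] || dt > cfg$so_cycle[2]) next
      span <- seg[c1:c2]
      ti <- which.min(span)
      trough <- span[ti]
      peak <- max(span[ti:length(span)])
      p2p <- peak - trough
      if (p2p >= mu + cfg$so_p2p_max * sig) next
      if (p2p <= mu - cfg$so_p2p_min * sig) next
      if (trough >= mu - cfg$so_trough_max * sig) next
      if (trough <= mu - cfg$so_trough_min * sig) next
      s0 <- (r[1] - 1L + c1 - 1L) / fs
      e0 <- (r[1] - 1L + c2 - 1L) / fs
      a0 <- (r[1] - 1L + c1 - 1L + ti - 1L) / fs
      out[[length(out) + 1L]] <-
        data.frame(start_s = s0, end_s = e0, anchor_s = a0, amplitude = p2p,
                   peak_freq_hz = 1 / dt)
    }
  }
  .assemble_events(out, "SO", channel)
}

#' Detect sleep spindles
#'
#' The spindle envelope is the magnitude of the analytic signal of the
#' 9-17 Hz filtered cortical trace, smoothed with a unit-sum Gaussian kernel
#' (width factor 2.0, 0.2 s). Candidate spans are maximal runs above
#' mean + 1 SD of the NREM envelope; spans separated by gaps of at most
#' 0.3 s are merged, then spans shorter than 0.5 s or lacking a sample above
#' mean + 2 SD are discarded. The anchor is the envelope maximum.
#'
#' @inheritParams detect_so
#' @return an \code{event_set} of SPINDLE events
#' @export
detect_spindles <- function(x, fs, epochs, cfg = detection_config(),
                            channel = "cortical") {
  xf <- bandpass(x, cfg$sp_band[1], cfg$sp_band[2], fs)
  env <- .conv_same(Mod(hilbert_analytic(xf)),
                    gauss_kernel(cfg$sp_kernel_alpha, cfg$sp_kernel_len, fs))
  mask <- .nrem_mask(epochs, fs, length(x))
  mu <- mean(env[mask]); sig <- stats::sd(env[mask])
  lower <- mu + cfg$sp_lower * sig
  upper <- mu + cfg$sp_upper * sig
  out <- list()
  for (r in .epoch_sample_ranges(epochs, fs, length(x))) {
    eseg <- env[r[1]:r[2]]
    spans <- .runs(eseg > lower)
    if (!nrow(spans)) next
    spans <- .merge_spans(spans, round(cfg$sp_merge_gap * fs))
    for (i in seq_len(nrow(spans))) {
      a <- spans[i, 1]; b <- spans[i, 2]
      if ((b - a) / fs < cfg$sp_min_dur) next
      if (max(eseg[a:b]) <= upper) next
      pk <- a - 1L + which.max(eseg[a:b])
      fseg <- xf[(r[1] - 1L + a):(r[1] - 1L + b)]
      dur <- (b - a) / fs
      out[[length(out) + 1L]] <-
        data.frame(start_s = (r[1] - 1L + a - 1L) / fs,
                   end_s = (r[1] - 1L + b - 1L) / fs,
                   anchor_s = (r[1] - 1L + pk - 1L) / fs,
                   amplitude = eseg[pk],
                   peak_freq_hz = .n_zero_cross(fseg) / (2 * dur))
    }
  }
  .assemble_events(out, "SPINDLE", channel)
}

#' Detect hippocampal sharp-wave ripples
#'
#' The detection envelope is the squared magnitude of the analytic signal of
#' the 150-250 Hz filtered hippocampal trace (squaring accentuates
#' small-amplitude ripples). Events are maximal spans above mean + 2 SD of
#' the NREM squared envelope whose peak exceeds mean + 5 SD and whose
#' duration falls in 30-100 ms. The anchor is the most negative sample of
#' the band-passed trace within the event (the maximal ripple trough).
#'
#' @param x z-scored hippocampal signal (numeric vector)
#' @inheritParams detect_so
#' @return an \code{event_set} of SWR events
#' @export
detect_swr <- function(x, fs, epochs, cfg = detection_config(),
                       channel = "hippocampal") {
  xf <- bandpass(x, cfg$swr_band[1], cfg$swr_band[2], fs)
  env2 <- Mod(hilbert_analytic(xf))^2
  mask <- .nrem_mask(epochs, fs, length(x))
  mu <- mean(env2[mask]); sig <- stats::sd(env2[mask])
  span_th <- mu + cfg$swr_env_thresh * sig
  peak_th <- mu + cfg$swr_peak_thresh * sig
  out <- list()
  for (r in .epoch_sample_ranges(epochs, fs, length(x))) {
    eseg <- env2[r[1]:r[2]]
    spans <- .runs(eseg > span_th)
    if (!nrow(spans)) next
    for (i in seq_len(nrow(spans))) {
      a <- spans[i, 1]; b <- spans[i, 2]
      dur <- (b - a) / fs
      if (dur < cfg$swr_dur[1] || dur > cfg$swr_dur[2]) next
      if (max(eseg[a:b]) <= peak_th) next
      fseg <- xf[(r[1] - 1L + a):(r[1] - 1L + b)]
      tr <- which.min(fseg)
      out[[length(out) + 1L]] <-
        data.frame(start_s = (r[1] - 1L + a - 1L) / fs,
                   end_s = (r[1] - 1L + b - 1L) / fs,
                   anchor_s = (r[1] - 1L + a - 1L + tr - 1L) / fs,
                   amplitude = sqrt(max(eseg[a:b])),
                   peak_freq_hz = .n_zero_cross(fseg) / (2 * dur))
    }
  }
  .assemble_events(out, "SWR", channel)
}

# merge index spans whose gap (samples) is <= gap
.merge_spans <- function(spans, gap) {
  if (nrow(spans) < 2L) return(spans)
  keep <- spans[1, , drop = FALSE]
  for (i in 2:nrow(spans)) {
    if (spans[i, 1] - keep[nrow(keep), 2] - 1L <= gap)
      keep[nrow(keep), 2] <- spans[i, 2]
    else keep <- rbind(keep, spans[i, ])
  }
  keep
}

.assemble_events <- function(rows, type, channel) {
  if (!length(rows))
    return(event_set())
  d <- do.call(rbind, rows)
  event_set(event_type = rep(type, nrow(d)),
            channel = rep(channel, nrow(d)),
            start_s = d$start_s, end_s = d$end_s, anchor_s = d$anchor_s,
            amplitude = d$amplitude, peak_freq_hz = d$peak_freq_hz)
}

#' Per-session event feature summary
#'
#' Session-level descriptors per event type: mean within-event band power
#' (z^2 units of the band-passed trace), mean within-event oscillation
#' frequency, mean duration, density in events per minute of retained NREM
#' sleep, and mean amplitude.
#'
#' @param events an \code{event_set} of one type
#' @param epochs the \code{sleep_epochs} the events were detected in;
#'   NREM time must be positive
#' @param band_signal the band-passed signal the events were detected on
#'   (used for mean within-event power); may be NULL to skip power
#' @param fs sampling rate (Hz), required with \code{band_signal}
#' @return one-row data.frame: \code{event_type, n, power, frequency,
#'   duration, density, amplitude}; means are NA when no events
#' @export
summarize_features <- function(events, epochs, band_signal = NULL, fs = NULL) {
  mins <- nrem_minutes(epochs)
  if (mins <= 0) stop("no retained NREM time")
  n <- nrow(events)
  pow <- NA_real_
  if (n > 0 && !is.null(band_signal)) {
    stopifnot(!is.null(fs))
    pw <- vapply(seq_len(n), function(i) {
      a <- floor(events$start_s[i] * fs) + 1L
      b <- min(length(band_signal), ceiling(events$end_s[i] * fs) + 1L)
      mean(band_signal[a:b]^2)
    }, 1)
    pow <- mean(pw)
  }
  data.frame(event_type = if (n) events$event_type[1] else NA_character_,
             n = n,
             power = pow,
             frequency = if (n) mean(events$peak_freq_hz) else NA_real_,
             duration = if (n) mean(events$duration_s) else NA_real_,
             density = n / mins,
             amplitude = if (n) mean(events$amplitude) else NA_real_)
}
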