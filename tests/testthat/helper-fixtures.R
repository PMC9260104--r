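# Shared fixtures, all built in code (no data files).

# sleep_epochs whose retained NREM covers [0, dur_s) contiguously
fx_all_nrem <- function(dur_s, window_s = 5) {
  ws <- seq(0, dur_s - window_s, by = window_s)
  sleeposc:::.sleep_epochs(
    data.frame(state = "NREM", start_s = ws, end_s = ws + window_s))
}

# two-channel white-noise recording
fx_noise_rec <- function(dur_s, fs = 1000, seed = 1) {
  set.seed(seed)
  n <- round(dur_s * fs)
  lfp_recording(cbind(rnorm(n), rnorm(n)), fs,
                data.frame(label = c("ctx", "hpc"),
                           role = c("cortical", "hippocampal")))
}

# insert a sinusoidal burst (flat envelope) into x at [t0, t0 + dur)
fx_add_burst <- function(x, fs, t0, dur, freq, amp, phase = 0) {
  idx <- (round(t0 * fs) + 1L):(round((t0 + dur) * fs))
  tloc <- (idx - 1) / fs
  x[idx] <- x[idx] + amp * sin(2 * pi * freq * tloc + phase)
  x
}

# SO rule fixture: cycles of duration d whose trough amplitudes repeat `amps`
fx_so_wave <- function(d, amps, total_s, fs = 200) {
  n <- round(d * fs)
  one <- -sin(2 * pi * (seq_len(n) - 1) / n)
  k <- ceiling(total_s / d)
  a <- rep(rep(amps, length.out = k), each = n)
  (a * rep(one, k))[seq_len(round(total_s * fs))]
}

# permissive-amplitude SO config isolating the cycle-duration rule
fx_so_cycle_only <- function(cyc) {
  detection_config(so_cycle = cyc, so_trough_max = 0.01,
                   so_p2p_max = 1000, so_trough_min = 1000)
}

# spindle/SWR rule fixture: constant carrier plus phase-aligned bursts
fx_carrier <- function(dur_s, freq, amp, fs = 1000) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs))
}

# anchor distances: recall/precision of detected vs true anchor times
fx_match <- function(det, tru, tol) {
  if (!length(tru)) return(c(recall = NA_real_, precision = NA_real_))
  if (!length(det)) return(c(recall = 0, precision = 0))
  d <- outer(det, tru, function(a, b) abs(a - b))
  c(recall = mean(apply(d, 2, min) <= tol),
    precision = mean(apply(d, 1, min) <= tol))
}
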