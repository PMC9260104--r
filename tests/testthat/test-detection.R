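# Deterministic constructed signals that put known events on the correct
# side of each detector rule. All amplitude margins are expressed in SD units
# of the filtered trace, so they are invariant to filter passband gain.

test_that("detect_so keeps deep cycles and rejects shallow troughs", {
  fs <- 200
  ep <- fx_all_nrem(55)
  # alternating deep (2) / shallow (0.8) 0.8 s cycles: deep troughs sit at
  # 1.9 SD of the filtered trace (inside the 1.5-3 SD pass window), shallow
  # at 0.76 SD (below the 1.5 SD floor)
  x <- fx_so_wave(0.8, c(2, 0.8), 55, fs)
  so <- detect_so(x, fs, ep)
  deep <- seq(1.8, 52, by = 1.6)
  shallow <- deep - 0.8
  expect_equal(unname(fx_match(so$anchor_s, deep, 0.05)["recall"]), 1)
  expect_equal(sum(vapply(so$anchor_s,
    function(a) min(abs(a - shallow)), 1) <= 0.05), 0)
  expect_true(all(so$duration_s > 0.75 & so$duration_s < 0.85))
  expect_true(all(so$amplitude > 0))
})

test_that("detect_so rejects cycles whose peak-to-trough exceeds mean + 3 SD", {
  fs <- 200
  ep <- fx_all_nrem(55)
  # one deep (2) cycle in six shallow (0.3): deep p2p is ~3.2 SD
  x <- fx_so_wave(0.8, c(2, 0.3, 0.3, 0.3, 0.3, 0.3), 55, fs)
  expect_equal(nrow(detect_so(x, fs, ep)), 0)
  # relaxing only the p2p ceiling recovers the deep cycles, proving the
  # ceiling (not the trough rules) rejected them
  relaxed <- detect_so(x, fs, ep, detection_config(so_p2p_max = 10))
  expect_gt(nrow(relaxed), 5)
})

test_that("detect_so rejects cycles outside 0.2-1.0 s", {
  fs <- 200
  ep <- fx_all_nrem(55)
  # 1.2 s cycles under permissive amplitude rules: only the cycle rule can
  # reject, and widening it recovers the events
  x_long <- fx_so_wave(1.2, c(2, 0.8), 55, fs)
  expect_equal(nrow(detect_so(x_long, fs, ep, fx_so_cycle_only(c(0.2, 1.0)))), 0)
  expect_gt(nrow(detect_so(x_long, fs, ep, fx_so_cycle_only(c(0.2, 2.0)))), 10)
  # 0.15 s cycles (above-band leakage keeps the crossing spacing at 0.15 s)
  x_short <- fx_carrier(55, 1 / 0.15, 2, fs)
  expect_equal(nrow(detect_so(x_short, fs, ep, fx_so_cycle_only(c(0.2, 1.0)))), 0)
  expect_gt(nrow(detect_so(x_short, fs, ep, fx_so_cycle_only(c(0.1, 1.0)))), 100)
})

test_that("spindle duration and merge rules are exact", {
  fs <- 1000
  ep <- fx_all_nrem(60)
  x <- fx_carrier(60, 12, 0.3, fs)
  x <- fx_add_burst(x, fs, 10, 0.35, 12, 3)                # short -> reject
  x <- fx_add_burst(x, fs, 20, 0.65, 12, 3)                # accept
  x <- fx_add_burst(x, fs, 30, 0.40, 12, 3)                # gap 0.25 s:
  x <- fx_add_burst(x, fs, 30.65, 0.40, 12, 3)             #   merge to one
  x <- fx_add_burst(x, fs, 40, 0.40, 12, 3)                # gap 0.5 s:
  x <- fx_add_burst(x, fs, 40.9, 0.40, 12, 3)              #   both rejected
  sp <- detect_spindles(x, fs, ep)
  expect_equal(nrow(sp), 2)
  expect_equal(sum(sp$start_s > 9 & sp$end_s < 11), 0)     # 0.35 s burst out
  expect_equal(sum(sp$start_s > 19 & sp$end_s < 22), 1)
  expect_equal(sum(sp$start_s > 29 & sp$end_s < 32), 1)    # merged pair = one
  expect_equal(sum(sp$start_s > 39 & sp$end_s < 42), 0)
  # the merged event spans both bursts
  m <- sp[sp$start_s > 29, ]
  expect_lt(m$start_s, 30.2)
  expect_gt(m$end_s, 30.85)
  # attribution: with merging disabled the 0.25 s-gap pair disappears too
  # (each 0.4 s run is under the 0.5 s minimum), proving the merge rule
  # created the event
  sp2 <- detect_spindles(x, fs, ep, detection_config(sp_merge_gap = 0.01))
  expect_equal(sum(sp2$start_s > 29 & sp2$end_s < 32), 0)
  # and with a 0.3 s minimum the short burst is recovered, proving the
  # duration rule rejected it
  sp3 <- detect_spindles(x, fs, ep, detection_config(sp_min_dur = 0.3))
  expect_equal(sum(sp3$start_s > 9 & sp3$end_s < 11), 1)
})

test_that("SWR duration bounds and 5 SD peak rule are exact", {
  fs <- 1000
  ep <- fx_all_nrem(60)
  x <- fx_carrier(60, 200, 0.5, fs)
  x <- fx_add_burst(x, fs, 10, 0.020, 200, 2)    # under 30 ms -> reject
  x <- fx_add_burst(x, fs, 20, 0.060, 200, 2)    # accept
  x <- fx_add_burst(x, fs, 30, 0.120, 200, 2)    # over 100 ms -> reject
  x <- fx_add_burst(x, fs, 40, 0.060, 200, 0.6)  # span ok, peak < 5 SD
  swr <- detect_swr(x, fs, ep)
  expect_equal(nrow(swr), 1)
  expect_gt(swr$start_s, 19.9)
  expect_lt(swr$end_s, 20.2)
  # duration attribution: widening the bounds recovers the 20 ms and 120 ms
  # bursts
  wide <- detect_swr(x, fs, ep, detection_config(swr_dur = c(0.005, 0.2)))
  expect_equal(sum(wide$start_s > 9 & wide$end_s < 11), 1)
  expect_equal(sum(wide$start_s > 29 & wide$end_s < 31), 1)
  # peak attribution: the weak burst crosses the 2 SD span threshold (it
  # appears once the peak rule is relaxed) but fails the 5 SD peak rule
  lowpk <- detect_swr(x, fs, ep, detection_config(swr_peak_thresh = 2.5))
  expect_equal(sum(lowpk$start_s > 39 & lowpk$end_s < 41), 1)
  expect_equal(sum(swr$start_s > 39 & swr$end_s < 41), 0)
})

test_that("raising thresholds never increases detection counts", {
  set.seed(31)
  fs <- 1000
  n <- 60 * fs
  t <- seq_len(n) / fs
  x <- rnorm(n) + 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 12 * t) *
    (1 + sin(2 * pi * 0.05 * t))
  ep <- fx_all_nrem(60)
  n_sp1 <- nrow(detect_spindles(x, fs, ep, detection_config(sp_upper = 1.5)))
  n_sp2 <- nrow(detect_spindles(x, fs, ep, detection_config(sp_upper = 2.5)))
  expect_lte(n_sp2, n_sp1)
  n_sw1 <- nrow(detect_swr(x, fs, ep, detection_config(swr_peak_thresh = 3)))
  n_sw2 <- nrow(detect_swr(x, fs, ep, detection_config(swr_peak_thresh = 6)))
  expect_lte(n_sw2, n_sw1)
})

test_that("events never straddle retained-epoch boundaries", {
  fs <- 500
  # two retained NREM epochs separated by an OTHER gap at 30-35 s
  st <- rep("NREM", 13); st[7] <- "OTHER"
  ws <- (0:12) * 5
  ep <- sleeposc:::.sleep_epochs(
    data.frame(state = st, start_s = ws, end_s = ws + 5))
  x <- fx_carrier(65, 12, 0.3, fs)
  x <- fx_add_burst(x, fs, 29.7, 0.65, 12, 3)  # straddles the 30 s boundary
  x <- fx_add_burst(x, fs, 50, 0.65, 12, 3)    # fully inside epoch 2
  sp <- detect_spindles(x, fs, ep)
  for (i in seq_len(nrow(sp))) {
    i1 <- iv_locate(ep$nrem, sp$start_s[i])
    i2 <- iv_locate(ep$nrem, sp$end_s[i] - 1e-9)
    expect_false(is.na(i1))
    expect_equal(i1, i2)
  }
  expect_equal(sum(sp$start_s > 49 & sp$end_s < 52), 1)
})

test_that(".merge_spans and .runs behave on hand cases", {
  expect_equal(sleeposc:::.runs(c(F, T, T, F, T)),
               cbind(c(2L, 5L), c(3L, 5L)))
  sp <- cbind(c(1L, 10L, 30L), c(5L, 20L, 40L))
  m <- sleeposc:::.merge_spans(sp, gap = 4L)
  expect_equal(m, cbind(c(1L, 30L), c(20L, 40L)))
  expect_equal(sleeposc:::.merge_spans(sp, gap = 3L), sp)
})

test_that("summarize_features reports density against NREM minutes", {
  ep <- fx_all_nrem(120)
  ev <- event_set(event_type = rep("SWR", 6), channel = rep("h", 6),
                  start_s = 1:6 * 10, end_s = 1:6 * 10 + 0.05,
                  anchor_s = 1:6 * 10 + 0.02, amplitude = rep(3, 6),
                  peak_freq_hz = rep(200, 6))
  s <- summarize_features(ev, ep)
  expect_equal(s$n, 6)
  expect_equal(s$density, 3)          # 6 events / 2 NREM minutes
  expect_equal(s$duration, 0.05)
  expect_equal(s$frequency, 200)
  expect_true(is.na(s$power))
  s2 <- summarize_features(ev, ep, band_signal = rep(2, 120 * 100), fs = 100)
  expect_equal(s2$power, 4)
  empty <- summarize_features(event_set(), ep)
  expect_equal(empty$n, 0)
  expect_equal(empty$density, 0)
  expect_true(is.na(empty$amplitude))
})
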