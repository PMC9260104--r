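test_that("simulate_lfp is fully reproducible from its seed", {
  cfg <- sim_config(duration_s = 240, seed = 9)
  a <- simulate_lfp(cfg)
  b <- simulate_lfp(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$so, b$truth$so)
  expect_identical(a$truth$spindle, b$truth$spindle)
  expect_identical(a$truth$swr, b$truth$swr)
  c2 <- simulate_lfp(sim_config(duration_s = 240, seed = 10))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("ground-truth events respect NREM margins and rates", {
  cfg <- sim_config(duration_s = 900, seed = 2)
  sim <- simulate_lfp(cfg)
  tr <- sim$truth
  mins <- iv_duration(tr$nrem) / 60
  for (ev in list(tr$so, tr$spindle, tr$swr)) {
    i1 <- iv_locate(tr$nrem, ev$start_s)
    i2 <- iv_locate(tr$nrem, ev$end_s)
    expect_false(anyNA(i1))
    expect_equal(i1, i2)
    # at least 1 s clearance from epoch boundaries
    expect_true(all(ev$start_s - tr$nrem$start[i1] >= 1))
    expect_true(all(tr$nrem$end[i1] - ev$end_s >= 1))
  }
  # realized densities near the configured rates (renewal thinning and
  # overlap pruning shave a little; allow a generous band)
  expect_gt(nrow(tr$so) / mins, cfg$so_rate * 0.6)
  expect_lt(nrow(tr$so) / mins, cfg$so_rate * 1.2)
  for (d in list(c(nrow(tr$spindle), cfg$sp_rate),
                 c(nrow(tr$swr), cfg$swr_rate))) {
    expect_gt(d[1] / mins, d[2] * 0.6)
    expect_lt(d[1] / mins, d[2] * 1.4)
  }
  # event amplitudes are in declared SD units of the measured band SDs
  expect_true(all(c("so", "sp", "swr") %in% names(tr$band_sd)))
  expect_true(all(tr$band_sd > 0))
})

test_that("coupled events are tagged with their placement phase", {
  sim <- simulate_lfp(sim_config(duration_s = 900, seed = 3,
                                 p_couple_so_sp = 1, kappa_sp = 50))
  sp <- sim$truth$spindle
  expect_true(all(sp$coupled))
  expect_false(anyNA(sp$phase))
  cs <- circular_stats(sp$phase)
  expect_gt(cs$resultant_r, 0.9)
  expect_equal(cs$preferred_phase, 90, tolerance = 10)
  # uncoupled events carry NA phase
  sim0 <- simulate_lfp(sim_config(duration_s = 600, seed = 4,
                                  p_couple_so_sp = 0, p_couple_so_swr = 0))
  expect_true(all(is.na(sim0$truth$spindle$phase)))
  expect_true(all(!sim0$truth$spindle$coupled))
})

test_that("zero event rates give featureless noise with a bounded FP count", {
  cfg <- sim_config(duration_s = 600, so_rate = 0, sp_rate = 0, swr_rate = 0,
                    seed = 6)
  sim <- simulate_lfp(cfg)
  expect_equal(nrow(sim$truth$so), 0)
  expect_equal(nrow(sim$truth$spindle), 0)
  expect_equal(nrow(sim$truth$swr), 0)
  rec <- zscore_recording(sim$recording)
  ep <- sim$truth$epochs
  mins <- nrem_minutes(ep)
  sp <- detect_spindles(channel_by_role(rec, "cortical"), rec$fs, ep)
  # on featureless 1/f noise the adaptive thresholds sit inside the noise
  # envelope distribution, so some false positives are expected; the
  # characterized budget is <= 10 per NREM minute
  expect_lte(nrow(sp) / mins, 10)
  sw <- detect_swr(channel_by_role(rec, "hippocampal"), rec$fs, ep)
  expect_lte(nrow(sw) / mins, 10)
})

test_that("staging features separate the simulated states", {
  sim <- simulate_lfp(sim_config(duration_s = 600, seed = 7))
  rec <- zscore_recording(sim$recording)
  feats <- band_features(rec, immobile = sim$truth$immobile)
  ep <- kmeans_stage(feats)
  truth_states <- sim$truth$windows$state
  acc <- mean(ep$windows$state == truth_states)
  expect_gt(acc, 0.95)
})

test_that("simulate_behavior allocation matches its own truth table", {
  sim <- simulate_behavior(n_trials = 4, preference_p = 0.8, seed = 11)
  expect_equal(length(sim$tracks), 4)
  expect_equal(sim$objects$displaced, c(TRUE, FALSE))
  for (tr in 1:4) {
    eb <- exploration_bouts(sim$tracks[[tr]], sim$objects)
    expect_equal(unname(eb$t_displaced), sim$truth$t_d[tr], tolerance = 0.2)
    expect_equal(unname(eb$t_nondisplaced), sim$truth$t_n[tr],
                 tolerance = 0.2)
  }
})

test_that("pipeline coupling significance is concordant with p_couple", {
  run <- function(p, seed) {
    sim <- simulate_lfp(sim_config(duration_s = 1200, p_couple_so_sp = p,
                                   p_couple_so_swr = p, seed = seed))
    rec <- zscore_recording(sim$recording)
    ep <- sim$truth$epochs
    ctx <- channel_by_role(rec, "cortical")
    hpc <- channel_by_role(rec, "hippocampal")
    so <- detect_so(ctx, rec$fs, ep)
    sp <- detect_spindles(ctx, rec$fs, ep)
    sw <- detect_swr(hpc, rec$fs, ep)
    c(montecarlo_coupling(so$anchor_s, sp$anchor_s, ep, n_perm = 500,
                          seed = seed)$significant,
      montecarlo_coupling(so$anchor_s, sw$anchor_s, ep, n_perm = 500,
                          seed = seed)$significant)
  }
  for (s in 1:3) {
    expect_true(all(run(1, s)))          # coupled -> significant
    expect_false(any(run(0, s + 100)))   # uncoupled -> not significant
  }
})
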