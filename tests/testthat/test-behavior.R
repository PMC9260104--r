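fx_track <- function() {
  # 10 Hz track, 30 s: two objects; nose visits each with correct heading,
  # plus one close approach facing AWAY that must not score
  t <- seq(0, 29.9, by = 0.1)
  n <- length(t)
  nx <- rep(20, n); ny <- rep(0, n); bx <- rep(20, n); by <- rep(-5, n)
  # object A (displaced) at (5, 5) r = 2; nose at boundary+1 facing it
  selA <- t >= 5 & t < 10                   # 5 s
  nx[selA] <- 5; ny[selA] <- 8              # 3 from center = boundary + 1
  bx[selA] <- 5; by[selA] <- 13             # heading (0,-5): toward center
  # object B at (30, 5): 4 s facing it
  selB <- t >= 15 & t < 19
  nx[selB] <- 30; ny[selB] <- 8
  bx[selB] <- 30; by[selB] <- 13
  # near A but heading away: must NOT count
  selC <- t >= 25 & t < 27
  nx[selC] <- 5; ny[selC] <- 8
  bx[selC] <- 5; by[selC] <- 3              # heading (0,+5): away
  data.frame(time_s = t, nose_x = nx, nose_y = ny, body_x = bx, body_y = by)
}

fx_objects <- function() {
  data.frame(label = c("A", "B"), x = c(5, 30), y = c(5, 5), radius = 2,
             displaced = c(TRUE, FALSE))
}

test_that("exploration_bouts scores proximity AND heading", {
  eb <- exploration_bouts(fx_track(), fx_objects())
  expect_equal(unname(eb$totals["A"]), 5, tolerance = 1e-9)
  expect_equal(unname(eb$totals["B"]), 4, tolerance = 1e-9)
  expect_equal(eb$t_displaced, 5, tolerance = 1e-9)
  expect_equal(eb$t_nondisplaced, 4, tolerance = 1e-9)
  # the facing-away approach created no extra A bout
  ba <- eb$bouts[eb$bouts$object == "A", ]
  expect_equal(nrow(ba), 1)
  expect_equal(ba$start_s, 5)
  expect_equal(ba$duration_s, 5, tolerance = 1e-9)
  bad <- fx_track(); bad$nose_x[3] <- NA
  expect_error(exploration_bouts(bad, fx_objects()),
               "missing nose coordinates")
  expect_error(exploration_bouts(fx_track()[, -2], fx_objects()),
               "missing nose/body coordinates")
  rev_t <- fx_track(); rev_t$time_s <- rev(rev_t$time_s)
  expect_error(exploration_bouts(rev_t, fx_objects()), "time must be monotone")
})

test_that("memory_index identities hold exactly", {
  expect_equal(memory_index(3, 1), 0.5)
  # antisymmetry
  for (p in list(c(2, 7), c(0.4, 0.1), c(5, 5)))
    expect_equal(memory_index(p[1], p[2]), -memory_index(p[2], p[1]))
  # bounds and extremes
  expect_equal(memory_index(4, 0), 1)
  expect_equal(memory_index(0, 4), -1)
  expect_equal(memory_index(2.5, 2.5), 0)
  expect_error(memory_index(0, 0), "zero total exploration")
})

test_that("binned_index is cumulative and its final bin equals the total", {
  eb <- exploration_bouts(fx_track(), fx_objects())
  bi <- binned_index(eb$bouts, bin_s = 10, total_s = 30)
  expect_equal(bi$bin_end, c(10, 20, 30))
  expect_equal(bi$t_d, c(5, 5, 5), tolerance = 1e-9)
  expect_equal(bi$t_n, c(0, 4, 4), tolerance = 1e-9)
  expect_equal(bi$index[1], 1)
  expect_equal(bi$index[3],
               memory_index(eb$t_displaced, eb$t_nondisplaced))
  # cumulative t_d and t_n never decrease
  expect_true(all(diff(bi$t_d) >= 0) && all(diff(bi$t_n) >= 0))
  # empty early bins are NA
  late <- eb$bouts[eb$bouts$start_s >= 15, ]
  bi2 <- binned_index(late, bin_s = 10, total_s = 30)
  expect_true(is.na(bi2$index[1]))
})

test_that("inclusion_filter applies the three exclusion reasons in order", {
  tr <- data.frame(enc_t_d = c(5, 0.5, 9, 5, 5),
                   enc_t_n = c(5, 5, 1.5, 5, 5),
                   slept = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- inclusion_filter(tr)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$reason, c("", "under-explored encoding",
                             "spontaneous preference",
                             "no sleep in retention", ""))
  expect_error(inclusion_filter(data.frame(enc_t_d = 1)),
               "unpaired trial records")
})

test_that("traveled_distance sums body displacement", {
  tr <- data.frame(body_x = c(0, 3, 3), body_y = c(0, 4, 10))
  expect_equal(traveled_distance(tr), 11)
  expect_error(traveled_distance(tr[1, ]), "need at least 2 samples")
})

test_that("index_vs_chance matches frozen exact enumerations", {
  # no ties: V and exact p match the closed-form enumeration
  v <- c(0.8, -0.4, 1.6, 2.3, -0.2, 0.9, 1.2, -1.7, 0.3, 2.8)
  r <- index_vs_chance(v)
  expect_equal(r$statistic, 43)
  expect_equal(r$p_value, 0.130859375, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # tied magnitudes, exact by convolution over doubled average ranks
  r2 <- index_vs_chance(c(1.5, 1.5, -1.5, 2.0, 3.0, -0.5))
  expect_equal(r2$statistic, 17)
  expect_equal(r2$p_value, 0.25, tolerance = 1e-12)
  # all positive, n = 6: smallest attainable two-sided p
  r3 <- index_vs_chance(rep(c(0.2, 0.4, 0.5), 2))
  expect_equal(r3$p_value, 0.03125, tolerance = 1e-12)
  # zeros are dropped before ranking
  r4 <- index_vs_chance(c(v, 0, 0))
  expect_equal(r4$n, 10)
  expect_equal(r4$p_value, r$p_value)
  expect_error(index_vs_chance(c(1, 2, 3, 4)), "need at least 5 indices")
  expect_error(index_vs_chance(numeric(10)), "all indices are zero")
})

test_that("large-n normal approximation tracks wilcox.test", {
  set.seed(71)
  x <- rnorm(40, mean = 0.3)
  r <- index_vs_chance(x)
  expect_equal(r$method, "normal approximation")
  w <- suppressWarnings(stats::wilcox.test(x, mu = 0, correct = TRUE,
                                           exact = FALSE))
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-6)
})

test_that("simulated behavior feeds the bout scorer end to end", {
  sim <- simulate_behavior(n_trials = 3, preference_p = 1, seed = 5)
  for (tr in 1:3) {
    eb <- exploration_bouts(sim$tracks[[tr]], sim$objects)
    expect_equal(memory_index(eb$t_displaced, eb$t_nondisplaced), 1)
    expect_gt(eb$t_displaced, 0)
    expect_equal(eb$t_nondisplaced, 0)
  }
  expect_error(simulate_behavior(2, 1.5), "invalid preference_p")
})
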