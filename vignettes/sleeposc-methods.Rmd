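---
title: "sleeposc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sleeposc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the analysis choices behind `sleeposc`: how each
stage of the pipeline works, why the rules are what they are, and what
the synthetic generator is designed to exercise. Code chunks are not
evaluated when building; the README shows a fully executed example.

## Background

During non-REM (NREM) sleep, three oscillatory events dominate the
rodent cortico-hippocampal dialogue: cortical slow oscillations (SO,
0.5–4 Hz alternations of down- and up-states), thalamocortical sleep
spindles (9–17 Hz waxing-and-waning bursts), and hippocampal sharp-wave
ripples (SWR, 150–250 Hz transients riding on sharp waves). Their
temporal nesting — spindles and ripples clustering around the SO
up-state — is widely viewed as the substrate of sleep-dependent memory
consolidation, and its developmental emergence can be tracked alongside
object-place recognition (OPR) memory. `sleeposc` implements the full
chain from raw LFP to that correlation.

## Sleep staging

`band_features()` computes delta (0.5–4 Hz) and theta (4–8 Hz) band
power from Welch periodograms in non-overlapping 5 s windows, paired
with an immobility mask from tracking. `kmeans_stage()` clusters the log
band powers (k = 2 on delta, with theta as a tie-breaker check) and
labels the high-delta cluster of immobile windows NREM. Two rules guard
against fragmentary staging:

* mobile windows are never NREM, regardless of band power;
* only *runs* of at least five consecutive NREM windows (25 s) are
  retained as epochs. A 4-window (20 s) run is always dropped — brief
  delta bouts during drowsiness are not scoreable sleep, and every
  downstream statistic (event densities, coupling nulls) is normalized
  by retained NREM time.

## Event detection

All detectors operate on z-scored signals and only within retained NREM
epochs; candidate events that straddle an epoch boundary are discarded
rather than truncated. Thresholds are adaptive — expressed in SDs of the
band-limited signal or envelope — so they transfer across recordings of
different absolute gain. The defaults live in `detection_config()` and
every rule below can be adjusted there; the defaults are the package's
reference operating point.

### Slow oscillations

The 0.5–4 Hz filtered cortical trace is segmented at negative-to-
positive zero crossings. A candidate cycle must satisfy, in order:

1. **cycle duration** between consecutive crossings within 0.2–1.0 s
   (1–5 Hz instantaneous rate; longer cycles are drifts, shorter ones
   band-edge leakage);
2. **trough amplitude** below −1.5 SD but not below −3 SD of the
   filtered trace (the ceiling rejects artifacts);
3. **peak-to-peak amplitude** within the cycle below the configured
   ceiling.

The event anchor is the trough (down-state) time. Because the candidate
is defined *between* crossings, trough depth and peak-to-peak amplitude
are nearly the same quantity for symmetric cycles; the rules only
dissociate for asymmetric waveforms, which is exactly where artifact
rejection matters.

### Spindles

The 9–17 Hz envelope (Hilbert magnitude, Gaussian-smoothed) must exceed
2.5 SD; the event spans the surrounding 1.5 SD crossing. Then:

* events closer than 300 ms are **merged** — a waxing-waning spindle
  whose envelope briefly dips must not be double-counted;
* merged events shorter than **500 ms are rejected** — brief sigma-band
  transients are not spindles.

Merging precedes the duration rule, so two sub-500 ms bursts 250 ms
apart form one valid spindle. The anchor is the envelope peak.

### Sharp-wave ripples

The 150–250 Hz envelope must exceed 3 SD, with the event spanning the
1.5 SD crossing, and:

* duration must lie within **30–100 ms**;
* the envelope peak must reach **5 SD** — a high bar that rejects
  muscle/EMG leakage, which is broadband and rarely reaches ripple-band
  peaks that extreme.

The anchor is the ripple trough (largest negative deflection).

## Temporal coupling

`crosscorrelogram()` histograms target-minus-reference anchor lags in a
±500 ms window (10 ms bins). All canonical pairs use each event's single
anchor timestamp — SO trough, spindle envelope peak, SWR trough — so a
coupled pair's lag reflects the offset of the events' cores and does not
depend on event durations or on where an event's onset happens to fall.

`montecarlo_coupling()` tests the count of coupled targets (targets
within the window of at least one reference, counted once each) against
a permutation null: per permutation, the target train is circularly
shifted within each retained NREM epoch by an independent uniform
offset. This preserves each epoch's event count and within-epoch
inter-event structure while destroying the alignment to the reference
train — epochs act as exchangeability blocks, so differences in event
density across the night cannot masquerade as coupling. Significance is
declared when the observed count exceeds the null mean + 2 SD. With
independent Poisson trains this rule is slightly conservative of a
nominal one-sided 2.3% (the null count distribution is mildly skewed);
the calibration tests bound the false-positive rate at 7%.

## SO phase coupling

`event_phase()` takes the instantaneous Hilbert phase of the 0.5–4 Hz
trace at each anchor, rotated so 0° is the rising zero crossing, 90° the
up-state peak and 270° the down-state trough. `circular_stats()` gives
the circular mean direction, resultant length, and the Rayleigh test of
non-uniformity (standard finite-n approximation). `rvonmises()` (Best–
Fisher sampler) is used by the generator to place coupled events at a
preferred phase.

## Event-triggered spectrograms and cluster statistics

`so_triggered_tfr()` computes a multitaper (DPSS, NW = 2, K = 3)
spectrogram in 250 ms windows stepped by 50 ms over ±1 s around each
anchor, expressed in dB relative to each event's own −4.5 to −2 s
baseline and averaged over events.

`cluster_perm_test()` deliberately does **not** test the dB map.
Per-pixel log-ratios of few-taper power estimates have a negative bias
(the Jensen inequality applied to the log of a scaled chi-square), so
"mean dB = 0" is not the correct null even for white noise. Instead the
test forms per-event *raw-power differences* (event window minus
baseline mean at each frequency), which are exactly mean-zero and
sign-symmetric under the null, thresholds per-pixel t statistics,
clusters supra-threshold pixels by 4-connectivity, and compares each
cluster's summed |t| mass against a sign-flipping permutation null of
the maximum cluster mass. This controls the family-wise error over the
whole time-frequency map while remaining sensitive to extended
oscillatory responses.

## Behavior

`exploration_bouts()` scores tracking against object positions: samples
count as exploration when the animal is within the interaction radius
*and* heading toward the object — proximity alone (e.g. sitting beside
an object facing away) is not exploration. `inclusion_filter()` applies
the standard OPR inclusion criteria (minimum total exploration, both
objects sampled, minimum distance traveled) and reports the failing
reason. The memory index is

\[ \mathrm{MI} = \frac{t_\mathrm{displaced} - t_\mathrm{non}}{t_\mathrm{displaced} + t_\mathrm{non}} \in [-1, 1], \]

with `binned_index()` giving the cumulative index over time bins (the
final bin equals the whole-trial index) and `index_vs_chance()` a
Wilcoxon signed-rank test against zero (exact for n ≤ 25 without ties,
normal approximation with continuity correction otherwise).

## The synthetic generator

`simulate_lfp()` is designed so the full pipeline, run on its output,
recovers the configured truth: state labels, event times, and coupling.
Design choices worth noting:

* **1/f background** noise, scaled per state, so adaptive SD thresholds
  face realistic spectra; delta power is raised in NREM blocks and theta
  in mobile blocks, putting k-means staging under genuine contrast.
* **Amplitudes are specified in SDs of the measured band-limited
  noise**, which is what the detectors threshold on — so "SNR 3" in the
  configuration is SNR 3 to the detector.
* Event templates are band-limited before insertion (SOs are filtered
  through the detection band) so ground-truth anchors are measured on
  the same waveform the detector sees; anchor truth is the template
  trough/peak, not the nominal insertion time.
* Events keep ≥1 s clearance from epoch boundaries and a minimum gap
  between like events, so recall/precision scores measure detector
  fidelity rather than collision bookkeeping.
* Coupled spindles/SWRs are placed at a von Mises phase of a host SO
  (`p_couple`, `mu`, `kappa` per pair); uncoupled events carry `NA`
  phase in the truth table, so phase-recovery tests can condition on the
  truth.

`simulate_behavior()` draws exploration bouts as a marked renewal
process with object preference `p`, writes the actual track (positions
and headings), and returns the per-trial ground-truth exploration
times — the expected memory index is `2p − 1`.

## Limitations

* Detectors assume clean, already-referenced LFP; no artifact rejection
  beyond the amplitude ceilings is included.
* The staging model is two-state (NREM vs everything else); REM is not
  separated.
* The Rayleigh test assumes independent phase samples; strongly
  autocorrelated event trains can inflate significance.
* The cluster test's per-pixel threshold (`cluster_alpha`) trades
  sensitivity between focal and diffuse effects; the default is tuned
  for burst-like responses.
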