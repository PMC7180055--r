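---
title: "Methods: event-series analysis of interval-timed licking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-series analysis of interval-timed licking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(licktime)
```

## The problem

Head-fixed mice on a fixed-time schedule receive a drop of reward every
10 s regardless of behavior. They learn the interval: licking ramps up in
anticipation of each reward and, on unrewarded *peak probe trials*, a
discrete bout of licking appears centered near the trained 10-s mark.
Licking itself is rhythmic — bouts of tongue protrusions at a relatively
fixed 4–8 Hz, generated by a brainstem central pattern generator (CPG) and
capped near 10 Hz. Optogenetic stimulation of the striatal direct (D1) or
indirect (A2A) pathway perturbs both the vigor of licking (evoked licking,
suppression, post-inhibitory rebound) and its timing (clock reset, clock
pause).

`licktime` implements the full analysis chain for such experiments —
event filtering, trial-aligned rate estimation, spectral band analysis,
single-trial peak detection, stimulation-effect metrics and rebound
classification — together with a synthetic session generator and a
leaky-integrator/CPG simulator so that every stage can be exercised and
validated without animal data.

## Event model and filtering

Lick timestamps are float seconds from session start; trial-relative times
are computed on demand from a single time base. Raw lickometer streams are
debounced with an 8-ms rule: a lick is kept iff it follows the previously
*retained* lick by at least 0.008 s (greedy forward scan). Applying the
rule against the retained rather than the raw predecessor matches the
debouncing intent and makes the filter idempotent; this reading is a
package decision, since either reading is defensible.

Unless an analysis states otherwise, only the first half of trials is used
(ceiling of N/2 for odd N), excluding late-session motivational drift.
The quartile analysis, which *measures* that drift, and the peak-shift
analysis, which needs all probe trials for statistical power, use the full
session.

Bout onsets are licks preceded by an inter-lick interval of at least 1 s;
the session's first lick counts as an onset, since no preceding interval
exists. All stimulation-window metrics (evoked-onset latency during the
1-s train, rebound onset in the closed window [0, 3] s after offset, lick
counts in the 1 s after offset) use raw counts over the window, not the
smoothed trace, and always carry a baseline computed over the identical
trial-relative window on matched no-laser trials. Window endpoints are
closed and the rebound-classification second-onset window is half-open
(onset, onset + 8]; boundary choices are deterministic conventions, not
claims about the original analysis.

## Rate traces and smoothing

Rates are estimated in 100-ms bins (counts divided by the bin width) and
smoothed with a Gaussian kernel. The nominal smoothing "width" of 1 s is
honored as kernel sd = 0.25 s, so the ±2 sd core spans 1 s; support is
truncated at ±2 s and the kernel renormalized, hence smoothing conserves
total count up to edge truncation. A wider reading of "width" (sd = 1 s)
would blur single-trial peaks into invisibility, defeating the
single-trial procedure; the choice is exposed as `smoothing_sd`.

## Spectral analysis

Each 1-s analysis epoch is binarized on a 2-ms grid (500 Hz), smoothed
with a light Gaussian kernel (sd 10 ms), mean-subtracted, Hann-tapered,
and its periodogram averaged across epochs, giving a 1-Hz frequency
resolution. The pre-smoothing matters: an ideal rhythmic train is a comb
whose harmonics carry as much power as the fundamental, so some low-pass
is required for the licking fundamental to carry the spectral peak; 10 ms
is of the order of natural inter-lick jitter and attenuates the first
harmonic of a 5-Hz train by ~30% in power while leaving the fundamental
nearly untouched. Every element of this dialect (sampling rate, epoch
length, smoothing, taper) is a function argument, because the original
spectral tooling's parameters are not published.

Band occupancy totals power over 0.5–20 Hz and reports the percentage in
the licking bands 4–6, 6–8 and 8–10 Hz, half-open on the right except the
last (i.e. 4–5.99, 6–7.99, 8–10). Peak frequency is the argmax over
2–12 Hz — excluding DC and stimulation-train artifacts — with ties
resolved to the lower frequency.

## Single-trial peak detection

For each probe trial, licks are aligned to the initiating reward and a
20-s window is analyzed:

1. bin (100 ms) and smooth (sd 0.25 s) the lick rate;
2. segment the smoothed trace by penalized change-in-mean: L2 segment
   cost, linear penalty per changepoint (default `2 log(n) var(signal)`),
   at most 8 changepoints, solved exactly by dynamic programming;
3. classify each changepoint rising/falling by the mean of the 5 bins
   after it minus the 5 bins before (clipped at edges) — a ±0.5-s
   neighborhood, matching the 1-s smoothing scale;
4. the first rising changepoint and the next falling changepoint delimit
   the candidate peak; a Gaussian `a exp(-(t-mu)^2/(2 sigma^2))` is fit to
   the smoothed rate between them by bounded least squares (initialized at
   the segment maximum, sigma = length/4; mu bounded inside the segment,
   sigma in [0.1, 10] s) and its mean taken as the peak time;
5. validity requires duration ≥ 2 s and maximum smoothed rate > 3 Hz
   (the rate criterion is applied to the peak's maximum — the most
   plausible reading of a threshold on "licking rate" for a bout whose
   mean includes its flanks);
6. on failure (no rising changepoint, no following falling changepoint,
   validity, or fit non-convergence) the window shifts +500 ms and the
   procedure retries, up to 5 shifts; then the trial is discarded. A
   candidate whose falling changepoint is missing is a failure even if the
   rate visibly returns to baseline — no improvisation of peak ends.

For probe trials with direct-pathway stimulation at +3/+5 s the window
start moves right by 3/5 s so evoked licking is not scored as the peak;
for rebound-recovery trials it moves to 6 s.

The changepoint penalty used by the original analysis tool is not
published; the default here is chosen to find coarse transitions in
smoothed traces and is validated against an exhaustive minimum-cost
segmentation oracle on planted-shift signals (≥95% agreement within ±1
bin), not against the original tool bit-for-bit.

Session statistics: width = end − start per valid peak; skewness = sample
third standardized moment of the pooled trial-relative lick times inside
each trial's detected peak; peak shift = mean laser-trial peak time minus
mean no-laser peak time within the same session.

## The synthetic session generator

The generator *defines* the study conditions for all tests; its defaults
are fixed to the task as published and are not tuned to analysis
outcomes.

* **Scheduler** — 10-s fixed-time trials; after three consecutive plain
  fixed trials a decision point draws laser-normal / laser-peak /
  plain-peak at 0.3/0.3/0.3 with 0.1 probability of redrawing (so each
  outcome is conditionally 1/3 — the geometric series 0.3·Σ0.1^k). Probe
  spans are 30 s plus a Gamma(shape 2.5, scale 4) excess, mean 10 s. The
  consecutive-reward counter resets after every decision-outcome trial.
* **Licking** — a bout-level renewal process, not a homogeneous Poisson
  process, because the downstream analyses (bout onsets, spectral peaks)
  require rhythmic structure. Within-bout intervals are a jittered
  metronome, `1/frequency + N(0, 0.01 s)`, truncated at 0.05 s;
  anticipatory bouts (5.5 Hz) start `|N(3, 1)|` s before each reward;
  consummatory bouts (7 Hz, 2 s) follow each reward; probe trials get a
  peak bout (halfwidth 2 s) centered `N(10, 1)` s after the initiating
  reward; sparse baseline licking at 0.2 Hz fills the interval. The 4–8 Hz
  bout rates and the 10-s center are the task's trained values; onset and
  jitter scales are chosen as realistic for head-fixed mice.
* **Stimulation effects** — `d1_evoke` replaces licking during the train
  with an evoked bout whose frequency follows a stimulation-frequency map
  capped at 10 Hz (evoked-bout intervals are truncated at 0.1 s so the cap
  binds strictly) and persists 0.5 s past offset; `a2a_suppress` deletes
  licking during the train and emits a rebound bout after a
  frequency-dependent latency. `timing_mode` implements the clock
  hypotheses: `reset` re-centers the probe-trial peak bout at stimulation
  onset + the trained interval; `pause` delays it by the train duration
  (plus rebound duration with `pause_plus_rebound`).
* **Satiety** — a linear per-trial multiplier inflates evoked/rebound
  latencies and deflates rebound probability; this is the minimal
  mechanism producing the quartile trends the motivation analysis is
  designed to detect.
* **Seeds** — one master seed derives per-trial substreams, so any single
  trial is reproducible in isolation.

What the generator does *not* emulate: lick-by-lick motor variability
beyond Gaussian jitter, video-scale kinematics, inter-animal variability,
or any neural signal. Passing tests therefore demonstrate that the
analysis chain recovers known structure from realistic event statistics —
not that it would be unbiased on any particular animal's data.

## The integrator–CPG simulator

The conceptual circuit model is a leaky integrator gating a discrete-mode
pattern generator. The published account of this model is qualitative; the
equations here are the package's own minimal formalization, with every
constant exposed:

* level: `dI/dt = -leak · I`, plus `fill_gain` per D1 pulse and minus
  `discharge_gain` per A2A pulse, clipped at 0 (leak 1/s, gains 0.2);
* modes: thresholds (0.3, 0.35, 2.5) map the level to off/low/mid/high,
  emitting licks at (5, 7, 9.5) Hz with a hard 0.1-s refractory floor
  (the 10-Hz cap). A fresh bout licks immediately; a mode switch within a
  bout keeps phase and adopts the new period — re-phasing with an
  immediate lick at every transition would double-count licks when the
  level hovers near a threshold;
* rebound: A2A pulses charge a hyperpolarization variable
  (`rebound_gain` 0.15 per pulse, decay 2/s); at drive offset a burst
  `rebound_boost · H` is injected into the level after latency
  `1/(1 + H)` s, so stronger or faster indirect-pathway drive yields
  earlier rebounds.

Numerics: between pulses the decay uses the exact exponential factor
`exp(-rate·dt)` per step rather than a forward-Euler increment, so the
free decay phase agrees with the closed-form solution to machine
precision (forward Euler at any practical step size would carry an
O(dt) relative bias); pulses act as impulses. The default step is 1 ms
and steps above 10 ms are rejected.

The mode thresholds and frequencies are free parameters of a hypothesis,
not measured quantities; the first two thresholds sit close together so
that pulsed direct-pathway drive predominantly recruits the mid (7 Hz)
mode, consistent with evoked licking running above the natural 4–6 Hz
band, and no quantitative claim is attached to them beyond the cap and
the monotonicity of latency/persistence in stimulation frequency. With
the defaults, a 1-s 50-Hz train drives the level through all three
thresholds within ~0.3 s and the output saturates near the cap; 5-Hz
stimulation produces ~7-Hz licking, not 5-Hz — pulse-to-lick mapping is
not one-to-one.

## Problem sizes and tolerances

The validation suite runs at sizes chosen to make Monte-Carlo error small
against each tolerance: 200 probe trials for peak-time recovery
(tolerance 0.3 s against the 10-s target), 100 trials for clock-reset
recovery, 500 planted-shift signals for the segmentation oracle (≥95%
agreement), 300 constructed trials for rebound classification (exact
match), 100,000 decision points for the scheduler statistics (±0.01 on
outcome frequencies, ±0.1 s on the 10-s mean probe excess), and 10,000
randomized protocols for the CPG cap invariant. Latency-recovery checks
use n = 200 and a 2-SEM band. `scripts/acceptance.R` re-runs the three
headline quantities from scratch at these sizes.

## Known limitations

* The changepoint penalty, the spectral dialect and the Gaussian-smoothing
  width are package choices where the original tooling is unpublished;
  all are configurable, and conclusions that depend on them should be
  checked for robustness.
* Peak detection assumes a single peak bout per probe trial; multi-peak
  trials are scored by their first detected peak.
* The integrator–CPG model is a simulator of a hypothesis, with free
  parameters; it is not fit to data.
* Group-level inference (ANOVA, post-hoc corrections) is deliberately out
  of scope: the package emits tidy per-trial tables for standard
  statistical routines.
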