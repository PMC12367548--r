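---
title: "Event-aligned analysis of basal ganglia output during reaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-aligned analysis of basal ganglia output during reaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`snrreach` implements the statistical chain used to ask whether tonically
active basal ganglia output neurons (substantia nigra pars reticulata, SNr)
encode skilled forelimb movements bidirectionally — with firing *pauses*
(putative disinhibition of downstream targets) as well as firing increases.
This vignette explains each model and procedure, the parameters that matter,
what the synthetic-session generator does and does not emulate, and the
numerical choices made where the design was open.

## The analysis problem

A session consists of (i) a bottom-view hand trajectory tracked by markerless
pose estimation at 100 frames/s, (ii) sorted spike times for a population of
simultaneously recorded neurons, and (iii) (for perturbation experiments) a
cued lever-task trial table. The pipeline segments reaching behaviour into
events (reach start, slit crossing, retraction start/stop, and manually
annotated handling events), tiles each trial with nine task windows, and asks
for every neuron and window whether firing is modulated relative to a
permutation null; downstream stages compare trial types, screen for
monosynaptic inhibition, estimate pre-movement modulation onsets, and
quantify optogenetic perturbation effects.

## Kinematic event detection

Tracking is cleaned either with a running median (size 5, the default) or a
zero-phase low-pass Butterworth filter (order 4, cutoff 15 Hz). Reaches are
found as prominence-thresholded peaks (default 5 px, configurable) of the
hand's displacement past the slit along the *main reach direction*. That
direction is not observable a priori: we first take the principal axis of
the hand trajectory, orient it toward the largest excursion from the resting
(median) position, then refine it once as the unit vector from mean position
at reach starts to mean position at retraction starts.

Within each detected reach:

* **retraction start** is the moment of maximum extension. Because a median
  filter clips single-frame extrema, we locate it as the outward-to-inward
  sign change of the velocity nearest the displacement peak, with sub-frame
  linear interpolation.
* **reach start** is found by rolling back (at most 0.5 s) to where velocity
  along the main direction falls below +1 px/s; **retraction stop** by
  rolling forward to where it rises above −1 px/s. The rollback anchors at
  the fastest frame of the movement rather than at the apex itself, whose
  velocity is already ~0. Crossing times are linearly interpolated between
  the bracketing frames; when the rollback window is exhausted the bound is
  used and the event flagged.
* velocity is the central difference of filtered position over ±2 frames,
  which spans the short flat plateaus median filtering leaves at zero
  crossings.

The ±1 px/s threshold is tiny compared with frame-to-frame tracking noise
(at 0.5 px noise, instantaneous velocity noise is tens of px/s), so accurate
event recovery relies on the velocity *slope* being steep where it crosses
the threshold; the interpolation then localizes the crossing far below the
frame period.

Trial stratification: isolated reaches are ≥ 0.75 s from both neighbours;
repeated pairs have retraction starts 0.3–0.6 s apart; duration strata are
the 1st–25th (short) and 73rd–97th (long) percentile bands of per-session
reach durations (linear interpolation, inclusive membership); abbreviated
reaches extend at most 0.45 cm past the slit on the major axis and 0.25 cm
on the minor axis (pixel scale 0.02 cm/px by default, configurable).
Handling events come from manual annotation tables; no automatic handling
detector is attempted.

## Task-window modulation

For each neuron and each of the nine windows, the observed statistic is the
mean over trials of (in-window spike count / window duration). The null is
built from 1,000 groups of N random windows placed uniformly over the whole
session, the k-th window of each group copying the k-th trial's duration —
required because several windows (reach, retraction, manipulation) have
trial-varying durations. Task periods are *not* excluded from the sampling
domain; this is conservative in the sense that strong task modulation
inflates the null, and it means a strongly positively modulated neuron can
show mild apparent negative modulation in its unmodulated windows.

The modulation index is

$$\mathrm{MI} = \frac{r_\mathrm{win} - \mathrm{median}(null)}{r_\mathrm{win} + \mathrm{median}(null)} \in [-1, 1],$$

robust to baseline-rate differences. Significance requires |MI| > 0.025
*and* a mid-rank percentile of the observed rate within the null at or below
the 1st (negative) or at or above the 99th percentile (positive). Ranks use
deterministic mid-ranks (ties get their average rank); the expected type-I
rate is therefore at most 2% per (neuron, window) before the |MI| clause,
which can only reduce it. A neuron is *bidirectional* when it has at least
one significant negative and one significant positive window.

The per-trial lever-press classifier compares, per neuron, trial modulation
values (rate in the 200 ms window centred on the press minus rate in the
200 ms pre-cue baseline) against values from ≥ 200 random session
timepoints, via a two-sided Mann–Whitney U test at p < 0.05 with the
direction given by the mean trial value. For random timepoints, the baseline
window is placed at the median cue-to-press offset before the timepoint,
mirroring the trial construction.

## Trial-type divergence test

Given N trials of type 1 and M ≥ N of type 2, each of 1,000 random groups
draws N trials split as evenly as possible between the types (a seeded coin
decides the extra trial when N is odd; sampling is without replacement
unless a type is smaller than its quota, which is flagged). Rates are 5 ms
bins, Gaussian-smoothed (σ = 10 bins, 100 ms truncated support), z-scored
per neuron with the mean and population s.d. of the concatenated per-type
averages, and averaged over the population. The null band is the per-bin
0.05th/99.95th percentile over groups (a 99.9% interval). A divergence
requires one type's curve below the lower band *and* the other's above the
upper band simultaneously — stricter than a difference statistic — and is
reported as maximal runs of flagged bins spanning at least 50 ms.

## Correlation structure and noise correlations

Event-aligned correlation matrices are pairwise Pearson correlations of
trial-averaged smoothed rates in ±2 s windows around a timestamp set
(first-retraction starts, repeated-reach retractions, or random timestamps
as a structure-abolishing control). Structure preservation between two
conditions is summarized by ordinary least squares of one condition's
off-diagonal upper-triangle correlations on the other's (pairwise-complete).
Noise correlations for putatively connected pairs use across-trial Pearson
correlations of single-trial rates in 20 ms bins over a 400 ms
event-centred window, reported per bin and at the postsynaptic peak-rate
bin.

## Monosynaptic-inhibition screening

Cross-correlograms use 0.5 ms lag bins over ±50 ms, positive lags meaning
post follows pre. The slow-comodulation predictor convolves the observed
correlogram with a partially hollowed Gaussian (s.d. 10 ms, central bin
weight reduced by the hollow fraction 0.6, kernel renormalized; reflect
padding at the edges). Deficit p-values are continuity-corrected lower
Poisson tails, `P(X < k) + 0.5 P(X = k)` under Poisson(predictor). The
z-score standardizes counts against the mean and s.d. of flank bins (|lag|
20–50 ms) rather than √predictor — robust to slow comodulation and the
source of the large |z| magnitudes the −10 threshold implies. A pair is
accepted when the minimum deficit p in the 1–2.5 ms band is below 0.02, the
most negative z over positive lags lies within 2.5 ms, and that trough z is
below −10. Duplicate timestamps fall in the lag-0 bin and cannot enter the
test band.

## Pre-movement onset detection

For every 20 ms window sliding by 1 ms over the 0.5 s before reach start,
the across-trial mean rate is ranked against 1,000 groups of duration-
matched windows drawn uniformly from the per-trial baseline epoch (−0.70 to
−0.50 s). The p-value is the smaller one-sided rank, floor 1/1001, so
"p < 0.001" means the observation lies beyond every resample. The onset is
the start of the earliest window in the contiguous p < 0.05 run containing
the earliest p < 0.001 anchor; rollback never crosses a p ≥ 0.05 window
(alternative readings of the rollback sentence are selectable by the
`roll_p`/`anchor_p` arguments).

Two systematic properties are worth knowing. First, a window must overlap a
rate step by a few milliseconds before it can rank significant, so onsets
carry a small early-side bias bounded by one window length; the bias shrinks
with baseline rate (higher tonic rates mean better-resolved 20 ms counts),
one reason the analysis is well-suited to high-rate SNr units. Second,
taking the *earliest* anchor over ~480 overlapping windows is a scan
statistic: a minority of unmodulated-epoch windows can reach the rank floor
by chance, so population summaries should use medians, as the recovery
checks here do.

## Optogenetic perturbation analysis

Cue-aligned average rates (20 ms bins) are computed per neuron for laser and
control trials, both z-scored with the control mean and s.d.; the
control-subtracted traces are averaged over neurons (then over mice). The
*effective activation duration* is the total time after cue offset at which
the population trace exceeds one control s.d. (computed from the post-cue
control trace); supra-threshold time is summed across runs, not just the
first contiguous one. Press-latency effects are quantified on responded
trials only: per-condition cumulative latency distributions, a two-sample
KS test, the laser/control response-rate ratio, and control-subtracted
press rates in 200 ms bins; no-response trials are reported separately.
The across-mice relation between effective duration and median latency
increase is an ordinary least-squares fit with a one-sided Wald test for a
positive slope.

The one-control-s.d. criterion only behaves when the control trace has real
structure: on a featureless control, its s.d. is pure estimation noise and
the criterion's signal-to-noise does not improve with population size. The
synthetic opto sessions therefore give every neuron a cue-evoked response
(gain 1.3–2 for 150 ms from cue onset, per-neuron), as task-engaged SNr
units show; with that structure in place, programmed activations are
recovered to one bin.

## The synthetic-session generator

Every stage is tested against sessions with known ground truth. The
generator emulates: tonic 5–100 Hz firing (uniform per-unit baselines);
event-locked multiplicative gains over any of the nine task windows (gain
< 1 a pause, > 1 an increase, 0 complete silence; overlapping windows
multiply); reach/retract durations log-normal around 0.28/0.20 s truncated
to [0.15, 0.45] s; handling lasting 1–3 s; repeated reaches 0.3–0.6 s
apart; isolation gaps of 0.75 s plus an exponential (mean 1 s); a cued
lever task with uniform 2–5 s intertrial intervals, a 100 ms cue, a 1.5 s
response window, laser on a configurable fraction of trials, and
gamma-distributed press latencies; and inhibitory pre→post coupling at 1–2.5
ms latency implemented by multiplying the postsynaptic rate by (1 −
strength) in the delay window after each presynaptic spike.

Spike trains are realized exactly: Poisson trains by Lewis–Shedler thinning
of a dominating homogeneous process, and the optional gamma-ISI trains
(shape 4, mimicking tonic regularity) by time rescaling through the inverse
integrated rate, since thinning is not exact for renewal processes. Empirical
windowed rates converge to baseline × gain, and session mean rates match the
analytic expectation.

Hand trajectories are rendered from a piecewise velocity model per reach:
a raised-cosine (Hann) velocity bell carries the bulk of the displacement,
flanked by short constant-velocity shoulders (150 px/s) and steep linear
ramps through zero at reach start, maximum extension and retraction stop,
with a brief backswing before and rebound after the movement. The speed
profile within each phase is bell-shaped, as real reach kinematics are, and
the grasp turnaround at maximum extension is sharp. A pure minimum-jerk
profile was rejected deliberately: its endpoints have zero velocity *and*
zero acceleration, which makes the maximum-extension frame cubically flat
and parks the ±1 px/s crossings inside noise-dominated regions — under
realistic tracking noise those events are then not identifiable to one
frame, which real reaches (with their abrupt grasp) do not suffer from. The
local antisymmetry of the velocity around each event also means zero-phase
filtering leaves the crossing times unchanged. Tracking noise is white
Gaussian (σ = 0.5 px default) on the hand coordinates; the likelihood
column is fixed at 1.

What the generator does **not** emulate: pose-estimation failure modes
(identity swaps, occlusions, likelihood dips), slow drift of posture or
electrode position, correlated population dynamics beyond what shared task
windows induce, bursting or pause-rebound dynamics within trains, and
history effects in behaviour (fatigue, satiation). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every pathology of real recordings.

## Numerical choices and conventions

* Times are double-precision seconds; all intervals are half-open
  `[start, stop)`; event-relative times are negative before the event.
* The Gaussian rate filter interprets "sigma 10" as 10 bins (50 ms at 5 ms
  bins) with total support 100 ms — truncation at ±1σ, renormalized; sigma
  in seconds is selectable. Kernel mass falling off the window edges is
  folded back, so smoothing conserves the per-trial mean rate exactly.
* z-scores use the population (divide-by-n) s.d. throughout; zero-variance
  neurons are flagged and excluded (set to z = 0) rather than propagating
  NaN.
* One top-level seed spawns named sub-seeds (`derive_seed`) per stage,
  neuron and test, so any stage can be rerun in isolation; full pipeline
  reruns are byte-identical.
* Percentiles use linear interpolation (R's type 7) everywhere.
* Trials clipped by the session edge are dropped with a warning rather than
  padded, avoiding boundary bias in the permutation nulls.

## Problem sizes used in the checks

The bundled checks run on sizes chosen to give stable statistics at
interactive runtimes: calibration on 200 neurons × 9 windows with
1,000-group nulls; gain recovery on 40 neurons per gain at 100 trials;
divergence specificity on 100 label-shuffled replicates and sensitivity on
50 injected-pause replicates (10 neurons, 20 trials/type); event detection
on 100 noisy reaches; connectivity on 20 coupled and 20 independent 30 min
pairs; onset recovery on 200 neurons at 100 trials; opto recovery at 30
neurons × 300 trials. The reproduction script (`scripts/acceptance.R`) uses
reduced replicate counts for a faster end-to-end run; its quantities are
the same.

## Known limitations

* The modulation null includes task periods, so strongly modulated neurons
  can pick up small opposite-sign artifacts in other windows (see above);
  this mirrors the method as described and is documented rather than
  "fixed".
* Onset estimates inherit the scan-statistic multiplicity of the
  earliest-anchor rule; use medians across units.
* The divergence test's simultaneous two-sided band rule is stricter than a
  difference test and will miss effects that move both conditions in the
  same direction.
* The event detector assumes a single dominant reach direction per session;
  sessions with several movement axes would need per-cluster directions.
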