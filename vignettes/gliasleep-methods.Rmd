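---
title: "Methods: sleep scoring, calcium events, sensor contrasts and bouton distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, calcium events, sensor contrasts and bouton distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliasleep)
```

gliasleep implements the signal-analysis stack used to study how microglia
Gi/Ca^2+^ signaling interacts with brain states and norepinephrine (NE)
transmission: EEG/EMG sleep scoring, calcium-transient detection in
two-photon ROI traces, state- and transition-aligned trace summaries,
GRAB-sensor pharmacology contrasts, and 3D bouton-to-microglia distances.
Every stage can be driven by a seeded synthetic-data generator with
embedded ground truth, so the whole pipeline is testable without any
recorded data. This vignette documents the models, the tunable parameters,
and the design decisions taken where the underlying procedures were open.

## Sleep scoring

EEG and EMG are digitized at 1,500 Hz and cut into non-overlapping 5-s
epochs (a trailing partial epoch is dropped; epochs are half-open
`[start, start + 5 s)`, 0-based). Each epoch gets a one-sided periodogram
(`epoch_spectrogram()`, 0.2-Hz resolution at the default geometry,
Parseval-exact), from which `extract_features()` integrates, by the
trapezoid rule with interpolated band edges:

- delta power over 0.5–4 Hz,
- theta power over 6–9 Hz,
- total power over 0–25 Hz (used to normalize state spectra),
- the theta/delta ratio, and
- EMG RMS after an ideal 10–300 Hz band-pass applied per epoch in the
  spectral domain (by Parseval, the RMS of the band-passed signal is the
  square root of its band power; rectification does not change RMS).

`classify_epochs()` applies a fully automatic two-gate rule per epoch:

1. EMG RMS above the wake threshold → **W** (wake);
2. otherwise theta/delta ratio above `ratio_threshold` (default 1.5) →
   **R** (REM);
3. otherwise **N** (NREM).

The wake threshold defaults to the midpoint (in log space) of a
deterministic 2-class k-means of log EMG RMS, so it adapts to the
recording's gain without manual input. Wake is gated on EMG alone — EMG is
the operative discriminator of wakefulness and using it avoids a third,
hard-to-specify "desynchronization" threshold. An optional smoothing pass
relabels isolated single epochs flanked by identical states, and a manual
override table (epoch → state) can replace any labels afterwards,
representing the manual step of semi-automatic scoring workflows. Epochs
with non-finite features are labeled W with a warning rather than silently
dropped.

`merge_episodes()` run-length-encodes the hypnogram into episodes that tile
the session exactly; `state_metrics()` reports per-bin time percentages
(summing to 100 by construction), mean episode durations (reported as
missing, not zero, for absent states, so per-animal averages are not
dragged toward zero) and episode rates per hour.

## The synthetic sleep generator

The hidden state sequence is a first-order Markov chain at epoch
resolution. A generative model is needed for testing, and a Markov chain is
the simplest process with approximately geometric episode durations; the
default transition matrix gives mean bouts of about 2 min (wake), 1.9 min
(NREM) and 1 min (REM), with REM entered essentially only from NREM.

The EEG is synthesized per epoch in the frequency domain: complex Gaussian
coefficients are drawn only in the configured bands (delta 0.5–4 Hz, theta
6–9 Hz, broadband 0.5–25 Hz), scaled so each band component's expected
variance equals the state's configured band power (defaults: NREM delta
10x wake delta; REM theta 6x NREM theta; equal broadband). The EMG is white
noise whose RMS is modulated by state (30 uV in wake vs 5 uV in sleep). All
randomness flows through one seeded generator per call, so identical
configurations give bit-identical sessions.

What the generator does *not* emulate: 1/f spectral background, spindles
and slow-wave morphology, movement and electrical artifacts,
micro-arousals, circadian drift, or gradual state transitions. Passing the
scoring benchmark (≥ 90% epoch agreement at 5x band-power and EMG
separation) therefore demonstrates correctness of the feature extraction
and decision rule, not expected performance on real recordings, where
separability is lower and artifacts dominate the error budget.

## Calcium traces: baseline, dF/F and transient detection

The baseline `F0` is the lower 25th percentile of the fluorescence in a
±600-s sliding window around each frame (`sliding_baseline()`), computed
with the linear-interpolation quantile definition and truncated (not
reflected) windows at the trace edges; dF/F is `(F - F0) / F0`. The window
is long relative to transients, so sparse activity leaves the quantile at
the true baseline, while slow drift is tracked and removed.

`detect_events()` flags a transient when dF/F stays above a threshold of
`n_sd` (default 3) standard deviations above the trace centre for at least
`min_frames` (default 3) consecutive frames; distinct suprathreshold runs
are distinct events, the onset is the first frame of the run, the peak the
within-run maximum, and the amplitude the peak dF/F (not peak minus
threshold). A variant applies the run criterion to the 3-frame moving
average instead (`variant = "moving_average"`).

The centre and SD are estimated robustly by default: centre = median of the
trace, SD = `1.4826 x MAD(diff(dff)) / sqrt(2)`, the standard
first-difference noise estimator used in calcium imaging. On an event-free
trace these coincide with the mean and SD, so null-rate calculations under
Gaussian noise are unchanged. The reason for the robust default is
quantitative: with transients of peak `a`, decay constant `tau` and rate
`lambda`, the transients themselves contribute `a * sqrt(lambda * tau / 2)`
to the whole-trace SD. Requiring three consecutive frames at 0.84 Hz
(2.38 s of decay) to clear a moment-based `mean + 3 SD` threshold requires
`3 * sqrt(lambda * tau / 2) < exp(-2.38 / tau)` even at zero noise, which
has no solution in `tau` at rates of order one event per minute — the
moment threshold rises to the peak level and recall collapses, regardless
of amplitude (the condition is scale-invariant). The moment estimator
remains available as `scale = "moment"` for comparison.

The synthetic benchmark (`calcium_synth_config()` defaults) emulates
infrequent, high-contrast microglia transients: 0.2 events/min per ROI,
instant rise with 8-s exponential decay, peak amplitudes of 1.0 ± 0.15
dF/F against a dF/F noise SD of 0.1 (so essentially all peaks exceed 5x
noise), on a baseline of 100 a.u. with a ±5 a.u. slow sinusoidal drift.
These are free parameters — no quantitative event-rate or SNR figures exist
for microglia Ca^2+^ transients in vivo — chosen once to be realistic for
resting microglia and held fixed. Two structural limits of Poisson event
trains are worth knowing: a second event landing inside the previous
event's suprathreshold window merges with it and cannot be recovered by any
onset-matched detector, and a stricter threshold can split one long run in
two, so event-count monotonicity in the threshold holds at trace-set level
but not necessarily per ROI.

Event statistics (`event_stats()`) assign events to analysis windows by
peak time (relevant for events straddling a treatment), report the mean
z-scored level, mean amplitude (missing when no event peaks fall in the
window) and events/min; `pre_post_change()` differences two windows,
propagating missing amplitudes.

## State and transition alignment

Frames map to epochs by `floor(time / epoch_s)`. `state_mean()` averages a
z-scored trace over the frames of one state, excluding REM by default
(calcium comparisons focus on wake vs NREM; REM epochs are confounded by
hemodynamic artifacts in the source imaging context). `find_transitions()`
requires flanking episodes of at least 30 s on both sides — long enough to
give a stable pre/post window, short enough to keep transitions plentiful —
and `align_traces()` stacks nearest-frame segments on a common offset grid
(default ±60 s; the tests use ±30 s with 30-s flanks so windows stay inside
pure flanking states). Both the flank and the window are configuration
parameters, not fixed constants.

## GRAB-sensor sessions and window contrasts

`session_zscore()` z-scores each ROI against its own baseline-period mean
and SD (n−1 denominator), drops zero-variance ROIs with a warning, and
averages ROIs into a session trace with equal weights (sessions carry 8–12
ROIs; the per-session dot in a population figure is this unweighted mean).
Two contrasts are provided:

- `delta_z()` — the local-drug rule: mean z in [40, 60] min minus mean z in
  [−20, 0] min around the treatment;
- `delta_z_injection()` — the systemic-injection rule: mean z in
  [20, 120] min minus the mean over the z-scoring baseline window itself
  (40-min baselines for injections, 20-min for cortical drug perfusion).

The synthetic drug effect is a saturating exponential step (default time
constant 600 s, emulating responses that develop over tens of minutes) of
`effect_size_z` baseline-SD units, optionally plus per-state level offsets
tied to a hypnogram. With a 300-s onset the [40, 60]-min window sees
> 99.9% of the plateau, so recovered contrasts are essentially unbiased;
bias grows monotonically with the onset constant relative to the
post-window start, which the tests verify.

## Bouton-to-microglia distances

The microglia mask lives on an anisotropic voxel grid (defaults: 1-um z
step, 0.41-um xy pixels; axis order (z, y, x); physical origin at the
centre of voxel (0,0,0)). `min_distances()` computes an exact Euclidean
distance transform of the background by the separable lower-envelope
method with per-axis sampling equal to the physical voxel size, then
measures each bouton from its exact physical position to the nearest
foreground voxel centre: the EDT value at the containing voxel plus the
bouton's offset bounds the search radius (triangle inequality), so only a
local box of candidates is scanned and the result is exact with respect to
the voxel-centre convention. Boutons whose containing voxel is foreground
are inside microglia and get distance 0. Boutons are treated as points;
their physical extent is ignored.

Distances are measured to voxel centres, not to a subvoxel-interpolated
surface; against analytic sphere ground truth the rasterization error is
bounded by about one voxel diagonal (1.16 um at the default geometry), and
the synthetic-volume test enforces that bound. `distance_histogram()` bins
with half-open intervals `[k*b, (k+1)*b)` and conserves counts.

## Group statistics

`paired_compare()` applies the reported decision procedure: test the
*paired differences* for normality (Shapiro–Wilk up to n = 50,
D'Agostino–Pearson K^2 above — the cutoff at 50 reflects Shapiro–Wilk's
oversensitivity at large n and is a convention, not a fact about the data),
then a paired t-test if normality is not rejected at alpha = 0.05,
otherwise a Wilcoxon signed-rank test. All-zero differences are reported as
the degenerate case with p = 1. The gate applies to differences, not raw
samples, because the paired test's assumptions concern the differences.
Null simulations (20,000 replicates of n = 12) put the procedure's overall
type-I error near the nominal 0.05 (the gate inflates it only mildly; the
acceptance bound is 0.07).

`two_way_rm_anova()` fits `value ~ group * time + Error(unit)` on a
balanced long table (group between units, time within) and adds per-time
unpaired contrasts corrected by Bonferroni (`min(1, m p)`) or step-down
Holm–Šídák; `one_way_anova()` exposes the one-way layout with the same
corrections. Sphericity is not corrected (no Greenhouse–Geisser
adjustment); with the short time layouts used here the per-time corrected
contrasts, not the omnibus F, carry the inference, and the limitation is
stated rather than hidden.

## Numerical conventions and degenerate inputs

- Quantiles use the linear-interpolation (type-7) definition everywhere.
- Sliding windows truncate at edges; nothing is reflected or padded.
- Event peaks tie-break to the first maximal frame.
- Zero-variance inputs error (z-scoring) or yield empty results with a
  warning (event detection, sensor ROI dropping).
- All generators restore the caller's RNG state; nothing touches the
  global stream.
- Integer seeds are kept below 2^31.

## Problem sizes

The test suite and the acceptance script use: ten 3-h sleep sessions at
1,500 Hz for scoring recovery; 100 random traces for the baseline oracle;
ten ROIs x 40 min x five seed sets for the detection benchmark; 100
pure-noise traces for the null-rate check; 20 seeds for sensor-effect
recovery and transition sign patterns; 50 random volumes up to 64^3 voxels
plus a 20-sphere scene with 500 boutons for the distance checks; and
20,000 null replicates for the type-I simulation. These sizes give stable
pass/fail behaviour at interactive runtimes on a single core.

## Known limitations

- The scoring rule is intentionally minimal (two thresholds); it does not
  model artifacts, transitional epochs or micro-arousals.
- The calcium generator's kernel is instant-rise/single-exponential; real
  transients have finite rise times and multi-exponential decays.
- Sensor sessions model one treatment step plus state coupling; receptor
  kinetics and dose-response are out of scope.
- Distances are voxel-centre based; surface-based distances would be
  smaller by up to half a voxel diagonal.
- The repeated-measures ANOVA assumes balance and does not correct for
  sphericity.
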