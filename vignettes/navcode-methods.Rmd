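---
title: "Methods: position and visual coding analysis with navcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: position and visual coding analysis with navcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navcode)
```

# Overview

`navcode` quantifies position-related and visually evoked activity in
cellular calcium-imaging sessions recorded while a head-fixed mouse runs on
a cued circular treadmill (150 cm belt, tactile cues at 50 and 100 cm,
reward at 0 cm), together with widefield Fourier retinotopy and
retrograde-tracing input quantification. A seeded synthetic-session
generator with known ground truth makes every stage testable without raw
imaging data. This vignette documents the models, the tunable parameters,
and the numerical decisions taken where the underlying procedure admits
more than one reading.

# Preprocessing model

## Neuropil correction and baseline

Somatic fluorescence is corrected as `F_corr = F_cell - 0.7 * F_np`, with
the conventional contamination coefficient 0.7 (configurable in `[0, 1]`).
The baseline `F0` is a morphological opening of `F_corr`: a rolling minimum
followed by a rolling maximum, both over a 60 s window, then Gaussian
smoothing with SD = 10 samples at the acquisition rate. We read the
"min/max filter" as min-then-max because the opening is the standard
transient-robust baseline: brief positive transients are erased by the
minimum stage while slow drift survives both stages. Window edges use
shrunken (clipped) windows, which makes the operator exact on constants and
translation-equivariant — two properties the test suite checks directly.
`dff = (F_corr - F0) / F0`; a neuron whose baseline is non-positive
anywhere is flagged invalid rather than raising an error, so one bad ROI
cannot abort a session.

## Deconvolution

Events are recovered by non-negative least squares under an AR(1)
observation model: find `s >= 0` minimizing `||c - dff||^2` subject to
`c[t] = gamma c[t-1] + s[t]`, with `gamma = exp(-1 / (rate_hz * decay_s))`
and a fixed `decay_s = 1.5` s appropriate for GCaMP6s. The solver is a
pool-adjacent-violators sweep (the zero-penalty special case of the usual
sparse deconvolution algorithms) implemented in C++; with no sparsity
penalty the fit is exact on noise-free forward-synthesized traces, which
gives the suite a machine-precision round-trip oracle. We deliberately fix
the kernel rather than estimating it per neuron: only the decay constant is
part of the quantification contract.

## Transients and task activity

Significant transients are samples where `dff` exceeds the per-neuron noise
scale by 3 SD. The noise SD is estimated as `1.4826 * MAD` about the
median, not the sample SD — transients themselves would inflate a sample
SD and make the threshold self-defeating; the MAD estimate is consistent
for the Gaussian noise floor (the suite checks the one-sided 3-sigma tail
rate on pure noise). The 3-SD rule is applied to neuropil-corrected
`dff`; whether correction precedes thresholding is not fixed by the
procedure we mirror, and corrected traces are the quantity every other
stage consumes. Lap reliability is the fraction of laps containing at
least one significant transient, and a neuron is task-active when lap or
visual reliability strictly exceeds 0.3.

# Behavioral segmentation

Speed, when not provided, comes from wrap-corrected position differences
smoothed with a 0.5 s boxcar. Running epochs are maximal runs with speed
at or above 5 cm/s; epochs separated by less than 0.5 s are merged
*before* the 1 s minimum-duration filter is applied, reading "epochs
separated by less than 0.5 s were merged" as defining the final epoch set
(merging after the duration filter would silently discard sub-second
bouts that together form a legitimate epoch). Forward movement is
equivalent to the speed criterion here because treadmill position is
monotone within laps. Laps are segmented where position drops by more
than half the track length between samples; the half-track hysteresis
makes the detector immune to jitter at the 0 cm seam. Position bins are
half-open, 0-based and left-closed (position exactly `L` maps to bin 1),
with 100 bins (1.5 cm) as the default everywhere.

# Position tuning

Per trial (complete lap) and bin, activity is summed deconvolved amplitude
divided by the time spent in the bin, restricted to running epochs —
running-only maps keep the tuning stage consistent with the decoder, which
is defined on running epochs. Each trial map is smoothed with a circular
Gaussian (SD = 3 bins; the belt loops, so smoothing and field contiguity
wrap at the seam), with kernel weights renormalized over the trial's
visited bins; unvisited bins stay missing and are excluded from the
across-trial mean and SEM (SEM uses `n - 1`).

## Shuffle test

The null model circularly shifts each neuron's event train by a uniform
random time between 20 s and the session duration minus 20 s, 200 times,
recomputing the trial-mean map each time. We use *per-bin* null
percentiles rather than one pooled distribution: the observed criterion
("mean - SEM exceeds the 97.5th percentile in any bin") compares bin-wise
quantities, and pooling would mix bins with different occupancy-driven
variance. The per-bin maximum over 100 bins inflates the family-wise rate
above 2.5%, but the conservative mean-minus-SEM lower bound offsets it;
the suite measures the realized null rate on position-independent neurons
and requires it to stay at or below 10%. Because the across-trial mean map
is linear in the per-(trial, bin) rates with a visitation pattern that is
fixed across shuffles, all 200 null maps per neuron reduce to one matrix
product, which is what makes the full test fast enough to run at
200 neurons x 200 shuffles inside the test suite.

## Fields, information, reliability

Field detection thresholds the smoothed mean map at
`baseline + 0.3 (peak - baseline)`, with the baseline taken as the map
minimum — "baseline activity" is otherwise undefined for an
occupancy-normalized map, and the minimum is the only choice that keeps
the threshold scale-invariant. Fields are circularly contiguous
supra-threshold runs with width in [15, 120] cm, and must be
supra-threshold (trial-mean over the field span above the same threshold)
in more than one third of trials. The reported field center is the
activity-weighted mean position along the field span rather than the raw
argmax; both estimators are unbiased, but the weighted mean averages
Poisson jitter over the whole field and is considerably less variable.
Spatial information is `SI = sum p_i (f_i / f) log2(f_i / f)` in
bits/event (zero-rate bins contribute zero), and trial reliability is the
median pairwise Pearson correlation over trials, computed on mutually
visited bins. A neuron is position-tuned when it is shuffle-significant
and has at least one valid field; the reported width is the widest field
and the field count is capped at three.

# Bayesian decoding

The encoding model `f_i(pos)` is the occupancy-normalized mean activity
per decoding time bin, fit on training laps, floored at `1e-3` times the
grand-mean rate because the log-likelihood term `a_i log f_i` diverges at
zero. The posterior is

$$P(\mathrm{pos} \mid a) \propto \Big(\prod_i f_i(\mathrm{pos})^{a_i}\Big)
  e^{-\tau \sum_i f_i(\mathrm{pos})},$$

evaluated in the log domain with log-sum-exp normalization; the suite
verifies agreement with the literal product formula to 1e-9 on small
instances. The activity `a_i` is the deconvolved event amplitude per time
bin, clipped at zero — the Poisson-form likelihood requires non-negative
exponents, which raw dF/F does not guarantee; dF/F input remains possible
by passing it as the activity matrix. `tau` defaults to one imaging frame.
The decoded position is the maximum-posterior bin, ties resolving to the
lowest index. Cross-validation splits complete laps odd/even (odd ordinal
laps train) or into 5 contiguous folds with every lap tested once.
Decoding error is the linear absolute difference between decoded and
actual position with the median as summary, matching a half-belt (75 cm)
chance reference; a circular error is available by flag but is not the
default, since the chance convention implies the linear reading. The
Gaussian-smoothed error trace (SD = 10 time bins) is provided for display
only and never feeds statistics.

# Visual tuning

Trials are de-randomized into a canonical condition order (directions
within SF-then-TF combos) and baseline-corrected by the median of the five
pre-stimulus frames. The reliability index is the 75th percentile of
Pearson correlations between the *concatenated* condition-ordered time
courses of repetition pairs — computing pairs per condition and pooling
would change the statistic's null distribution with condition count, and
the concatenated form matches the de-randomized display the index is
defined on. Responsiveness is strict `r > 0.3`. The condition response
scalar is the mean baseline-corrected dF/F over the 3 s stimulus window
(the window statistic is otherwise unspecified; the mean is the least
noisy unbiased choice). The preferred SF/TF combo maximizes the
direction-averaged response, ties resolving to the lowest canonical combo
with a flag. OSI and DSI are computed at the preferred combo only, on the
12-point direction curve with negative condition means rectified to zero
so both indices stay in [0, 1]; `R_ortho` averages both orthogonal
directions. Selectivity uses strict `> 0.33`.

# Widefield retinotopy

Pixels are normalized to the pre-stimulation baseline, optionally
contrast-enhanced by `(x - rollingmin) / (rollingmax - rollingmin +
delta)` (window 10 s by default — the window length is a free parameter;
10 s covers several stimulus cycles at the frequencies used), and the
trial-averaged movie is projected onto the complex exponential at the
stimulus frequency. For `baseline + A cos(2 pi f t - phi)` the recovered
amplitude is `A` and the recovered phase is `phi`, so positive phase means
a later response; the sign convention is part of the map object. Non-
integer cycle coverage triggers a Hann window with a warning. HSV encoding
maps phase to hue (circularly), normalized amplitude to value, saturation
one.

# Input tracing

Labeled cells aggregate up a rooted region hierarchy to any requested
antichain level; unresolvable acronyms are reported as rejects, never
silently dropped, and counts are conserved across levels. Input fractions
normalize per injection target; densities divide by the sum of leaf-region
volumes. The bias index is `log2(f_posterior / f_anterior)`. When any
region-by-target count is zero, a pseudocount of one cell is added to
every cell of the table before fractions are computed — applied at the
count stage so both targets' denominators shift consistently — and raw
counts are always reported alongside. The package ships a small synthetic
ontology (~40 regions with nominal volumes) in place of a full
atlas-derived table; densities computed against it are only internally
comparable. Dorsoventral profiles compare per-target empirical CDFs of
the DV coordinate with a two-sample KS test. The RSP regions are included
as input regions by default; exclude them by filtering the cell table.

# Synthetic sessions: what they emulate, and what they do not

The generator reproduces the study conditions: 150 cm belt with cues at
50/100 cm and reward at 0 cm, 30 Hz sampling (a 7.5 Hz volumetric preset
mirrors tunable-lens acquisition), 15 min default duration, run/pause
bouts from a two-state Markov model (mean dwell 30 s running, 5 s paused,
mean speed 15 cm/s) chosen so that sessions exercise the epoch detector's
1 s / 5 cm/s / 0.5 s rules, circular Gaussian position fields convolved
with the 1.5 s exponential kernel, a shared neuropil channel re-entering
the cell channel with gain 0.7 (so the default correction coefficient is
exactly right on synthetic data), additive Gaussian noise, and a
pseudo-randomized grating protocol (12 directions x 3 SF x 2 TF, 3 s
stimulus / 2 s gray, each repetition a fresh permutation of all 72
conditions). Per-neuron event rates and single-event dF/F amplitudes are
not reported by any source we mirror; the defaults (baseline 0.05
events/s, field amplitude 3 events/s, 0.25 dF/F per event, noise SD 0.05)
were chosen once as values a practitioner would call realistic for GCaMP6s
at 30 Hz, and are testability choices, not claims about any deposited
dataset. The generator omits slow baseline drift, motion artifacts,
correlated network events, eye movements and licking; passing tests
therefore demonstrate correctness of the quantification chain under the
stated generative model, not robustness to every artifact of real
recordings.

# Problem sizes and randomness

All randomness flows from one master seed through named substreams
(`derive_seed`), so a configuration reproduces every output bit for bit.
The test suite and the acceptance script run sessions of 200-300 s with
40-200 neurons and 100-200 shuffles, and a 20-session cohort (10 per
group, 60 neurons each, tuned fractions 0.45 vs 0.21) — sizes chosen so
the whole suite completes in a few minutes while keeping every statistic
in its asymptotic regime; the defaults users see (`sim_config()`) remain
the full 15 min session.

# Known limitations

- The decoder assumes independent Poisson-like activity across neurons;
  correlated noise is neither simulated nor modeled.
- The shuffle test's per-bin percentile choice is one of two defensible
  readings (the other pools shuffled values across bins); the per-bin form
  is slightly more permissive at fixed percentile and is the one
  calibrated here.
- Volumes in the bundled ontology are nominal; use an atlas-derived CSV
  for absolute densities.
- CCF registration, ROI segmentation and motion correction are upstream of
  this package; it starts from extracted traces.
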