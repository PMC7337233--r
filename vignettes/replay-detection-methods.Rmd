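---
title: "Detecting learned firing-sequence replay: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting learned firing-sequence replay: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `neuroreplay`, the
choices made where the method leaves room for interpretation, and what the
synthetic-data validation does and does not establish.

## The problem

A participant with intracortical microelectrode arrays plays a
brain-controlled sequence game: one **repeated** ordering of four targets is
presented many times (66 per session by default), pseudo-randomly
interleaved with **control** orderings (11 distinct orderings, twice each)
chosen so that no control contains any of the repeated ordering's three
ordered target-to-target transitions — `enumerate_control_sequences()`
verifies that exactly 11 of the 24 permutations qualify for any repeated
ordering. Rest blocks of 20–30 minutes flank the game. The analysis asks
whether firing patterns expressed during the game re-occur more strongly in
post-task rest (Rest2) than pre-task rest (Rest1), and whether that increase
is specific to the learned, repeated sequence. Because the control trials
are veridical neural activity recorded interleaved with the repeated trials,
they absorb nonstationarity, arousal and drift confounds that defeat
shuffle-based nulls.

## Preprocessing

**Adaptive z-scoring** (`adaptive_zscore()`). Each feature is normalized by
causal exponentially weighted moments with time constant `tau = 120` s
(`alpha = exp(-bin_width/tau)`): the output at bin *t* is
`(x_t - mu_{t-1}) / max(sigma_{t-1}, 1e-6)`. The method's comparisons span
tens of minutes, over which feature baselines and scales drift; a causal
running normalization removes this without leaking future information
(output at bin *t* depends only on bins up to *t*, which the tests verify).
Design choices the method statement leaves open:

* *Which "adaptive" scheme.* Exponentially weighted mean **and** variance,
  both with the same `alpha`. Initialization `mu_0 = x_1`, `sigma_0 = 1`;
  the first `ceiling(tau / bin_width)` bins are flagged burn-in. Burn-in
  bins are kept in the output (so lag bookkeeping stays trivial) but
  excluded when centile thresholds are computed. Consequence: exact scale
  equivariance holds only once the `sigma_0` term has decayed, which the
  tests acknowledge by comparing well after burn-in.
* *Per-block reset.* Task and rest blocks are normalized independently.
  Whether the original analysis carried running state across block
  boundaries is not stated; a per-block reset is the conservative choice
  (no cross-block leakage) and is what the burn-in flag communicates.

**Temporal resampling** (`resample_pattern()`). Variable-duration
trajectories are brought to a common length, and templates are
dilated/compressed, by per-feature linear interpolation onto uniformly
spaced points. A polyphase anti-aliasing resampler would be the
signal-processing default, but 20 ms binned rates are already heavily
smoothed, linear interpolation is exactly reproducible across platforms,
and it preserves affine ramps exactly (tested). `new_length == T` returns
the input bit-for-bit.

## Template matching

**Templates.** Single-target templates average all successful
repeated-trial trajectories to a target after resampling each to the mean
segment length (rounded to the nearest bin). Trial templates are the raw
z-scored T x F span of each correctly played trial, labeled
repeated/control. Only successful trials contribute — an unsuccessful trial
truncates the sequence and its pattern is not the learned object of
interest.

**Normalized 2D cross-correlation** (`normalized_xcorr()`). `CC(l)` is the
Pearson correlation between the flattened template and the flattened window
starting at lag `l` (both centered over all T*F entries). Peak time is the
window-*start* bin throughout the package. Implementation: window sums and
sums of squares come from prefix sums; the cross term is a per-lag dot
product in compiled code (`src/cc_core.cpp`). A full-length scan
(T = 225, F = 40, N = 75,000) takes well under a second; the naive
per-lag Pearson loop exists only as the test oracle. Zero-variance windows
yield CC = 0 with a warning — a flat window cannot evidence replay, and NaN
propagation would poison downstream percentiles.

**Thresholding and peak extraction** (`centile_threshold()`,
`extract_peaks()`). The centile threshold is computed from the template's
**pooled** Rest1+Rest2 CC values (burn-in lags excluded), so that peak
selection is identical in both blocks and the Replay Index reflects CC
magnitude changes rather than threshold differences; a per-block threshold
would build a Rest1-vs-Rest2 asymmetry into the statistic being tested.
Percentiles use the linear-interpolation convention (R type 7). Candidates
are strict local maxima ("above threshold" is strict); a plateau
contributes its leftmost bin, and a boundary bin qualifies when it exceeds
its single neighbor — the method statement does not specify
plateau handling, and ties have measure zero for continuous CC values.
Non-maximum suppression is greedy in descending CC (ties to the earlier
lag); "0% overlap" is interpreted as: accepted spans `[lag, lag + T)` may
not overlap, so the minimum accepted separation is exactly `T`, and a
separation of exactly `T` survives (tested at the boundary).

## Replay statistics

**Sequenced single-target replay.** The four single-target peak sets are
interleaved into one time-ordered labeled stream (ties ordered by target
ID). Every window of 4 *consecutive* labels (step 1, any temporal spacing)
is a hit for an ordering iff the labels match exactly; windows overlap,
giving `n_peaks - 3` windows per tested ordering. Control hits accumulate
over the 11 admissible orderings of the same stream, making the control
denominator exactly 11x the per-ordering window count — the published
accumulated tables satisfy this identity (121,363 = 11 x 11,033;
95,733 = 11 x 8,703). Rest2 vs Rest1 proportions are compared with the
pooled two-proportion chi-square, 1 df, **no continuity correction**: the
uncorrected statistic reproduces both published values (7.40 and 0.437) to
print precision, the Yates-corrected one does not.

**Replay Index.** For one template at one (dilation, centile):
`RI = (m2 - m1)/m1` with `m1`, `m2` the mean peak CCs per rest block. A
template with zero peaks in either block (or `m1 = 0`) has no defined RI;
such records are marked invalid, logged with peak counts, and excluded from
the distributions — the original handling is unstated, and imputing any
value would bias small-peak-count cells. Within-session comparison:
pooled-variance (Student) two-sample one-tailed t, the conventional default
of the original analysis environment, recorded in the output so an
unequal-variance variant could be swapped in. Across sessions: paired
one-tailed t on per-session mean RIs. Both are computed in closed form so
degenerate inputs behave sensibly (identical groups give t = 0, p = 0.5,
where generic implementations error). The sweep covers dilations
`{0.05, 0.075, 0.1, 0.2, ..., 2.5}` and centiles `{75, 90, 95, 99, 99.9}`
(27 x 5 cells at `full_sweep = TRUE`; a reduced default keeps interactive
runs fast). No multiple-comparison correction is applied across the sweep —
neighboring cells share almost all their data, so standard corrections do
not apply; instead every cell also runs the **swapped** test
(control > repeated), whose rejection count estimates the number of
significant outcomes expected by chance.

**Behavior.** Per session: success rate and mean completion time of
successful trials, by sequence kind; across sessions, two-tailed Wilcoxon
signed-rank tests (exact sign-pattern enumeration for n <= 12, the standard
exact method in `stats::wilcox.test`).

## Sleep/wake restriction

`theta_envelope()` follows the stated LFP chain: 2 Hz zero-phase
forward-reverse Butterworth high-pass (order 6; verified stable and
accurate at this cutoff at 1 kHz), 4–7 Hz zero-phase FIR band-pass
(windowed-sinc; order 750 = 3 cycles of the 4 Hz cutoff at 1 kHz — the
filter family is stated but not the order, and 3 low-edge cycles is a
common rule giving ~1.3 Hz transition width), analytic-signal magnitude
(FFT half-spectrum method), then the median envelope over each 20 ms bin.
`score_states()` thresholds rest bins at the 80th percentile of
task-period theta; used-bin counts are equalized (waking = equally many
lowest-theta bins; if NREM1 exceeds half the block, both sets shrink to the
waking count). Peaks are attributed to the state of their window-start bin
by default; a `"majority"` rule over the template span is available behind
a switch, since the original attribution is unstated and spans can cross
state boundaries.

## The synthetic-session generator

`synthesize_session()` emulates the session structure so every stage is
testable without access to clinical data: 66 + 22 trials (orders satisfying
the transition constraint; per-target durations jittered by U[0.85, 1.15]
to emulate variable completion times), per-feature AR(1) noise (unit
stationary variance, coefficient 0.3) plus a slow sinusoidal mean drift
(amplitude 0.5 z-units, ~10 min period, random phase per feature) to
exercise the adaptive z-scoring, rest blocks of 23.5/26.2 min, and replay
events inserted **additively** (replacement would create detectable
discontinuities in the noise statistics) at configured compression, gain
and rates, with more repeated-template events in Rest2 than Rest1 by
default and control-template events at a flat rate in both blocks — the
configuration therefore separates the signal (repeated, Rest2-enriched)
from the null (control, flat), which a single shared rate could not.
The LFP carries 5.5 Hz theta at amplitude 25 during scheduled NREM1 epochs
(30 s epochs, 30% of bins by default) and ~3 during quiet rest waking,
while task-period waking theta wanders over 1.5–6 — task engagement
produces more variable theta than eyes-closed rest, and this gives the
task-derived 80th-percentile threshold a genuine margin over quiet-rest
waking theta. Event rates, gains and the NREM1 fraction are free
parameters of the simulation, not estimates of any participant's
physiology: no empirical event rates are published to calibrate against.

What passing tests on these sessions show: the pipeline recovers embedded
replay at the correct timescale, its null calibration is nominal on
event-free data, and state restriction isolates events placed in NREM1.
What they do not show: performance under real spiking statistics
(point-process variance, burst structure, electrode instabilities,
correlated noise across features), real sleep architecture, or behavioral
confounds — the generator's noise is Gaussian AR(1) with sinusoidal drift
by construction.

## Problem sizes

Validation runs use reduced conditions chosen to keep the full suite in a
few minutes while retaining power: 12–23 trials per session, 16 features,
0.6 s per target, 2.5–8 min rest blocks, `tau = 45` s (so burn-in does not
swallow a scaled block), reduced dilation grids, and 4–20
sessions/replicates per experiment. The acceptance script's recovery study
uses 10 sessions with repeated-template events only in Rest2
(2.5 events/min, gain 1.3, compression 0.1) — conditions selected for
stable power across seeds, since the script must reproduce its conclusions
under any seed. The generator's *defaults* remain the full study-sized
conditions.

## Known limitations

* The Replay Index is undefined for templates without peaks in both blocks;
  at extreme centiles (99.9) or extreme dilations this can thin the RI
  distributions and drop sweep cells (reported as missing, with counts).
* The chi-square on accumulated hit counts treats overlapping 4-windows as
  independent observations, as in the original analysis; the swapped test
  does not cover this statistic.
* State scoring is a two-state theta proxy; it does not stage deeper sleep
  and inherits the task-theta baseline assumption.
* CC values are clamped to [-1, 1] against floating-point excursions;
  prefix-sum window statistics are exact for z-scored magnitudes but, like
  any running-sum scheme, lose precision for raw inputs with enormous
  offsets — normalize first (the pipeline always does).
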