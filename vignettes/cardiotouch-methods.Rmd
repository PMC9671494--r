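---
title: "Methods: cardiac-cycle coupling analysis of active touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac-cycle coupling analysis of active touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotouch)
```

# The model and its assumptions

The package analyses experiments in which participants freely initiate,
hold and end touches while a single-lead ECG is recorded. The cardiac
cycle is treated as a circle: an event at time $t_E$ after the R-peak of a
cycle of length $t_R$ has phase $\theta = t_E / t_R \times 360^\circ$,
with $0^\circ$ at the R-peak. This assumes that within one cycle,
"cardiac time" advances linearly with clock time — the conventional
simplification for beat-locked analyses; the biphasic structure is then
restored by the window analysis below.

**Electrical systole** is operationalised as the R-peak to T-wave-end
interval. Because diastole is longer than systole, raw event counts per
phase are not comparable; the package therefore builds, for every beat, a
**diastole window of exactly the systole's length**, anchored at the end
of the cycle. Under uniform event times, both windows then have equal
occupancy probability (verified by a Monte-Carlo property test), so a
systole proportion can be tested against a chance level of 0.5 and the
diastole proportion is its complement. Events in the mid-cycle gap are
excluded from phase-conditional analyses and proportions are renormalised
over assigned events — the alternative (assigning gap events to the nearer
window) would dilute both phases with mid-cycle events and change the
chance level.

Electrical systole is not mechanical systole; the R-to-T-end interval is
used as its standard ECG-accessible proxy, and no claim about ejection
timing is made.

# ECG event detection

*Filtering.* R-peak detection runs on a 3–30 Hz band-passed signal. No
zero-phase IIR filter implementation is available in the dependency
budget, so the filter is a frequency-domain (FFT) gain with raised-cosine
transition bands and reflection padding. Being real and symmetric in the
frequency domain it is exactly zero-phase and length-preserving; its
response is verified against sinusoid oracles (1 Hz attenuated below 10%,
10 Hz preserved above 90%, DC removed).

*R-peaks.* Local maxima with a minimum separation of 550 ms, accepted
greedily from the largest down. The amplitude threshold is
$0.5 \times$ the 95th percentile of the absolute filtered signal — a
scale-free rule that transfers across recordings without per-recording
tuning.

*T-wave end.* Delineation runs on a gently filtered copy (0.5–40 Hz): a
3 Hz high-pass would visibly distort the low-frequency T-wave morphology
that the delineator depends on. The T-peak is the maximum in the window
$[R + 150\,\mathrm{ms},\; R + \min(500\,\mathrm{ms},\, 0.6\,\mathrm{IBI})]$
(physiologic T latency). The T-end maximises the trapezium area
$A_i = \tfrac12 (y_m - y_i)(2x_r - x_i - x_m)$ over all candidate samples
between the T-peak $(x_m, y_m)$ and the reference abscissa $x_r$. The
reference is $x_r = x_m + 2\,(t_s - x_m)$ capped at
$\text{next } R - 50$ ms, where $t_s$ is the **end of the steep descent**:
the last sample whose downward slope is at least half the steepest slope
after the T-peak. On rounded T-waves this coincides with the classical
minimum-slope point; on a linear descent (where the slope is constant and
an argmin is ill-defined) it selects the end of the ramp, which keeps the
reference beyond the true T-end. The implementation is an exhaustive
vectorised scan and is required by test to equal an independently coded
brute-force loop on every trace; ties take the earliest sample.

The original workflow included manual inspection of detected events; this
implementation is deliberately fully automatic, so residual disagreement
with manually adjusted event series is expected at the level of a few
milliseconds per beat.

*Consistency filter.* Beats whose R-to-T-end interval deviates from the
participant's median by more than $1.5 \times$ the median are flagged;
trials overlapping flagged beats are excluded. Fewer than three surviving
beats rejects the recording outright.

# Trial construction and exclusion

The touch channel encodes the stimulus level in the pulse amplitude. Runs
of non-zero samples become trials; runs closer than 150 ms (`merge_gap`,
a value the source protocol does not specify — chosen well above contact
bounce and well below deliberate re-touches) merge into a single
multi-contact event, which is excluded. Exclusion rules are applied in a
fixed order, first match recorded: consecutive contacts, response before
release, hold < 100 ms, hold > 5000 ms, hold beyond ±3 SD of the
participant's mean, overlap with a rejected beat.

The ±3 SD rule is computed per participant over all trials of a condition
pooled (not per difficulty level), after the fixed-bound exclusions; the
per-level variant is available via `sd_pooling = "per_level"`. Pooling
matches the singular "the individual's mean duration" reading and is the
default. Participants enter the analysis only if an exact two-sided
binomial test (null 0.5) shows above-chance accuracy at some difficulty
level; control trials carry no correctness and bypass this test.

# Circular statistics

`circular_mean` returns the direction and length (R̄) of the mean unit
vector; below an R̄ of $10^{-12}$ the direction is reported `NA`. The
Rayleigh statistic is $z = n\bar R^2$ with the finite-$n$ series p-value
$$p = e^{-z}\Big[1 + \frac{2z - z^2}{4n}
      - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\Big],$$
clipped into $(0, 1]$. This approximation reproduces the printed group
p-values from the printed statistics at their printed precision —
consistent with the printed "z" values being mean resultant lengths, which
is why the package reports both R̄ and $z = n\bar R^2$ explicitly.
Holm–Bonferroni is the textbook step-down with running-maximum
monotonicity and capping at 1, validated against `stats::p.adjust`.

Group-level circular tests are **second level**: one circular mean per
participant per cell, then a Rayleigh test across participant means.
Per-difficulty tests are Holm-corrected over the seven levels.

The hold phase is the circular mean of the event phase sampled at the
midpoints of 1 ms bins across $[{\rm onset}, {\rm offset})$. Midpoint
sampling makes the estimate exact for symmetric arcs and second-order
accurate, so a 0.1 ms grid agrees to well under $0.1^\circ$; a hold
spanning whole cycles has numerically zero resultant and its mean is
flagged undefined (threshold $10^{-9}$).

# Interbeat-interval context

For each touch onset the five IBIs at beat positions $-2\ldots+2$ around
the onset cycle are decomposed into electrical systole and the **diastole
remainder** (IBI − systole — the full remainder, not the equal-length
event window, because this analysis concerns phase durations rather than
event probabilities). Trials lacking two complete cycles on either side
are dropped from this analysis only.

One estimator caveat, discovered with the generator and relevant to real
data: the beat *preceding* the onset beat is a size-biased draw (longer
cycles are more likely to contain any given point in time), so its
expected IBI sits above the marginal mean by roughly
$\sigma^2/\mu$. Parameter-recovery tests therefore baseline the position-0
elevation on positions $-2, +1, +2$.

# The synthetic generator: what it emulates, and what not

The generator's defaults state the world of a typical session: mean IBI
793 ms with within-participant SD 110 ms (between-participant SD 60 ms),
electrical systole 342 ms (between-participant SD 23.4 ms, fixed within
participant by default, Bazett-like $\sqrt{\rm IBI}$ scaling optional),
140 gratings + 28 control trials (12 blocks of 14, last two control),
baseline holds of 975 ms for difficulty levels 1–4 and 1250–1300 ms for
levels 5–7 (700 ms for control) with trial-to-trial SD 430 ms — chosen so
the marginal mean and median hold land near 1.1 s / 1.0 s — and
per-level accuracies (0.97, 0.95, 0.93, 0.92, 0.78, 0.68, 0.57) averaging
0.83 with the flat-then-declining difficulty profile. Participant hold
SDs are spread uniformly ±50% to create the between-subject variability
the covariate analysis targets.

Three coupling knobs, all **0 by default** (a true null world):
`onset_phase_kappa`/`onset_phase_mu` (von Mises phase coupling of touch
onsets), `hold_systole_delta` (ms added to holds initiated in systole),
and `ibi_deceleration` (ms added to the diastole of the onset beat, all
later beats shifted). Ground-truth labels (onset cycle, phase, systole
flag) are stored with each trial so tests never re-derive truth from the
code under test.

Numerical choices inside the generator:

* IBI gaps are truncated-normal with lower bound $2 \times$ systole (so
  both phase windows always fit). The location is adjusted (one `uniroot`
  solve on the truncated mean) so the *realised* mean equals the stated
  793 ms; without this the bound would inflate the mean by ~30 ms. The
  realised SD is correspondingly a little below the nominal 110 ms. When
  a participant draw makes the stated mean unreachable (bound at or above
  it), the adjustment is skipped rather than failing.
* Holds are clipped just inside (100, 5000) ms, so a clean generator run
  triggers no fixed-bound exclusions; about 0.3% of trials can still fall
  outside ±3 SD of their own sample, so realised retention is slightly
  below 100% — planted-violation tests therefore use bounded hold sets.
* One root seed; per-participant child seeds are drawn from the root
  stream first, in participant order. Identical configurations are
  bit-identical.
* `hold_systole_delta` applies to every trial initiated in systole,
  control condition included; condition-specific effects are simulated by
  running conditions with separate configurations.

The rendered ECG is a template PQRST (Gaussian P, triangular R apex at
the true R time, Q/S dips, half-cosine T rise and a *linear* T descent
reaching baseline exactly at the true T-end) plus optional white noise.
It exists to round-trip the detectors — it does not emulate morphology
pathology, baseline wander, electrode artefacts, respiratory modulation
(no respiratory sinus arrhythmia unless `ar1` is used as a crude
surrogate), or 12-lead geometry. A green detector round-trip therefore
establishes correctness of the algorithmic chain, not robustness to
clinical-grade artefacts.

# Other numerical conventions

* Event times in a `beat_series` are snapped to a dyadic $2^{-10}$ ms
  (~1 µs) grid — far below any measurement resolution — which makes
  differences of beat times exact in floating point; the systole and
  diastole windows of a beat are then equal-length *exactly*, not merely
  to rounding error.
* Cycles are half-open $[R_i, R_{i+1})$; an event exactly at an R-peak
  has phase $0^\circ$ in the cycle it opens.
* Degenerate inputs are flagged, not fatal: flat signals yield no peaks
  (with a warning), beats violating event ordering or lacking a T-end are
  QC-flagged and excluded trials merely marked. The paired duration
  contrast falls back from a t-test to Wilcoxon when Shapiro–Wilk rejects
  normality of the differences (the t-based CI of the mean difference is
  reported either way); identically-zero difference vectors report p = 1
  by convention.
* Repeated-measures ANOVA/ANCOVA machinery (sphericity corrections,
  effect sizes) is intentionally out of scope: the package exports the
  tidy per-participant tables those routines consume.

# Test scaling

The full-scale recovery study (46 participants × 154 trials × 20
replicates for the 50 ms hold effect) runs in the acceptance suite. Two
properties are run scaled down to fit the time budget, with the scaling
chosen so the property itself is unaffected: null calibration uses 600
replicates of 12-participant groups (the null rejection rate of the
group-level tests does not depend on group size — participant mean
directions of uniform samples are themselves uniform), and the
delta-in-{0, 100} coverage property uses 12-participant replicates.

# Known limitations

* Real-data reproduction of the published group statistics requires the
  original deposited recordings, which cannot be bundled; the pipeline
  accepts their exported event tables via `import_event_tables()`.
* The automatic T-end delineator matches the manually adjusted original
  workflow only up to its automatic tolerance (≈5 ms on clean synthetic
  signals, degrading with noise).
* The generator's hold-duration noise is Gaussian; real hold
  distributions are right-skewed. Median-based summaries are available
  (`stat = "median"`) and both are reported.
* The equal-length diastole window equates event *probability*, not
  baroreceptor physiology; results conditional on the window labels
  inherit that operationalisation.
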