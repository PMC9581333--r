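---
title: "Quantifying scratching from induction-current traces: methods and design"
author: "scratchquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scratching from induction-current traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scratchquant)
```

## The measurement problem

Scratching in mice is a stereotyped hind-limb behavior: the paw oscillates
against the skin at roughly 10–20 cycles per second. When small magnets are
implanted in the hind paws and the cage sits inside a magnetic coil, every
hind-limb movement induces a current, and scratching appears in that current
as an amplitude-modulated oscillation burst in the 10–20 Hz band. Slower
hind-limb behaviors — locomotion (roughly 1–4 Hz) and grooming (roughly
5–8 Hz) — also induce current, but below the scratch band, which is what
makes a frequency discriminator workable.

The behavioral hierarchy this package quantifies is:

* **beat** — one paw oscillation cycle;
* **bout** — an uninterrupted run of beats ("uninterrupted" is
  operationalized below);
* **event** — one or more bouts executed between a single paw lift and
  paw-down.

The three session metrics are scratch time (summed bout durations), bout
count and event count over a 30-min post-injection window, plus bout counts
in 5-min bins for time courses.

Because raw recordings from such monitors are generally not redistributable,
everything here is exercised against a synthetic-signal generator that emits
traces *with exact ground-truth annotations*, so detector output can be
scored as true/false positives rather than eyeballed.

## Signal model of the generator

A session is scheduled top-down: events, bouts within events, beats within
bouts.

* Per bout, a base frequency is drawn uniformly from the scratch band and
  inter-beat intervals are jittered around the base period with a
  coefficient of variation of 0.15. Intervals are then clamped 2 ms inside
  the band `[1/20, 1/10] s`, and if a bout's interval CV still exceeds 0.38
  the deviations are shrunk about their mean. The clamping alone does not
  bound the *sample* CV of short bouts (three intervals at the two band
  edges already exceed 0.40), hence the explicit shrink; together they make
  every emitted bout satisfy the detector's own acceptance rules — the
  generator emits detectable-by-construction bouts, so any detection miss is
  attributable to the detector, not to ambiguous truth.
* A bout is rendered as a continuous-phase oscillation whose positive peaks
  fall exactly on the beat times (phase interpolated linearly between
  anchors, i.e. one sinusoid cycle per beat at the bout's instantaneous
  frequency), with half-cycle raised-cosine ramps at both edges. We chose
  peak-anchored rendering over concatenating independent windowed cycles
  because it gives the detector's natural anchors (cycle peaks) an exact
  ground-truth counterpart, which is what makes "each detected beat within
  10 ms of a truth beat" a meaningful assertion. The annotated bout support
  is the rendered support: first beat minus half the first cycle to last
  beat plus half the last cycle.
* Confounders are Hann-windowed sinusoidal bursts in their own bands,
  scheduled as a Poisson stream and placed only in the gaps between scratch
  events (a mouse does not walk or groom mid-scratch), with a 0.5 s guard
  band. Gaussian baseline noise is added last.

### Generator defaults and why

| parameter | default | rationale |
|---|---|---|
| sampling rate | 200 Hz | 10x the top of the scratch band; comfortably resolves cycle peaks |
| duration | 1800 s | one 30-min post-injection observation window |
| events per session | 40 | with 1–5 bouts/event and 4–30 beats/bout this yields on the order of 100–150 bouts per session, a mid-range acute response |
| beat jitter CV | 0.15 | visibly irregular rhythm yet clearly inside the 0.40 bout rule |
| intra-event bout gap | 0.2–0.8 s | below the 1.0 s event-gap threshold, so the bout/event hierarchy is recoverable from the signal |
| inter-event gap | >= 1.5 s | above the event-gap threshold; events stay separable |
| bout amplitude / noise SD | 1 / 0.1 | burst SNR of 10; the band-passed noise floor sits near 0.03, so the default threshold (5x the robust scale) is at about 0.16 |
| locomotion | 1–4 Hz, 2/min, amplitude 2 | high-amplitude, clearly sub-band |
| grooming | 5–8 Hz, 2/min, amplitude 1 | the harder confounder, adjacent to the band from below |

The simulator deliberately does **not** model coil physics, magnet
kinematics, amplitude calibration, electrode drift, or broadband movement
artifacts that overlap the scratch band. Passing the validation suite
therefore demonstrates that the detection logic is correct and robust to
out-of-band interference and stationary noise — not that the detector would
reach the same PPV on any particular hardware. That caveat is inherent to
any synthetic validation and is why the match tolerance, band and thresholds
are all configurable.

## The detector

Beat extraction is unspecified in most descriptions of such monitors, so the
package uses a deliberately standard, parameter-light burst detector:

1. zero-phase band-pass (order-2 Butterworth, applied forward and backward)
   over the scratch band;
2. envelope as the magnitude of the analytic signal (FFT-based Hilbert
   transform);
3. amplitude threshold at `k = 5` times a robust noise scale, 1.4826 x the
   median absolute deviation of the band-passed trace — the MAD ignores
   sparse bursts and tracks the noise floor. On (near-)noiseless traces the
   MAD collapses to zero and the threshold would admit filter ringing
   between bursts (about 3% of burst amplitude), so the scale is floored at
   2% of the band-passed peak;
4. cycle-peak picking with minimum separation `1/(2 f_hi)`; peaks whose
   envelope clears the threshold become beats.

Bout segmentation is a greedy left-to-right run construction: a run extends
while the next inter-beat interval lies in `[1/f_hi, 1/f_lo]`; runs shorter
than 3 beats (the smallest run with a defined interval CV) are discarded; a
surviving run whose interval CV — sample SD over mean, `n-1` denominator —
exceeds 0.40 is split at the interval most deviant from the run's median
(leftmost on ties) and both halves are re-evaluated recursively. The CV is
computed on intervals rather than instantaneous frequencies because the
bout rule is phrased in terms of variation *between beats*. The in-band
test carries a measurement-resolution allowance of one sample period
(5 ms at the default rate): beat times live on the sampling grid, so a true
98 ms interval is legitimately measured as 100 ms ± one sample, and without
the allowance grid quantization splits perfectly valid bouts.

Event grouping merges consecutive bouts separated by at most 1.0 s. The paw
lift itself is invisible in the induction signal, so this threshold is a
proxy; the ground truth carries explicit lift/down times for calibrating it.

Scratch time is the plain sum of bout durations (last beat support minus
first), with no padding — the simplest definition consistent with "total
time spent scratching".

### Validation

Detected bouts are matched to ground-truth bouts one-to-one, greedily by
midpoint distance, within 0.5 s. Matching is per bout (not per event)
because the bout is the unit most validation-by-video protocols count. On
the default 20-session suite (both confounder classes, default noise) the
pooled PPV is above 99% and sensitivity above 99.9%; the residual errors
are almost exclusively bout splits at grid-quantization edges, each of
which costs one false positive. A noise-only suite (50 sessions) yields
zero false bouts, and with noise and confounders switched off the detector
recovers ground-truth bout counts exactly.

## The cohort simulator and the statistics workflow

The cohort generator reproduces the *design* of a two-strain,
seven-pruritogen, four-dose repeated-measures study: every animal receives
all four doses of its pruritogen on days 1/3/5/8 in the order 3-, 1-, 10-,
0.3-fold (lowest dose last, to expose sensitization). Bout counts are drawn
per cell from a negative binomial matched to the cell's mean and SD
(variance at or below the mean falls back to Poisson; a rounded lognormal is
available as the alternative model, since most groups in such data are
approximately normal on this scale). Counts are independent across doses
within an animal by default, so cell means and SDs converge exactly to their
targets; event counts and scratch time are derived from the bout count with
multiplicative noise, giving the three metrics the strong mutual
correlations they show in real cohorts.

The shipped mean table anchors each strain x pruritogen curve at the
printed group values (flagged `printed`); unprinted cells are filled by
log-dose interpolation between anchors where bracketed and by
curve-shape-consistent values otherwise, flagged `synthetic-default`, with
SEM defaulting to 25% of the mean. These fills parameterize simulations and
carry no evidential weight.

Downstream statistics follow the standard behavioral-pharmacology chain:

* **Outliers**: single-pass Tukey fences at 2.2 x IQR per
  strain x pruritogen x dose cell. Quartiles are linear-interpolation
  (type 7) by default; Tukey hinges are available by flag since the fence
  convention is hinge-based in its original formulation. The difference
  only matters at small n and is surfaced as an option rather than
  silently chosen.
* **Normality**: Shapiro–Wilk by default, Lilliefors-corrected
  Kolmogorov–Smirnov as the alternative; both appear in practice and the
  package takes no position beyond the default.
* **RM-ANOVA**: classical univariate partitioning (subject, dose, residual),
  complete cases only — a subject that lost a dose to outlier removal is
  dropped entirely, the conservative reading of how removal interacts with
  the repeated-measures structure. No sphericity correction by default;
  Greenhouse–Geisser is available for within-only designs. The fit is
  checked in the test suite against an explicit group-mean sums-of-squares
  decomposition (relative tolerance 1e-8) and against the `F = t^2`
  identity at two levels.
* **Tukey HSD**: studentized-range p-values on the RM residual mean square
  with its degrees of freedom (the error term is not prescribed anywhere;
  the RM residual is the term the omnibus F uses). The compact letter
  display assigns one letter to every maximal run of mutually
  non-significant levels in mean-sorted order; with a distance-monotone
  statistic the homogeneous sets are contiguous in mean order, and the
  letters are verified against the pairwise matrix exhaustively in tests.
* **Wilcoxon rank-sum** (fallback for non-normal groups): exact by the null
  permutation distribution when there are no ties, `min(n) <= 8` and
  combined `n <= 16`; otherwise normal approximation with tie and
  continuity correction. The exact branch is verified against full
  enumeration of all rank assignments up to combined n = 10.
* **Ratios and ranking**: the cross-strain report takes each pruritogen's
  peak (max-over-dose) cell mean per strain and reports
  `100 * peak_resistant / peak_sensitive` (nearest-integer percent) and the
  reciprocal fold (one decimal) — the rounding conventions of results
  prose. Potency ranking averages each animal over its four doses and runs
  a one-way ANOVA with Tukey HSD across pruritogens on those grand means;
  whether such rankings should instead stay inside the RM framework is
  genuinely open, and the per-animal grand-mean reduction is our documented
  choice.

## Numerical choices and degenerate inputs

* Ties in the peak dose go to the *lowest* dose; ties in the CV split go to
  the leftmost most-deviant interval.
* Cells with one animal report `sem = NA` and are flagged, never a silent 0.
* Constant samples are rejected by the normality screen ("degenerate
  sample"), zero-variance metrics by the correlation step ("degenerate
  metric"), and `ms_error <= 0` by the post hoc ("invalid error term").
* Infeasible event schedules (events cannot fit the session) fail fast
  rather than truncating silently.
* All intervals everywhere are half-open `[onset, offset)`; all times are
  seconds from injection.

## Problem sizes

The shipped tests and scripts run at the sizes the analyses are reported
at: 20 full 30-min sessions for the validation suite, 50 five-minute
noise-only sessions for the false-positive floor, 20 four-minute clean
sessions for the exact round trip, cohorts of 200 animals per group for
anchor recovery and 10^4 for distributional convergence. The full suite
completes in well under a minute on a single core.

## Known limitations

* The event-gap threshold (1.0 s) is a proxy for an unobservable paw-down;
  against real video-annotated data it would need calibration.
* The synthetic confounders are band-limited and stationary; broadband
  artifacts (cage knocks, rearing against the coil frame) that leak into
  10–20 Hz are not modeled, and the reported PPV does not speak to them.
* The RM-ANOVA is the classical univariate one; with missing-at-random
  dropouts a mixed-effects model would retain incomplete subjects, which is
  out of scope here.
* Dose–response summaries are cell means ± SEM only; no sigmoidal or
  inverted-U curve fitting and no ED50 estimation is attempted.
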