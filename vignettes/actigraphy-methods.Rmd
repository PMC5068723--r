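---
title: "Methods: circadian analysis of home-cage actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian analysis of home-cage actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

This vignette documents the models, parameters and numerical choices behind
`actirhythm`: what the synthetic actigraphy generator assumes, how each
analysis is computed, which defaults were genuinely open design decisions,
and what the validation suites do and do not establish about real data.

## Time axes and light schedules

All analyses run on zeitgeber time (ZT): hours since the most recent
lights-on, so ZT 0 is the light onset and, under a 12:12 schedule, the dark
phase spans ZT 12–24 with mid-dark at ZT 18. A `light_schedule` is an ordered
set of contiguous segments, each LD or DD (constant darkness). In DD the ZT
axis is extrapolated from the last LD segment; after a shift of the schedule
the axis follows the new schedule from its first lights-on, which is how
jet-lag experiments are conventionally re-plotted. `phase_advance_schedule()`
places the segment boundary at the first *shifted dark onset*, so the advance
truncates a light phase rather than a night: every dark phase — and therefore
every nightly active phase — stays complete on both sides of the shift.

Activity counts are visit onsets per epoch (5 min by default), with half-open
epochs labeled by their start time; an event exactly on a boundary belongs to
the later epoch. Onset counting keeps counts additive across re-binning,
which the test suite verifies (binning at 5 min and aggregating equals direct
binning at 15 min).

## The synthetic actigraphy generator

Events are drawn from an inhomogeneous Poisson process by thinning a
homogeneous upper bound, which is exact for the piecewise-constant (per
epoch) rate used here:

rate(t) = `mean_rate` × circadian modulation × photic gate × noise factor

* **Circadian modulation** is `1 + a·cos(2π(t − φ)/P)` with modulation depth
  `a` in [0, 1], acrophase `φ` (ZT hours), and period `P` — the entrained
  period under LD, the intrinsic (free-running) period in DD, with phase
  continuous at the transition.
* **The photic gate** multiplies the rate by 1 inside the nightly activity
  window and by `gate_floor` outside it. The window opens
  `anticipation_hours` before dark onset and closes `offset_lag_hours` after
  lights-on. Edges are raised-cosine ramps of total duration
  `gate_ramp_hours`: a near-zero ramp is abrupt light masking (activity
  switched by the lights), a 2-h ramp is a gradual, clock-driven build-up and
  wind-down. Gating is disabled in DD.
* **The noise factor** is `exp(σ·z − σ²/2)`, `z` fractional Gaussian noise
  (fGn) with Hurst exponent `H` generated exactly by Davies–Harte circulant
  embedding. Multiplicative log-normal noise keeps the rate positive and
  gives the count series the long-range correlation structure that DFA is
  designed to measure; the `−σ²/2` term keeps the mean rate unbiased.

**Calibration of σ (`noise_sd`).** The generator should produce count series
whose DFA exponent, measured below the circadian scale, equals the preset's
`H`. On a grid of σ values, DFA of simulated free-running counts (5-min
epochs, scales 8–48 epochs = 40 min–4 h, 10 seeds) was ≈ 0.80 for σ between
0.2 and 0.35; σ = 0.25 minimized the deviation (0.803 ± 0.019 at H = 0.8) and
is the default. Smaller σ lets Poisson (shot) noise dilute the correlations
at small scales; larger σ distorts the rate distribution without improving
the match.

**Re-entrainment transients.** Two situations relax exponentially with the
preset's time constant `reentrainment_rate_cycles` (k, in cycles; weight
`w = exp(−(c+1)/k)` in post-transition cycle `c`):

* *Forced resynchronization* (LD resumed after DD): the effective parameters
  blend a "rigid gating" set — acrophase at mid-dark, no anticipation,
  transiently raised modulation depth, strong photic suppression — into the
  animal's entrained preset. This reproduces the classic transient: during
  the first resynchronization cycles activity is driven by the lights
  (acrophase delayed toward ZT 18, amplitude up), and anticipation re-emerges
  as entrainment consolidates. A fast re-entrainer (small k) shows no
  transient because its steady state is already rigid.
* *Phase advance*: the gate onset carries a lag `shift·w` that decays cycle
  by cycle, while the gate offset follows the new lights-on immediately
  (light masking); the modulation acrophase carries the same decaying lag.
  With small k the activity locks to the new dark onset from the first
  cycle; with k ≈ 3 cycles the onset lags behind the new dark onset and the
  active phase is transiently shortened.

The exponential-relaxation form is the package's own modeling choice — the
phenomenon is qualitative in the source designs (fast vs slow re-locking)
and no quantitative time constant is available to fit; presets encode only
the ordinal contrast (0.3 vs 3 cycles).

**Presets.**

| parameter | control | dex | mehg |
|---|---|---|---|
| entrained period (h) | 24 | 24 (23.6 "old") | 24 |
| intrinsic period (h) | 23.7 | 23.7 | 23.7 |
| modulation depth | 0.85 | 0.8 | 0.3 |
| acrophase (ZT h) | 16.5 | 18 | 16.5 |
| anticipation (h) | 1.5 | 0 | 1.5 |
| offset lag (h) | 1 | 0.1 | 1 |
| gate floor | 0.7 | 0.03 | 0.7 |
| gate ramp (h) | 2 | 0.2 | 2 |
| Hurst exponent | 0.8 | 0.8 | 0.8 |
| re-entrainment (cycles) | 3 | 0.3 | 3 |
| mean rate (visits/h) | 60 | 60 | 60 |

The load-bearing design decision is the *division of labor between the
endogenous rhythm and the gate*. The control phenotype carries a strong
endogenous rhythm (depth 0.85) that persists unchanged in DD, with mild,
gradual gating: light adds almost nothing to its diurnal rhythm, so its
scaling exponent under entrainment matches its free-running value, and its
active phase anticipates the dark onset. The dex phenotype inverts this: the
rhythm is confined to the dark phase by a hard, abrupt gate (floor 0.03,
0.2-h edges), so >95% of events fall in the dark, the acrophase sits at
mid-dark, the active phase starts exactly at dark onset and ends at
lights-on, and entrainment adds rhythm the free-run does not have — raising
the scaling exponent under LD relative to DD. An earlier parameterization
with a weaker control rhythm (depth 0.6) and deeper control gating put most
of the control's diurnal rhythm under light control and produced an
LD-vs-DD exponent gap in *both* phenotypes, contradicting the contrast the
pipeline is meant to resolve; the present values were fixed before the
acceptance suite was written and are exercised end to end by it. The mehg
phenotype is control-like in timing with a low-amplitude rhythm.

## Cosinor rhythmometry

`cosinor_fit()` solves the linear least-squares problem
`y = M + β_c·cos(ωt) + β_s·sin(ωt)` (ω = 2π/τ) by QR; amplitude is
`√(β_c² + β_s²)` and the acrophase is the fitted peak time mapped to ZT hours
in [0, 24) — the axis the field plots — rather than the classical
negative-radians convention. The fit is exact on noiseless cosines (verified
to machine precision) and matches an independent dense-grid-search oracle to
1e-6 on noisy input. A constant series returns amplitude exactly 0 with the
acrophase flagged undefined rather than an arbitrary number. Fewer than 3
distinct phases (mod τ), or a rank-deficient design, is an error.

Multi-day LD windows are fitted at fixed τ = 24 h (the entrainment question
is "what does the rhythm do at the zeitgeber period"); for free-running
windows τ is set to the periodogram peak, since no external period exists.
That linkage, and fitting one pooled model over the 3-cycle windows rather
than averaging per-cycle fits, are package choices; per-cycle fits are
available by passing per-cycle windows (as `phase_shift_response()` does).

## χ²-periodogram

For each trial period `P` in epochs (20–25 h at 5-min steps, 61 values) the
series is folded into `P` phase columns and scored with
`Q_P = N · Σ_h n_h(M_h − M̄)² / Σ_i(x_i − M̄)²`, distributed ~χ²(P−1) under
white noise. By default **all** points are folded, so column counts differ by
one between columns. The alternative — truncating to whole cycles so every
column has equal count — makes the number of points used grow with `P`
inside each whole-cycle plateau, and on 6–7-day records that reward
outweighs fold sharpness and displaces the peak of even a noiseless
23.5-h cosine by one grid step. The all-points fold keeps `N` constant
across the grid, so on noiseless periodic input the peak provably lands on
the true period (the suite checks a 24-h square wave and a 23.5-h cosine);
truncation remains available via `truncate = TRUE`. Ties in the argmax are
broken toward the period closest to 24 h, then the smaller period, making
output deterministic. Significance values (`pchisq`, df = P−1) are computed
and reported but never used for peak selection — the estimator is "highest
peak", unconditionally.

With 3-cycle windows the periodogram is intrinsically coarse (its peak width
over 72 h is measured in hours, against a 5-min grid), so single-window peak
estimates scatter by a few grid steps under realistic noise; 6-day windows
are markedly tighter. This is a property of the estimator at short record
lengths, not of the implementation.

## Detrended fluctuation analysis

Counts are mean-centered and integrated; for each scale `n` the profile is
cut into ⌊N/n⌋ non-overlapping windows in a forward pass plus a backward pass
(so the tail is used), each window is detrended by an order-1 polynomial, and
`F(n)` is the pooled RMS residual. The exponent is the least-squares slope of
log F on log n. The implementation is verified against a naive per-window
reference to 1e-10 and is exactly affine-invariant. Defaults: ~15 log-spaced
scales from 6 epochs to N/4 for generic use; the *pipeline* fixes the fit
range at 8–48 epochs (40 min–4 h on 5-min epochs, ≥ 12 distinct scales).
The sub-circadian upper end is deliberate: above ~4 h the 24-h rhythm
dominates `F(n)` and the "exponent" measures rhythm strength, not noise
structure. The same range is used when recovering the generator's Hurst
parameter, and it is the range on which σ was calibrated. White noise,
fGn(H = 0.8) and integrated white noise come out at 0.5, 0.8 and 1.5 within
the suite's tolerances on 2^14-point series.

## Active-phase detection

The algorithm follows the published rule set exactly: 5-min epochs, sliding
Gaussian smoothing with a 4-h window, "active" = above the individual's
average, bouts merged across gaps of at most 1 h, one active phase per LD
cycle.

Numerical choices the rule set leaves open, fixed here and recorded in the
outputs:

* "4-h window" is read as the *total* kernel span, with σ = span/4 = 1 h and
  truncation at 2σ; weights renormalize where the window is clipped at the
  record edges, so a constant series maps to itself. A different σ can be
  passed explicitly (`sigma_hours`).
* "The individual's average" is the mean of the *smoothed* series over the
  analysis window (equal to the raw mean up to edge effects), applied per
  window rather than per lifetime.
* "Gaps no larger than 1 h" is inclusive: a gap of exactly 12 five-minute
  epochs merges.
* Each merged bout is assigned to the LD cycle whose window
  (dark onset − 6 h, dark onset + 18 h] contains the bout midpoint; the −6 h
  reach keeps anticipatory onsets attached to the correct night. If several
  bouts land in one cycle the longest is the cycle's active phase and the
  rest are flagged secondary.
* Onset/offset are reported unwrapped relative to the assigned cycle (dark
  onset = ZT 12), so an offset 42 min past lights-on reads 24.7 and
  duration = offset − onset stays linear; wrapped ZT values are also
  emitted. Summaries average over cycles on the unwrapped axis.
* Smoothing is restarted per analysis window, not carried across the LD/DD
  regime boundary.

On a noiseless 12-h dark-locked box the detected duration is within one
epoch of 12 h because the mean threshold bisects the symmetric smoothed
edges. On the simulated rigid-gating phenotype the mean detected duration is
~11.5 h rather than 12: its within-night cosine hump raises the window mean
above the box edges, so the above-mean crossings sit slightly inside the
gate. This is an honest property of mean-threshold detection on a
hump-on-box profile, and it is left as is.

## What the validation does and does not show

The acceptance-style suite validates the pipeline on data whose generating
parameters are known: DFA calibration on canonical noise classes, exactness
of cosinor and periodogram on their model classes, the active-phase rule
set on constructed masks, and — over 20 simulation seeds — the separation of
the control and rigid-gating phenotypes on every entrainment signature
(anticipatory onset, shortened active phase, forced-resynchronization
acrophase delay present only with slow re-entrainment, LD-vs-DD exponent gap
present only with rigid gating, immediate vs lagging re-locking after a 6-h
advance).

Parameter recovery is tested with photic gating disabled (`gate_floor = 1`):
under a gate, the cosinor acrophase estimand is a mixture of the gate box
and the endogenous cosine, so the generator's acrophase parameter is not
what the estimator estimates; the gated presets are instead exercised by the
end-to-end contrast suite. Recovery tolerances: expressed period within
5 min (mean over 10 six-day simulations), acrophase within 0.5 h per seed,
Hurst within 0.05 (mean over 10 seeds), amplitude rank order exact on the
depth grid {0, 0.25, 0.5, 0.75, 1} at fixed noise.

The generator emulates circadian modulation, photic gating, re-entrainment
dynamics and long-range-correlated rate noise. It does **not** emulate
ultradian feeding bouts, antenna dropout or collisions, multi-animal
interference in a shared cage, weekend husbandry disturbances, or
age-dependent parameter drift within one recording. Passing tests therefore
establish correctness of the *estimators* and internal consistency of the
*models*, not that any particular laboratory system is described by these
presets.

Problem sizes in the default suites were chosen to keep the full test run
around ten seconds on one core: 2^14 points for noise-class DFA, 6-day
records for period estimation, 3-cycle windows for entrainment metrics,
7-day DD segments for Hurst recovery, 20 seeds for the contrast suite.

## Known limitations

* The periodogram grid step equals one 5-min epoch; finer steps would
  require sub-epoch folding, which is out of scope.
* No crossover detection in DFA: a single global fit over the chosen scale
  range.
* Population-mean cosinor inference (group-level statistics) is deliberately
  not implemented; the pipeline emits tidy per-animal tables for external
  statistical tooling.
* The DD cosinor period is taken from the periodogram peak of the same
  window, so their errors are not independent.
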