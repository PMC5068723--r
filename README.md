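# actirhythm

Circadian rhythm analysis of home-cage actigraphy in R.

Spontaneous locomotor activity of group-housed rodents can be recorded
continuously as RFID "visit" events — each visit is the interval during which
an animal is read by the same antenna, and each visit onset is one activity
count. `actirhythm` turns such event streams into the standard circadian
readouts used to characterize light–dark (LD) entrainment and its disorders:

* **Cosinor rhythmometry** — least squares fit of
  `y(t) = M + A·cos(2π(t − φ)/τ)` at a fixed trial period τ, giving the mesor
  `M` (rhythm-adjusted mean), amplitude `A` (half the peak-to-trough range)
  and acrophase `φ` (time of the fitted peak, reported in zeitgeber-time
  hours; ZT 0 = lights-on, so the dark phase of a 12:12 cycle spans
  ZT 12–24).
* **χ²-periodogram** (Sokolove–Bushell) — the series is folded at each trial
  period `P` on a 20–25 h grid with 5-min resolution and scored with
  `Q_P = N · Σ_h n_h (M_h − M̄)² / Σ_i (x_i − M̄)²`, which is ~χ²(P−1) under
  white noise; the circadian period is the highest peak.
* **Detrended fluctuation analysis (DFA)** — root-mean-square fluctuation of
  the integrated, per-window linearly detrended series against window size on
  a log–log axis. Uncorrelated noise gives a scaling exponent near 0.5,
  healthy fractal-like activity about 0.8, and a dominant regular rhythm
  pushes it higher.
* **Active-phase detection** — activity counts in 5-min epochs are smoothed
  with a sliding 4-h Gaussian window; epochs above the individual's window
  mean are "active"; runs of active epochs separated by gaps of at most 1 h
  merge into the day's active phase, whose onset, offset (unwrapped past
  lights-on when activity spills over) and duration are reported per LD
  cycle.
* **Study orchestration** — segmentation of a recording into acclimation,
  baseline LD, free-running (last 72 h of constant darkness, DD), forced
  resynchronization and phase-advance windows; a metrics table per
  animal × window; per-cycle response to a 6-h phase advance; double-plotted
  actogram matrices.

Because raw recordings of this kind are rarely public, the package includes a
**synthetic actigraphy generator**: an inhomogeneous Poisson process whose
rate is a circadian cosine × a photic gate tied to the light schedule × a
log-normal long-range-correlated noise factor built from exact fractional
Gaussian noise (Davies–Harte). Phenotype presets (`control`, `dex`, `mehg`)
encode healthy entrainment, rigid light-driven gating, and low-amplitude
rhythms, so every stage of the pipeline can be validated against known ground
truth. A damped-cosine generator for sparse clock-gene expression courses
(6–36 h post-synchronization) supports the same cosinor analysis in vitro.

## Worked example

Simulate one healthy (`ctrl`) and one rigidly light-gated (`dex`) animal for
three 12:12 LD cycles and run the full analysis chain:

```r
library(actirhythm)
t0 <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")
sched <- ld_schedule(t0, days = 3)                      # lights on 06:00
cfg <- simulation_config(sched,
  list(ctrl = preset("control"), dex = preset("dex")), seed = 42)
ev <- simulate_activity(cfg)

b <- bin_events(ev$ctrl, sched, t0, t0 + 3 * 86400, epoch_seconds = 300)
cosinor_fit(b, trial_period = 24)
#> <cosinor_fit> tau = 24 h, n = 864
#>   mesor 4.721  amplitude 4.364  acrophase ZT 16.322
#>   percent rhythm 57.8%
chi_square_periodogram(b)
#> <chisq_periodogram> 20-25 h grid (61 trial periods)
#>   peak period 23.83 h (Qp = 629.4)
dfa(b, min_scale = 8, max_scale = 48)
#> <dfa_result> N = 864, 15 scales in [8, 48], order-1 detrend
#>   scaling exponent 0.848 (r2 = 0.9822)

ph <- detect_active_phases(classify_active_epochs(gaussian_smooth(b)), sched)
active_phase_summary(ph)
#>   animal_id n_cycles    onset   offset duration
#> 1      ctrl        3 10.80556 22.30556     11.5
```

The control animal's acrophase sits before mid-dark (ZT 16.3 < 18) and its
active phase starts at ZT 10.8 — more than an hour *before* the dark onset at
ZT 12, the behavioral signature of genuine circadian entrainment
(anticipation). Running the same chain on the `dex` animal gives an onset of
ZT 12.2: activity simply follows the lights. Its cosinor acrophase lands at
mid-dark (≈ ZT 18). The periodogram peak (23.83 h here; 3 days is a short
window for a 5-min grid) estimates the expressed period, and the scaling
exponent 0.85 reflects the preset's persistent (Hurst 0.8) activity
fluctuations measured below the circadian scale (40 min–4 h).

## Analysis workflow

The `analysis/` scripts chain the package into the full study design; each
writes tidy CSVs under `results/`:

1. `01_simulate_cohort.R` — 6 animals × 3 phenotypes through
   acclimation → baseline LD → 14 d DD → forced resynchronization.
2. `02_entrainment_metrics.R` — the per-animal × window metrics table and
   group means (amplitude, acrophase, period, scaling exponent, active
   phase).
3. `03_phase_advance.R` — per-cycle response to a 6-h phase advance.
4. `04_actograms.R` — double-plotted actogram matrices.
5. `05_fibroblast_expression.R` — damped-cosine expression courses and their
   cosinor fits.

Run them in order from the repository root: `Rscript analysis/01_simulate_cohort.R` etc.

## Layout

```
R/                  package code (schedules, simulator, cosinor, periodogram,
                    DFA, active phase, study pipeline)
tests/testthat/     unit, property and end-to-end validation suites
analysis/           the numbered workflow scripts
scripts/            acceptance.R
vignettes/          methods vignette (model, parameters, design choices)
```
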