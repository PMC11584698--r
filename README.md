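# cardiophase

Does it matter *when in the cardiac cycle* a movement cue arrives?
Baroreceptor afferents fire most strongly during ventricular systole (R peak
to T-wave offset) and are thought to transiently inhibit cortex, so a cue
delivered in diastole — the quiet phase — may be processed more effectively.
For motor imagery, the readout of "processed more effectively" is
event-related desynchronization (ERD): deeper suppression of alpha
(8–13 Hz) and beta (14–30 Hz) power over the hemisphere contralateral to the
imagined hand. `cardiophase` is an R package for researchers in heart–brain
interaction and motor-imagery BCI work who want to run this analysis
end-to-end on region-level neural traces, one ECG lead and two EMG channels,
or to validate every stage of it against synthetic data with known ground
truth.

## What the pipeline computes

* **Cardiac skeleton** — zero-phase FIR band-pass (0.2–40 Hz), R-peak
  detection with refractory period and polarity check, tangent-method T-wave
  offsets; each cue is labelled systole/diastole (half-open intervals
  [R, T-off) / [T-off, next R)) and given a cycle angle
  θᵢ = 2π (Cᵢ − Rᵢ)/IBIᵢ, with IBIᵢ the mean of the four preceding R–R
  intervals.
* **Cardiac-field artifact removal** by per-channel OLS regression of the
  neural trace on the concurrent ECG.
* **Spectral chain** — epochs [−1, 4) s around the cue, 5-cycle Morlet
  power at 1 Hz bins (8–30 Hz), z-scored to the [−0.5, 0) s baseline,
  averaged to alpha/beta band time courses.
* **EMG chain** — 10 Hz high-pass, full-wave rectification, 100 ms
  moving-RMS envelope, ipsilateral/contralateral assignment per trial.
* **Group statistics** — timewise within-subject permutation tests (500
  sign-flip permutations, two-tailed, add-one convention), adaptive
  two-stage linear step-up FDR control at q = 0.05, probability of
  superiority for dependent samples (Δ_dep) as effect size, and
  trial-count-balancing control runs (10 redraws of the diastole pool down
  to the systole count).
* **Circular statistics** — trial-wise suppression index (ipsilateral minus
  contralateral z power over the significant window), percentile-thresholded
  trial selection (50/75/90), subject- then group-level Rayleigh tests
  (P = exp(√(1+4n+4(n²−R²)) − (1+2n)), R = n·R̄), a 1000-draw Monte-Carlo
  null for the group statistic, and the overlap of the significant window
  with the next systolic interval.
* **Synthetic generator** — coupled ECG/neural/EMG sessions (~8 s trials,
  100+100 cues by default) with programmed phase-dependent ERD depths, EMG
  burst gains, cardiac-field leakage and pink noise; fully seeded, with
  exact ground-truth event times, phases and angles.

## Worked example

Simulate a small study in which contralateral ERD depth is 0.5 for
diastole-timed cues but only 0.2 for systole-timed cues (ipsilateral fixed
at 0.2), then run the full analysis:

```r
library(cardiophase)

cfg <- simulation_config(sampling_rate = 128, n_trials_left = 12,
                         n_trials_right = 12, seed = 1L)
sessions <- simulate_study(8, cfg, seed = 1L)
report <- run_pipeline(sessions, run_config(seed = 1L))
print(report)
#> phase_report: 8 subjects, window 0.50-2.00 s, 500 permutations
#>   M1.alpha laterality: all 132 sig; systole 0 sig; diastole 192 sig
#>   M1.beta laterality: all 192 sig; systole 0 sig; diastole 192 sig
#>   S1.alpha laterality: all 192 sig; systole 0 sig; diastole 192 sig
#>   S1.beta laterality: all 192 sig; systole 0 sig; diastole 192 sig
```

Every region/band shows sustained FDR-significant laterality in the
diastole-cued subset (all 192 time points of the 0.5–2 s window) and none in
the systole-cued subset — exactly the programmed asymmetry. Drilling into
one contrast:

```r
print(report$neural[["S1.alpha"]]$diastole)
#> timewise_test: 192 time points, 8 subjects, 500 permutations
#>   192 significant points (P_FDR = 0.001996-0.03992), delta_dep = 1
```

`delta_dep = 1` means every subject's ipsilateral z exceeded their
contralateral z when averaged over the significant window. The
suppression-index circular analysis reports, per region/band/percentile, the
group mean resultant length R̄, Z = nR̄², the approximate p and a Monte-Carlo
p (`report$circular`); the overlap summary (`report$overlap`) gives the mean
intersection of the significant window with the next systolic interval in
seconds. Reports are written to disk with `write_report(report, dir)` as
JSON plus one TSV per timewise contrast.

The Rayleigh machinery is also usable standalone, e.g. the p-value for 29
subject mean directions with mean resultant length 0.3229:

```r
rayleigh_p(29, 0.3229)
#> [1] 0.04729634
```

## Package layout

* `R/simulate.R` — synthetic session/study generator and configuration
* `R/cardiac.R` — ECG preprocessing, R/T delineation, phase & angle
  labelling, artifact regression
* `R/spectral.R` — epoching, Morlet power, baseline z-score, band averaging
* `R/emg.R` — EMG envelopes and ipsi/contra assignment
* `R/group_stats.R` — timewise permutation tests, adaptive FDR, Δ_dep,
  control draws
* `R/circular.R` — suppression index, trial selection, Rayleigh tests,
  Monte-Carlo null, systole overlap
* `R/orchestration.R` — `run_pipeline()` and `run_config()`
* `vignettes/cardiac-phase-pipeline.Rmd` — the methods account: model,
  assumptions, parameter choices, numerical caveats, limitations
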