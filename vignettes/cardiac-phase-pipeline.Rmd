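---
title: "Cardiac-phase-resolved analysis of sensorimotor rhythm suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-phase-resolved analysis of sensorimotor rhythm suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiophase)
```

## The scientific question

Baroreceptors fire most strongly during ventricular systole — the interval
from the R peak of the ECG to the offset of the T wave — and their afferent
volleys are thought to transiently dampen cortical excitability ("pulse
inhibition"). If a movement cue arrives during systole, the sensory
processing of that cue may therefore be blunted, and the downstream
sensorimotor response weakened. The signature of interest is event-related
desynchronization (ERD): after a cue to move (or to imagine moving) one
thumb, alpha (8–13 Hz) and beta (14–30 Hz) power over the *contralateral*
primary motor (M1) and somatosensory (S1) cortex drops below baseline. The
pipeline in this package asks whether that contralateral suppression is
deeper and more sustained when the cue falls in diastole than in systole,
and whether lateralized EMG activity shows the same phase preference.

The package operates on region-level neural traces (M1/S1 by hemisphere), a
single ECG lead and two EMG channels, together with a cue table
(onset, side, task). How those region traces are obtained (e.g. by source
reconstruction of scalp EEG) is outside its scope.

## The processing model, stage by stage

**Cardiac skeleton.** The ECG is band-pass filtered 0.2–40 Hz with a
zero-phase FIR filter (symmetric windowed-sinc kernel applied once with
group-delay compensation, which is exactly zero-phase; transition width
0.2 Hz). R peaks are detected by thresholded peak picking with automatic
polarity correction and a 250 ms refractory period. T-wave offsets use the
tangent method: within a search window from R + 150 ms to R + 0.6 IBI, the
tangent through the steepest point of the descending T limb is intersected
with a local late-diastolic baseline level. Beats without a credible T wave
are flagged and their cues excluded rather than interpolated — the cost of a
dropped trial is far lower than that of a mislabelled phase.

**Phase and angle of each cue.** Systole is the half-open interval
[R, T-offset); diastole is [T-offset, next R). A cue exactly at the T-wave
offset is diastolic, exactly at R systolic — deterministic tie-breaks,
stated rather than left to chance. For circular statistics each cue is also
given an angle

$$\theta_i = 2\pi\,\frac{C_i - R_i}{\mathrm{IBI}_i} \pmod{2\pi},$$

where $C_i$ is the cue onset, $R_i$ the preceding R peak and
$\mathrm{IBI}_i$ the mean of up to four preceding R–R intervals. Averaging
several beats makes the normalization robust to a single mis-delineated
beat; when fewer than four intervals exist the available ones are averaged.
Latencies longer than the averaged cycle wrap around the circle, since the
Rayleigh statistics below only make sense for angles on $[0, 2\pi)$.

**Cardiac-field artifact.** The heartbeat leaks electrically into neural
channels. Per channel, the neural trace is regressed on the concurrent ECG
(ordinary least squares across all epoch samples pooled; a per-epoch mode
exists but the pooled slope is stabler), and only the ECG-aligned component
is subtracted, leaving the channel mean untouched. The operation is
idempotent and a no-op when no leakage exists.

**Spectral chain.** Epochs span $[-1, 4)$ s around each cue (half-open at
the sample grid, so shapes are unambiguous: 5 s × rate samples). Power is
computed by convolution with 5-cycle complex Morlet wavelets at one bin per
integer frequency, 8–30 Hz, over the full epoch; the first and last 0.3 s
never enter any statistic, so wavelet edge effects cannot. Power is z-scored
to the $[-0.5, 0)$ s pre-cue baseline and averaged into alpha (6 bins) and
beta (17 bins) band time courses.

One numerical property of the z-scoring deserves a warning. With per-trial
baseline statistics (the default convention), a 0.5 s baseline contains only
about two independent wavelet samples at 8 Hz, so the baseline SD is a very
noisy estimate and the post-cue z of even a perfectly stationary signal has
a positive expectation (about +0.6 at 8 Hz, shrinking rapidly with
frequency). This bias is identical for the two hemispheres and cancels
exactly in every paired ipsilateral-vs-contralateral contrast the pipeline
reports, but absolute z values at low frequencies should not be
over-interpreted. A trial-pooled baseline mode (`mode = "pooled"` in
`baseline_zscore()`), whose estimator is consistent, is available for
analyses that need unbiased absolute levels.

**EMG chain.** EMG is high-pass filtered at 10 Hz (zero-phase FIR),
full-wave rectified and smoothed with a 100 ms moving-RMS window. The
literature phrase "filtered at 10 Hz" is ambiguous; a low-pass reading would
destroy the EMG band, so the high-pass interpretation is used and both the
cutoff and window are configurable. Channels are mapped per trial to the
hand ipsilateral/contralateral to the cue.

**Group statistics.** Contrasts are paired at the subject level: one average
time course per subject and condition. At each time point the statistic is
the group mean of the paired differences; the null is built from 500 random
sign flips of each subject's whole difference trace (the flip pattern is
shared across time, preserving the temporal correlation structure of the
null). Sign flipping is the exact pairing-preserving null when the
permutation scheme is otherwise unspecified; the mean difference is the
default statistic. Two-tailed p-values use the add-one convention
$p = (\#\{|\mathrm{null}| \ge |\mathrm{obs}|\} + 1)/(n_{\mathrm{perm}}+1)$,
which can never return zero. The family of time points is corrected with the
two-stage adaptive linear step-up procedure at $q = 0.05$: a first
Benjamini–Hochberg pass at $q/(1+q)$ estimates the true-null count, a second
pass at the adjusted level recovers power when much of the family carries
signal. Effect sizes are the dependent-samples probability of superiority
$\Delta_{dep} = (\#\{x_i > y_i\} + \tfrac12\#\{x_i = y_i\})/n$, computed on
subject values averaged over each contrast's significant window.

A granularity caveat: with $n$ subjects the sign-flip null has only $2^n$
distinct patterns, so p-values are discrete with floor roughly $2^{1-n}$
(two-tailed). Group analyses should use at least 8 subjects at $q = 0.05$;
the recovery simulations in the test suite use 8 for exactly this reason,
and published designs with ~29 subjects are far from the limit.

**Trial-count balancing.** Diastole occupies the larger part of the cycle,
so diastole-cued trials outnumber systole-cued ones. Ten control runs redraw
the diastole (and all-trials) pools with replacement down to each subject's
systole count and repeat the timewise tests, so that sustained
diastole-subset effects cannot be an artifact of trial numbers.

**Circular analysis.** A trial-wise suppression index — ipsilateral minus
contralateral z power averaged over the significant window of the
*all-trials* contrast (chosen independently of cardiac phase to avoid
selection bias; if no window is significant the full 0.5–2 s analysis
window is used and logged as a fallback) — selects trials above each
subject's 50th/75th/90th percentile. The angles of selected trials enter a
subject-level Rayleigh test; subject mean directions, taken as unit vectors,
enter a second-order group Rayleigh test. The p-value uses the standard
small-sample approximation
$P = \exp\!\big(\sqrt{1+4n+4(n^2-R^2)}-(1+2n)\big)$ with $R = n\bar R$.
Because published values named "Rayleigh's Z" are sometimes numerically the
mean resultant length $\bar R$ rather than $n\bar R^2$, the package always
reports $\bar R$, $Z = n\bar R^2$ and $p$ separately. The unit-vector
second-order test discards subject-level concentration — a subject with
$\bar R_s = 0.1$ counts as much as one with $\bar R_s = 0.9$; this is a
documented property of the design, not repaired silently, and a
$\bar R_s$-weighted mode is available. The observed group statistic is also
compared against a Monte-Carlo null (1000 permutations of uniform angles
drawn per trial and subject, then aggregated exactly like the data), which
respects the per-subject trial counts. Finally, for diastole-cued trials the
temporal overlap between the significant suppression window and the *next*
systolic interval is summarized per subject — if suppression outlasts the
brief systole that follows the cue, the effect is not merely a systolic
echo.

## The synthetic generator

Real recordings of this kind are rarely shareable, so every stage is
validated against `simulate_session()`, which produces coupled signals with
known ground truth:

* **ECG** — stereotyped beats of Gaussian P/R/T bumps at R times drawn from
  a truncated normal IBI distribution (default 0.9 ± 0.05 s; the T bump is
  centered $2\sigma_T$ before the programmed T offset so the tangent rule
  recovers the offset analytically). The T offset of beat $k$ sits at
  $R_k + f_{\mathrm{sys}}\,\mathrm{IBI}_k$ with $f_{\mathrm{sys}} = 0.35$,
  giving a mean systole of ~0.32 s, inside the 243–546 ms range typical of
  resting adults.
* **Neural channels** — pink noise plus alpha and beta oscillators whose
  amplitude drops inside the 0.5–2 s post-cue window: by 0.5 contralaterally
  for diastole-timed cues, 0.2 contralaterally for systole-timed cues, 0.2
  ipsilaterally (all configurable), plus `artifact_gain` × ECG.
* **EMG** — white baseline noise plus a Hann-enveloped noise burst after
  each cue, larger on the ipsilateral hand and multiplied by 1.3 when the
  cue is diastolic.
* **Cues** — an 8 s trial grid jittered by ±0.25 s, which decouples the
  trial rhythm from the heartbeat and makes cue angles effectively uniform
  on the cycle; sides are randomly interleaved (defaults 100 + 100,
  matching a motor-imagery session; 25 + 25 for a motor-execution block).

Each channel's noise comes from an independent substream derived from the
master seed, so sessions are bit-reproducible and stages can be re-run
independently. What the generator does *not* emulate: volume conduction and
scalp topography (it emits region traces directly), heart-rate variability
beyond independent Gaussian IBIs, respiratory or movement artifacts,
non-stationary background spectra, and any genuine physiological coupling
between cardiac phase and neural noise. Passing tests therefore demonstrate
that the *pipeline* recovers what was programmed under realistic noise — not
that real cortex behaves this way.

## Default parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| epoch window | [-1, 4) | s | covers baseline and the full trial |
| baseline | [-0.5, 0) | s | pre-cue, clear of the previous trial |
| analysis window | [0.5, 2) | s | movement onset ~1 s post cue; [0.5, 4) exploratory mode |
| wavelet cycles | 5 | — | standard time/frequency compromise |
| edge exclusion | 0.3 | s | > half a 5-cycle wavelet at 8 Hz |
| permutations | 500 | — | p floor 1/501, ample for q = 0.05 |
| FDR level q | 0.05 | — | convention |
| control runs | 10 | — | trial-count balancing |
| percentiles | 50/75/90 | — | suppression-trial selection |
| Monte-Carlo draws | 1000 | — | circular null |
| refractory | 0.25 | s | maximum plausible heart rate |

## Simulation scales used by the test suite

The suite runs everything at 128 Hz — every signal of interest lives below
40 Hz, so this retains full fidelity at a quarter of the typical recording
rate. Type-I suites use 200 replicates (12 subjects × 150 time points for
the timewise chain; 29 subjects × 190 trials for the circular chain).
Recovery suites use 20 independent studies of 8 subjects × 24 trials
(8 subjects being the sign-flip granularity minimum discussed above) for
the laterality effect, and 29 subjects × 95 selected trials (von Mises
concentration κ = 1 at 4.0 rad) for the circular effect. These sizes were
fixed as a scaled study design before the suites were run; the programmed
effect sizes are the module defaults.

## Known limitations

* The tangent T-offset rule assumes a single-peaked T wave; biphasic T
  waves would be flagged missing rather than delineated.
* The second-order group Rayleigh test ignores subject-level concentration
  (see above).
* Per-trial baseline z carries a low-frequency positive bias (see above);
  all shipped contrasts are immune, custom absolute-level analyses should
  use the pooled mode.
* The pipeline consumes region-level traces; nothing in it corrects for
  volume conduction or source leakage.
* `simulate_study()` varies only heart rate across subjects; real
  between-subject variability (ERD depth, latency, spectra) is wider, so
  group-level power on real data will be lower than on synthetic data at
  equal n.
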