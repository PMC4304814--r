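---
title: "Latency-compensated ERP analysis with erpride"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency-compensated ERP analysis with erpride}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpride)
```

## The problem

An event-related potential (ERP) is estimated by averaging EEG epochs
time-locked to a stimulus. Averaging assumes every component occurs at the
same post-stimulus latency in every trial. For late endogenous components —
the N400 (semantic integration difficulty) and the P600 (syntactic
reanalysis/repair) — that assumption is wrong: their single-trial latencies
vary by tens of milliseconds. A component of temporal width $w$ whose
latency jitters with standard deviation $\sigma$ survives averaging with
only a fraction

$$\frac{w}{\sqrt{w^2 + \sigma^2}}$$

of its single-trial peak (for a Gaussian bump under Gaussian jitter; see
`smearing_factor()`). Smearing attenuates between-condition amplitude
differences, so a real effect can look absent — or two conditions that
differ can look alike.

`erpride` implements a two-track analysis of such data:

1. **Conventional track** — stimulus-locked averaging, window amplitudes,
   and fully-within-subjects repeated-measures ANOVA.
2. **Reconstructed track** — residue iteration decomposition (RIDE), which
   estimates per-trial component latencies, decomposes the single trials
   into a stimulus-locked cluster `S` plus two latency-variable clusters
   `C1` (N400 complex) and `C2` (P600 complex), and rebuilds a
   latency-compensated ERP with every cluster placed at its most probable
   latency.

The intended design is a three-condition sentence-reading experiment:
congruent (`CON`), semantic violation (`SEM`), and combined
semantic-plus-syntactic violation (`SEM+SYN`), with ~40 trials per
condition and 18 subjects on a 38-channel 10–20 montage at 500 Hz.

## The RIDE model

A single trial $i$ at channel $c$ is modelled as

$$x_{ic}(t) = S_c(t) + C1_c(t - \tau^{1}_i) + C2_c(t - \tau^{2}_i) + \varepsilon_{ic}(t),$$

with cluster waveforms shared across trials and per-trial latencies
$\tau_i$. Fitting alternates two steps until convergence (`ride()`):

* **Latency estimation.** Initial latencies come from Woody's adaptive
  filter (`woody_latency()`): a template (the trial average over the
  latency channels, restricted to the search window) is cross-correlated
  with each trial; the arg-max lag is that trial's latency; the template is
  re-averaged at the aligned latencies and the procedure repeats until the
  assignments stabilize. Search windows default to 200–600 ms for C1 and
  400–800 ms for C2. In later iterations latencies are updated the same
  way, but against the current cluster template after subtracting the other
  two clusters from each trial (`update_latencies()`). Matching uses the
  normalized cross-correlation (cosine) criterion, the classical Woody
  choice; it proved slightly more robust than the raw inner product on
  simulated data.
* **Decomposition.** Given latencies, cluster waveforms are re-estimated by
  iterative subtraction (`decompose_components()`): for each cluster in
  turn, subtract the current estimates of the other clusters (each shifted
  to its own trial latency), align the residual trials to the target
  cluster's latencies, and take the pointwise **median** across trials —
  the robust variant of the algorithm; the median resists residual
  mis-alignment and outlier trials. Each cluster is restricted to its
  window with a 50 ms raised-cosine roll-off so subtraction introduces no
  hard edges. All shifts are non-circular at integer samples (2 ms at
  500 Hz), zero-filled with a cosine edge taper.

The reconstructed ERP (`reconstruct_erp()`) is $S + C1 + C2$ with C1 and C2
placed at the median of their trial latencies ("most probable latency";
since latencies are median-centered this is the template position).

### Numerical behaviour and convergence

Two properties of this estimator shaped the implementation, and both are
visible in simulation:

* The inner decomposition is a coordinate-descent scheme whose slowest mode
  — exchange of broad, low-frequency structure between the full-epoch `S`
  cluster and the windowed jittered clusters — contracts with a ratio of
  roughly 0.96–0.99 per sweep. Exact fixed-point convergence would need
  thousands of sweeps while the scientifically relevant quantities (peaks,
  window means) settle far earlier. The loop therefore stops when the
  relative RMS waveform change per sweep falls below `tol` (default `1e-3`,
  max 100 sweeps) and is warm-started across outer iterations.
* With integer-sample lags the cross-correlation arg-max is flat near its
  peak, so latency assignments can flip forever between neighbouring
  samples. A small hysteresis (a trial keeps its current latency when its
  score is within `2e-3` of the maximum) lets the outer loop settle. The
  fit is flagged `converged` when the median absolute latency change drops
  below one sample and the decomposition met its tolerance; a condition
  that carries no sizeable latency-variable component (e.g. `CON`, where
  the N400 cluster is absent) never settles — its latency estimates chase
  noise — and is honestly flagged unconverged after the residual stops
  improving.

A useful exact property: the decomposition is channel-wise independent
given the latency sets, and latency updates read only the configured
latency channels (default Cz, CPz, Pz — the centro-parietal sites where
N400/P600 are maximal). `ride()` therefore runs its outer loop on the
latency channels only and decomposes the full montage once at the final
latencies; `subset_channels()` exposes the same trick when only latencies
are needed.

## The synthetic generator

`simulate_subject()`/`simulate_trials()` generate the statistical structure
the analysis assumes, with full ground truth:

* **S**: early fronto-central positive Gaussian bump (170 ms, width 30 ms,
  4 µV), stimulus-locked (zero jitter).
* **C1**: N400-like centro-parietal negative bump (400 ms, width 50 ms),
  amplitude 0 in `CON` and −3 µV in both violation conditions — the
  "semantic violation effect equal in SEM and SEM+SYN" pattern.
* **C2**: P600-like centro-parietal positive bump (650 ms, width 80 ms),
  ordered `SEM+SYN` (4 µV) > `SEM` (2.5 µV) > `CON` (0.5 µV).
* Latencies of C1/C2 are truncated-Gaussian (±3 SD, re-drawn on violation)
  with SD 40 ms by default — published reading studies rarely quantify
  their single-trial latency variability, so 30–60 ms is treated as a free
  parameter of the test bed, not an estimate of any real dataset.
* Noise is AR(1) with ρ = 0.95 scaled to 8 µV by default; temporally
  correlated noise is markedly less favourable to latency estimation than
  white noise, hence the realistic default. A per-subject amplitude offset
  (SD 1 µV) makes the between-subject ANOVA error strata non-degenerate.
* Scalp topographies are Gaussian fall-offs on a schematic 2-D layout of
  the montage; mastoid channels carry noise only, so re-referencing can be
  exercised; optional contamination plants >80 µV spikes in known trials
  for artifact-rejection tests.

What the generator does **not** emulate: biophysical volume conduction
(channels share a smooth gain map but noise is channel-independent), ocular
artifacts, non-Gaussian latency distributions, overlap from adjacent
stimuli, and drifting impedances. Passing recovery tests on this generator
therefore shows the estimator is correct under its own assumptions — not
that those assumptions hold for any particular real recording.

### Validation scenarios

The test suite fixes these scenarios once (seeds included) and checks:

* zero jitter + zero noise → reconstruction equals the conventional
  average (<1% RMS per channel) and the fit converges immediately;
* jitter σ = 50 ms on a width-50 ms C1, 200 trials, 0.5 µV noise →
  conventional peak = 0.707 ± 0.03 of the single-trial peak (the closed
  form), RIDE recovers ≥ 90% (closed-form checks run at low noise so that
  Monte-Carlo error does not mask the quantity being tested);
* single-trial peak = 2× noise SD, 100 trials → estimated-vs-true C1
  latency correlation averages ≥ 0.8 over ten seeded replicates;
* on converged zero-noise fits the trial-average of the summed shifted
  clusters matches the conventional average within 2% RMS (completeness is
  checked without noise because the model average contains no noise term
  while the conventional average does, and the two would otherwise differ
  by the averaged noise rather than by decomposition error);
* the full 18-subject pipeline reproduces the qualitative pattern: no
  SEM vs SEM+SYN difference in the 300–500 ms window, a SEM+SYN > SEM
  difference in the late window, with the reconstructed-track effect size
  at least the conventional one.

## Statistics

`rm_anova()` fits the standard fully-within-subjects partition (1–3
factors; each effect tested against its own effect-by-subject interaction)
via `stats::aov` on a balanced long table, and adds:

* **Greenhouse–Geisser ε** per effect, from the eigenvalues of the
  covariance of orthonormal contrast scores
  (ε̂ = (Σλ)² / (d·Σλ²), clipped to [1/d, 1]); for multi-factor effects the
  data are averaged over the factors not in the effect and the contrast
  basis is the Kronecker product of the per-factor bases. Corrected and
  uncorrected p-values are always reported side by side; no sphericity
  pre-test gates the correction.
* **Partial η²** = SS_effect / (SS_effect + SS_error), the convention
  consistent with reported within-subject effect sizes.

`planned_pairwise()` runs paired two-sided t-tests per condition pair and
unit, uncorrected by default (Holm optional); a pair with zero within-pair
variance is flagged degenerate rather than reported as an infinite t.
`simple_effects()` runs the one-way condition ANOVA inside each stratum
level. The default designs mirror the intended study: midline
(3 conditions × 8 electrodes) and lateral (3 conditions × 3 regions ×
2 hemispheres, ROIs of four electrodes each). The two analysis windows are
300–500 ms and 570–810 ms for the conventional track; the late window of
the reconstructed track is 500–800 ms, where the latency-compensated P600
effect concentrates.

The type-I calibration check simulates null amplitude tables directly at
the window-amplitude level (`simulate_null_table()`: subject intercepts +
fixed electrode effects + independent noise, no condition effect) rather
than through the full EEG chain — 1000 end-to-end pipelines would be
prohibitive, and the property under test (calibration of the GG-corrected
F test) lives entirely at the table level.

## Preprocessing choices

* Band-pass: 4th-order Butterworth, 0.02–30 Hz, applied forward-backward
  (`signal::filtfilt`) so the filter is zero-phase — latency comparisons
  cannot tolerate group delay. Both continuous and epoched entry points
  exist; the pipeline filters continuous data by default.
* Epochs span −200…1000 ms (half-open at the sample level, 600 samples at
  500 Hz); baseline is the mean over [−200, 0) ms, subtracted per trial and
  channel; baseline correction is idempotent.
* Artifact rejection drops a trial when any scalp channel exceeds ±80 µV
  after re-referencing and baseline correction (the screening order is not
  universal; this package fixes it in that order). EOG channels are
  excluded from the screen. Rejected trials are dropped, never imputed, and
  per-condition counts are logged.
* Re-referencing subtracts the mean of the two mastoids from every channel.

## I/O

The epochs container is a delimited-text layout (header lines for `fs` and
`subject_id`; one row per trial and channel, one column per sample) written
and read by `write_epochs()`/`read_epochs()` — a deliberately simple,
diff-able format. Continuous recordings can be read from plain 16-bit EDF
(`read_edf()`, a minimal reader for equal-rate signals) together with a
tab-separated events table, then cut with `epoch_recording()`. Montage and
ROI definitions ship as YAML (`roi_layout()`). Note the posterior ROIs use
PO5/PO6, the sites actually present in the 38-channel montage.

## Known limitations

* No response-locked cluster: the design has no overt response during the
  critical word, so RIDE is configured for S/C1/C2 only.
* Integer-sample latencies (2 ms resolution); no sub-sample refinement.
* The amplitude of a reconstructed cluster can overshoot the true value by
  ~5–15% at low SNR because latency estimates partially align noise — a
  known property of latency-resynchronized averages; comparisons between
  conditions remain valid because the bias is shared.
* `rm_anova()` supports within-subject factors only (no grouping factors),
  matching the intended design.
* The generator's problem sizes used in the test suite (e.g. 100–200-trial
  single-subject runs, one 18-subject pipeline) were chosen to exercise the
  study-scale design while keeping the whole suite comfortably runnable on
  a laptop.
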