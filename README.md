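# erpride

Two-track analysis of event-related potentials (ERPs): conventional
stimulus-locked averaging side by side with **residue iteration
decomposition (RIDE)**, which compensates trial-to-trial component latency
variability and reconstructs an un-smeared ERP.

## The problem

Averaging EEG epochs time-locked to a stimulus assumes each component
occurs at the same latency on every trial. Late components such as the
N400 and P600 violate that assumption: their single-trial latencies jitter
by tens of milliseconds, and a Gaussian component of width *w* under
latency jitter of SD *σ* keeps only

&nbsp;&nbsp;&nbsp;&nbsp;*w* / √(*w*² + *σ*²)

of its single-trial peak after averaging (`smearing_factor()`). Amplitude
differences between experimental conditions are attenuated accordingly.
RIDE separates the single trials into a stimulus-locked cluster **S** and
two latency-variable clusters **C1** (N400 complex, searched in
200–600 ms) and **C2** (P600 complex, 400–800 ms), estimates per-trial
latencies by Woody-style template matching plus cross-correlation
updating, decomposes the trials by iterative subtraction with a pointwise
median across latency-aligned trials, and rebuilds the ERP with every
cluster at its most probable latency.

The package targets three-condition sentence-violation designs (congruent
`CON`, semantic violation `SEM`, combined violation `SEM+SYN`; 38-channel
10–20 montage, 500 Hz, ~40 trials per condition, 18 subjects) and includes:

* epoched-EEG preprocessing: zero-phase 0.02–30 Hz band-pass, mastoid
  re-referencing, baseline correction, ±80 µV artifact rejection;
* a synthetic single-trial generator with full ground truth (jittered
  N400-like and P600-like clusters, AR(1) noise, planted artifacts);
* window amplitudes (300–500 ms; 570–810 ms conventional / 500–800 ms
  reconstructed), difference topographies, grand averages;
* fully-within-subjects repeated-measures ANOVA with Greenhouse–Geisser
  correction and partial η², planned pairwise comparisons, simple effects;
* an end-to-end pipeline exporting tidy CSV tables plus a run manifest,
  and a thin CLI (`inst/exec/erpride`).

## Worked example

Simulate one subject, fit RIDE to the semantic-violation trials, and
compare the reconstruction with the conventional average:

```r
library(erpride)
cfg <- sim_config(n_subjects = 1, trials_per_condition = 40, seed = 11,
                  noise_sd = 1, include_mastoids = FALSE,
                  components = default_components(latency_sd = 50))
sim <- simulate_subject(cfg)
fit <- ride(sim$epochs, condition = "SEM")
summary(fit)
```

```
RIDE fit: SEM - 40 trials
  4 outer iteration(s); converged: TRUE
  residual RMS trace: 1.083 -> 1.075 -> 1.069 -> 1.061
  cluster latency SD (ms): S=0.0, C1=52.1, C2=74.7
  cluster peak amplitude (muV): S=4.19, C1=-2.57, C2=2.19
```

The conventional average of these trials retains only 66% of the true
3 µV N400 peak (close to the closed-form 50/√(50²+50²) ≈ 0.71 under the
simulated 50 ms jitter), while the reconstruction recovers it in full
(with a mild overshoot at this noise level); the estimated per-trial C1
latencies correlate at r = 0.96 with the generator's ground truth.
`plot(fit)` overlays both tracks and the three cluster waveforms.

The full study-scale analysis is one call:

```r
res <- run_pipeline(pipeline_config(seed = 7, out_dir = "out"))
res
```

```
<erp_pipeline> 18 subject(s), seed 7
ANOVA condition effects (midline):
  conventional.N400.midline    F(2, 34) =  19.41, p_gg = 2.29e-05, pes = 0.533
  conventional.P600.midline    F(2, 34) =  23.50, p_gg = 7.204e-07, pes = 0.580
  reconstructed.N400.midline   F(2, 34) =  16.75, p_gg = 0.0002396, pes = 0.496
  reconstructed.P600.midline   F(2, 34) =  26.53, p_gg = 7.219e-07, pes = 0.609
```

Both tracks show strong condition effects in both windows (the simulated
N400 is absent in `CON`, and the P600 is ordered `SEM+SYN > SEM > CON`).
In the late window the SEM+SYN − SEM difference at Pz is +1.12 µV
(p = .013) conventionally and +1.46 µV (p = .013) after reconstruction,
with a larger condition effect size in the reconstructed track
(partial η² .609 vs .580) — the latency-compensated track concentrates the
smeared effect. In the N400 window the two violation conditions do not
differ in either track, matching the generator's ground truth.
`out/` receives `window_amplitudes.csv`, `anova_tables.csv`,
`pairwise_tables.csv`, `difference_topographies.csv`, per-subject evoked
CSVs and `manifest.json`.

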