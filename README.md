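# mreeg

Simultaneous EEG–fMRI recordings are contaminated by MR-induced artifacts
that dwarf the neural signal: the **imaging (gradient) artifact** — a
deterministic, TR-periodic waveform of tens of millivolts composed of
harmonics of the slice repetition frequency convolved with harmonics of the
volume repetition frequency; the **ballistocardiogram (BCG)** — a
heartbeat-locked artifact exceeding 50 µV at 3 T with most of its power
below 25 Hz, right on top of the alpha band; and **helium-pump vibration**
harmonics at and above 30 Hz. `mreeg` is a laboratory for studying how well
the standard correction methods recover known neural signals. It provides:

* a **synthetic session generator** with exact ground truth — task-locked
  neural activity (eyes-open/eyes-closed alpha blocks, finger-tapping
  ERD/ERS, quadrant-checkerboard visual evoked potentials) plus imaging,
  BCG, pump and motion artifacts, six artifact-only carbon-wire-loop (CWL)
  reference channels, an ECG trace, and volume/task markers;
* the **correction methods** under study:
  - *AAS* (average artifact subtraction): channel-wise sliding-mean
    templates over 25 volume epochs (imaging artifact) or 21 heartbeat
    epochs (BCG), subtracted at each occurrence;
  - *OBS* (optimal basis set): per channel, the heartbeat-epoch mean plus
    the first 3 principal components, least-squares fitted to and
    subtracted from every epoch;
  - *CWL regression*: per 4-s Hann window, each EEG channel regressed on
    the six loop signals and their ±21 ms lagged copies, with the fitted
    artifact removed by weight-normalized overlap-add;
  - plus derivative-energy **R-peak detection** for the BCG stage;
* the **evaluation features** used to compare them: Welch power spectral
  densities (2¹² Hamming segments, 50 % overlap, dB scale), band power in
  alpha (8–12 Hz), beta (15–25 Hz) and gamma (70–80 Hz), z-score
  summary-channel selection, contralateral/ipsilateral VEP difference
  waves, sliding-RMS SNR, and RMSD;
* **hierarchical Bayesian comparison models** (via JAGS): a two-level
  varying-intercept/varying-slope regression with per-method residual SDs,
  a pooled per-participant effect-size variant, single-level regressions,
  and a bivariate Student-t robust correlation — all with rank-normalized
  split-R̂, bulk/tail effective sample sizes and MCSE computed natively;
* bit-faithful **BrainVision** (`.vhdr`/`.vmrk`/`.eeg`) reading and
  writing.

The centrepiece, `run_study()`, simulates a cohort, derives the reference
signal (clean neural activity + sensor noise) and the five MR data variants
— `NC` (no correction), `IAR` (imaging-artifact reduction only), `AAS`,
`OBS` (IAR + BCG correction) and `CWL` (IAR + loop regression) — extracts
per-block alpha power, and fits

y<sub>ij</sub> ~ Normal(x<sub>ij</sub>ᵀ(β + u<sub>j</sub>), σ<sub>method</sub>),  u<sub>j</sub> ~ MVN(0, Σ),

with participants *j* as the second level, reporting the eyes-closed minus
eyes-open alpha power difference (ΔPSD, dB) per variant with full
posteriors.

## Worked example

Simulate one session, correct it every way, and compare alpha recovery:

```r
library(mreeg)
library(dplyr)

cfg <- session_config(task = "resting", seed = 7, fs_hz = 500,
                      n_channels = 16, n_blocks = 6, block_s = 10)
session <- assemble_session(cfg)
session$recording
#> <eeg_recording> 23 channels (16 scalp, 6 cwl, 1 ecg) x 33000 samples @ 500 Hz (66.0 s), ref: FCz

variants <- session_variants(session)
fx <- resting_band_features(variants, session)
fx$summary_channels      # channels > 1 SD in the reference EC-EO topography
#> [1] "CP1" "PO7" "PO4"

fx$features |>
  group_by(variant, condition) |>
  summarise(alpha_db = round(mean(power_db), 1), .groups = "drop") |>
  tidyr::pivot_wider(names_from = condition, values_from = alpha_db) |>
  mutate(delta = EC - EO) |>
  arrange(desc(delta))
#>   variant   EC   EO delta
#> 1     REF  8.8  0.5   8.3
#> 2     CWL  6.8 -1.0   7.8
#> 3     OBS  8.1  6.1   2.0
#> 4     AAS 15.3 14.6   0.7
#> 5      NC 24.2 23.9   0.3
#> 6     IAR 22.2 22.8  -0.6
```

The pattern of this single noisy session already tells the story: the raw
(`NC`) and imaging-artifact-corrected-only (`IAR`) data sit on a hugely
elevated alpha-band baseline (the BCG artifact) that masks the eyes-closed
alpha increase; BCG correction (`AAS`, `OBS`) recovers part of the
contrast; loop regression (`CWL`) recovers almost all of it. The full
cohort comparison with posterior uncertainty:

```r
report <- run_study(study_config(seed = 101))   # 8 participants, ~1 min
report
#> <evaluation_report> 8 participants, task resting
#> eyes-closed minus eyes-open alpha power (dB), posterior medians:
#>  variant     median p_positive
#>      REF  9.4410315    1.00000
#>      CWL  8.2397707    1.00000
#>      AAS  1.8982035    0.99225
#>      OBS  4.4636695    1.00000
#>      IAR  1.0328085    0.94750
#>       NC -0.1522349    0.39775
autoplot(report)
```

Only the BCG-corrected variants (`CWL`, `AAS`, `OBS`) support the alpha
effect with posterior probability ≥ 0.95, and the recovered contrast is
ordered `REF > CWL > {OBS, AAS} > IAR > NC` — the reference data recover
the most, loop regression comes closest to it, template-based BCG
correction recovers a partial contrast, and imaging-artifact reduction
alone leaves the effect masked.

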