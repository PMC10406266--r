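---
title: "Methods: simulating, correcting and comparing MR-contaminated EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, correcting and comparing MR-contaminated EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: what the
synthetic sessions contain and why, how each correction algorithm is
implemented and parameterized, how the evaluation features are defined, how
the Bayesian comparison models are specified and sampled, and where we made
judgement calls that a reader should know about before trusting a result.

## 1. The synthetic session and its ground truth

`assemble_session()` produces a multichannel recording whose decomposition
is exact by construction:

```
data = neural + imaging + bcg + pump + motion + sensor noise
```

with every term retained in the `ground_truth` object, per channel and per
sample, so any corrector can be scored against the clean signal rather than
against another corrector. The reference variant (`REF`) is defined as
neural activity plus sensor noise — the signal a recording outside the
scanner would deliver.

**Imaging (gradient) artifact.** A deterministic sum of cosines at
`k·f_slice ± m·f_volume` (defaults: 5 slice harmonics, 2 volume sidebands,
1/(k·(1+m)) amplitude decay, fixed TR-locked phases). The default slice
frequency is 16/1.1 s ≈ 14.5 Hz — 64 slices acquired in multiband groups
of 4 within a 1.1-s TR — and the waveform is built once per TR and tiled,
so it is *exactly* periodic in the volume clock. The peak amplitude
(default 20 mV, i.e. 20 000 µV on a gain-1 channel) reflects the tens of
millivolts that survive amplifier filtering. Because the artifact is tens
of mV against µV-scale EEG, any analysis of uncorrected data is dominated
by it — including, through spectral leakage of the Welch taper, bands that
contain no harmonic.

**Ballistocardiogram (BCG).** A per-beat template — a sum of three
Gaussian-windowed oscillations at 4.5, 10.5 and 3 Hz on a [−0.2, 0.5] s
support, edge-tapered, normalized to a 150 µV peak — is placed at every
R peak plus a 0.21-s pulse-arrival delay, with per-beat amplitude jitter
(CV 0.15) and latency jitter (SD 5 ms). Two properties drive the defaults:
≥ 90 % of the template's power lies below 25 Hz, and its *dominant*
component sits in the alpha range. The second point matters: published BCG
spectra at 3 T concentrate power across roughly 1–14 Hz, and the
evaluation phenomenon this package reproduces — imaging-artifact reduction
alone failing to recover the eyes-closed alpha contrast — only occurs when
the beat spectrum genuinely masks the alpha band. A template with its
power mostly below 8 Hz would make IAR-only data look spuriously clean.

**Helium pump.** Stationary harmonics of a 42-Hz fundamental (3 harmonics,
1/k decay) with a slow ±10 % random amplitude modulation; ≥ 99 % of its
power lies above 30 Hz.

**Motion.** Band-limited (1–25 Hz) random bursts coupled into scalp and
loop channels during finger-tapping blocks only, emulating
movement-induced potentials that counteract event-related
desynchronization. Absent in the other tasks.

**Carbon-wire loops.** Each of the six loops is a weighted (0.5–1.5),
lag-shifted (±10 ms) mixture of the *same* artifact source waveforms that
reach the scalp, plus white sensor noise (SD 1 µV) — and no neural signal,
since the loops are isolated from the scalp. Artifact components are
rank-one (a source waveform times a gain vector), so in the noise-free
limit the loop span contains the scalp artifact exactly; the loop noise is
what keeps CWL regression from being trivially perfect.

**Neural signal.** All tasks ride on per-channel 1/f background noise
(2 µV RMS). Resting blocks alternate eyes-open/eyes-closed occipital
alpha (8–12 Hz band-limited noise at 5 vs 15 µV RMS — the EC/EO contrast
is the study's target effect, and 3× amplitude is a robust occipital
alpha reactivity); finger tapping attenuates left-pericentral mu-alpha
and beta amplitudes by `1 − depth` (depths 0.7 and 0.5) during 3-s blocks
and adds a gamma burst (70–80 Hz, gain 2.5×) in the first second;
checkerboard trials add a biphasic kernel (positive peak ≈ 5 µV at
120 ms, negative ≈ −6 µV at 175 ms) with a topography contralateral to
the stimulated hemifield. Condition transitions use 0.25-s raised-cosine
ramps to avoid spectral clicks.

**What the generator does not emulate.** No volume conduction or dipole
physics (topographies are parametric Gaussian blobs on a schematic
layout); no respiration, sweat or electrode-pop artifacts; no
non-stationary imaging artifact (the TR waveform never drifts, so AAS's
stationarity assumption holds exactly for the imaging stage); beat
templates are identical across channels up to gain. Passing tests
therefore certify algorithmic correctness and the direction and rough
magnitude of method differences under controlled violations (beat jitter,
loop noise, motion) — not performance on any particular scanner's data.

## 2. The correction algorithms

**AAS** (`aas_correct()`). For each anchor the template is the channel-wise
mean of the `n_windows` nearest epochs — a *centered sliding* window over
anchor index, truncated at the recording edges — subtracted over that
anchor's epoch. Defaults follow the standard toolboxes: 25 windows on
volume anchors for the imaging stage, 21 on delayed R peaks for the BCG
stage. When heartbeat epochs overlap (the default span is [−0.25, +0.65] s
around the delayed R peak, and RR intervals can be shorter than 0.9 s),
each sample is corrected by its *nearest* anchor: overlapping stretches
are split at the overlap midpoint. Samples outside all epochs are
untouched.

**OBS** (`obs_correct()`). Per channel, R-peak-aligned constant-length
epochs are stacked; the epoch mean and the first 3 principal components
(SVD of the centered stack) form the basis, which is least-squares fitted
to and subtracted from every epoch, with the same nearest-anchor ownership
for overlaps. Residuals are orthogonal to the basis by the normal
equations — the suite checks this identity directly. If the stack cannot
support the requested components the count is reduced with a warning. A
property worth knowing: when no artifact dominates the stack, the mean and
leading components align with smooth background EEG and the per-epoch fit
removes a noticeable share of it. This overcorrection is inherent to the
method (removing leading components can eat neural signal), shrinks with
the number of beats, and is asserted — as a bounded, decreasing quantity —
rather than assumed away.

**CWL regression** (`cwl_regress()`). The recording is processed in 4-s
Hann-tapered windows at 50 % hop. Per window, the tapered EEG segment is
regressed on the tapered lagged loop signals (all integer lags within
±0.021 s, six loops — 259 columns at 500 Hz) plus an intercept; the *loop
part* of the fit is subtracted. Subtracting only the loop contribution —
the intercept column participates in fitting but not in subtraction —
makes a zero-regressor pass an exact identity, which the suite checks to
10⁻¹⁰. Windows are placed fully inside the recording (an extra final
window is pinned at the end) and recombined by overlap-add with a strictly
positive taper, normalized by the accumulated taper weight, so edges are
reconstructed exactly without zero-padding artifacts. Rank-deficient
designs (e.g. silent loops) fall back to a tiny ridge
(10⁻⁸ × mean diagonal), logged.

One consequence of the method's own design deserves emphasis: ~259
regressors per 2000-sample window project out roughly p/W ≈ 13 % of *any*
uncorrelated signal's variance in expectation (less after overlap-add
averaging; ~5–10 % measured). CWL regression therefore attenuates neural
signal slightly even with perfectly independent loops — the no-harm
correlation plateaus near 0.95, not at 1 — and this is the main reason the
reference variant stays ahead of CWL in the study results.

**R-peak detection** (`detect_rpeaks()`). Band-pass 5–15 Hz (zero-phase
FIR), derivative, squaring, 150-ms integration, adaptive signal/noise
threshold with a 300-ms refractory period, and refinement to the largest
absolute band-passed deflection — a standard derivative-energy scheme,
polarity-invariant by construction.

**Variant composition** (`run_variant()`). `NC` is the identity; `IAR` is
volume-anchored AAS on every channel; `AAS`/`OBS`/`CWL` always run *after*
IAR; R peaks come from the ECG channel post-IAR unless supplied.

## 3. Signal processing and evaluation features

Welch PSDs use 2¹²-sample Hamming segments at 50 % overlap, density
scaling (band *means* are compared, so the density/spectrum choice only
shifts a constant), and conversion to dB; inputs shorter than a segment
are zero-padded to segment length (a 3000-sample trial gets 1096 padding
samples) and the padding is recorded in the result. Zero-power bins floor
at −300 dB so downstream models stay finite. Multi-channel summaries
always average per-channel PSDs in the dB domain, never time-domain
signals — an anti-phase pair would otherwise cancel — and the suite pins
this convention with a constructed counterexample.

FIR low-pass filters are Hamming-windowed sincs with the length set by the
22-dB-per-transition rule `N = atten / (22·Δf/fs)`, rounded up to odd and
applied by centered convolution (zero phase, reflection padding); at
30 dB, 1 Hz transition and 500 Hz this yields 683 taps. The transition
width is an explicit parameter (default 1 Hz) because the length rule is
meaningless without it. Downsampling applies an anti-alias low-pass at
0.9× the new Nyquist before integer decimation and rescales marker samples
by the rate ratio.

Band definitions are alpha 8–12, beta 15–25, gamma 70–80 Hz, with
inclusive edges at grid resolution. Summary channels are selected by
z-scoring a topography over channels and keeping channels beyond the
threshold (1 SD for resting alpha, 2 SD for tapping and VEP topographies),
ordered by |z| with ties broken by label for determinism. Evoked-response
SNR is the maximum of a 20-ms sliding RMS over the peak window (P1
100–140 ms, N1 150–200 ms) divided by the mean sliding RMS over the
−200–0 ms baseline; the 20-ms support is configurable since "maximum RMS
in a window" is undefined without one.

## 4. The comparison models

The core model is a two-level normal regression: per-block (or per-trial)
outcomes with variant/condition predictors at the first level,
participants at the second, and residual SDs per method. Priors follow the
weakly-informative convention: normal(0, 10) on regression coefficients,
half-Cauchy(0, 2.5) on residual SDs, gamma(2, 0.1) on the
robust-correlation degrees of freedom, normal(0, 100) on its means and
uniform(−1, 1) on its correlation.

Sampling uses JAGS (Gibbs). This drives one structural choice: the
participant-covariance parameterization. The default (`"conjugate"`)
writes the likelihood as `y ~ N(Xβ + X·u_j, σ_method)` with zero-centered
participant deviations `u_j ~ MVN(0, Σ)` and an inverse-Wishart prior
`Σ⁻¹ ~ Wishart(2.5²·I, p+1)` — non-centered in location, and with every
block update (deviations, group coefficients, covariance) conjugate, which
is what makes the sampler mix well: at the reference problem size
(8 participants × 20 observations) the maximum rank-normalized split-R̂
stays ≤ 1.01 and the minimum bulk/tail effective sample size well above
400 from 4 chains × 1000 draws. The cost is that the *implied* prior on
the coefficient SDs is the heavy-tailed inverse-Wishart marginal rather
than an explicit half-Cauchy, and the implied correlation prior is the
near-uniform Wishart marginal rather than an LKJ shape. For two-coefficient
designs the exact forms are available (`parameterization = "noncentered"`
or `"centered"`: half-Cauchy SDs, correlation prior `2·Beta(η, η) − 1`,
i.e. exactly LKJ(η) for a 2×2 matrix, η = 2 by default); they mix
noticeably worse under Gibbs, and the suite verifies that the centered and
non-centered forms agree in distribution on a well-identified fit. There
are no divergent-transition diagnostics in a Gibbs framework; convergence
is policed by R̂ ≤ 1.01 instead, and a failing fit is returned flagged,
never silently discarded.

The effect-size model extends the residual structure to one SD per
participant and method, partially pooled on the log scale toward its
method-level SD; the within-participant effect size of a coefficient is
that coefficient's participant-level posterior divided by the
participant-method residual SD, averaged over participants. The exact
estimator is a reconstruction — which SD standardizes the difference is a
genuine judgement call — and it is exposed as draws so other conventions
can be computed from the same fit.

Diagnostics (rank-normalized split-R̂, bulk and tail ESS, MCSE) are
implemented natively from the rank-normalization definitions, with
constant parameters reported as `NA` rather than 1, and are calibrated in
the suite against i.i.d. draws and constructed non-convergent chains.

## 5. The study harness and problem sizes

`run_study()` simulates each participant (heart rate and amplitude
multipliers drawn per participant to populate the second level), derives
REF and the five MR variants from the same raw session, extracts per-block
alpha power on reference-selected summary channels, and fits the two-level
model with a condition × variant interaction; the per-variant ΔPSD is the
condition effect plus the matching interaction.

Default sizes are desk-scale and stated here as the package's own choice:
8 participants, 10 alternating 10-s EO/EC blocks, 32 scalp channels,
sessions generated at 500 Hz — the rate the spectral analysis operates at;
generating at the 5-kHz acquisition rate and downsampling changes the
arithmetic only through the (tested) resampler. A full study fits in about
a minute; acquisition-scale sessions (5 kHz, 22 × 40-s blocks) remain
available through `session_config()` for users who want them. Posterior
coverage is checked over 50 reduced datasets (6 participants × 10
blocks, 2 × 400 draws); the convergence-bound check runs at the full
reference size.

## 6. Numerical conventions and degenerate inputs

Sample indexing is 0-based with half-open windows everywhere; BrainVision's
1-based marker positions are converted on read. Amplitudes are microvolts
throughout. Epochs that would cross a recording boundary are dropped, not
padded. Welch segments are mean-detrended per segment. Channel-selection
ties break by label; quantile summaries use linear interpolation (median
and equal-tailed 66 %/95 % intervals). Flat ECG yields an empty peak list
with a warning; a flat topography yields an empty channel set with a
warning; constant MCMC parameters yield `NA` diagnostics; zero-power PSD
bins floor at −300 dB. All randomness is seed-derived: a session is a pure
function of its config, and a study of its master seed.

## 7. Known limitations

* Artifact topographies are rank-one per component; real BCG varies in
  waveform across the scalp, which would make OBS's per-channel basis more
  valuable than it appears here.
* The imaging artifact is perfectly stationary and marker-locked, so the
  imaging-stage AAS is exact up to neural leakage; real scanner clock
  drift and head motion would leave residuals this simulator cannot show.
* CWL loop noise and lag ranges are the only imperfections limiting loop
  regression; real loops can also pick up cable-specific artifacts absent
  from the scalp.
* The Gibbs sampler's conjugate covariance prior deviates from the
  half-Cauchy/LKJ convention for designs wider than two coefficients, as
  discussed in section 4.
* Evaluation analyses beyond the resting-state comparison (tapping band
  features, VEP amplitudes/SNR/similarity) are implemented and tested as
  feature extractors; `run_study()` orchestrates the resting-state
  comparison end to end.
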