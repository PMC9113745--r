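---
title: "NREM sleep EEG microarchitecture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NREM sleep EEG microarchitecture: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. Everything quantitative stated here
is computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted that the code does not measure.

## The pipeline in one paragraph

Multichannel N2-sleep EEG (200 Hz, linked-mastoid reference, 0.3–35 Hz)
is scanned per channel for sleep spindles (a wavelet detector at 11 and
15 Hz center frequencies) and slow oscillations (a zero-crossing detector
on the 0.3–4 Hz trace). Event morphology, SO-phase/spindle coupling with
surrogate normalization, intra-spindle frequency dynamics, Welch spectra,
and phase-slope-index (PSI) connectivity each yield one number per
subject × channel (× frequency). Those metric tables feed a logistic
group model with age and sex covariates, a min-p permutation correction
across channels, and an SVD-component ("principal spectral component",
PSC) reduction with a joint, optimism-corrected case/control classifier
that transfers to new cohorts by fixed-basis projection.

## Preprocessing and artifact handling

Preprocessing re-references to linked mastoids, resamples to 200 Hz
(polyphase), and applies a zero-phase FIR bandpass (0.3–35 Hz; 1100 taps
so the transition band stays inside ~0.6 Hz and DC sits in the stopband).
A zero-phase filter matters here because SO slope and phase metrics are
phase-sensitive; an IIR run one way would tilt every slow wave.

Artifact rejection works on Hjorth parameters (activity, mobility,
complexity; derivative = first difference × fs) per 30-s epoch and
separately per sleep stage:

1. a channel is bad when >30% of its epochs sit >2 SD from the
   cross-channel mean (any parameter, within epoch); bad channels are
   spherical-spline interpolated everywhere;
2. per channel, epochs >4 SD from that channel's distribution — or with
   |amplitude| > 500 µV, or flat/clipped >10% of samples — are
   interpolated;
3. per channel, remaining >4 SD epochs cause the epoch to be dropped for
   all channels; this pass runs twice. The retained epoch set is
   therefore identical across channels, which the tests assert.

The stage-1 pooling window is all epochs of a stage (the natural reading
of stage-wise processing); statistics are never pooled across stages.
Spherical-spline interpolation uses the classic g-function expansion
(stiffness 4, 50 Legendre terms, 10⁻⁵ diagonal regularization) and
needs ≥4 good channels with unit-sphere positions.

## Spindle detection

The detector magnitude is `|x * ψ|` for a complex Morlet ψ with **7
cycles** (σ_t = 7/(2π·fc)), smoothed with a 0.1-s moving average, and all
thresholds are multiples of the *mean* magnitude over clean in-stage
samples — so detection is exactly scale-equivariant, which is tested.
Seven cycles is a compromise the tests make concrete: enough frequency
resolution that the 11 and 15 Hz detectors cross-talk at <15%, short
enough in time that 0.3-s cores survive smoothing. The cycle count is
exposed in `spindle_detector_config()`.

Event QC compares each event's relative band-power increase (event window
over stage mean) in sigma (fc ± 2 Hz) against delta (0.5–4), theta (4–8)
and beta (15–30 Hz); the event survives only if sigma wins against all
three. Band edges for sigma/beta are a declared choice: the band *names*
are standard but their edges are not, and the ±2 Hz sigma window matches
the instantaneous-frequency filter so the two analyses see the same band.
Event-window powers use one Tukey(0.5) periodogram (events are too short
for multi-segment Welch); stage means use 4-s Welch segments.

Chirp is `f(second half) − f(first half)` with each half's implied
frequency `1/(2 × mean zero-crossing interval)`, requiring ≥4 crossings
per half. The generator realizes a requested chirp c as a linear
instantaneous-frequency ramp from fc−c to fc+c: the measured quantity is
the difference of *half-means*, and a ramp spanning only c would measure
c/2. Two caveats the tests document: (i) the zero-crossing estimate on a
clean ramp is slightly conservative (≈0.96 of the generated value, from
harmonic-mean averaging of crossing intervals); (ii) through the full
detector, chirp attenuates further because detected intervals are
threshold-crossing spans — the central portion of the event — so the
measured ramp is truncated. Group *contrasts* in chirp survive this
(the analysis scripts show case/control ordering is preserved), but
absolute chirp values are estimator-specific.

## Slow oscillations

Candidates start at a positive-to-negative zero crossing of the 0.3–4 Hz
trace (a stated convention — the polarity tests show detection is *not*
invariant to sign flips, which is why EEG polarity must be trusted before
SO metrics are compared across montages). Temporal criteria: negative
half-wave 0.3–1.5 s, following positive half-wave ≤1 s. Absolute mode
keeps events with negative peak < −40 µV *and* peak-to-peak > 75 µV;
adaptive mode keeps events whose negative-peak magnitude and peak-to-peak
both exceed 2× the mean over that channel's *candidates* (the candidate
pool, not some broader half-wave set — an assumption stated here because
the method descriptions in the literature leave it open). The up-slope is
|negative peak| divided by the time from the peak to the next rising zero
crossing: deterministic and robust at 200 Hz, in preference to a maximal
first derivative which is noise-limited at this sampling rate.

## Coupling and its surrogates

SO phase comes from the analytic signal of the 0.5–4 Hz trace with
0° = positive peak, 180° = negative peak, 180–270° = rising slope. The
convention is fixed by geometry: with it, fast spindles preferring the
rising slope toward the positive peak land near 240°, and the package's
generator/estimator round trip recovers a requested 240° preference to
within ±10° at κ = 20 with ≥50 events (tested).

Three metrics per channel: gross overlap (spindle intervals intersecting
any SO), coupling magnitude (inter-trial phase clustering = resultant
length of SO phases at spindle peaks), and the circular mean angle. Raw
values are normalized against surrogates: the overlap null relocates
whole spindles uniformly within clean in-stage samples; the magnitude
null relocates spindle peaks uniformly within the union of SO intervals,
preserving gross overlap so magnitude is judged conditional on overlap.
Z = (obs − null mean)/null SD; the per-subject empirical p is
`(r+1)/(n+1)` counting null ≥ observed (the conservative tie rule). The
full pipeline uses 10,000 shuffles; the tests use 500–2,000, which the
calibration block shows is already enough for the null Z to have mean
within ±0.2 and SD within 0.8–1.2.

Instantaneous spindle frequency is the smoothed (3-sample) derivative of
the unwrapped analytic phase after a ±2 Hz bandpass around the
subject/channel mean spindle frequency. Profiles are averaged per
spindle-progression quintile (five equal-time fifths of each event — the
per-event reading of "duration quantiles"), per 20° SO-phase bin (18
bins), and jointly (5 × 18). The circular–linear correlation uses the 18
bin means, not raw samples. The joint matrix is fit by least squares with
a cubic polynomial in progression, 3rd-order circular harmonics in phase,
and their additive union, reporting adjusted R².

## Spectra and PSI

Welch PSD: per 30-s epoch, 4-s segments with 50% overlap and a
Tukey(0.5) taper, averaged within then across epochs; 0.25 Hz bins; the
white-noise Parseval check holds to 5%. The spectral slope is the
least-squares slope of log₁₀ power on log₁₀ frequency over 0.5–20 Hz;
generated exponents 0–3 are recovered within ±0.1.

PSI follows the imaginary-coherency construction: complex coherency
C(f) from 2-s Hann sub-segments (50% overlap, three per non-overlapping
4-s segment; δf = 0.5 Hz, the sub-segment resolution), then
`PSI(fc) = Σ Im(C*(f) C(f+δf))` over [fc−2.5, fc+2.5] Hz for fc = 3…20.
Each epoch's PSI is normalized by its jackknife (leave-one-sub-segment-
out) SD, and normalized values are averaged over 20 randomly selected
clean N2 epochs (seeded; all available epochs with a warning when fewer).
The phrase "4-s segments, using a 2-s interval with 50% overlap" admits
two segmentations; the sub-segment reading adopted here is the one that
leaves a meaningful jackknife ensemble per epoch. Sign convention:
positive PSI(x→y) means x leads. The tests verify exact antisymmetry, a
>+2 normalized response to a 25-ms band-limited lead in ≥90% of runs,
|PSI| ≤ 2 in ≥95% of zero-lag mixtures (the volume-conduction case PSI
exists to reject), and correct sender→relay→receiver ranking of net PSI
(the per-channel row sum) on a lagged three-channel chain.

## Group statistics

Per metric and channel: 3 SD outliers removed (pooled groups, single
pass, strict inequality), then logistic regression
`group ~ metric + age + sex` with the Wald p for the metric coefficient.
The reported effect size is the residualized Cohen's d — metric
residualized on age and sex, then standardized mean difference with
pooled SD — because "SD units" needs an operational definition and this
one is covariate-consistent with the model.

Multiple testing across channels uses the min-p max-statistic method: one
set of group-label permutations (age and sex stay with the individual) is
shared by all channels, the minimum null p across channels is recorded
per replicate, and `adj_p = (#{min-p ≤ p_obs} + 1)/(R + 1)`. Sharing the
permutation set across channels is what makes the correction respect
inter-channel correlation; the tests confirm FWER 5% ± 2.5% on 57
correlated null channels and that 57 duplicated channels cost nothing
compared with one. The inner loop (millions of logistic fits during
calibration) runs in compiled code whose Wald p agrees with `stats::glm`
to 10⁻⁶; `glm` remains the single-fit path.

## Components and prediction

Feature matrices (subject × channel-by-metric or channel-by-frequency)
are column-centered and decomposed `A = U D Vᵀ`; scores are columns of U,
variance explained is d²/Σd², retention needs ≥1%, and each component is
oriented so its largest-magnitude loading is positive (the decomposition
leaves signs free). Selection additionally requires a group difference at
p < 0.01 in the age/sex-adjusted logistic model after residualizing age
and sex from the scores. Out-of-sample projection is
`U_B = (B − training means) V D⁻¹` — the algebra consistent with
`A = U D Vᵀ` (a transposed variant sometimes printed elsewhere is not
dimensionally consistent and is deliberately not supported) — and
centering always uses *training* means, without which transfer would be
confounded by cohort-mean shifts. Self-projection reproduces U to 10⁻⁸.

The joint classifier is a multivariable logistic fit on selected
(residualized) scores; AUC is the rank statistic (verified against an
independent ROC implementation to 10⁻¹²). Overfitting is corrected by
bootstrap optimism: refit on resamples, evaluate on resample and
original, subtract the mean difference. The optimism estimate is floored
at zero so the corrected value can never exceed the apparent one — with
finite B the raw mean can go slightly negative by Monte-Carlo noise, and
a "correction" that increases apparent performance is not meaningful.

## The synthetic generator: what it emulates, and what it does not

The generator produces: 1/f^s background (spectrally shaped white noise;
direct control of the exponent, unlike AR approximations), 30-s staged
epochs, biphasic SO waveforms (half-sines, durations mirroring the
detector's temporal criteria), and enveloped spindle bursts with linear
chirp and optional von-Mises SO-phase coupling (peaks placed where the
clean SO phase matches each draw). Defaults are study-typical: 200 Hz,
slope 2, 20 µV rms background; fast-spindle density 2.7/min (the
control-group mean at the best channel in the motivating literature),
slow 2.0/min; spindle amplitude 25–30 µV peak-to-peak; SO −60/+40 µV.
Event counts in `simulate_subject()` are exact
(`round(density × N2 minutes)`) so truth densities are fixed by
construction; standalone injectors draw Poisson counts. Injected SOs
keep ≥1.25 s spacing: closer biphasic waves merge at the filter level
into compound waves whose positive half-wave exceeds the 1-s criterion,
which is a property of slow waves, not a detector defect.

Deliberately not emulated: realistic topographic field spread (only an
optional linear mixing matrix), EOG/EMG artifacts, sleep-cycle structure,
and any nonstationarity of densities across the night. Passing tests
therefore demonstrate *estimator correctness and calibration*, not
robustness to everything real recordings contain.

One unit convention worth stating: where a test pins detection
performance at "in-band SNR 4", the spindle amplitude is set so the
burst's rms over its duration equals 4× the rms of the 11–15 Hz-filtered
background (for a Hann-enveloped sinusoid, rms = 0.433 × half the
peak-to-peak). On the default background that is ≈25 µV peak-to-peak — a
physiological fast spindle. Defining "amplitude × background sigma rms"
peak-to-peak instead would describe a ~5 µV event whose wavelet response
cannot clear a 4.5×-mean threshold for any detector, so the SNR reading
is the meaningful one.

## Numerical choices and problem sizes

Narrowband event filters are 2nd-order Butterworth applied
forward–backward; the wide preprocessing band uses the long FIR above.
The Hilbert transform and Morlet convolution are FFT-based. Degenerate
inputs are defined: constant epochs give activity 0 and NA
mobility/complexity; zero spindles give NA coupling with a flag; zero SD
in a surrogate null flags Z as undefined; empty component selections are
allowed. Monte-Carlo test sizes (200 calibration seeds, R = 500
permutations, 100 PSI seeds, B = 100–200 bootstraps, 10-minute synthetic
recordings) were chosen as the smallest sizes at which the binomial or
jackknife standard errors are comfortably inside the asserted bands; the
full-scale analysis uses 10,000 coupling shuffles and R = 3,000
permutations as in the analysis scripts.

## Known limitations

Chirp magnitude is estimator-dependent (see above). The artifact
pipeline's stage-2/stage-3 distinction (interpolate vs drop) follows the
three-pass description literally; other orderings are defensible.
Adaptive SO thresholds depend on the candidate pool and therefore on
recording length and noise level; absolute mode is the right choice for
amplitude-calibrated comparisons. PSI needs tens of sub-segments per
epoch for a stable jackknife; below ~3 sub-segments an epoch is skipped.
The EDF writer covers continuous 16-bit recordings with per-second
records — the subset this pipeline produces and consumes — not the EDF+
annotation extensions.
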