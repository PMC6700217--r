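---
title: "Methods: corticostriatal LFP features and drinking-phenotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticostriatal LFP features and drinking-phenotype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdrink)
```

This vignette is the package's account of its science: the signal model
behind the synthetic cohorts, the analysis constants and where each comes
from, the statistical procedures, and the numerical choices made where the
design was genuinely open.

## The analysis in one paragraph

Four LFP channels (bilateral nucleus accumbens shell and medial prefrontal
cortex) are notch-filtered at 60 Hz, decimated from 2 kHz to 400 Hz,
cleaned of ±2 mV artifacts, and cut into 3-s epochs. Welch spectra and
magnitude-squared coherence summarize each subject into 60 features: per
channel and per channel pair, the mean value in each of six rodent
frequency bands as a percent of the 1–90 Hz broadband mean. Subjects are
labelled high- or low-drinking (HD/LD) by a median split of their last
three training sessions' alcohol intake (g/kg). An L1-penalized logistic
regression predicts the label from the features under repeated 4-fold
cross-validation, judged against a label-permutation null; exhaustive
single-feature logistic regressions rank the information content of each
feature; a 2×2 mixed ANOVA tests whether brain stimulation changes
drinking differently in the two phenotypes.

## Analysis constants

Every constant sits in `pipeline_config()` and is asserted against a
frozen table in the test suite:

| Stage | Parameter | Default |
|---|---|---|
| Notch | Chebyshev type I, order | 4 |
| | center / stop band | 60 Hz, 59–61 Hz |
| Decimation | factor | 5 (2 kHz → 400 Hz) |
| Artifacts | threshold | ±2 mV |
| | removal window | 12.5 ms before, 1 s after |
| Epochs | length | 3 s |
| Welch | window / overlap | 1.28 s Hamming, 50% |
| Bands | δ, θ, α, β, lγ, hγ | 1–4, 5–10, 11–14, 15–30, 45–65, 70–90 Hz |
| Normalization | range / exclusion | 1–90 Hz, excluding 59–61 Hz |
| Phenotype | sessions averaged | last 3 |
| Classifier | folds × repetitions | 4 × 100 |
| Null | label permutations | 100 |

## Preprocessing choices

**Stage order.** Notch → decimate → threshold → segment. Artifact
detection runs on the notch-filtered, decimated 400 Hz signal, following
the narrative order of the recording methods. Whether detection belongs
before or after decimation is not decidable from the description we work
from; the choice matters little because the injected artifacts (half-sine,
20 ms) survive decimation essentially intact.

**Notch design.** The band-stop is applied forward–backward (zero phase),
which squares the magnitude response; the design ripple is therefore set
to 0.5 dB so the effective passband ripple stays within 1 dB, and the
stop band 59–61 Hz matches the spectral exclusion band. A 60 Hz tone is
attenuated by more than 20 dB; a 10 Hz tone passes within 1 dB.

**Masking.** Any sample on any channel at or beyond the threshold marks an
event; removal intervals are merged and applied jointly to all channels,
because coherence needs time-aligned clean data on both channels of a
pair. Intervals are half-open sample ranges, 0-based, with
seconds-to-samples conversion by rounding to the nearest sample.

**Epoching.** The unmasked complement decomposes into maximal runs; each
run yields `floor(run / 3 s)` epochs starting at the run's first sample,
remainder dropped. Total analyzed time is not equalized across subjects by
default; `segment_epochs(max_epochs =)` caps it when a fixed amount of
data per subject is wanted.

## Spectral estimation

No installed R package provides Welch cross-spectral estimators, so the
engine is implemented directly on `stats::fft()` with a symmetric Hamming
window: one-sided power spectral densities (power doubled except at DC and
Nyquist, normalized by `fs * sum(w^2)`), segments of 1.28 s advancing by
half a window, periodograms averaged within an epoch and then across
epochs in the linear domain. The implementation is pinned, value-for-value,
to reference spectra computed externally with an independent scientific
Python stack on a deterministic tone-plus-chirp fixture (frozen in the
test suite), and to analytic oracles: a pure tone peaks at its grid
frequency, white-noise PSD integrates to the signal variance, identical
channels have coherence exactly 1.

**Coherence.** Magnitude-squared coherence per epoch is
`|⟨Sxy⟩|² / (⟨Sxx⟩⟨Syy⟩)` over the epoch's Welch segments, then averaged
across epochs, mirroring the PSD treatment. With L segments per epoch the
estimator has the classical positive bias of order 1/L under independence;
a 3-s epoch holds 3 windows, so the independent-noise floor is far above
zero (≈ 1/3). This is a property of the estimator at the prescribed
window and epoch lengths, not a defect; the synthetic-data tests measure
the floor empirically rather than assuming zero.

**The dB reference.** Band power features average *dB* values inside each
band and express them as a percent of the broadband dB mean (the
linear-domain alternative sits behind `band_power_features(domain =
"linear")`). A percent of dB values is direction-inverting when the dB
values are negative, so the dB conversion is referenced to 1 µV²/Hz,
which keeps physiological millivolt-scale spectra comfortably positive
(~20–30 dB) and the normalization direction-consistent. A flat spectrum
scores exactly 100 in every band under either domain.

**Compositionality.** Percent-of-broadband features are compositional: if
gamma power rises, every other band's share must fall. A strong injected
gamma effect therefore shows up, with opposite sign, in non-gamma features
too. This is a property of the feature definition, not a bug, and it is
why the synthetic cohorts give every band its own inter-subject
variability (below): effect localization is only identifiable when the
normalizer leakage is small against between-subject noise.

## The synthetic cohort generator

Each channel is the sum of three components, with RMS amplitudes in mV
chosen so the combined signal sits near 0.2 mV — an order of magnitude
inside the ±2 mV artifact threshold, so thresholding fires only on
injected artifacts. No amplitude statistics are available for the real
recordings; this scale is a stand-in.

* **1/f (pink) background** (RMS 0.12 mV): white noise shaped by
  `1/sqrt(f)` in the frequency domain, giving the falling spectrum real
  LFPs show.
* **White floor** (RMS 0.03 mV): wideband sensor noise.
* **Band-limited processes** (RMS 0.05 mV each at 0 dB): white noise with
  its spectrum zeroed outside the band. FFT-domain masking is used instead
  of IIR band-pass filtering because a 1–4 Hz band-pass at a 2 kHz rate
  has normalized edges near 5×10⁻⁴ where IIR designs are numerically
  fragile; the FFT construction is exact, zero-phase and stable at any
  band.

**Power offsets.** A subject's per-channel, per-band dB offsets scale the
band process amplitudes (`10^(dB/20)`). With the background switched off,
a +6 dB offset quadruples measured band power; with it on, the ratio is
diluted by the pink floor — the tests verify the clean case exactly and
the realistic case for monotonicity.

**Coherence couplings.** Each coupled pair has its own shared band-limited
source; a channel in pairs with weights `w_p` receives
`Σ w_p s_p + sqrt(1 − Σ w_p²) · own`, so pair coherence rises
monotonically from the estimator floor at weight 0 toward 1 at weight 1
(exactly 1 when the background is off), and multiple pairs can be coupled
simultaneously. Weights are rescaled if a channel's shared variance would
exceed 1.

**Artifacts.** Poisson-placed half-sine transients, 20 ms wide, on a
random channel: broad-band, unambiguous threshold crossings whose ground
truth (time, channel) travels with the recording so detection can be
validated event-for-event.

**Inter-subject variability.** Real cohorts are heterogeneous; without
that, any group effect separates subjects deterministically and every
feature classifies perfectly. `cohort_spec()` therefore draws, per
subject, (a) per-channel band power offsets with a between-subject SD that
declines with frequency (4 dB at delta/theta down to 1.5 dB in the gamma
bands — low-frequency power varies strongly with behavioral state across
animals, gamma is comparatively stable) and (b) baseline coupling weights
per pair and band with means and SDs that also decline with frequency
(0.45 at delta to 0.2 in gamma — inter-regional coherence is strongest
and most variable at low frequencies, low and focal in gamma).

**The HD effect.** HD subjects optionally receive a gamma power offset on
`hd_gamma_channels` and extra gamma coupling on `hd_gamma_pairs`; the
defaults place the effect on the right-hemisphere sites and the pairs
anchored at right mPFC, matching the reported lateralization of
gamma-band phenotype differences. `hd_gamma_offset_db = 0` with
`hd_gamma_coupling = 0` gives a null cohort.

**Drinking.** Per-session g/kg values are normal draws truncated at zero;
HD means sit `drinking_group_effect` above LD. With the default SD of
0.25 g/kg and an effect of 1 g/kg, the phenotype is essentially
deterministic — mirroring a design where the median split *defines* the
groups — while `drinking_group_effect = 0` yields exchangeable subjects
for type-I-error checks.

**What the generator does not emulate.** Nonstationarity within a session,
cross-frequency coupling, volume conduction, stimulation-evoked changes in
the LFP, and real amplitude statistics. Passing tests on these cohorts
show the *pipeline* recovers known structure under realistic noise; they
say nothing about whether real corticostriatal LFPs carry phenotype
information.

## Phenotype statistics

**Median split.** Subjects at or above the median are HD. For an odd
cohort the median subject lands in HD — 7 HD / 6 LD for 13 subjects —
and exact ties follow the same ≥ rule with a logged notice. The split is
invariant to strictly monotone transforms of the drinking summary.

**Group comparison.** Pooled-variance (Student) t, two-sided, with
`df = n_a + n_b − 2`; the pooled form is used because the reference
degrees of freedom (11 for 7 vs 6) equal n − 2, which Welch df would not
reproduce. Zero pooled variance is handled explicitly (t = 0 or ±∞).

**Mixed ANOVA.** The 2×2 design (pre vs. stimulation × HD vs. LD)
decomposes into group, subjects-within-group, time, time×group and
time×subjects-within-group sums of squares; each F uses df (1, n − 2) and
partial η² = SS_effect / (SS_effect + SS_error). The three stimulation
sessions are averaged per subject before the ANOVA, matching a
two-level within factor. Two classical identities serve as oracles in the
tests: the decomposition agrees with `aov()` with an `Error(subject/time)`
stratum to 10⁻⁸, and the interaction F equals the squared pooled t on
per-subject difference scores. With df1 = 1, partial η² equals
F / (F + df2), asserted as an internal consistency check. Sphericity
corrections are unnecessary with two within levels.

## Classification

**The model.** L1-penalized logistic regression (glmnet). One repetition
draws a stratified 4-fold assignment (per class, shuffled indices dealt
round-robin), runs a single-level cross-validation in the `cv.glmnet`
style — the λ path fit on each training split, λ chosen by minimum mean
CV deviance across the folds, features standardized inside each training
fit — and scores the prevalidated held-out predictions at that λ:
probability ≥ 0.5 (link ≥ 0) classifies as HD, so exact ties go to HD.
The headline accuracy is the mean over repetitions, each with a fresh
fold draw. The one-standard-error rule is available via
`lambda_rule = "lambda.1se"`.

**Fold feasibility.** glmnet's binomial fitter rejects classes with fewer
than two training observations, so any fold draw leaving a training split
with fewer than two members of a class is re-drawn; stratification makes
this rare.

**The permutation null.** Labels are shuffled (features untouched) and
the entire repeated-CV procedure re-run per permutation; the permutation
mean accuracies form the null distribution. Summary intervals are
percentile 95% intervals — over repetition accuracies for the real model,
over permutation means for the null. The real model "outperforms chance"
when its mean exceeds the null's 97.5th percentile.

**Where chance sits.** For a 7/6 cohort the null is not exactly 50%:
whenever the selected λ is the null model, the prevalidated prediction is
the training majority class, which under stratified folds is always HD,
scoring exactly 7/13 ≈ 53.8%; repetitions whose λ admits noise features
score below 50% because fitted noise anti-generalizes. The acceptance
script estimates the resulting chance level by simulating null cohorts
end-to-end and averaging the permutation-null means over three cohorts —
a single 13-subject cohort's null mean inherits its feature geometry and
is noticeably noisier.

**Single-feature ranking.** Each feature alone enters an unpenalized
logistic regression under the same repeated stratified-CV accuracy
scheme, with its own per-feature label-permutation null; a feature is
flagged informative when its real mean accuracy exceeds its null's 95th
percentile, and the output is ranked by real accuracy. Null repetitions
run at a quarter of the real repetition count (minimum 2) to keep the
60-feature sweep tractable; the null mean is an average over permutations,
so fewer repetitions per permutation widen it only slightly. A constant
feature yields the majority-class rate and is never flagged; the all-noise
false-flag rate sits near the nominal 5% (asserted over pooled
simulations).

## Problem sizes in the tests

The study design is 13 subjects with two 30-minute recording sessions at
2 kHz and 12 drinking sessions. Spectral estimates stabilize within tens
of seconds, so the test and acceptance cohorts use 30–60 s recordings
(one or two sessions) and run the classifier at 15–25 repetitions with
15–30 permutations, and simulation-based properties use 4–50 seeds per
assertion; these sizes are the package's choices for its own checks, and
every routine accepts the full-scale parameters.

## Known limitations

* The percent-of-dB normalization makes features compositional; effect
  localization claims should always be read jointly with the broadband
  normalizer's behavior.
* The coherence estimator's small-sample floor (≈ 1/3 at the default
  window and epoch lengths) means absolute coherence values are
  comparable only within a fixed window/epoch configuration.
* The mixed ANOVA is restricted to the 2×2 design it implements;
  session-level within factors (four or more levels) are out of scope.
* The synthetic generator's amplitude scale and variability structure are
  plausible stand-ins, not fits to real recordings.
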