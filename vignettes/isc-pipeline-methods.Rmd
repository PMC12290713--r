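---
title: "Inter-subject correlation analysis of naturalistic fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject correlation analysis of naturalistic fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsisc)
```

# The scientific problem

When different people watch or listen to the same narrative, stimulus-driven
cortical activity is time-locked across them. Inter-subject correlation
(ISC) — the correlation between one participant's hemodynamic time series
and the average of everyone else's — indexes that shared processing without
requiring an explicit task model. `nirsisc` implements a complete ISC
pipeline for functional near-infrared spectroscopy (fNIRS): preprocessing
raw light intensities into hemoglobin concentration changes, group-level
inference against phase-scrambled surrogates, single-participant
reproducibility via a normalized-dot-product consistency statistic, ensemble
decoding of Intact versus Scrambled narrative conditions, and a GLM linking
hemoglobin dynamics to continuous suspense ratings.

Because fNIRS datasets of this kind are typically shareable only on
request, the package ships a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, with full ground truth. All
calibration and power claims in the test suite are statements about this
generator, not about any particular real dataset (see *What the generator
does and does not emulate* below).

# Preprocessing model

## Optical density and the modified Beer–Lambert law

Raw intensities $I(t)$ per channel and wavelength are converted to optical
density changes $\Delta OD(t) = -\ln(I(t)/\bar I)$, using the series mean
as reference and then zero-centering. The mean-reference-plus-centering
choice makes $\Delta OD$ exactly zero-mean (the plain log-ratio has a small
Jensen offset), and makes the forward/inverse round trip linear: the
recovered concentrations equal the true ones up to their (unidentifiable)
temporal mean. All round-trip tests therefore compare mean-centered series;
the pipeline's later band-pass and standardization discard the mean anyway.

Concentration changes follow the modified Beer–Lambert law: for wavelengths
$\lambda_1 \ldots \lambda_k$ ($k \ge 2$),
$$\frac{\Delta OD(\lambda)}{DPF(\lambda)\,\rho} =
  \epsilon_{HbO,\lambda}\,\Delta HbO + \epsilon_{HbR,\lambda}\,\Delta HbR,$$
solved per channel and time point by the exact $2\times 2$ inverse for
two-wavelength devices and by least squares for four-wavelength devices.
Extinction coefficients are the HOMER `GetExtinctions` values at 760, 785,
808, 830 and 850 nm (`extinction_table()`); $\rho$ is the source–detector
distance in cm; concentrations are reported in µM. The differential
pathlength factor uses the general age- and wavelength-dependent equation
of Scholkmann & Wolf (2013), stored as a pluggable coefficient list
(`dpf_model()`); at age 23.3 it predicts 6.09 at 760 nm and 5.04 at
850 nm, consistent with published adult cohort values.

## Motion correction

The hybrid correction runs per channel and wavelength on optical density:

1. **Spline stage.** Artifact segments are flagged where a 1-s sliding-window
   SD exceeds 3× a robust channel baseline. The baseline is the MAD-scaled
   SD of the first differences, which tracks fast sample-to-sample
   variation and is insensitive to slow signal, spikes and steps; a slow
   band-limited signal's windowed SD (which measures local slope) therefore
   never trips the threshold, while 20-SD spikes exceed it roughly
   ten-fold. Genuine baseline steps across a flagged run (clean-median
   difference larger than 3× the natural lagged-difference scale) are
   subtracted from all subsequent samples; short runs are bridged by linear
   interpolation and longer runs keep the residual around a flexible
   smoothing-spline fit of the artifact trajectory.
2. **Wavelet stage.** A periodic 4-tap Daubechies decomposition
   (implemented in-package, with a perfect-reconstruction unit test) on the
   mirror-extended series; per level, detail coefficients outside
   median ± 4×IQR are zeroed. Levels with fewer than 128 coefficients are
   left untouched — their IQR estimate is unstable and the coarse band
   overlaps genuine signal.

Two defaults deviate from common textbook settings and deserve note. A
1.5×IQR wavelet rejection — the usual boxplot rule — zeroes about 4 % of
genuinely Gaussian coefficients and costs roughly 15 % RMS on clean
band-limited signal; 4×IQR keeps clean-signal distortion at the 0.1 % level
while spikes remain far outside the envelope. Both stages are fully
configurable (`analysis_config()$motion`), and the clean-passthrough and
spike-rejection contracts are tested explicitly.

## Scalp physiology and standardization

Short channels (≤ 1 cm) see scalp and systemic physiology but no cortex. A
short channel is *good* when its raw intensity shows a cardiac spectral
peak: on a Welch-averaged periodogram (8 segments), a local maximum in
0.5–2 Hz at least 3× the median in-band power, for every wavelength. The
Welch averaging matters: a raw periodogram's max/median ratio in that band
exceeds 3 even for white noise (exponential tail over hundreds of bins),
which would defeat the criterion; averaging makes the statistic
well-behaved. Participants with no good short channel are signalled for
exclusion (`nirsisc_exclusion` condition), mirroring standard practice.

All good short-channel HbO *and* HbR series form one variable set; their
principal components (via SVD, all components kept) are regressed out of
every long channel of both chromophores by OLS with intercept. Using one
common component set for both chromophores is a deliberate choice — the
scalp signal is shared, and the OLS projection can only reduce residual
variance (tested). Finally each channel is standardized to mean 0, SD 1;
standardization is idempotent.

# Inter-subject correlation and group inference

For participant $p$, channel $c$, chromophore $h$: $r$ = Pearson
correlation of $p$'s series with the mean of all others (truncated to the
common length), $z = \mathrm{atanh}(r)$ with $r$ clipped to
$\pm(1-10^{-7})$, and the channel ISC is $(z_{HbO}+z_{HbR})/2$ —
neurovascular coupling makes the two chromophores carry the same
synchrony with opposite sign, so averaging their $z$ values is a
robustness device, not double counting.

Nulls come from phase-scrambled surrogates: each series is Fourier
transformed, every positive frequency rotated by an independent uniform
phase (DC and Nyquist fixed), conjugate symmetry restored, and inverted.
The same phase draws are applied to HbO and HbR of a channel, preserving
their cross-correlation; amplitude spectra — hence variance and
autocorrelation — are preserved exactly. Phases are drawn independently
across channels and participants.

Group inference uses the max-statistic correction: a one-tailed one-sample
t per channel on the observed ISC matrix; the same statistic on each of
$B$ surrogate ISC matrices with the per-surrogate maximum across channels
recorded; corrected $p_c$ = proportion of surrogate maxima ≥ observed
$t_c$. This controls the family-wise error rate across channels (the
procedure is sometimes loosely called FDR in the applied literature; what
is implemented and documented here is the max-statistic FWE method). The
Intact > Scrambled contrast applies the identical machinery to
participant-wise ISC differences and surrogate difference pairs.

## Leave-one-out masks and the no-leakage rule

Single-participant analyses must not let a participant's data shape the
reference they are compared against. For every left-out participant the
ISC matrices, surrogate nulls, per-condition significance and the contrast
are recomputed on the remaining participants only; the resulting channel
sets are that participant's masks. The implementation enforces this by
construction (the left-out row is excluded from the covariance arithmetic)
and the test suite verifies it by perturbation: replacing a participant's
data leaves their own masks bit-identical.

A note on surrogate bookkeeping: one scrambled cohort per iteration serves
every leave-one-out dataset. Within any single LOO dataset the $B$
surrogates are independent, so each dataset's max-t null is valid; only
the (never jointly used) masks of different participants share surrogate
randomness. This is what makes n-fold mask construction affordable at
$B$ = 1000.

# Consistency: the normalized dot product

Participant $l$'s consistency is
$\frac{1}{n}\sum_{i=1}^n a_{l,i}\,g_{l,i}$ over the $n$ channels of their
LOO Intact > Scrambled mask, where $a$ is their Intact ISC vector and $g$
the LOO group mean. Division by $n$ makes scores comparable across
different mask sizes; the sign is kept because systematically *inverted*
patterns are evidence against reproducibility, not for it. The null
phase-scrambles the entire cohort (the left-out participant included),
recomputes ISCs, group means and the score with the original mask held
fixed; $p$ = (1 + #{null ≥ observed})/(B + 1), one-sided — small $p$ means
more consistent than chance. Benjamini–Hochberg FDR is applied across
participants; participants with an empty mask are marked indeterminate and
excluded from the FDR family. Validation compares Intact-condition scores
with scores computed from the participant's Scrambled ISCs against the
same Intact references, by a paired two-sided t test (a two-sample test on
26 paired observations would report 50 degrees of freedom; the printed
form t(n−1) corresponds to pairing, which we adopt).

# Decoding: weighted-voting ensemble

Each left-out participant's Intact and Scrambled ISC vectors are test
items; training items are the remaining participants' ISC vectors
*recomputed within the LOO dataset*, masked to the union of the LOO
Intact- and Scrambled-significant channels (empty unions fall back to all
channels with a warning). Every registered classifier is tuned by random
search (budget configurable, default 25 evaluations) maximizing the median
balanced accuracy over stratified 3-fold cross-validation, refit, and
votes with weight equal to its tuned training score; the class with the
larger weight sum wins, ties going to Scrambled (the conservative outcome
for claims of narrative processing). Pooled predictions give one confusion
matrix; balanced accuracy, recall and precision (Intact positive) are
tested by permutation — condition labels are swapped within participant,
preserving the paired design — with add-one p-values and a reduced tuning
budget during permutations (recorded in the configuration).

The registry holds 14 classifier families available in R: logistic, ridge,
LDA, QDA, linear/RBF/nu SVM, Gaussian naive Bayes, kNN, nearest centroid,
random forest, extremely randomized trees, gradient boosting and a
Gaussian process. Ensembles of this kind are deliberately insensitive to
any single library's version behavior; the package's claims are tested at
the ensemble level, and the registry is configurable. Hyperparameter
search is budgeted random search; Bayesian (TPE-style) optimizers would be
a drop-in replacement but are not required by any tested property.

Single-channel decoding repeats the procedure with each channel as the
sole feature and reports the mean balanced accuracy across LOO folds —
a map of which channels carry condition information.

# Suspense GLM

Group-averaged Intact hemoglobin series are resampled to the 2-s suspense
rating grid by averaging samples in a window centered on each rating time
(centered averaging introduces no lag and is anti-aliasing by
construction; point decimation is available via `method = "decimate"`).
Per channel and chromophore, OLS regresses the resampled Intact series on
an intercept, the z-scored ratings and the z-scored same-channel Scrambled
series — the nuisance regressor removes dynamics that correlate with the
ratings for non-narrative reasons (e.g. audio envelope). The suspense
beta's t is tested two-sided, with BH-FDR across all channel × chromophore
tests; near-collinear designs (condition number > 1e6) are recorded as NA
rather than fitted. With anticorrelated HbR the suspense betas mirror the
HbO betas with opposite sign, which the tests assert on generator data.

# The synthetic cohort generator

`generate_cohort()` draws, per condition, one latent "narrative" signal
$s(t)$: white noise filtered by the same zero-phase Butterworth band-pass
used in preprocessing (0.005–0.20 Hz), so the shared signal survives the
analysis filter by construction. Participant-level series are
$$\Delta HbO_i = w_i\,s(t)\,[i \in \text{signal set}] + \text{scalp}(t)
  + \text{noise},\qquad
  \Delta HbR = \text{hbr\_ratio}\,(w_i s + \text{scalp}) + \text{noise},$$
with per-cohort mixing weights $w_i \sim U(0.5, 1.5)$, a per-participant
band-limited scalp component shared between short and long channels, and
white participant noise. Scrambled conditions draw an independent latent
signal confined to a subset of the Intact signal channels, mimicking the
focal (temporal-cortex) synchrony low-level features still produce. Raw
intensities follow the same Beer–Lambert forward model the inverse uses
($I_0 = 1$, identical extinction table and DPF, so round trips are exact),
plus a 1.1 Hz cardiac sinusoid with participant-specific phase (4× larger
on short channels) and multiplicative measurement noise. Motion artifacts
(single-sample spikes and persistent baseline shifts at Poisson times, in
OD units) are injected on demand.

Defaults are the study conditions: 26 participants, 121 long + 8 short
channels, 3.9063 Hz, 302 s per condition, ages drawn from N(23.3, 3.1)
clipped to 19–31, wavelengths 760/850 nm. Signal scales
(`shared_signal_sd` 1 µM, `noise_sd` 2 µM, `scalp_sd` 0.5 µM,
`hbr_ratio` −0.8) were chosen once, analytically, to put chromophore-
averaged signal-channel ISC near 0.3 — the magnitude single-participant
ISC maps typically span — and are verified by a generator test.

**What the generator does not emulate.** Hemodynamic response convolution
with event structure, inter-regional correlation structure, heteroscedastic
or heavy-tailed noise, optode-scalp coupling drift, the fixed
Scrambled-before-Intact presentation order, and biophysically detailed
photon transport. Passing calibration and power tests on this generator
shows the *statistics* behave as designed (correct false-positive control,
recovery of planted effects at realistic SNR); it does not certify
performance numbers on real recordings.

# Numerical choices and degenerate inputs

* Fisher transform: $r$ clipped to $\pm(1-10^{-7})$; ceiling
  $\mathrm{atanh}(1-10^{-7}) \approx 8.4$.
* Zero-variance series: ISC recorded as 0 with a warning; zero-variance
  short-channel sets are an error.
* Surrogate p-values: the max-t corrected $p$ is the plain proportion of
  surrogate maxima at or above the observed statistic; consistency and
  permutation p-values use the add-one estimator
  $(1+\#\{null \ge obs\})/(B+1)$, whose null distribution is uniform on
  its support.
* Ill-conditioned extinction matrices or GLM designs (condition
  number > 1e6) raise errors / are recorded as NA.
* Classifiers that fail to fit (e.g. QDA with singular within-class
  covariance at small n) are dropped from the ensemble for that fold.
* All randomness flows from explicit integer seeds; one master seed spawns
  per-stage streams by fixed offsets, and saved manifests record the seed.

# Problem sizes used by the test suite

Calibration uses 100 null cohorts (8 participants, 20 channels, 300
samples, 200 surrogates); power, consistency and decoding use cohorts of
10 participants, 20 long channels (signal in 5, Scrambled subset 2) at the
default ~302 s duration with 200 surrogates, 99 label permutations and a
reduced tuning budget; these sizes were chosen as the smallest designs at
which the tested effects are comfortably identified. The full-scale
defaults (26 participants, 121 channels, 1000 surrogates and permutations)
are what an analysis of a real cohort would run.

# Known limitations

* SNIRF (HDF5) I/O is not included; recordings exchange through the
  documented CSV + JSON fixture format.
* The hybrid motion correction is a faithful implementation of the
  spline-then-wavelet family, not a numerical clone of any particular
  MATLAB toolbox; dense artifact storms on short, noisy channels are only
  partially repaired.
* The decoder's absolute accuracy depends on the classifier registry and
  search budget; only ensemble-level properties are asserted.
* Consistency p-values share surrogate randomness across participants
  within an iteration (scores are computed from one scrambled cohort per
  iteration); each participant's marginal null is exact, and the BH step
  is robust to the induced positive dependence.

# A worked example

```{r example, eval = FALSE}
library(nirsisc)
par <- cohort_params(n_participants = 10, n_long_channels = 20,
                     n_short_channels = 4,
                     signal_channels_intact = 1:5,
                     signal_channels_scrambled = 1:2)
co  <- generate_cohort(par, seed = 11)
cfg <- analysis_config(n_surrogates = 200, seed = 11)
chb <- list(intact    = preprocess_cohort(co, "Intact", cfg),
            scrambled = preprocess_cohort(co, "Scrambled", cfg))
isc <- loo_isc(chb$intact, "Intact")
st  <- group_significance(isc, isc_surrogates(chb$intact, 200, seed = 1))
masks <- build_loo_masks(chb, cfg)
cons  <- consistency_analysis(chb, masks, cfg)
dec   <- decode_cohort(chb, masks, cfg, seed = 2)
```
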