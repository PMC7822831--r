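---
title: "Microstate and task-related alpha power analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate and task-related alpha power analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegms)
```

`eegms` analyses multichannel EEG recorded under loosely controlled,
self-paced task designs, where a participant works on a task for up to a few
minutes rather than responding to a time-locked stimulus. Because such data
cannot be averaged around stimulus onsets, the package relies on two
complementary descriptions of the ongoing signal: *task-related power* (TRP)
in the lower (8–10 Hz) and upper (10–12 Hz) alpha sub-bands, and *EEG
microstates*, brief (tens of milliseconds) periods during which the scalp
potential field holds a quasi-stable spatial configuration.

This vignette explains the models the package fits, the parameters that
matter and their defaults, what the synthetic study generator does and does
not emulate, and the numerical choices made where the design was open.

## The montage

The montage is the 10-10 layout of a 64-channel cap referenced to Cz, so 63
analysis channels. For regional statistics the lateral channels are grouped
into five cortical areas per hemisphere — frontal (9), central (4), temporal
(5), parietal (4), occipital (4) — 52 channels in all; midline channels and
the lowest lateral ring (FT9/FT10, TP9/TP10) belong to no group and never
enter regional aggregation. The published grouping lists one right-hemisphere
electrode (FC4) under both the frontal and the central area; `make_montage()`
resolves this by mirroring the left hemisphere exactly (FC4 frontal, mirror
of FC3; FC6 central, mirror of FC5), which keeps the ten groups a partition.
The grouping is exposed as an argument for users who prefer a different
resolution.

Channel positions are schematic 10-10 spherical coordinates (18 degrees of
polar angle per 10% step from the vertex). They are used only for
neighbour-weighted interpolation and for building smooth synthetic
topographies, not for source analysis, so digitized positions are not needed.

## Task-related power

For each recording, kept 2-s epochs are Welch-averaged (Hann taper, 1000
sample windows, 500 samples overlap at 500 Hz, one-sided density scaling) and
the band power at each channel is the composite-Simpson integral of the PSD
between the band edges on the PSD's own frequency grid. TRP of channel $i$ in
task condition $k$ is

$$\mathrm{TRP}_{ki} = \mathrm{mean}_j\,\big(\log \mathrm{Pow}_{i,\mathrm{task}(k,j)} - \log \mathrm{Pow}_{i,\mathrm{rest}}\big),$$

the mean over runs $j$ of the log power change against the resting reference
recorded at the start of the experiment. Natural log is the default
(`log_base`); conclusions are invariant to the base up to scale. Negative TRP
is alpha desynchronization. Regional values are the mean TRP over each
area-by-hemisphere electrode group.

Two numerical properties are worth knowing:

* **Quadrature parity.** Composite Simpson weights alternate 4 and 2 across
  interior grid points. A spectral *line* that sits on a single grid bin is
  therefore weighted by the parity of its bin: a tone exactly on an
  even-indexed bin integrates ~11% low, on an odd-indexed bin ~11% high.
  Band-limited *smooth* spectra are unaffected, and TRP is a log-ratio in
  which the quadrature factor cancels; only absolute band power of grid-locked
  sinusoids shows the effect. The tests probe tone recovery at an off-grid
  frequency for this reason.
* **Noise-floor bias.** With additive background noise of in-band power $N$
  and alpha signal power $S$, measured TRP is
  $\ln\frac{g^2 S + N}{S + N}$, biased toward zero relative to the planted
  $\ln g^2$. At the generator's default signal-to-noise ratio this bias is
  5–10% of the effect. A second variance source is coverage sampling: a
  channel's alpha power depends on how much time each template was active,
  so short independent rest/task recordings disagree beyond the gain effect.
  Both are properties of TRP under finite data, not of the implementation;
  the closed-form recovery check therefore uses a controlled pair (identical
  label sequence and noise stream, only the gain differs), while study-level
  TRP is reported as measured.

## Microstate model

Microstate analysis runs on 1–30 Hz, average-referenced data. The global
field power (GFP) of a map $u$ is its spatial standard deviation
$\sqrt{\tfrac{1}{N_S}\sum_i (u_i - \bar u)^2}$ (population form). Maps at
strict local maxima of the GFP curve — the moments of highest topographic
signal-to-noise — are clustered by a polarity-invariant modified k-means:
each peak map $V_t$ is assigned to the template maximizing $(V_t' \Gamma_k)^2$,
the intensity of the assigned class is $a_{kt} = V_t'\Gamma_k$, and each
template is re-estimated as the unit-norm principal eigenvector of its
cluster's scatter matrix. The fitted cost is

$$F = \frac{1}{N_T (N_S - 1)} \sum_t \lVert V_t - a_{kt}\Gamma_{k(t)} \rVert^2 ,$$

non-increasing across iterations (the eigenvector step is computed by power
iteration started at the current template, whose Rayleigh quotient is
monotone, so descent holds even before full convergence). The best of 100
random restarts (K distinct maps each) is kept; convergence is a relative
cost change below `1e-6` or 1000 iterations. The number of classes is chosen
over K = 1..10 by the cross-validation criterion

$$CV = \frac{\sum_t \big(V_t'V_t - (V_t'\Gamma_{k(t)})^2\big)}{N_T(N_S-1)} \cdot
       \Big(\frac{N_S-1}{N_S-1-N_K}\Big)^2 ,$$

whose penalty factor is singular at $N_K = N_S - 1$. Ties in CV (exact fits
at several K) resolve to the smallest K within a data-scale tolerance of
`1e-9`. `fit_modified_kmeans()` returns a classed model object with `print`,
`summary`, `coef`, `plot` and `predict` (backfitting) methods.

**Group templates.** Run-level models are averaged up the hierarchy (runs →
participant-by-condition → condition → global). At each step all $K!$ class
permutations of each model are scored by the summed absolute spatial
correlation (Pearson across channels) with the current mean templates;
polarity is ignored throughout because source oscillation inverts the scalp
field. The best permutation is applied, signs are flipped positive, templates
averaged and re-normalized, and the loop repeats until assignments are
stable. $K!$ is capped (default 10!) because full permutation is the
specified matching procedure; K beyond 10 is refused rather than silently
approximated. For group statistics K is fixed at 6 regardless of the per-run
CV optimum, which keeps classes comparable across participants and
conditions. Class letters A–F are assigned by correlation with a packaged
reference set; since canonical published topographies cannot be shipped, the
reference maps are synthetic geometric stand-ins built from the montage
(two diagonal gradients, an anterior–posterior gradient, and vertex,
parieto-occipital, and frontal blobs), stored at
`inst/extdata/canonical_templates_synthetic.csv` and configurable.

**Backfitting and parameters.** Global templates are fit back to the
GFP-peak maps by maximal absolute spatial correlation; every other sample
inherits the label of its temporally nearest peak (boundary at the midpoint
between neighbouring peaks, ties to the earlier peak) — the labels must cover
all of recording time for coverage to mean "percentage of recording time".
Maximal runs of one label form microstates. The first and last run of every
2-s epoch are discarded because their onset/offset is unobserved; epochs with
fewer than two GFP peaks are excluded. Coverage of a class is its fraction of
retained samples per epoch; duration is the mean retained run length (ms).
Both are averaged over epochs (durations only over epochs where the class
occurs), then reported per participant, condition, and run.

## Statistics

* **TANOVA.** Topographic differences are tested nonparametrically.
  Participant maps are GFP-normalized; the effect statistic is the sum over
  factor levels of the GFP of (level-mean map − grand-mean map). The null
  permutes, within each participant, the labels of the factor under test
  (condition labels, class labels, or both cells jointly for the
  interaction). P-values use the add-one estimator
  $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$ with a
  mandatory seed, 5000 permutations by default. The statistic follows the
  generalized-dissimilarity convention of the randomization-test literature;
  this is the largest interpretive choice in the package, since the procedure
  is usually described rather than written as a formula. Paired TANOVAs use
  the GFP of the difference of GFP-normalized grand means, with random A/B
  swaps within participants.
* **RM-ANOVA with Greenhouse–Geisser correction.** Fully within-subject
  designs (1–3 factors; the study's shapes are condition 3-level, TRP
  3×5×2, parameters 4×K) are decomposed via orthonormal contrasts per
  effect; Mauchly's test on the contrast covariance decides (at p < 0.05)
  whether the Greenhouse–Geisser epsilon rescales both degrees of freedom.
  Partial eta squared is $SS_e/(SS_e + SS_{err})$. The implementation is
  validated in the tests against base R's `aov()` error-stratum
  decomposition on random tables.
* **Paired t-tests** with 95% CIs and Bonferroni adjustment
  ($p_\text{adj} = \min(1, m\,p)$ over the requested family); completion
  times are z-scored within participants (per-condition family for run
  contrasts, all tasks for condition contrasts) before testing.

## The synthetic study generator

`generate_study()` emulates the experiment's structure: per participant one
3-min rest baseline plus three runs of three self-paced task conditions
(idea generation, idea evolution, evaluation) at 500 Hz, completion times
drawn truncated-normal on [5, 180] s with condition means 54.047, 92.785,
and 16.476 s (sds scaled from the reported standard errors at n = 28).

Each recording is rendered from a planted label sequence over six template
topographies: run lengths are gamma-distributed (shape 2, mean 100 ms —
microstate dwell times are non-exponential and typically 60–125 ms), with no
immediate self-transitions and condition-specific class weights. The signal
at each sample is the active template times an activity waveform — a 10 Hz
alpha oscillation plus template-locked broadband 1–30 Hz fluctuation at half
its amplitude — so GFP peaks occur every ~20–30 ms as in real broadband EEG
rather than only at alpha crests (otherwise dwell times shorter than half an
alpha cycle would be invisible to peak-based backfitting). The alpha
intensity scale (100 µV, peak GFP ≈ 12.6 µV over 63 channels) and channel
noise (1/f-shaped, 5 µV sd, plus a 1 µV white floor) give a realistic
alpha-dominated band. Task conditions multiply the activity amplitude by
region-wise gains below 1 (alpha desynchronization, strongest centrally
during evaluation), and per-participant templates are jittered mixtures
(spatial correlation ≥ 0.9 with the group template) so the permutation
alignment stage is non-trivial but solvable.

What the generator does *not* emulate: eye/muscle/cardiac artifacts and bad
channels (artifact detection is out of scope; bad-channel masks are an
input), within-recording non-stationarity of condition effects, spatially
correlated sensor noise, biophysical forward modelling (templates are smooth
geometric maps, not dipole fields), and individual alpha-frequency
variability. Passing recovery tests therefore demonstrates that the
estimators are correct and well-calibrated under the assumed signal model,
not that the pipeline is robust to real-world artifacts.

## Preprocessing stand-in

The published preprocessing chain behind the original study (automated
artifact pipelines, wavelet-ICA, channel-quality classifiers) is external to
this package. The package's preprocessing is deliberately minimal and fully
specified: zero-phase 4th-order Butterworth band-pass (forward–backward, so
microstate timing is preserved; the band families are 1–30 Hz for
microstates and 8–10/10–12 Hz for alpha power), average reference,
consecutive non-overlapping 2-s epochs with the trailing partial epoch
dropped, an epoch kept iff its bad-channel ratio is strictly below 0.25, and
bad channels in kept epochs replaced by a distance-weighted (1/d) mean of
the 4 nearest good channels — an intentionally simple, replaceable stand-in
for spherical-spline interpolation.

## Problem sizes used by the tests and the acceptance script

The recovery checks run on a 4-participant synthetic study. The test suite
uses reduced recording durations (40 s rest; task completion means 30/45/12 s)
— the package's choice of a test-scale instance; shorter recordings make
recovery harder, not easier. The acceptance script uses the generator's
default durations. TANOVA calibration uses 500 (tests) or 300 (script) null
replicates at 200 permutations, n = 16 participants; the power check plants
a condition topography correlated 0.8 with the others at n = 28 with
between-subject map noise of 0.6 sd (subject-to-group correlation ≈ 0.85,
typical of template topographies).

## Known limitations

* Backfitted durations are upward-biased by a few percent: dwell runs
  shorter than the local GFP-peak spacing leave no peak and merge into their
  neighbours. The bias shrinks as peak density grows and is within the 15%
  recovery tolerance at the default signal model.
* The CV criterion's penalty assumes independent maps; GFP-peak maps are
  weakly dependent, so the selected K can drift by ±1 at low SNR.
* TANOVA assumes exchangeability of cells within participants under the
  null; unbalanced or incomplete designs are refused rather than
  approximated.
* `rm_anova_gg()` requires complete, balanced within-subject tables.
* The BrainVision and EDF readers cover continuous recordings with a single
  sampling rate (the formats' common case for this design), not segmented or
  mixed-rate files.
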