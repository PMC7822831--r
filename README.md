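# eegms

Microstate and task-related alpha power analysis for EEG recorded under
loosely controlled, self-paced task designs.

## The problem

In a loosely controlled creativity experiment a participant works on each
task — idea generation, idea evolution, evaluation — at their own pace for up
to three minutes, after a resting baseline, across three runs. There is no
stimulus to average around, so the analysis characterizes the ongoing signal
in two ways:

* **Task-related power (TRP)** in the lower (8–10 Hz) and upper (10–12 Hz)
  alpha sub-bands: for channel *i* and condition *k*,

  `TRP_ki = mean_j ( log Pow_i,task(k,j) − log Pow_i,rest )`,

  the mean over runs of the log band-power change against the resting
  reference (Welch spectra on 2-s windows, composite Simpson band
  integration). Negative values are alpha desynchronization. Channel values
  are aggregated into five cortical areas per hemisphere.

* **EEG microstates**: brief quasi-stable scalp field configurations. Maps at
  the peaks of global field power (GFP, the spatial sd of the field) are
  clustered by a polarity-invariant modified k-means into K unit-norm
  template topographies Γ_k, minimizing

  `F = Σ_t ||V_t − a_kt Γ_k||² / (N_T (N_S − 1))`, with `a_kt = V_t'Γ_k`,

  K selected over 1..10 by a cross-validation criterion with penalty
  `((N_S−1)/(N_S−1−N_K))²`. Run-level templates are averaged up the
  run → participant → condition → global hierarchy by full-permutation class
  matching with polarity ignored; the global templates are backfit to the
  data, the first and last microstate of every 2-s epoch are discarded, and
  per-class coverage and mean duration are computed.

Statistics follow the study's families: TANOVA randomization tests on
topographies (GFP of level-mean minus grand-mean maps, labels permuted
within participants), within-subject ANOVA with Greenhouse–Geisser
correction and partial eta squared, paired t-tests with Bonferroni
adjustment, and within-participant normalization of completion times.

A synthetic study generator (`generate_study()`) emulates the full design —
planted template sequences, condition-dependent alpha gains and coverage
weights, 1/f channel noise, condition-dependent completion times — and
returns the ground truth, so every stage has a recoverable target. See the
methods vignette (`vignettes/eegms-methods.Rmd`) for the models, parameter
defaults, and design choices.

## Worked example

Simulate one minute of EEG with six planted microstate classes, fit the
model on GFP peaks, and read off the parameters:

```r
library(eegms)
montage <- make_montage()
tpl     <- canonical_templates(montage)
labels  <- sample_label_sequence(K = 6, mean_dur = 100, n_samples = 30000,
                                 srate = 500, seed = 42)
rec     <- render_recording(labels, tpl, alpha_gain = 1, noise_sd = 5, seed = 7)
ep      <- epoch_and_reject(rereference_average(bandpass_filter(rec, c(1, 30))),
                            montage)
fit     <- fit_modified_kmeans(gfp_peak_maps(ep), K = 6, restarts = 100, seed = 1)
print(assign_class_letters(fit))
#> Microstate model: K = 6 (run level), fitted on 1640 maps
#>   cost F = 13.8902, CV = 17.0261, GEV = 0.936
#>   class letters: E D B A C F

round(compute_parameters(predict(fit, ep)), 3)
#>   class coverage duration_ms n_epochs
#> 1     1    0.176     101.256       30
#> 2     2    0.137      91.143       29
#> 3     3    0.183     105.031       30
#> 4     4    0.161     109.637       29
#> 5     5    0.174     102.774       29
#> 6     6    0.170     107.614       29
```

The model explains 93.6% of the topographic variance at the GFP peaks
(`GEV`), every planted class is recovered (each fitted template correlates
|r| ≈ 1.0 with a distinct planted template), coverages are near the planted
uniform 1/6 and durations near the planted 100 ms mean dwell time. A full
study runs through `run_pipeline()` (or the CLI in `inst/cli.R`:
`simulate`, `preprocess`, `trp`, `microstates`, `stats`, `run-all`), which
writes stage CSVs and a seed-stamped `report.json` that is byte-identical
across reruns with the same config and seed.

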