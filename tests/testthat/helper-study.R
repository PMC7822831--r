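# Shared fixtures, generated in code. The "test study" is a scaled-down
# synthetic study (shorter recordings than the generator defaults, same noise
# and effect structure) so the recovery checks run at test-suite scale; it is
# generated once and cached for the session.

.eegms_cache <- new.env(parent = emptyenv())

test_montage <- function() {
  if (is.null(.eegms_cache$montage)) .eegms_cache$montage <- make_montage()
  .eegms_cache$montage
}

test_templates <- function() {
  if (is.null(.eegms_cache$templates))
    .eegms_cache$templates <- canonical_templates(test_montage())
  .eegms_cache$templates
}

# 4 participants, default noise/effects, reduced durations.
test_study_config <- function() {
  cfg <- study_config(n_participants = 4)
  cfg$rest_duration_s <- 40
  cfg$time_means <- c(generation = 30, evolution = 45, evaluation = 12)
  cfg$time_sds <- c(generation = 6, evolution = 8, evaluation = 3)
  cfg$time_range <- c(8, 60)
  cfg
}

test_study <- function() {
  if (is.null(.eegms_cache$study))
    .eegms_cache$study <- generate_study(test_study_config(), seed = 20260901)
  .eegms_cache$study
}

# 1-30 Hz average-referenced epochs of the test study, computed lazily.
test_study_epochs <- function() {
  if (is.null(.eegms_cache$epochs)) {
    study <- test_study()
    .eegms_cache$epochs <- lapply(study$recordings, function(rec)
      epoch_and_reject(rereference_average(bandpass_filter(rec, c(1, 30))),
                       study$montage))
  }
  .eegms_cache$epochs
}

# Run-level K=6 fits on the test study (cached; used by the recovery checks).
test_run_models <- function(restarts = 100L) {
  if (is.null(.eegms_cache$run_models)) {
    study <- test_study()
    eps <- test_study_epochs()
    .eegms_cache$run_models <- lapply(seq_along(eps), function(i) {
      r <- study$index[i, ]
      fit_modified_kmeans(gfp_peak_maps(eps[[i]]), 6, restarts = restarts,
                          seed = seed_stream(20260901,
                                             sprintf("fit/p%d/%s/r%d",
                                                     r$participant,
                                                     r$condition, r$run)))
    })
  }
  .eegms_cache$run_models
}

# Small single-recording fixture for unit-level microstate tests.
test_single_recording <- function(weights = rep(1 / 6, 6), seconds = 40,
                                  seed = 42) {
  labels <- sample_label_sequence(6, weights, 100, seconds * 500, 500,
                                  seed = seed)
  rec <- render_recording(labels, test_templates(), 1, 5, seed = seed + 1)
  list(labels = labels, rec = rec)
}
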