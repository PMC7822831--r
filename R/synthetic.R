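# Synthetic study generator. Emulates the structure of a loosely controlled,
# self-paced creativity experiment: a 3-min rest baseline followed by three
# runs of three task conditions (idea generation, idea evolution, evaluation)
# at 500 Hz, with planted microstate template sequences, condition-dependent
# alpha-band amplitude, 1/f background noise, and condition-dependent task
# completion times. Every planted quantity is returned as ground truth so
# downstream stages have a recoverable target.

#' Six canonical reference topographies (synthetic)
#'
#' Builds six smooth, average-referenced, unit-norm reference maps from the
#' montage geometry: two diagonal gradients (left-posterior/right-anterior
#' and its mirror), an anterior-posterior gradient, and three radial blobs
#' (vertex, parieto-occipital, frontal). They serve as (a) the default
#' planted templates of the generator and (b) the packaged reference set used
#' to assign class letters A-F; they are geometric stand-ins, not empirical
#' group maps.
#'
#' @param montage A [make_montage()] montage.
#' @return channels x 6 matrix with columns `A`..`F`.
#' @export
canonical_templates <- function(montage = make_montage()) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  blob <- function(center, sd = 0.55) {
    center <- center / sqrt(sum(center^2))
    exp(-rowSums(sweep(p, 2L, center)^2) / (2 * sd^2))
  }
  tpl <- cbind(
    A = drop(p %*% c(1, 1, 0)) / sqrt(2),
    B = drop(p %*% c(-1, 1, 0)) / sqrt(2),
    C = drop(p %*% c(0, 1, 0)),
    D = blob(c(0, 0, 1)),
    E = blob(c(0, -0.9, 0.44)),
    F = blob(c(0, 0.9, 0.44))
  )
  tpl <- unit_norm(avg_ref_cols(tpl))
  rownames(tpl) <- montage$channel
  tpl
}

# Column-wise average reference for a channels x maps matrix.
avg_ref_cols <- function(m) sweep(m, 2L, colMeans(m))

#' Sample a piecewise-constant microstate label sequence
#'
#' Run lengths are drawn from a gamma distribution with shape 2 and the
#' requested mean (microstate dwell times are non-exponential); each run's
#' class is drawn from `weights`, with no immediate self-transition when
#' `K > 1`.
#'
#' @param K Number of classes (>= 1).
#' @param weights Per-class probabilities (sum to 1).
#' @param mean_dur Mean run duration in ms (> 0).
#' @param n_samples Sequence length in samples.
#' @param srate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Integer vector of length `n_samples` with values in `1..K`.
#' @export
sample_label_sequence <- function(K, weights = rep(1 / K, K), mean_dur = 100,
                                  n_samples, srate = 500, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  if (mean_dur <= 0) stop("mean_dur must be positive")
  stopifnot(length(weights) == K, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  with_seed(seed, {
    labels <- integer(0)
    prev <- 0L
    while (length(labels) < n_samples) {
      dur_ms <- stats::rgamma(1L, shape = 2, scale = mean_dur / 2)
      len <- max(1L, as.integer(round(dur_ms * srate / 1000)))
      if (K == 1L) {
        cls <- 1L
      } else {
        w <- weights
        if (prev > 0L) w[prev] <- 0
        cls <- sample.int(K, 1L, prob = w)
      }
      labels <- c(labels, rep(cls, len))
      prev <- cls
    }
    labels[seq_len(n_samples)]
  })
}

# 1/f-amplitude ("pink"-like) noise, channels x samples, each row unit sd.
# Synthesis runs at a highly composite FFT length and truncates, so
# arbitrary recording durations do not hit slow prime-length transforms.
.pink_noise <- function(nch, n, srate) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  w <- matrix(stats::rnorm(nch * n2), nrow = n2, ncol = nch)
  f <- c(0, seq_len(n2 - 1)) * srate / n2
  f <- pmin(f, srate - f)                       # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))                     # flat below 1 Hz
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n2
  x <- x[seq_len(n), , drop = FALSE]
  x <- sweep(x, 2L, apply(x, 2L, stats::sd), "/")
  t(x)
}

# Band-limited (1-30 Hz) unit-sd series used as template-locked broadband
# activity; generated spectrally so no filter transients.
.broadband_activity <- function(n, srate) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(n2)
  f <- c(0, seq_len(n2 - 1)) * srate / n2
  f <- pmin(f, srate - f)
  g <- as.numeric(f >= 1 & f <= 30)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n2
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Render a multichannel EEG recording from a planted label sequence
#'
#' Each sample is the active template scaled by an activity waveform (an
#' 8-12 Hz alpha oscillation plus template-locked broadband 1-30 Hz
#' fluctuation), plus spatially white 1/f-shaped channel noise and a small
#' white-noise floor. Per-channel alpha gains modulate the signal amplitude
#' (power scales with gain squared). The output is average-referenced.
#'
#' @param labels Integer label sequence (values index `templates` columns).
#' @param templates channels x K matrix of average-referenced unit-norm maps.
#' @param alpha_gain Scalar or per-channel multiplicative amplitude factor.
#' @param noise_sd Per-channel sd of the 1/f noise in microvolts (a white
#'   floor of `0.2 * noise_sd` is added); 0 gives a noiseless rendering.
#' @param seed Integer seed.
#' @param srate Sampling rate, Hz.
#' @param amp Alpha intensity scale in microvolts (peak template intensity;
#'   default 100 gives peak GFP near 12.6 \eqn{\mu}V over 63 channels).
#' @param bb_frac Broadband activity amplitude as a fraction of `amp`.
#' @param alpha_freq Alpha frequency in Hz.
#' @param condition,run Annotations for the returned recording.
#' @param channels Channel names (default from `templates` rownames).
#' @return An `eeg_recording`.
#' @export
render_recording <- function(labels, templates, alpha_gain = 1, noise_sd = 5,
                             seed = 1L, srate = 500, amp = 100, bb_frac = 0.5,
                             alpha_freq = 10, condition = NA_character_,
                             run = 0L, channels = rownames(templates)) {
  templates <- as.matrix(templates)
  nch <- nrow(templates)
  n <- length(labels)
  if (any(labels < 1L) || any(labels > ncol(templates)))
    stop("labels index templates out of range")
  if (length(alpha_gain) == 1L) alpha_gain <- rep(alpha_gain, nch)
  if (length(alpha_gain) != nch)
    stop("alpha_gain must be scalar or one value per channel (",
         nch, "), got ", length(alpha_gain))
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  dat <- with_seed(seed, {
    phase <- stats::runif(1L, 0, 2 * pi)
    osc <- sin(2 * pi * alpha_freq * seq_len(n) / srate + phase)
    bb <- if (bb_frac > 0) .broadband_activity(n, srate) else numeric(n)
    activity <- amp * (osc + bb_frac * bb)
    sig <- templates[, labels, drop = FALSE] *
      rep(activity, each = nch) * alpha_gain
    if (noise_sd > 0) {
      sig <- sig + noise_sd * .pink_noise(nch, n, srate) +
        (0.2 * noise_sd) * matrix(stats::rnorm(nch * n), nrow = nch)
    }
    sig
  })
  dat <- sweep(dat, 2L, colMeans(dat))
  recording(dat, srate, channels, condition, run)
}

#' Default configuration of the synthetic study
#'
#' Encodes the emulated experiment: 3-min rest baseline, three runs each
#' containing the three task conditions at 500 Hz, self-paced completion
#' times truncated to `[5, 180]` s with the reported condition means
#' (generation 54.047 s, evolution 92.785 s, evaluation 16.476 s; sds scaled
#' from the reported standard errors at n = 28), 100 ms mean microstate
#' dwell time over six planted classes, mild condition-specific coverage
#' biases, and task alpha amplitude gains below 1 (alpha desynchronization
#' relative to rest, strongest centrally during evaluation).
#'
#' @param n_participants Number of participants (default 28).
#' @param condition_effects Set `FALSE` for a null study: all alpha gains 1
#'   and uniform coverage in every condition.
#' @return A named list; override entries freely before passing to
#'   [generate_study()].
#' @export
study_config <- function(n_participants = 28, condition_effects = TRUE) {
  uniform <- rep(1 / 6, 6)
  cov_bias <- rbind(
    rest       = uniform,
    generation = c(1, 1, 1, 1.6, 1, 1.4) / 7,
    evolution  = c(1, 1, 1.6, 1, 1.5, 0.9) / 7,
    evaluation = c(0.9, 1, 1.3, 1, 0.8, 1.7) / 6.7
  )
  cov_bias <- cov_bias / rowSums(cov_bias)
  gains <- list(rest = list(default = 1),
                generation = list(default = 0.75),
                evolution  = list(default = 0.9),
                evaluation = list(default = 0.8, central = 0.7))
  if (!condition_effects) {
    cov_bias[] <- rep(uniform, each = 4)
    gains <- lapply(gains, function(g) list(default = 1))
  }
  list(
    n_participants = n_participants,
    n_runs = 3L,
    srate = 500,
    K = 6L,
    rest_duration_s = 180,
    time_means = c(generation = 54.047, evolution = 92.785, evaluation = 16.476),
    time_sds = c(generation = 4.441, evolution = 5.192, evaluation = 1.089) * sqrt(28),
    time_range = c(5, 180),
    mean_run_duration_ms = 100,
    condition_coverage_bias = cov_bias,
    condition_alpha_gain = gains,
    amp = 100,
    bb_frac = 0.5,
    noise_sd = 5,
    alpha_freq = 10,
    template_jitter = 0.3,
    condition_effects = condition_effects
  )
}

# Expand a per-condition gain spec (list(default=, central=, frontal=, ...))
# into a per-channel vector using montage area labels.
.gains_per_channel <- function(spec, montage) {
  g <- rep(spec$default %||% 1, nrow(montage))
  for (a in setdiff(names(spec), "default"))
    g[montage$area == a] <- spec[[a]]
  g
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Jitter a template set: mix each column with a random average-referenced
# direction so the spatial correlation with the original stays near
# sqrt(1 - eps^2) (>= 0.9 for eps <= 0.43).
.jitter_templates <- function(templates, eps) {
  nch <- nrow(templates)
  out <- templates
  for (k in seq_len(ncol(templates))) {
    d <- unit_norm(avg_ref(stats::rnorm(nch)))
    d <- d - sum(d * templates[, k]) * templates[, k]   # orthogonal component
    d <- unit_norm(d)
    out[, k] <- sqrt(1 - eps^2) * templates[, k] + eps * d
  }
  unit_norm(avg_ref_cols(out))
}

#' Generate a full synthetic study with ground truth
#'
#' For each participant: one rest recording plus `n_runs` recordings of each
#' task condition, rendered from participant-jittered versions of the planted
#' group templates, with condition-dependent coverage weights, alpha gains,
#' and completion times (truncated normal). All randomness derives from
#' `seed` via named streams, so any single recording is reproducible in
#' isolation.
#'
#' @param config A [study_config()] list (entries may be overridden).
#' @param seed Master integer seed.
#' @param montage Montage (default [make_montage()]).
#' @param templates Planted group templates (default [canonical_templates()]).
#' @return An object of class `eeg_study`: list with `recordings` (flat list
#'   of `eeg_recording`s), `index` (data frame participant/condition/run),
#'   `times` (data frame of completion times, s), `ground_truth`, `montage`,
#'   `config`.
#' @export
generate_study <- function(config = study_config(), seed = 1L,
                           montage = make_montage(),
                           templates = canonical_templates(montage)) {
  if (config$n_participants < 2L)
    stop("at least 2 participants are required for paired statistics")
  K <- config$K
  stopifnot(ncol(templates) >= K)
  templates <- templates[, seq_len(K), drop = FALSE]
  conds <- condition_levels()

  times <- expand.grid(participant = seq_len(config$n_participants),
                       condition = task_conditions(),
                       run = seq_len(config$n_runs),
                       stringsAsFactors = FALSE)
  times <- times[order(times$participant, match(times$condition, conds), times$run), ]
  times$seconds <- NA_real_
  for (i in seq_len(nrow(times))) {
    cond <- times$condition[i]
    times$seconds[i] <- with_seed(
      seed_stream(seed, sprintf("times/p%d/%s/r%d", times$participant[i],
                                cond, times$run[i])),
      .truncnorm(1L, config$time_means[[cond]], config$time_sds[[cond]],
                 config$time_range[1], config$time_range[2]))
  }

  recordings <- list()
  index <- data.frame(participant = integer(0), condition = character(0),
                      run = integer(0))
  label_store <- list()
  participant_templates <- list()
  for (p in seq_len(config$n_participants)) {
    ptpl <- with_seed(seed_stream(seed, sprintf("jitter/p%d", p)),
                      .jitter_templates(templates, config$template_jitter))
    participant_templates[[p]] <- ptpl
    cells <- rbind(data.frame(condition = "rest", run = 0L),
                   expand.grid(condition = task_conditions(),
                               run = seq_len(config$n_runs),
                               stringsAsFactors = FALSE))
    for (ci in seq_len(nrow(cells))) {
      cond <- cells$condition[ci]; run <- cells$run[ci]
      dur_s <- if (cond == "rest") config$rest_duration_s else
        times$seconds[times$participant == p & times$condition == cond &
                        times$run == run]
      n <- as.integer(round(dur_s * config$srate))
      key <- sprintf("p%d/%s/r%d", p, cond, run)
      labels <- sample_label_sequence(
        K, config$condition_coverage_bias[cond, ], config$mean_run_duration_ms,
        n, config$srate, seed_stream(seed, paste0("labels/", key)))
      gains <- .gains_per_channel(config$condition_alpha_gain[[cond]], montage)
      rec <- render_recording(
        labels, ptpl, gains, config$noise_sd,
        seed_stream(seed, paste0("render/", key)), config$srate, config$amp,
        config$bb_frac, config$alpha_freq, cond, run, montage$channel)
      recordings[[length(recordings) + 1L]] <- rec
      index <- rbind(index, data.frame(participant = p, condition = cond,
                                       run = run))
      label_store[[key]] <- labels
    }
  }

  ground_truth <- list(
    templates = templates,
    participant_templates = participant_templates,
    label_sequences = label_store,
    mean_run_duration_ms = config$mean_run_duration_ms,
    condition_alpha_gain = config$condition_alpha_gain,
    condition_coverage_bias = config$condition_coverage_bias,
    time_means = config$time_means,
    time_sds = config$time_sds
  )
  structure(list(recordings = recordings, index = index, times = times,
                 ground_truth = ground_truth, montage = montage,
                 config = config, seed = seed),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("Synthetic EEG study: %d participants, %d recordings, %g Hz\n",
              x$config$n_participants, length(x$recordings), x$config$srate))
  invisible(x)
}

#' Write / read a study directory
#'
#' Recordings are stored in the matrix + sidecar interchange format, next to
#' `times.csv`, `montage.csv` and `ground_truth.json`.
#'
#' @param study An `eeg_study`.
#' @param dir Output directory (created).
#' @return `read_study` returns an `eeg_study` (ground-truth label sequences
#'   and participant templates are restored from JSON).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study$recordings)) {
    r <- study$index[i, ]
    write_recording_matrix(
      study$recordings[[i]],
      file.path(dir, sprintf("p%02d_%s_r%d.tsv", r$participant, r$condition, r$run)))
  }
  utils::write.csv(study$times, file.path(dir, "times.csv"), row.names = FALSE)
  write_montage_csv(study$montage, file.path(dir, "montage.csv"))
  gt <- study$ground_truth
  gt$templates <- unname(as.data.frame(gt$templates))
  gt$participant_templates <- lapply(gt$participant_templates,
                                     function(m) unname(as.data.frame(m)))
  gt$condition_coverage_bias <- as.data.frame(gt$condition_coverage_bias)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(study$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  montage <- read_montage_csv(file.path(dir, "montage.csv"))
  times <- utils::read.csv(file.path(dir, "times.csv"), stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "^p[0-9]+_.*\\.tsv$", full.names = TRUE))
  recordings <- list()
  index <- data.frame(participant = integer(0), condition = character(0),
                      run = integer(0))
  for (f in files) {
    m <- regmatches(basename(f),
                    regexec("^p([0-9]+)_([a-z]+)_r([0-9]+)\\.tsv$", basename(f)))[[1]]
    rec <- read_recording_matrix(f, montage)
    recordings[[length(recordings) + 1L]] <- rec
    index <- rbind(index, data.frame(participant = as.integer(m[2]),
                                     condition = m[3], run = as.integer(m[4])))
  }
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  if (!is.null(gt$templates)) gt$templates <- as.matrix(gt$templates)
  if (!is.null(gt$participant_templates))
    gt$participant_templates <- lapply(gt$participant_templates, as.matrix)
  if (!is.null(gt$condition_coverage_bias))
    gt$condition_coverage_bias <- as.matrix(gt$condition_coverage_bias)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  ord <- order(index$participant, match(index$condition, condition_levels()),
               index$run)
  structure(list(recordings = recordings[ord], index = index[ord, ],
                 times = times, ground_truth = gt, montage = montage,
                 config = config, seed = NA_integer_),
            class = "eeg_study")
}
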