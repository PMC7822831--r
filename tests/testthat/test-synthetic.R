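test_that("label sequences partition time and hit the requested mean dwell", {
  # degenerate single class
  lab1 <- sample_label_sequence(1, 1, 80, 500, 500, seed = 1)
  expect_true(all(lab1 == 1L))
  expect_length(lab1, 500L)

  # empirical mean run length within 10% of 80 ms at K = 6
  lab <- sample_label_sequence(6, rep(1 / 6, 6), 80, 30000, 500, seed = 2)
  r <- rle(lab)
  expect_equal(sum(r$lengths), 30000L)
  mean_ms <- mean(r$lengths) * 1000 / 500
  expect_lt(abs(mean_ms - 80) / 80, 0.10)

  # no immediate self-transitions
  expect_true(all(r$values[-1] != r$values[-length(r$values)]))

  expect_error(sample_label_sequence(0, numeric(0), 80, 100, 500, 1), "K")
  expect_error(sample_label_sequence(3, rep(1 / 3, 3), -5, 100, 500, 1),
               "positive")
})

test_that("noiseless renderings are template-pure, average-referenced, deterministic", {
  tpl <- test_templates()
  lab <- sample_label_sequence(6, rep(1 / 6, 6), 100, 2000, 500, seed = 5)
  rec <- render_recording(lab, tpl, 1, noise_sd = 0, seed = 9)
  # every sample correlates +-1 with its active template
  cc <- abs(vapply(seq_len(2000), function(t)
    suppressWarnings(cor(rec$data[, t], tpl[, lab[t]])), numeric(1)))
  expect_true(all(cc[is.finite(cc)] > 1 - 1e-9))
  expect_lt(max(abs(colMeans(rec$data))), 1e-10)

  rec2 <- render_recording(lab, tpl, 1, noise_sd = 0, seed = 9)
  expect_identical(rec$data, rec2$data)

  expect_error(render_recording(c(1, 7), tpl, 1, 0, 1), "range")
  expect_error(render_recording(lab, tpl, c(1, 2), 0, 1), "per channel")
})

test_that("alpha band power scales monotonically with the alpha gain", {
  tpl <- test_templates()
  lab <- sample_label_sequence(6, rep(1 / 6, 6), 100, 10000, 500, seed = 6)
  bp <- vapply(c(0.5, 0.8, 1, 1.3), function(g) {
    rec <- render_recording(lab, tpl, g, noise_sd = 5, seed = 31)
    psd <- welch_psd(rec$data, 500, 1000, 500)
    mean(band_power(psd, c(8, 12)))
  }, numeric(1))
  expect_true(all(diff(bp) > 0))
})

test_that("backfitting true templates onto a noiseless rendering recovers labels", {
  tpl <- test_templates()
  lab <- sample_label_sequence(6, rep(1 / 6, 6), 100, 10000, 500, seed = 7)
  rec <- render_recording(lab, tpl, 1, noise_sd = 0, seed = 8)
  ep <- epoch_and_reject(rec, test_montage())
  model <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  seg <- backfit_labels(ep, model, at = "samples")
  got <- unlist(seg$labels)
  truth <- lab[seq_along(got)]
  expect_gt(mean(got == truth), 0.99)
})

test_that("study structure matches the experimental design", {
  study <- test_study()
  idx <- study$index
  expect_equal(length(study$recordings), 4 * (1 + 9))
  for (p in 1:4) {
    expect_equal(sum(idx$participant == p & idx$condition == "rest"), 1L)
    expect_equal(sum(idx$participant == p & idx$condition != "rest"), 9L)
  }
  # durations: tasks bounded by the configured range, rest as configured
  secs <- vapply(study$recordings, function(r) ncol(r$data) / r$srate,
                 numeric(1))
  expect_true(all(secs[idx$condition != "rest"] <= 60 + 1e-9))
  expect_equal(unique(secs[idx$condition == "rest"]), 40)
  # planted coverage weights sum to 1 per condition
  expect_equal(unname(rowSums(study$ground_truth$condition_coverage_bias)),
               rep(1, 4))
  expect_error(generate_study(study_config(n_participants = 1), 1),
               "2 participants")
})

test_that("a null configuration plants no condition effects", {
  cfg <- study_config(n_participants = 2, condition_effects = FALSE)
  gains <- unlist(lapply(cfg$condition_alpha_gain, unlist))
  expect_true(all(gains == 1))
  expect_true(all(abs(cfg$condition_coverage_bias - 1 / 6) < 1e-12))
})

test_that("completion times are truncated normal with the configured ordering", {
  cfg <- study_config()
  draw <- function(cond) with_seed(seed_stream(99, cond),
    eegms:::.truncnorm(400, cfg$time_means[[cond]], cfg$time_sds[[cond]],
                       cfg$time_range[1], cfg$time_range[2]))
  g <- draw("generation"); ev <- draw("evolution"); ee <- draw("evaluation")
  expect_true(mean(ev) > mean(g) && mean(g) > mean(ee))
  expect_true(all(c(g, ev, ee) >= 5 & c(g, ev, ee) <= 180))
})

test_that("participant template jitter stays close to the group templates", {
  study <- test_study()
  tpl <- study$ground_truth$templates
  for (p in 1:4) {
    ptpl <- study$ground_truth$participant_templates[[p]]
    cc <- abs(diag(cor(ptpl, tpl)))
    expect_true(all(cc >= 0.9))
  }
})

test_that("study directories round-trip through write_study/read_study", {
  cfg <- study_config(n_participants = 2)
  cfg$rest_duration_s <- 4
  cfg$time_means <- c(generation = 4, evolution = 5, evaluation = 3)
  cfg$time_sds <- c(generation = 1, evolution = 1, evaluation = 0.5)
  cfg$time_range <- c(2.5, 8)
  study <- generate_study(cfg, seed = 77)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(length(back$recordings), length(study$recordings))
  i <- which(back$index$participant == 2 & back$index$condition == "evolution" &
               back$index$run == 2)
  j <- which(study$index$participant == 2 & study$index$condition == "evolution" &
               study$index$run == 2)
  expect_identical(unname(back$recordings[[i]]$data),
                   unname(study$recordings[[j]]$data))
  expect_equal(as.matrix(back$ground_truth$templates),
               unname(study$ground_truth$templates), tolerance = 1e-12,
               ignore_attr = TRUE)
})
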