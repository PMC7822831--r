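# Build an eeg_epochs object directly from a list of channels x samples blocks.
as_epochs <- function(blocks, srate = 500) {
  structure(list(epochs = blocks, kept_mask = rep(TRUE, length(blocks)),
                 srate = srate, channels = paste0("ch", seq_len(nrow(blocks[[1]]))),
                 condition = NA_character_, run = 0L, band = "1-30"),
            class = "eeg_epochs")
}

test_that("exact template maps are labeled regardless of polarity", {
  tpl <- test_templates()
  model <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  # samples proportional to +Gamma_3 / -Gamma_3 with varying gain
  gains <- rep(c(5, -7, 9, -11), length.out = 40)
  block <- tpl[, 3, drop = FALSE][, rep(1, 40)] * rep(gains, each = nrow(tpl))
  seg <- backfit_labels(as_epochs(list(block)), model, at = "samples")
  expect_true(all(seg$labels[[1]] == 3L))
  # a single run spans the epoch: edge removal retains nothing
  expect_false(any(seg$retained[[1]]))
})

test_that("edge-removal worked example: runs A(2) B(3) A(1) leave only B", {
  tpl <- test_templates()
  model <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  lab <- c(1, 1, 2, 2, 2, 1)
  block <- tpl[, lab] * 10
  seg <- backfit_labels(as_epochs(list(block)), model, at = "samples")
  expect_equal(seg$labels[[1]], lab)
  expect_equal(which(seg$retained[[1]]), 3:5)
  par <- compute_parameters(seg, srate = 500)
  expect_equal(par$coverage[2], 1.0)
  expect_equal(sum(par$coverage), 1.0)
  expect_equal(par$duration_ms[2], 6)               # 3 samples at 500 Hz
  expect_true(all(is.na(par$duration_ms[-2])))
  expect_true(all(par$coverage[-2] == 0))
})

test_that("between-peak samples inherit the nearest peak label with early ties", {
  tpl <- test_templates()
  model <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  # two separated bumps: peak 1 (class 1) at t=3, peak 2 (class 2) at t=9
  env1 <- c(1, 2, 5, 2, 1, 0, 0, 0, 0, 0, 0)
  env2 <- c(0, 0, 0, 0, 0, 0, 1, 2, 5, 2, 1)
  block <- tpl[, 1, drop = FALSE][, rep(1, 11)] * rep(env1, each = nrow(tpl)) +
    tpl[, 2, drop = FALSE][, rep(1, 11)] * rep(env2, each = nrow(tpl))
  seg <- backfit_labels(as_epochs(list(block)), model, at = "peaks")
  lab <- seg$labels[[1]]
  # midpoint of peaks 3 and 9 is 6; samples 1..6 -> class 1, 7..11 -> class 2
  expect_equal(lab, c(rep(1L, 6), rep(2L, 5)))
})

test_that("epochs with fewer than two peaks are excluded", {
  tpl <- test_templates()
  model <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  flat <- tpl[, 1, drop = FALSE][, rep(1, 20)]      # constant GFP, no peaks
  seg <- backfit_labels(as_epochs(list(flat)), model)
  expect_equal(seg$excluded, 1L)
  expect_false(any(seg$retained[[1]]))
  expect_error(compute_parameters(seg), "retained")
})

test_that("coverage and duration are invariant to template relabeling and sign", {
  sr <- test_single_recording(seconds = 10)
  ep <- epoch_and_reject(rereference_average(bandpass_filter(sr$rec, c(1, 30))),
                         test_montage())
  tpl <- test_templates()
  m1 <- structure(list(templates = tpl, K = 6L), class = "microstate_model")
  perm <- c(3, 6, 1, 4, 2, 5)
  signs <- c(-1, 1, -1, 1, 1, -1)
  m2 <- structure(list(templates = sweep(tpl[, perm], 2, signs, "*"), K = 6L),
                  class = "microstate_model")
  p1 <- compute_parameters(backfit_labels(ep, m1))
  p2 <- compute_parameters(backfit_labels(ep, m2))
  expect_equal(p2$coverage, p1$coverage[perm], tolerance = 1e-12)
  expect_equal(p2$duration_ms, p1$duration_ms[perm], tolerance = 1e-12)
})

test_that("per-epoch coverages sum to one over classes", {
  sr <- test_single_recording(seconds = 10)
  ep <- epoch_and_reject(rereference_average(bandpass_filter(sr$rec, c(1, 30))),
                         test_montage())
  model <- structure(list(templates = test_templates(), K = 6L),
                     class = "microstate_model")
  par <- compute_parameters(backfit_labels(ep, model))
  expect_equal(sum(par$coverage), 1, tolerance = 1e-12)
})
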