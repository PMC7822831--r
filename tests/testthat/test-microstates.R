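test_that("GFP follows its defining formula", {
  expect_equal(gfp_curve(matrix(c(3, 3, 3), 3, 1))[1], 0)
  expect_equal(gfp_curve(matrix(c(1, -1), 2, 1))[1], 1)
  # offset invariance
  set.seed(30)
  v <- rnorm(63)
  expect_equal(unname(gfp_curve(cbind(v))[1]),
               unname(gfp_curve(cbind(v + 12.5))[1]), tolerance = 1e-12)
})

test_that("GFP peak detection finds strict interior maxima with plateau rule", {
  expect_length(detect_gfp_peaks(1:50), 0L)
  expect_equal(detect_gfp_peaks(c(0, 1, 2, 2, 1, 0)), 3L)
  expect_equal(detect_gfp_peaks(c(0, 3, 0, 2, 0)), c(2L, 4L))

  # oracle recheck on a synthetic alpha-burst recording
  sr <- test_single_recording(seconds = 6)
  ep <- epoch_and_reject(rereference_average(bandpass_filter(sr$rec, c(1, 30))),
                         test_montage())
  g <- gfp_curve(ep)[[1]]
  pk <- detect_gfp_peaks(g)
  expect_gt(length(pk), 10L)
  for (t in pk) expect_true(g[t] > g[t - 1] && g[t] > g[t + 1])
  expect_false(1L %in% pk || length(g) %in% pk)
})

test_that("modified k-means fits exact structure exactly", {
  tpl <- test_templates()
  # all maps identical, K = 1
  V <- tpl[, 3, drop = FALSE][, rep(1, 10)] * 7
  fit <- fit_modified_kmeans(V, 1, restarts = 5, seed = 1)
  expect_lt(fit$F, 1e-20)
  expect_gt(abs(cor(fit$templates[, 1], tpl[, 3])), 1 - 1e-12)

  # two orthogonal templates with random polarity, K = 2
  set.seed(2)
  q <- qr.Q(qr(cbind(avg_ref(rnorm(20)), avg_ref(rnorm(20)))))
  truth <- q[, 1:2]
  V2 <- sapply(1:30, function(i) truth[, 1 + i %% 2] * sample(c(-3, 3), 1))
  fit2 <- fit_modified_kmeans(V2, 2, restarts = 20, seed = 3)
  expect_lt(fit2$F, 1e-12)
  cc <- abs(cor(fit2$templates, truth))
  expect_equal(sort(apply(cc, 2, max)), c(1, 1), tolerance = 1e-9)

  # cost trace is non-increasing
  sr <- test_single_recording(seconds = 8)
  pk <- gfp_peak_maps(epoch_and_reject(
    rereference_average(bandpass_filter(sr$rec, c(1, 30))), test_montage()))
  fit3 <- fit_modified_kmeans(pk, 4, restarts = 10, seed = 4)
  expect_true(all(diff(fit3$trace) <= 1e-10))

  expect_error(fit_modified_kmeans(V2, 40, restarts = 1, seed = 1), "exceeds")
})

test_that("templates are unit-norm with zero channel mean", {
  sr <- test_single_recording(seconds = 8)
  pk <- gfp_peak_maps(epoch_and_reject(
    rereference_average(bandpass_filter(sr$rec, c(1, 30))), test_montage()))
  fit <- fit_modified_kmeans(pk, 3, restarts = 10, seed = 5)
  expect_equal(unname(colSums(fit$templates^2)), rep(1, 3), tolerance = 1e-9)
  expect_lt(max(abs(colMeans(fit$templates))), 1e-9)
})

test_that("the CV criterion matches hand arithmetic on a toy instance", {
  # N_S = 4 channels, 2 maps, K = 1
  v1 <- c(1, -1, 1, -1); v2 <- c(2, 0, 0, -2)
  V <- cbind(v1, v2)
  g <- unit_norm(avg_ref(c(1, -0.5, 0.5, -1)))
  model <- structure(list(templates = cbind(g), K = 1L),
                     class = "microstate_model")
  by_hand <- (sum(v1^2) - sum(v1 * g)^2 + sum(v2^2) - sum(v2 * g)^2) /
    (2 * (4 - 1)) * ((4 - 1) / (4 - 1 - 1))^2
  expect_equal(cv_criterion(V, model), by_hand, tolerance = 1e-12)

  # perfect fit -> CV = 0
  Vp <- cbind(3 * g, -2 * g)
  expect_equal(cv_criterion(Vp, model), 0, tolerance = 1e-24)

  # penalty factor strictly larger for K = 2 at equal residuals
  pen <- function(K, ns = 4) ((ns - 1) / (ns - 1 - K))^2
  expect_gt(pen(2), pen(1))

  expect_error(cv_criterion(V, structure(list(templates = cbind(g, g, g)),
                                         class = "microstate_model")),
               "N_S")
})

test_that("select_k returns 1 for single-template data and stays in range", {
  tpl <- test_templates()
  V <- tpl[, 2, drop = FALSE][, rep(1, 30)] * rep(c(-5, 3, 8), 10)
  s <- select_k(V, 1:4, restarts = 5, seed = 6)
  expect_equal(s$best_k, 1L)
  expect_true(all(as.integer(names(s$cv)) %in% 1:4))
})

test_that("GEV lies in [0, 1] and is non-decreasing in K on a fixed map set", {
  sr <- test_single_recording(seconds = 12)
  pk <- gfp_peak_maps(epoch_and_reject(
    rereference_average(bandpass_filter(sr$rec, c(1, 30))), test_montage()))
  s <- select_k(pk, 1:6, restarts = 20, seed = 7)
  gevs <- vapply(s$models, function(m) gev(pk, m), numeric(1))
  expect_true(all(gevs >= 0 & gevs <= 1))
  expect_true(all(diff(gevs) >= -1e-9))
})
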