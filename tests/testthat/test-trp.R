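test_that("Welch PSD locates tones, obeys Parseval, vanishes on silence", {
  x <- sin(2 * pi * 10 * (1:20000) / 500)
  psd <- welch_psd(x, 500, 1000, 500)
  expect_equal(psd$freq[which.max(psd$psd[1, ])], 10)

  set.seed(20)
  wn <- rnorm(50000)
  p2 <- welch_psd(wn, 500, 1000, 500)
  df <- p2$freq[2] - p2$freq[1]
  expect_lt(abs(sum(p2$psd[1, ]) * df - var(wn)) / var(wn), 0.05)

  z <- welch_psd(rep(0, 5000), 500, 1000, 500)
  expect_true(all(z$psd == 0))

  expect_error(welch_psd(rnorm(500), 500, 1000, 500), "longer")
  expect_error(welch_psd(rnorm(2000), 500, 1000, 1000), "overlap")
})

test_that("band power integrates an off-grid tone to its analytic power", {
  # amplitude 2 -> power A^2/2 = 2; mid-bin frequency avoids the parity
  # sensitivity of Simpson weights to single-bin spectral lines
  x <- 2 * sin(2 * pi * 9.25 * (1:20000) / 500)
  psd <- welch_psd(x, 500, 1000, 500)
  bp <- band_power(psd, c(8, 10))
  expect_lt(abs(bp - 2) / 2, 0.05)

  zero <- list(freq = psd$freq, psd = psd$psd * 0)
  expect_equal(unname(band_power(zero, c(8, 10))), 0)

  # shared-edge additivity
  lhs <- band_power(psd, c(8, 10)) + band_power(psd, c(10, 12))
  expect_lt(abs(lhs - band_power(psd, c(8, 12))), 1e-9)

  expect_error(band_power(psd, c(8, 8.5)), "3 frequency bins")
  expect_error(band_power(psd, c(240, 260)), "range")
})

test_that("TRP reproduces hand-computed log ratios", {
  m <- test_montage()
  ch <- m$channel
  mk <- function(cond, run, pw) data.frame(participant = 1, condition = cond,
                                           run = run, channel = ch, power = pw)
  # activation = reference -> 0
  pow <- rbind(mk("rest", 0, rep(4, 63)), mk("generation", 1, rep(4, 63)))
  trp <- compute_trp(pow)
  expect_true(all(trp$trp == 0))

  # activation = e * reference, one run -> 1
  pow <- rbind(mk("rest", 0, rep(2, 63)), mk("evolution", 1, rep(2 * exp(1), 63)))
  expect_equal(unique(compute_trp(pow)$trp), 1, tolerance = 1e-12)

  # runs with ratios 2 and 8 -> (ln 2 + ln 8) / 2 = ln 4
  pow <- rbind(mk("rest", 0, rep(3, 63)),
               mk("evaluation", 1, rep(6, 63)), mk("evaluation", 2, rep(24, 63)))
  expect_equal(unique(compute_trp(pow)$trp), log(4), tolerance = 1e-12)

  pow$power[5] <- 0
  expect_error(compute_trp(pow), pow$channel[5])
})

test_that("TRP is invariant to a common rescaling of all recordings", {
  m <- test_montage()
  set.seed(22)
  pw <- runif(63, 1, 5)
  mk <- function(cond, run, p) data.frame(participant = 1, condition = cond,
                                          run = run, channel = m$channel,
                                          power = p)
  pow1 <- rbind(mk("rest", 0, pw), mk("generation", 1, pw * 0.6))
  # scaling amplitude by c scales power by c^2
  pow2 <- rbind(mk("rest", 0, pw * 9), mk("generation", 1, pw * 0.6 * 9))
  expect_equal(compute_trp(pow1)$trp, compute_trp(pow2)$trp, tolerance = 1e-12)
})

test_that("region aggregation means the printed electrodes, never the midline", {
  m <- test_montage()
  base <- data.frame(participant = 1, condition = "generation",
                     channel = m$channel, trp = 0.7)
  class(base) <- c("trp_table", "data.frame")
  reg <- aggregate_regions(base, m)
  expect_equal(nrow(reg), 10L)
  expect_true(all(abs(reg$trp - 0.7) < 1e-12))

  # left-frontal value = mean of its 9 printed electrodes
  tt <- base
  lf <- montage_group(m, "frontal", "left")
  tt$trp <- seq_len(63)
  reg2 <- aggregate_regions(tt, m)
  expect_equal(reg2$trp[reg2$area == "frontal" & reg2$hemisphere == "left"],
               mean(tt$trp[tt$channel %in% lf]))

  # perturbing a midline electrode changes nothing
  tt2 <- tt
  tt2$trp[tt2$channel == "Fz"] <- 1e6
  expect_equal(aggregate_regions(tt2, m)$trp, reg2$trp)
})
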