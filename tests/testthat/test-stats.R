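test_that("TANOVA returns p = 1 when condition maps are identical", {
  set.seed(40)
  n <- 8; ch <- 20
  base <- matrix(rnorm(n * ch), n)
  arr <- array(NA_real_, c(n, 3, ch))
  for (l in 1:3) arr[, l, ] <- base
  res <- tanova(arr, "condition", n_perm = 200, seed = 1)
  expect_equal(res$p, 1)
  expect_lt(res$statistic, 1e-12)
})

test_that("paired TANOVA finds planted shifts and not identical maps", {
  set.seed(41)
  n <- 12; ch <- 30
  a <- matrix(rnorm(n * ch), n)
  res0 <- paired_tanova(a, a, n_perm = 300, seed = 2)
  expect_equal(res0$p, 1)

  shift <- rnorm(ch) * 2
  b <- a + matrix(shift, n, ch, byrow = TRUE)
  res1 <- paired_tanova(a, b, n_perm = 5000, seed = 3)
  expect_lt(res1$p, 0.01)

  # invariance (within Monte-Carlo error) to global rescaling
  res2 <- paired_tanova(a * 37, b * 37, n_perm = 5000, seed = 3)
  expect_equal(res2$p, res1$p)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(42)
  arr <- array(rnorm(6 * 3 * 15), c(6, 3, 15))
  r1 <- tanova(arr, "condition", n_perm = 200, seed = 9)
  r2 <- tanova(arr, "condition", n_perm = 200, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_error(tanova(arr, "condition", n_perm = 200), "seed")
  expect_error(tanova(arr, "condition", n_perm = 50, seed = 1), "100")
})

test_that("RM-ANOVA matches a hand sums-of-squares oracle on a 3x3 table", {
  d <- expand.grid(participant = 1:3, condition = c("a", "b", "c"))
  d$value <- c(2, 4, 3,  5, 7, 6,  8, 9, 10)
  res <- rm_anova_gg(d, within = "condition")
  # hand decomposition
  Y <- matrix(d$value, 3, 3)
  gm <- mean(Y)
  ss_cond <- 3 * sum((colMeans(Y) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(res$F, f_hand, tolerance = 1e-10)
  expect_equal(res$eta_p2, ss_cond / (ss_cond + ss_err), tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 4)
})

test_that("RM-ANOVA agrees with the aov() oracle on random tables", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(4:8, 1); la <- sample(2:4, 1); lb <- sample(2:3, 1)
    d <- expand.grid(participant = factor(1:n), A = factor(1:la),
                     B = factor(1:lb))
    d$value <- rnorm(nrow(d))
    mine <- rm_anova_gg(d, within = c("A", "B"))
    oracle <- summary(aov(value ~ A * B + Error(participant / (A * B)),
                          data = d))
    get_f <- function(stratum, term) {
      tab <- oracle[[stratum]][[1]]
      tab[trimws(rownames(tab)) == term, "F value"]
    }
    expect_equal(mine$F[mine$effect == "A"],
                 get_f("Error: participant:A", "A"), tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "B"],
                 get_f("Error: participant:B", "B"), tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "A x B"],
                 get_f("Error: participant:A:B", "A:B"), tolerance = 1e-8)
  }
})

test_that("RM-ANOVA handles degenerate and 2-level inputs", {
  d <- expand.grid(participant = 1:4, condition = c("x", "y", "z"))
  d$value <- 5
  res <- rm_anova_gg(d, within = "condition")
  expect_equal(res$F, 0)
  expect_equal(res$eta_p2, 0)

  d2 <- expand.grid(participant = 1:6, condition = c("x", "y"))
  set.seed(44)
  d2$value <- rnorm(12)
  res2 <- rm_anova_gg(d2, within = "condition")
  expect_equal(res2$epsilon, 1)            # sphericity trivial with 1 df

  d3 <- d[-1, ]
  expect_error(rm_anova_gg(d3, within = "condition"), "complete")
})

test_that("Greenhouse-Geisser epsilon shrinks the dfs when sphericity fails", {
  set.seed(45)
  n <- 12
  base <- rnorm(n)
  d <- expand.grid(participant = 1:n, condition = 1:4)
  # strongly non-spherical: conditions 1-2 nearly identical, 3-4 independent
  d$value <- c(base, base + rnorm(n, sd = 0.05), rnorm(n, sd = 3), rnorm(n, sd = 3))
  res <- rm_anova_gg(d, within = "condition")
  expect_lt(res$epsilon, 0.9)
  expect_true(is.finite(res$mauchly_p))
  if (res$corrected) {
    expect_equal(res$df1_gg, res$epsilon * res$df1)
    expect_equal(res$df2_gg, res$epsilon * res$df2)
  }
})

test_that("paired t-tests follow the closed form and Bonferroni caps at 1", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)        # differences 1, 2, 3
  res <- paired_tests_bonferroni(list(d1 = list(x, y)))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 2)

  same <- paired_tests_bonferroni(list(eq = list(x, x)))
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)

  # m = 6 contrasts, raw p = 0.3 -> adjusted capped at 1
  set.seed(46)
  contr <- replicate(6, {
    a <- rnorm(10); list(a, a + rnorm(10, 0.05))
  }, simplify = FALSE)
  res6 <- paired_tests_bonferroni(contr)
  expect_true(all(res6$p_adj == pmin(1, 6 * res6$p)))
})

test_that("time normalization z-scores within families and keeps rank order", {
  set.seed(47)
  times <- expand.grid(participant = 1:5, condition = task_conditions(),
                       run = 1:3)
  times$seconds <- runif(nrow(times), 10, 120)
  norm <- normalize_times(times, family = "condition")
  for (p in 1:5) for (cond in task_conditions()) {
    sel <- norm$participant == p & norm$condition == cond
    expect_equal(mean(norm$normalized[sel]), 0, tolerance = 1e-10)
    expect_equal(sd(norm$normalized[sel]), 1, tolerance = 1e-10)
    expect_equal(order(norm$normalized[sel]), order(norm$seconds[sel]))
  }
  avg <- normalize_times(times, family = "all", average = TRUE)
  expect_equal(nrow(avg), 15L)

  bad <- times
  bad$seconds[bad$participant == 2 & bad$condition == "generation"] <- 30
  expect_error(normalize_times(bad, family = "condition"), "participant 2")
})
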