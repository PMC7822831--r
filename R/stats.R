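# Topographic randomization tests (TANOVA) and the parametric repeated-
# measures machinery (RM-ANOVA with Greenhouse-Geisser correction, paired
# t-tests with Bonferroni adjustment, completion-time normalization).

# GFP of a single map (population form).
.map_gfp <- function(v) sqrt(mean((v - mean(v))^2))

# Normalize each participant map to unit GFP.
.gfp_normalize <- function(arr) {
  # arr: participants x cells x channels; constant maps carry no topography
  # and are zeroed (they cannot contribute to a GFP-based statistic)
  g <- apply(arr, c(1, 2), .map_gfp)
  if (any(g == 0)) warning("constant map(s) encountered in TANOVA input")
  out <- sweep(arr, c(1, 2), pmax(g, .Machine$double.eps), "/")
  if (any(g == 0)) {
    zero <- which(g == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(zero))) out[zero[r, 1], zero[r, 2], ] <- 0
  }
  out
}

# Effect statistic: sum over levels of GFP(level mean map - grand mean map).
.tanova_stat <- function(arr, level_of_cell) {
  # arr: participants x cells x channels (already GFP-normalized)
  cell_means <- apply(arr, c(2, 3), mean)          # cells x channels
  lv <- unique(level_of_cell)
  level_means <- t(vapply(lv, function(l)
    colMeans(cell_means[level_of_cell == l, , drop = FALSE]),
    numeric(dim(arr)[3])))
  grand <- colMeans(level_means)
  sum(apply(sweep(level_means, 2L, grand), 1L, .map_gfp))
}

.perm_p <- function(observed, perm_stats) {
  (1 + sum(perm_stats >= observed - 1e-12)) / (1 + length(perm_stats))
}

#' Topographic ANOVA (TANOVA) randomization test
#'
#' Nonparametric test of topographic differences. Maps are GFP-normalized per
#' participant and cell; the effect statistic is the sum over factor levels
#' of the GFP of (level-mean map - grand-mean map). The null distribution is
#' built by permuting, within each participant, the labels of the factor
#' under test (both factors jointly for the interaction). P-values use the
#' add-one estimator.
#'
#' @param maps Participant maps: for one factor, a 3-d array
#'   `participants x levels x channels` (dimnames on dim 2 name the levels);
#'   for two factors, a 4-d array `participants x levelsA x levelsB x
#'   channels`.
#' @param factors Character names of the factor(s), e.g. `"condition"` or
#'   `c("condition", "class")`.
#' @param n_perm Number of permutations (>= 100; default 5000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Data frame of class `tanova_result`: effect, statistic, p, n_perm.
#' @export
tanova <- function(maps, factors, n_perm = 5000L, seed) {
  if (missing(seed)) stop("a seed is required for the randomization test")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  d <- dim(maps)
  if (length(d) == 3L) {
    res <- .tanova_one(maps, factors[1], n_perm, seed)
  } else if (length(d) == 4L) {
    res <- .tanova_two(maps, factors, n_perm, seed)
  } else stop("maps must be a 3-d or 4-d array")
  class(res) <- c("tanova_result", "data.frame")
  res
}

.tanova_one <- function(maps, factor_name, n_perm, seed) {
  n <- dim(maps)[1]; L <- dim(maps)[2]
  if (any(!is.finite(maps))) stop("incomplete design: non-finite maps")
  arr <- .gfp_normalize(maps)
  lv <- seq_len(L)
  obs <- .tanova_stat(arr, lv)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuf <- arr
      for (s in seq_len(n)) shuf[s, , ] <- arr[s, sample.int(L), ]
      .tanova_stat(shuf, lv)
    }, numeric(1))
  })
  data.frame(effect = factor_name, statistic = obs,
             p = .perm_p(obs, perm_stats), n_perm = n_perm)
}

.tanova_two <- function(maps, factors, n_perm, seed) {
  n <- dim(maps)[1]; A <- dim(maps)[2]; B <- dim(maps)[3]; ch <- dim(maps)[4]
  if (any(!is.finite(maps))) stop("incomplete design: non-finite maps")
  flat <- array(maps, dim = c(n, A * B, ch))       # cells vary A fastest
  arr <- .gfp_normalize(flat)
  a_of_cell <- rep(seq_len(A), times = B)
  b_of_cell <- rep(seq_len(B), each = A)

  # interaction statistic on double-centered cell means
  inter_stat <- function(x) {
    cm <- apply(x, c(2, 3), mean)                  # cells x channels
    am <- apply(cm, 2L, function(col) tapply(col, a_of_cell, mean))
    bm <- apply(cm, 2L, function(col) tapply(col, b_of_cell, mean))
    gr <- colMeans(cm)
    resid <- cm - am[a_of_cell, ] - bm[b_of_cell, ] +
      matrix(gr, nrow(cm), ch, byrow = TRUE)
    sum(apply(resid, 1L, .map_gfp))
  }

  obs_a <- .tanova_stat(arr, a_of_cell)
  obs_b <- .tanova_stat(arr, b_of_cell)
  obs_ab <- inter_stat(arr)

  perms <- with_seed(seed, {
    pa <- matrix(0, n_perm, 1); pb <- matrix(0, n_perm, 1); pab <- matrix(0, n_perm, 1)
    for (i in seq_len(n_perm)) {
      shuf_a <- arr; shuf_b <- arr; shuf_ab <- arr
      for (s in seq_len(n)) {
        # permute A labels within participant (consistently over B)
        pa_s <- sample.int(A)
        shuf_a[s, , ] <- arr[s, pa_s[a_of_cell] + (b_of_cell - 1L) * A, ]
        pb_s <- sample.int(B)
        shuf_b[s, , ] <- arr[s, a_of_cell + (pb_s[b_of_cell] - 1L) * A, ]
        shuf_ab[s, , ] <- arr[s, sample.int(A * B), ]
      }
      pa[i] <- .tanova_stat(shuf_a, a_of_cell)
      pb[i] <- .tanova_stat(shuf_b, b_of_cell)
      pab[i] <- inter_stat(shuf_ab)
    }
    list(a = pa, b = pb, ab = pab)
  })
  data.frame(
    effect = c(factors, paste(factors, collapse = " x ")),
    statistic = c(obs_a, obs_b, obs_ab),
    p = c(.perm_p(obs_a, perms$a), .perm_p(obs_b, perms$b),
          .perm_p(obs_ab, perms$ab)),
    n_perm = n_perm)
}

#' Paired TANOVA
#'
#' Post hoc topographic comparison of two conditions: the statistic is the
#' GFP of the difference between the GFP-normalized grand-mean maps; the null
#' swaps the two maps within participants at random.
#'
#' @param a,b Participant maps, `participants x channels` matrices with
#'   matching rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-row data frame: statistic, p, n_perm.
#' @export
paired_tanova <- function(a, b, n_perm = 5000L, seed) {
  if (missing(seed)) stop("a seed is required for the randomization test")
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  n <- nrow(a)
  norm1 <- function(m) m / pmax(apply(m, 1L, .map_gfp), .Machine$double.eps)
  an <- norm1(a); bn <- norm1(b)
  stat <- function(x, y) .map_gfp(colMeans(x) - colMeans(y))
  obs <- stat(an, bn)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flip <- stats::runif(n) < 0.5
      x <- an; y <- bn
      x[flip, ] <- bn[flip, ]; y[flip, ] <- an[flip, ]
      stat(x, y)
    }, numeric(1))
  })
  data.frame(effect = "paired", statistic = obs,
             p = .perm_p(obs, perm_stats), n_perm = n_perm)
}

# Normalized orthonormal contrast matrix for a factor with l levels
# ((l-1) x l, rows orthonormal, orthogonal to the constant).
.ortho_contrasts <- function(l) {
  if (l == 1L) return(matrix(1, 1, 1))  # placeholder, never used as contrast
  C <- stats::contr.helmert(l)           # l x (l-1)
  C <- sweep(C, 2L, sqrt(colSums(C^2)), "/")
  t(C)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA on a complete, balanced design with one to
#' three within factors. For each effect, orthonormal contrast scores are
#' formed per participant; `F = (n ||zbar||^2 / d) / (SS_err / ((n-1) d))`.
#' Sphericity is assessed with Mauchly's test on the contrast covariance;
#' when violated (p < 0.05) the Greenhouse-Geisser epsilon rescales both
#' degrees of freedom. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame with a participant column, one column per
#'   within factor, and a value column.
#' @param within Character vector of within-factor column names.
#' @param value Name of the value column (default `"value"`).
#' @param id Name of the participant column (default `"participant"`).
#' @param gg_threshold Mauchly p-value below which the correction is applied.
#' @return Data frame of class `rm_anova`: effect, df1, df2, F, p, eta_p2,
#'   epsilon (GG), mauchly_p, corrected (logical), df1_gg, df2_gg, p_gg
#'   (corrected values equal the uncorrected ones when sphericity holds or
#'   the effect has 1 df).
#' @export
rm_anova_gg <- function(data, within, value = "value", id = "participant",
                        gg_threshold = 0.05) {
  data[[id]] <- factor(data[[id]])
  for (f in within) data[[f]] <- factor(data[[f]])
  subjects <- levels(data[[id]])
  n <- length(subjects)
  if (n < 2L) stop("at least 2 participants required")
  lvl <- lapply(within, function(f) levels(data[[f]]))
  names(lvl) <- within
  cells <- expand.grid(lvl, stringsAsFactors = FALSE)  # first factor fastest
  key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  cell_key <- key(cells)
  Y <- matrix(NA_real_, n, nrow(cells))
  di <- match(data[[id]], subjects)
  ci <- match(key(data), cell_key)
  Y[cbind(di, ci)] <- data[[value]]
  if (anyNA(Y)) stop("missing cells: the design must be complete and balanced")

  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (eff in effects) {
    M <- matrix(1, 1, 1)
    for (f in within) {
      l <- length(lvl[[f]])
      Mf <- if (f %in% eff) .ortho_contrasts(l) else matrix(1 / l, 1, l)
      M <- kronecker(Mf, M)   # first factor fastest => kron in reverse
    }
    Z <- Y %*% t(M)                         # n x d contrast scores
    d <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    R <- sweep(Z, 2L, zbar)
    ss_err <- sum(R^2)
    df1 <- d; df2 <- (n - 1) * d
    # rounding floor: contrast scores of a constant table are ~eps, not 0
    zero_tol <- 1e-12 * (sum(Y^2) + 1)
    if (ss_eff < zero_tol && ss_err < zero_tol) { ss_eff <- 0; ss_err <- 0 }
    if (ss_eff == 0) {              # no effect variance: F = 0 by convention
      Fv <- 0; p <- 1; eta <- 0
    } else if (ss_err == 0) {
      Fv <- Inf; p <- 0; eta <- 1
    } else {
      Fv <- (ss_eff / df1) / (ss_err / df2)
      p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
      eta <- ss_eff / (ss_eff + ss_err)
    }
    if (d > 1L) {
      S <- crossprod(R) / (n - 1)
      lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      eps <- sum(lam)^2 / (d * sum(lam^2))
      # Mauchly's sphericity test
      lam_pos <- pmax(lam, .Machine$double.eps)
      W <- prod(lam_pos) / (mean(lam_pos))^d
      fac <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
      chi2 <- -(n - 1) * fac * log(W)
      m_df <- d * (d + 1) / 2 - 1
      m_p <- if (n - 1 < d) NA_real_ else
        stats::pchisq(chi2, m_df, lower.tail = FALSE)
    } else {
      eps <- 1; m_p <- NA_real_
    }
    corrected <- d > 1L && !is.na(m_p) && m_p < gg_threshold
    df1_gg <- if (corrected) eps * df1 else df1
    df2_gg <- if (corrected) eps * df2 else df2
    p_gg <- stats::pf(Fv, df1_gg, df2_gg, lower.tail = FALSE)
    out[[paste(eff, collapse = " x ")]] <- data.frame(
      effect = paste(eff, collapse = " x "),
      df1 = df1, df2 = df2, F = Fv, p = p, eta_p2 = eta,
      epsilon = eps, mauchly_p = m_p, corrected = corrected,
      df1_gg = df1_gg, df2_gg = df2_gg, p_gg = p_gg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' Paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-tests with 95% confidence intervals of the mean
#' difference; adjusted p-values are `min(1, m * p)` over the requested
#' family.
#'
#' @param contrasts Named list; each element is a list/pair with numeric
#'   vectors `x` and `y` of equal length (paired samples).
#' @return Data frame: contrast, mean_diff, t, df, p, p_adj, ci_lo, ci_hi.
#'   Contrasts with zero-variance differences get `NA` statistics.
#' @export
paired_tests_bonferroni <- function(contrasts) {
  m <- length(contrasts)
  rows <- lapply(seq_len(m), function(i) {
    x <- contrasts[[i]][[1]]; y <- contrasts[[i]][[2]]
    stopifnot(length(x) == length(y), length(x) >= 2L)
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        # identical pairs: no difference, p = 1 by convention
        return(data.frame(contrast = names(contrasts)[i] %||% paste0("c", i),
                          mean_diff = 0, t = NA_real_, df = length(d) - 1,
                          p = 1, p_adj = 1, ci_lo = 0, ci_hi = 0))
      }
      return(data.frame(contrast = names(contrasts)[i] %||% paste0("c", i),
                        mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
                        p = NA_real_, p_adj = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(contrast = names(contrasts)[i] %||% paste0("c", i),
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, p_adj = NA_real_,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2])
  })
  res <- do.call(rbind, rows)
  res$p_adj <- ifelse(is.na(res$p), NA_real_,
                      stats::p.adjust(res$p, method = "bonferroni", n = m))
  rownames(res) <- NULL
  res
}

#' Normalize task completion times within participants
#'
#' Z-scores each participant's times within a normalization family:
#' `family = "condition"` normalizes across the runs of each condition
#' separately (for within-condition run contrasts); `family = "all"`
#' normalizes across all of the participant's tasks (for between-condition
#' contrasts), after which values may be averaged per condition.
#'
#' @param times Data frame: participant, condition, run, seconds.
#' @param family `"condition"` or `"all"`.
#' @param average Average normalized values per condition (only meaningful
#'   with `family = "all"`).
#' @return The input data frame with a `normalized` column (or the averaged
#'   participant x condition table when `average = TRUE`).
#' @export
normalize_times <- function(times, family = c("condition", "all"),
                            average = FALSE) {
  family <- match.arg(family)
  times$normalized <- NA_real_
  for (p in unique(times$participant)) {
    sel_p <- times$participant == p
    groups <- if (family == "condition")
      split(which(sel_p), times$condition[sel_p]) else list(which(sel_p))
    for (g in groups) {
      if (length(g) < 2L)
        stop("normalization group with fewer than 2 values for participant ", p)
      v <- times$seconds[g]
      if (stats::sd(v) == 0)
        stop("zero-variance completion times for participant ", p)
      times$normalized[g] <- (v - mean(v)) / stats::sd(v)
    }
  }
  if (average) {
    agg <- stats::aggregate(normalized ~ participant + condition, data = times,
                            FUN = mean)
    return(agg)
  }
  times
}
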