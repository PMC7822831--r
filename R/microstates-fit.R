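# Microstate model fitting: global field power, GFP-peak extraction,
# polarity-invariant modified k-means on the peak maps, and the
# cross-validation criterion that selects the number of classes.

#' Global field power
#'
#' The spatial standard deviation of the potential at each sample:
#' `sqrt(mean((u_i - mean(u))^2))` over channels (population form,
#' divide-by-N). Invariant under re-referencing.
#'
#' @param x channels x samples matrix, an `eeg_recording`, or an
#'   `eeg_epochs` object.
#' @return Numeric vector of per-sample GFP (list of vectors for epochs).
#' @export
gfp_curve <- function(x) {
  if (inherits(x, "eeg_epochs")) return(lapply(x$epochs, gfp_curve))
  if (inherits(x, "eeg_recording")) x <- x$data
  if (nrow(x) < 2L) stop("GFP needs >= 2 channels")
  m <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, m)^2))
}

#' Detect GFP peaks
#'
#' Strict local maxima of the GFP curve (`gfp[t] > gfp[t-1]` and
#' `gfp[t] > gfp[t+1]`); a plateau counts once, at its first sample; the
#' first and last samples are never peaks. Computed within each epoch when
#' given epoch-wise curves.
#'
#' @param gfp Numeric GFP vector, or a list of per-epoch vectors.
#' @return Integer peak indices (list of such for epoch input).
#' @export
detect_gfp_peaks <- function(gfp) {
  if (is.list(gfp)) return(lapply(gfp, detect_gfp_peaks))
  n <- length(gfp)
  if (n < 3L) return(integer(0))
  # plateau rule: compare against the previous *different* value on the left
  idx <- integer(0)
  t <- 2L
  while (t <= n - 1L) {
    if (gfp[t] > gfp[t - 1L]) {
      # scan over any plateau starting at t
      e <- t
      while (e < n && gfp[e + 1L] == gfp[t]) e <- e + 1L
      if (e <= n - 1L && gfp[e + 1L] < gfp[t]) idx <- c(idx, t)
      t <- e + 1L
    } else t <- t + 1L
  }
  idx
}

#' Collect GFP-peak topographies from epoched data
#'
#' @param epochs An `eeg_epochs` object (expected on 1-30 Hz filtered,
#'   average-referenced data).
#' @return List with `maps` (channels x n_peaks matrix), `epoch` and
#'   `sample` indices of each peak.
#' @export
gfp_peak_maps <- function(epochs) {
  curves <- gfp_curve(epochs)
  peaks <- detect_gfp_peaks(curves)
  maps <- list(); ep <- integer(0); sm <- integer(0)
  for (e in seq_along(epochs$epochs)) {
    pk <- peaks[[e]]
    if (length(pk) == 0L) next
    maps[[length(maps) + 1L]] <- epochs$epochs[[e]][, pk, drop = FALSE]
    ep <- c(ep, rep(e, length(pk)))
    sm <- c(sm, pk)
  }
  if (length(maps) == 0L) stop("no GFP peaks found")
  list(maps = do.call(cbind, maps), epoch = ep, sample = sm)
}

# One modified-k-means pass from a given template initialization.
# V: channels x n maps; returns list(templates, assign, a, F, trace).
# The template update runs power iterations on the cluster scatter starting
# from the current template: the Rayleigh quotient is non-decreasing, so the
# cost F is non-increasing across iterations without a full eigendecomposition.
.mkmeans_once <- function(V, K, init, tol = 1e-6, max_iter = 1000L) {
  ns <- nrow(V); nt <- ncol(V)
  tot <- sum(V * V)
  gamma <- init
  f_old <- Inf
  f <- NA_real_
  trace <- numeric(0)
  assign <- integer(nt); a <- numeric(nt)
  for (it in seq_len(max_iter)) {
    proj <- crossprod(gamma, V)            # K x n, V_t' Gamma_k
    assign <- max.col(t(proj^2), ties.method = "first")
    a <- proj[cbind(assign, seq_len(nt))]
    f <- (tot - sum(a^2)) / (nt * (ns - 1))
    trace <- c(trace, f)
    if (is.finite(f_old) && abs(f_old - f) <= tol * max(f_old, .Machine$double.eps))
      break
    f_old <- f
    # template update: principal eigenvector of each cluster's scatter
    for (k in seq_len(K)) {
      sel <- assign == k
      if (!any(sel)) {                     # empty cluster: reseed at worst fit
        resid <- colSums(V^2) - a^2
        worst <- which.max(resid)
        gamma[, k] <- unit_norm(V[, worst])
        next
      }
      S <- tcrossprod(V[, sel, drop = FALSE])
      g <- gamma[, k]
      for (p in 1:50) {
        g_new <- unit_norm(as.vector(S %*% g))
        if (sum(abs(g_new - g)) < 1e-10 || sum(abs(g_new + g)) < 1e-10) {
          g <- g_new; break
        }
        g <- g_new
      }
      gamma[, k] <- g
    }
  }
  list(templates = gamma, assign = assign, a = a, F = f, trace = trace)
}

#' Fit a microstate model by polarity-invariant modified k-means
#'
#' Each GFP-peak map is assigned to the template maximizing the squared
#' projection (polarity ignored); the intensity of the assigned class is the
#' projection itself; each template is updated as the unit-norm principal
#' eigenvector of its cluster's scatter matrix. The cost is the mean residual
#' variance per map and channel,
#' `F = sum_t ||V_t - a_t Gamma_assign(t)||^2 / (N_T (N_S - 1))`,
#' which is non-increasing across iterations. The best of `restarts` random
#' initializations (K distinct maps each) is returned.
#'
#' @param maps channels x n matrix of average-referenced peak maps, or a
#'   [gfp_peak_maps()] result.
#' @param K Number of classes, `1 <= K <= n`.
#' @param restarts Number of random restarts (default 100).
#' @param seed Integer seed.
#' @param tol Relative cost-change convergence tolerance.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `microstate_model`: list with `templates`
#'   (channels x K unit-norm, zero-mean columns), `K`, `F` (converged cost),
#'   `cv` (cross-validation criterion, `NA` when `K >= N_S - 1`), `assign`,
#'   `a` (intensities of the fitted maps), `gev`, `n_maps`, `level`,
#'   `trace` (per-iteration cost of the winning restart).
#' @export
fit_modified_kmeans <- function(maps, K, restarts = 100L, seed = 1L,
                                tol = 1e-6, max_iter = 1000L) {
  V <- if (is.list(maps)) maps$maps else as.matrix(maps)
  nt <- ncol(V); ns <- nrow(V)
  if (K < 1L) stop("K must be >= 1")
  if (K > nt) stop("K (", K, ") exceeds the number of maps (", nt, ")")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- unit_norm(V[, sample.int(nt, K), drop = FALSE])
      fit <- .mkmeans_once(V, K, init, tol, max_iter)
      if (is.null(best) || fit$F < best$F) best <- fit
    }
  })
  tot <- sum(V * V)
  gev <- if (tot > 0) sum(best$a^2) / tot else NA_real_
  cv <- if (K < ns - 1L)
    .cv_value(tot - sum(best$a^2), nt, ns, K) else NA_real_
  structure(list(templates = best$templates, K = as.integer(K), F = best$F,
                 cv = cv, assign = best$assign, a = best$a, gev = gev,
                 n_maps = nt, level = "run", labels = NULL,
                 trace = best$trace),
            class = "microstate_model")
}

.cv_value <- function(resid_sum, nt, ns, K) {
  resid_sum / (nt * (ns - 1)) * ((ns - 1) / (ns - 1 - K))^2
}

#' Cross-validation criterion of a fitted model on a map set
#'
#' `CV = [sum_t (V_t'V_t - (V_t'Gamma_label(t))^2)] / (N_T (N_S - 1)) *
#' ((N_S - 1)/(N_S - 1 - N_K))^2`, where `label(t)` is the polarity-invariant
#' best-matching class of map t. The penalty factor is singular for
#' `N_K >= N_S - 1`.
#'
#' @param maps channels x n matrix (or [gfp_peak_maps()] result).
#' @param model A `microstate_model` (only `templates` is used).
#' @return The CV value (smaller is better).
#' @export
cv_criterion <- function(maps, model) {
  V <- if (is.list(maps)) maps$maps else as.matrix(maps)
  ns <- nrow(V); nt <- ncol(V); K <- ncol(model$templates)
  if (K >= ns - 1L)
    stop("CV undefined: number of classes (", K,
         ") must be below N_S - 1 = ", ns - 1L)
  proj <- crossprod(model$templates, V)
  a2 <- apply(proj^2, 2L, max)
  .cv_value(sum(V * V) - sum(a2), nt, ns, K)
}

#' Global explained variance of a model on a map set
#'
#' `GEV = 1 - sum(residual) / sum(total)` over the supplied (GFP-peak) maps,
#' with polarity-invariant assignment.
#'
#' @inheritParams cv_criterion
#' @return GEV in `[0, 1]`.
#' @export
gev <- function(maps, model) {
  V <- if (is.list(maps)) maps$maps else as.matrix(maps)
  proj <- crossprod(model$templates, V)
  a2 <- apply(proj^2, 2L, max)
  sum(a2) / sum(V * V)
}

#' Select the number of microstate classes by the CV criterion
#'
#' Fits every K in `k_range` and returns the K minimizing the
#' cross-validation criterion together with the whole curve.
#'
#' @inheritParams fit_modified_kmeans
#' @param k_range Candidate class counts (default `1:10`).
#' @return List with `best_k`, `cv` (named per-K vector), and `models`
#'   (per-K fits).
#' @export
select_k <- function(maps, k_range = 1:10, restarts = 100L, seed = 1L) {
  V <- if (is.list(maps)) maps$maps else as.matrix(maps)
  if (max(k_range) >= nrow(V) - 1L)
    stop("k_range exceeds CV validity (K < N_S - 1)")
  models <- lapply(k_range, function(k)
    fit_modified_kmeans(V, k, restarts = restarts,
                        seed = seed_stream(seed, paste0("select_k/", k))))
  cv <- vapply(models, `[[`, numeric(1), "cv")
  names(cv) <- names(models) <- as.character(k_range)
  # ties (e.g. exact fits at several K) resolve to the smallest K; the
  # tolerance is relative to the data scale so a ~eps residual at K = 1
  # does not lose to an exact 0 at larger K
  tol <- 1e-9 * sum(V * V) / (ncol(V) * (nrow(V) - 1))
  best <- k_range[which(cv <= min(cv) + tol)[1]]
  list(best_k = best, cv = cv, models = models)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("Microstate model: K = %d (%s level), fitted on %d maps\n",
              x$K, x$level, x$n_maps))
  cat(sprintf("  cost F = %.6g, CV = %.6g, GEV = %.3f\n",
              x$F, x$cv, x$gev))
  if (!is.null(x$labels))
    cat("  class letters:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.microstate_model <- function(object, ...) {
  counts <- tabulate(object$assign, nbins = object$K)
  out <- data.frame(class = seq_len(object$K),
                    letter = if (is.null(object$labels)) NA_character_
                             else object$labels,
                    n_maps = counts,
                    share = counts / max(1L, object$n_maps))
  cat(sprintf("Microstate model (K = %d, level = %s)\n", object$K, object$level))
  cat(sprintf("F = %.6g, CV = %.6g, GEV = %.3f\n\n", object$F, object$cv,
              object$gev))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.microstate_model <- function(object, ...) object$templates

#' Plot microstate templates as schematic scalp maps
#'
#' Draws each template as colored discs at the 2-D projected electrode
#' positions (red positive, blue negative).
#'
#' @param x A `microstate_model`.
#' @param montage Montage supplying positions.
#' @param ... Unused.
#' @export
plot.microstate_model <- function(x, montage = make_montage(), ...) {
  K <- x$K
  op <- graphics::par(mfrow = c(1, K), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  # azimuthal projection: radius ~ polar angle
  theta <- acos(pmin(pmax(montage$z, -1), 1))
  r <- theta / max(theta)
  px <- r * montage$x / pmax(sqrt(montage$x^2 + montage$y^2), 1e-9)
  py <- r * montage$y / pmax(sqrt(montage$x^2 + montage$y^2), 1e-9)
  for (k in seq_len(K)) {
    v <- x$templates[, k]
    cols <- grDevices::rgb(pmax(v, 0) / max(abs(v)), 0, pmax(-v, 0) / max(abs(v)))
    graphics::plot(px, py, pch = 19, cex = 1.5, col = cols, axes = FALSE,
                   xlab = "", ylab = "", asp = 1,
                   main = if (is.null(x$labels)) paste0("class ", k)
                          else x$labels[k])
  }
  invisible(x)
}
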