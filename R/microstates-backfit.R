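# Backfitting a template set onto epoched data and computing microstate
# coverage/duration parameters under the edge-run removal rule.

#' Backfit microstate templates onto epoched data
#'
#' At `at = "peaks"` (the standard procedure) each GFP-peak map is labeled by
#' the template with maximal absolute spatial correlation, and every other
#' sample inherits the label of its temporally nearest peak within the epoch
#' (boundary at the midpoint between neighbouring peaks; ties go to the
#' earlier peak). At `at = "samples"` every sample is labeled directly.
#' Maximal runs of equal labels form microstates; the first and last run of
#' every epoch are dropped from the retained mask because their true onset /
#' offset is unknown. Epochs with fewer than 2 peaks are excluded entirely.
#'
#' @param epochs An `eeg_epochs` object (1-30 Hz, average-referenced).
#' @param model A `microstate_model` (or a bare channels x K template matrix).
#' @param at `"peaks"` or `"samples"`.
#' @return An object of class `microstate_segmentation`: per-epoch `labels`
#'   (integer vectors), `retained` (logical vectors), `a` (intensity
#'   `V_t' Gamma_label(t)`, zero where not retained), plus `srate`, `K`,
#'   `excluded` (indices of excluded epochs), `condition`, `run`.
#' @export
backfit_labels <- function(epochs, model, at = c("peaks", "samples")) {
  at <- match.arg(at)
  tpl <- if (inherits(model, "microstate_model")) model$templates else as.matrix(model)
  K <- ncol(tpl)
  n_ep <- length(epochs$epochs)
  labels <- vector("list", n_ep)
  retained <- vector("list", n_ep)
  intens <- vector("list", n_ep)
  excluded <- integer(0)
  for (e in seq_len(n_ep)) {
    X <- epochs$epochs[[e]]
    n <- ncol(X)
    if (at == "peaks") {
      pk <- detect_gfp_peaks(gfp_curve(X))
      if (length(pk) < 2L) {
        excluded <- c(excluded, e)
        labels[[e]] <- rep(NA_integer_, n)
        retained[[e]] <- rep(FALSE, n)
        intens[[e]] <- rep(0, n)
        next
      }
      pk_lab <- .label_maps(X[, pk, drop = FALSE], tpl)
      # nearest peak (midpoint boundary, ties to the earlier peak)
      lab <- integer(n)
      bounds <- c(0L, floor((pk[-length(pk)] + pk[-1L]) / 2), n)
      for (i in seq_along(pk))
        lab[(bounds[i] + 1L):bounds[i + 1L]] <- pk_lab[i]
    } else {
      lab <- .label_maps(X, tpl)
    }
    r <- rle(lab)
    keep <- rep(TRUE, length(r$lengths))
    keep[1L] <- FALSE
    keep[length(keep)] <- FALSE
    retained[[e]] <- rep(keep, r$lengths)
    labels[[e]] <- lab
    a <- colSums(X * tpl[, lab, drop = FALSE])
    a[!retained[[e]]] <- 0
    intens[[e]] <- a
  }
  structure(list(labels = labels, retained = retained, a = intens,
                 srate = epochs$srate, K = K, excluded = excluded,
                 condition = epochs$condition, run = epochs$run),
            class = "microstate_segmentation")
}

# Polarity-invariant template labeling of maps (columns) by maximal absolute
# spatial (Pearson) correlation.
.label_maps <- function(maps, tpl) {
  C <- abs(suppressWarnings(stats::cor(maps, tpl)))   # n x K
  C[is.na(C)] <- -1                    # zero-variance maps: arbitrary class 1
  max.col(C, ties.method = "first")
}

#' Predict method: backfit new epochs with a fitted model
#'
#' @param object A `microstate_model`.
#' @param newdata An `eeg_epochs` object.
#' @param ... Passed to [backfit_labels()] (e.g. `at`).
#' @return A `microstate_segmentation`.
#' @export
predict.microstate_model <- function(object, newdata, ...) {
  backfit_labels(newdata, object, ...)
}

#' Coverage and duration of microstate classes
#'
#' Per epoch, coverage of class k is the fraction of retained samples labeled
#' k, and duration is the mean length (ms) of the retained runs of class k.
#' Parameters are then averaged over epochs: coverage over all epochs with
#' retained samples, duration only over epochs where the class occurs.
#' Classes absent from every epoch get coverage 0 and duration `NA`.
#'
#' @param seg A [backfit_labels()] segmentation.
#' @param srate Sampling rate (default from `seg`).
#' @return Data frame: class, coverage, duration_ms, n_epochs (epochs where
#'   the class occurred).
#' @export
compute_parameters <- function(seg, srate = seg$srate) {
  K <- seg$K
  cov_acc <- matrix(NA_real_, 0L, K)
  dur_acc <- matrix(NA_real_, 0L, K)
  for (e in seq_along(seg$labels)) {
    ret <- seg$retained[[e]]
    if (!any(ret)) next
    lab <- seg$labels[[e]][ret]
    cov_e <- tabulate(lab, nbins = K) / length(lab)
    r <- rle(lab)
    dur_e <- rep(NA_real_, K)
    for (k in unique(r$values))
      dur_e[k] <- mean(r$lengths[r$values == k]) * 1000 / srate
    cov_acc <- rbind(cov_acc, cov_e)
    dur_acc <- rbind(dur_acc, dur_e)
  }
  if (nrow(cov_acc) == 0L)
    stop("no retained samples in any epoch")
  data.frame(
    class = seq_len(K),
    coverage = colMeans(cov_acc),
    duration_ms = apply(dur_acc, 2L, function(col)
      if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)),
    n_epochs = colSums(!is.na(dur_acc))
  )
}

#' Residuals of a microstate model on epoched data
#'
#' Per retained sample, the squared norm of `V_t - a_t Gamma_label(t)`.
#'
#' @param object A `microstate_model`.
#' @param epochs An `eeg_epochs`.
#' @param ... Unused.
#' @return List of per-epoch numeric vectors (`NA` at non-retained samples).
#' @export
residuals.microstate_model <- function(object, epochs, ...) {
  seg <- backfit_labels(epochs, object)
  out <- vector("list", length(epochs$epochs))
  for (e in seq_along(epochs$epochs)) {
    X <- epochs$epochs[[e]]
    lab <- seg$labels[[e]]
    res <- colSums(X^2) - seg$a[[e]]^2
    res[!seg$retained[[e]]] <- NA_real_
    out[[e]] <- res
  }
  out
}
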