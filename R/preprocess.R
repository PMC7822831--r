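# Minimal fully-specified preprocessing: zero-phase band-pass, average
# reference, fixed-length epoching with the bad-channel-ratio rule and a
# distance-weighted interpolation stub. Published artifact-removal pipelines
# (wavelet-ICA, channel-quality classifiers) are intentionally out of scope;
# bad-channel masks are an input here.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward ([signal::filtfilt()]),
#' so the passband gain is within a few percent of unity and phase (hence
#' microstate timing) is preserved. Length is preserved.
#'
#' @param rec An [recording()] object.
#' @param band Numeric `c(lo, hi)` in Hz, `0 < lo < hi < srate/2`.
#' @param order Filter order per pass (default 4).
#' @return A filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, band, order = 4L) {
  stopifnot(length(band) == 2L)
  lo <- band[1]; hi <- band[2]
  nyq <- rec$srate / 2
  if (!(lo > 0 && hi > lo && hi < nyq))
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist=%g)", lo, hi, nyq))
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- rec$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- signal::filtfilt(bf, out[i, ])
  res <- rec
  res$data <- out
  res
}

#' Re-reference to the average reference
#'
#' Subtracts the per-sample mean over channels, so every column of the data
#' matrix sums to zero. Idempotent; leaves global field power unchanged.
#'
#' @param rec An [recording()] object with at least 2 channels.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  res <- rec
  res$data <- sweep(rec$data, 2L, colMeans(rec$data))
  res
}

#' Cut a recording into fixed 2-s epochs and apply the bad-channel-ratio rule
#'
#' Consecutive non-overlapping epochs of `epoch_seconds`; a trailing partial
#' epoch is dropped. An epoch is kept iff its bad-channel ratio
#' (#bad / #channels) is strictly below `reject_ratio`. Bad channels in kept
#' epochs are replaced by a distance-weighted (1/d) mean of the 4 nearest
#' good channels — a deliberately simple stand-in for spherical-spline
#' interpolation.
#'
#' @param rec An [recording()] object.
#' @param montage Montage with channel positions (used for interpolation).
#' @param bad_channels Optional epoch-wise bad-channel specification: a list
#'   (one integer/character vector per epoch) or a single vector applied to
#'   all epochs. `NULL` means no bad channels.
#' @param epoch_seconds Epoch length in seconds (default 2).
#' @param reject_ratio Rejection threshold on the bad-channel ratio
#'   (default 0.25, strict inequality keeps an epoch).
#' @return An object of class `eeg_epochs`: list with `epochs` (list of
#'   channels x samples matrices, kept epochs only), `kept_mask` (over all
#'   cut epochs), `srate`, `channels`, `condition`, `run`, `band`.
#' @export
epoch_and_reject <- function(rec, montage = NULL, bad_channels = NULL,
                             epoch_seconds = 2, reject_ratio = 0.25) {
  len <- as.integer(round(epoch_seconds * rec$srate))
  n <- ncol(rec$data)
  if (n < len) stop(sprintf("recording (%d samples) shorter than one %gs epoch",
                            n, epoch_seconds))
  n_ep <- n %/% len
  nch <- nrow(rec$data)

  bad_idx <- function(e) {
    spec <- if (is.null(bad_channels)) integer(0)
            else if (is.list(bad_channels)) {
              if (e <= length(bad_channels)) bad_channels[[e]] else integer(0)
            } else bad_channels
    if (is.character(spec)) match(spec, rec$channels) else as.integer(spec)
  }

  epochs <- vector("list", n_ep)
  kept <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    cols <- ((e - 1L) * len + 1L):(e * len)
    block <- rec$data[, cols, drop = FALSE]
    bad <- unique(bad_idx(e))
    bad <- bad[!is.na(bad)]
    kept[e] <- (length(bad) / nch) < reject_ratio
    if (!kept[e]) next
    if (length(bad) > 0L) {
      if (is.null(montage)) stop("bad channels present but no montage given")
      block <- .interpolate_channels(block, bad, montage)
    }
    epochs[[e]] <- block
  }
  structure(list(epochs = epochs[kept], kept_mask = kept, srate = rec$srate,
                 channels = rec$channels, condition = rec$condition,
                 run = rec$run, band = NA_character_),
            class = "eeg_epochs")
}

# Replace rows `bad` of a channels x samples block by the 1/d-weighted mean
# of the 4 nearest good channels (montage unit-sphere distance).
.interpolate_channels <- function(block, bad, montage) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  good <- setdiff(seq_len(nrow(block)), bad)
  for (b in bad) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
    nn <- good[order(d)][seq_len(min(4L, length(good)))]
    w <- 1 / pmax(d[order(d)][seq_len(length(nn))], 1e-9)
    w <- w / sum(w)
    block[b, ] <- as.vector(w %*% block[nn, , drop = FALSE])
  }
  block
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("EEG epochs: %d kept of %d (%d channels, %g Hz)\n",
              length(x$epochs), length(x$kept_mask),
              length(x$channels), x$srate))
  invisible(x)
}
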