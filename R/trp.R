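# Task-related power: Welch spectra on 2-s windows, composite Simpson band
# integration, log power change of each task run against the resting
# reference, and aggregation into the ten cortical area x hemisphere groups.

#' Welch power spectral density
#'
#' Hann-tapered, mean-detrended segments of `win` samples advanced by
#' `win - overlap`, one-sided density scaling (power integrates to variance).
#' Frequency resolution is `srate / win`.
#'
#' @param x Numeric vector, channels x samples matrix, or an `eeg_epochs`
#'   object (kept epochs are concatenated, one segment per epoch boundary is
#'   never spanned when epochs equal the window length).
#' @param srate Sampling rate in Hz (taken from `x` for `eeg_epochs`).
#' @param win Segment length in samples (default 1000, i.e. 2 s at 500 Hz).
#' @param overlap Overlapping samples between neighbouring segments
#'   (default 500).
#' @return List with `freq` (Hz) and `psd` (channels x frequencies matrix,
#'   \eqn{\mu V^2/Hz}).
#' @export
welch_psd <- function(x, srate = NULL, win = 1000L, overlap = 500L) {
  if (inherits(x, "eeg_epochs")) {
    srate <- x$srate
    x <- do.call(cbind, x$epochs)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (win > n) stop("window (", win, ") longer than available samples (", n, ")")
  if (overlap >= win) stop("overlap must be smaller than the window")
  step <- win - overlap
  starts <- seq(1L, n - win + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hann
  u <- sum(w^2)
  nf <- win %/% 2L + 1L
  acc <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, s:(s + win - 1L), drop = FALSE]
    seg <- sweep(seg, 1L, rowMeans(seg))
    seg <- sweep(seg, 2L, w, "*")
    ft <- t(stats::mvfft(t(seg)))[, seq_len(nf), drop = FALSE]
    p <- (Mod(ft)^2) / (srate * u)
    # one-sided: double all bins except DC (and Nyquist when win is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (win %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + sweep(p, 2L, dbl, "*")
  }
  list(freq = (seq_len(nf) - 1L) * srate / win, psd = acc / length(starts))
}

#' Integrate a PSD over a band with the composite Simpson rule
#'
#' Integrates each channel's PSD between the band edges (inclusive) on the
#' PSD's own frequency grid. With an odd number of grid points the classic
#' composite rule applies; with an even number the last interval is handled
#' by the trapezoid rule, so adjacent bands sharing an edge bin sum exactly
#' to the enclosing band when each piece has an odd point count.
#'
#' @param psd A [welch_psd()] result.
#' @param band Numeric `c(lo, hi)` in Hz, inside the PSD frequency range.
#' @return Named numeric vector of band power per channel (\eqn{\mu V^2}).
#' @export
band_power <- function(psd, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[1] < min(psd$freq) || band[2] > max(psd$freq))
    stop("band outside the PSD frequency range")
  sel <- which(psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9)
  if (length(sel) < 3L)
    stop("composite Simpson needs at least 3 frequency bins in the band")
  f <- psd$freq[sel]
  y <- psd$psd[, sel, drop = FALSE]
  apply(y, 1L, .simpson, x = f)
}

# Composite Simpson on a uniform grid; even point counts fall back to
# Simpson on the leading odd-length stretch plus a trapezoid on the last
# interval.
.simpson <- function(y, x) {
  n <- length(x)
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) stop("Simpson rule needs a uniform grid")
  h <- h[1]
  simp <- function(yy) {
    m <- length(yy)                                  # odd
    wgt <- c(1, rep(c(4, 2), (m - 1L) / 2))[seq_len(m)]
    wgt[m] <- 1                                      # 1, 4, 2, ..., 2, 4, 1
    sum(wgt * yy) * h / 3
  }
  if (n %% 2L == 1L) simp(y)
  else simp(y[seq_len(n - 1L)]) + (y[n - 1L] + y[n]) * h / 2
}

#' Band power of every run in a study, per channel
#'
#' Convenience wrapper: band-pass to `prefilter`, average-reference, epoch,
#' Welch, Simpson. Returns one row per (participant, condition, run, channel).
#'
#' @param study An `eeg_study` (or any list with `recordings`, `index`,
#'   `montage`).
#' @param band Integration band `c(lo, hi)` Hz.
#' @param prefilter Band-pass applied before the PSD (default `c(1, 30)`).
#' @param win,overlap Welch parameters in samples.
#' @param epoch_seconds Epoch length for the bad-epoch rule.
#' @return Data frame: participant, condition, run, channel, power.
#' @export
study_band_power <- function(study, band, prefilter = c(1, 30),
                             win = 1000L, overlap = 500L, epoch_seconds = 2) {
  out <- vector("list", length(study$recordings))
  for (i in seq_along(study$recordings)) {
    rec <- rereference_average(bandpass_filter(study$recordings[[i]], prefilter))
    ep <- epoch_and_reject(rec, study$montage, epoch_seconds = epoch_seconds)
    psd <- welch_psd(ep, win = win, overlap = overlap)
    pow <- band_power(psd, band)
    r <- study$index[i, ]
    out[[i]] <- data.frame(participant = r$participant, condition = r$condition,
                           run = r$run, channel = study$montage$channel,
                           power = unname(pow))
  }
  do.call(rbind, out)
}

#' Task-related power (log power change against the resting reference)
#'
#' For each channel i and task condition k, the mean over runs j of
#' `log(power_activation[k, j, i]) - log(power_reference[i])`. The reference
#' is the rest block recorded at the start of the experiment. Natural log by
#' default.
#'
#' @param power Data frame as returned by [study_band_power()] (must contain
#'   the rest rows of each participant).
#' @param log_base Base of the logarithm (`exp(1)` or `10`).
#' @return Data frame of class `trp_table`: participant, condition, channel,
#'   trp (one value per task condition, averaged over runs).
#' @export
compute_trp <- function(power, log_base = exp(1)) {
  if (any(power$power <= 0)) {
    bad <- unique(power$channel[power$power <= 0])
    stop("non-positive band power for channel(s): ", paste(bad, collapse = ", "))
  }
  lp <- log(power$power, base = log_base)
  out <- list()
  for (p in unique(power$participant)) {
    sel_p <- power$participant == p
    ref <- lp[sel_p & power$condition == "rest"]
    ref_ch <- power$channel[sel_p & power$condition == "rest"]
    if (length(ref) == 0L) stop("participant ", p, " has no rest reference")
    names(ref) <- ref_ch
    for (cond in intersect(task_conditions(), unique(power$condition[sel_p]))) {
      sel <- sel_p & power$condition == cond
      d <- lp[sel] - ref[power$channel[sel]]
      agg <- tapply(d, power$channel[sel], mean)
      out[[length(out) + 1L]] <- data.frame(
        participant = p, condition = cond,
        channel = names(agg), trp = as.vector(agg), row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("trp_table", "data.frame")
  res
}

#' Aggregate a TRP table into cortical area x hemisphere regions
#'
#' Mean TRP over each of the ten area-by-hemisphere electrode groups; midline
#' and ungrouped channels never contribute.
#'
#' @param trp A [compute_trp()] table.
#' @param montage The montage defining the groups.
#' @return Data frame: participant, condition, area, hemisphere, trp.
#' @export
aggregate_regions <- function(trp, montage) {
  areas <- c("frontal", "central", "temporal", "parietal", "occipital")
  out <- list()
  for (a in areas) for (h in c("left", "right")) {
    chs <- montage_group(montage, a, h)
    sel <- trp$channel %in% chs
    sub <- trp[sel, , drop = FALSE]
    agg <- stats::aggregate(trp ~ participant + condition, data = sub, FUN = mean)
    agg$area <- a; agg$hemisphere <- h
    out[[length(out) + 1L]] <- agg[, c("participant", "condition", "area",
                                       "hemisphere", "trp")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
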