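# Recording container and readers/writers. All stages consume recordings in
# canonical montage channel order, in microvolts.

#' Create an EEG recording object
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param srate Sampling rate in Hz.
#' @param channels Character vector of channel names (row order of `data`).
#' @param condition One of `"rest"`, `"generation"`, `"evolution"`,
#'   `"evaluation"` (or `NA`).
#' @param run Run index, 1..3 for task conditions, 0 for rest.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, srate, channels, condition = NA_character_, run = 0L) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), srate > 0, ncol(data) >= 1L)
  if (length(channels) != nrow(data))
    stop("channel name count (", length(channels),
         ") does not match data rows (", nrow(data), ")")
  if (!is.na(condition) && !condition %in% condition_levels())
    stop("unknown condition: ", condition)
  rownames(data) <- channels
  structure(list(data = data, srate = as.numeric(srate),
                 channels = as.character(channels),
                 condition = condition, run = as.integer(run)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              if (is.na(x$condition)) "" else
                sprintf(", condition=%s run=%d", x$condition, x$run)))
  invisible(x)
}

# Reorder recording rows to montage channel order; hard error naming any
# montage channel missing from the recording.
conform_to_montage <- function(rec, montage) {
  missing <- setdiff(montage$channel, rec$channels)
  if (length(missing) > 0L)
    stop("recording is missing montage channels: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(rec$channels, montage$channel)
  if (length(extra) > 0L)
    stop("recording has channels unknown to the montage: ",
         paste(extra, collapse = ", "))
  idx <- match(montage$channel, rec$channels)
  recording(rec$data[idx, , drop = FALSE], rec$srate, montage$channel,
            rec$condition, rec$run)
}

#' Write / read a recording in the matrix + sidecar interchange format
#'
#' The data file is a tab-separated channels x samples matrix printed at full
#' double precision (`%.17g`), so a write/read round trip is bit-exact. The
#' JSON sidecar (`<path>.json`) carries channel names, sampling rate,
#' condition and run.
#'
#' @param rec An [recording()] object.
#' @param path Path of the matrix file; the sidecar is written next to it.
#' @param montage Optional montage; when given, channels are conformed to
#'   montage order on read.
#' @return `read_recording_matrix` returns an `eeg_recording`.
#' @export
write_recording_matrix <- function(rec, path) {
  sidecar <- paste0(path, ".json")
  lines <- apply(rec$data, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(channels = rec$channels, srate = rec$srate,
         condition = rec$condition, run = rec$run),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_recording_matrix
#' @export
read_recording_matrix <- function(path, montage = NULL) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
  dimnames(dat) <- NULL
  rec <- recording(dat, meta$srate, meta$channels,
                   meta$condition %||% NA_character_,
                   meta$run %||% 0L)
  if (!is.null(montage)) rec <- conform_to_montage(rec, montage)
  rec
}

# --- BrainVision -----------------------------------------------------------

# Minimal reader for continuous BrainVision files: INI-style .vhdr header plus
# a multiplexed or vectorized binary .eeg data file (IEEE_FLOAT_32 or INT_16
# with per-channel resolution). Values are returned in microvolts.

.parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\ufeff", "", lines)
  section <- ""
  kv <- list()
  chans <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (identical(section, "Channel Infos")) chans[[key]] <- val
    else kv[[paste(section, key, sep = "/")]] <- val
  }
  list(kv = kv, chans = chans)
}

#' Read a continuous BrainVision recording
#'
#' Supports binary data files in `IEEE_FLOAT_32` or `INT_16` with multiplexed
#' or vectorized orientation. Channel resolutions and units are applied so the
#' returned data are in microvolts.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @param montage Optional montage to conform channel order to.
#' @param condition,run Study annotations to attach.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr_path, montage = NULL,
                             condition = NA_character_, run = 0L) {
  hdr <- .parse_vhdr(vhdr_path)
  kv <- hdr$kv
  fmt <- toupper(kv[["Common Infos/DataFormat"]] %||% "BINARY")
  if (fmt != "BINARY") stop("only BINARY BrainVision data supported, got ", fmt)
  orient <- toupper(kv[["Common Infos/DataOrientation"]] %||% "MULTIPLEXED")
  nchan <- as.integer(kv[["Common Infos/NumberOfChannels"]])
  sint_us <- as.numeric(kv[["Common Infos/SamplingInterval"]])  # microseconds
  srate <- 1e6 / sint_us
  binfmt <- toupper(kv[["Binary Infos/BinaryFormat"]] %||% "IEEE_FLOAT_32")

  ch <- lapply(seq_len(nchan), function(i) {
    spec <- hdr$chans[[paste0("Ch", i)]]
    if (is.null(spec)) stop("header lacks Ch", i)
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    list(name = parts[1],
         resolution = if (length(parts) >= 3 && nzchar(parts[3]))
           as.numeric(parts[3]) else 1,
         unit = if (length(parts) >= 4) parts[4] else "\u00b5V")
  })

  datafile <- file.path(dirname(vhdr_path), kv[["Common Infos/DataFile"]])
  con <- file(datafile, "rb")
  on.exit(close(con))
  sz <- file.size(datafile)
  if (binfmt == "IEEE_FLOAT_32") {
    n <- sz / 4L
    raw_vals <- readBin(con, "numeric", n = n, size = 4L)
    res_applies <- FALSE
  } else if (binfmt == "INT_16") {
    n <- sz / 2L
    raw_vals <- readBin(con, "integer", n = n, size = 2L, signed = TRUE)
    res_applies <- TRUE
  } else stop("unsupported BinaryFormat: ", binfmt)
  nsamp <- length(raw_vals) %/% nchan
  if (orient == "MULTIPLEXED") {
    dat <- matrix(raw_vals[seq_len(nsamp * nchan)], nrow = nchan)
  } else if (orient == "VECTORIZED") {
    dat <- t(matrix(raw_vals[seq_len(nsamp * nchan)], ncol = nchan))
  } else stop("unsupported DataOrientation: ", orient)

  for (i in seq_len(nchan)) {
    scale <- if (res_applies || binfmt == "IEEE_FLOAT_32") ch[[i]]$resolution else 1
    if (binfmt == "IEEE_FLOAT_32") scale <- ch[[i]]$resolution  # usually 1
    u <- ch[[i]]$unit
    if (u %in% c("V", "Volt")) scale <- scale * 1e6
    else if (u %in% c("mV")) scale <- scale * 1e3
    if (scale != 1) dat[i, ] <- dat[i, ] * scale
  }
  rec <- recording(dat, srate, vapply(ch, `[[`, "", "name"), condition, run)
  if (!is.null(montage)) rec <- conform_to_montage(rec, montage)
  rec
}

# --- EDF -------------------------------------------------------------------

#' Read a continuous EDF recording
#'
#' Minimal EDF (European Data Format) reader for continuous recordings whose
#' signals share one sampling rate. Digital values are mapped to physical
#' units via the per-signal calibration, and converted to microvolts when the
#' physical dimension is V or mV.
#'
#' @inheritParams read_brainvision
#' @param edf_path Path to the `.edf` file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(edf_path, montage = NULL,
                     condition = NA_character_, run = 0L) {
  con <- file(edf_path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  rd(8); rd(80); rd(80); rd(8); rd(8)            # version, patient, rec, date, time
  rd(8)                                           # header byte count
  rd(44)                                          # reserved
  ndr <- as.integer(rd(8))                        # number of data records
  dur <- as.numeric(rd(8))                        # record duration, s
  ns <- as.integer(rd(4))                         # number of signals
  f <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- f(16); f(80); dims <- f(8)
  pmin_ <- as.numeric(f(8)); pmax_ <- as.numeric(f(8))
  dmin_ <- as.numeric(f(8)); dmax_ <- as.numeric(f(8))
  f(80)                                           # prefiltering
  nspr <- as.integer(f(8))                        # samples per record
  f(32)                                           # reserved
  if (length(unique(nspr)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported")
  srate <- nspr[1] / dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_
  dat <- matrix(0, nrow = ns, ncol = ndr * nspr[1])
  for (r in seq_len(ndr)) {
    block <- readBin(con, "integer", n = ns * nspr[1], size = 2L,
                     signed = TRUE, endian = "little")
    m <- matrix(block, nrow = nspr[1])             # samples x signals
    cols <- ((r - 1L) * nspr[1] + 1L):(r * nspr[1])
    dat[, cols] <- t(m) * gain + offset
  }
  for (i in seq_len(ns)) {
    if (dims[i] %in% c("V")) dat[i, ] <- dat[i, ] * 1e6
    if (dims[i] %in% c("mV")) dat[i, ] <- dat[i, ] * 1e3
  }
  rec <- recording(dat, srate, labels, condition, run)
  if (!is.null(montage)) rec <- conform_to_montage(rec, montage)
  rec
}

#' Read a recording in any supported format
#'
#' Dispatches on `format`: `"brainvision"` (.vhdr), `"edf"`, or
#' `"matrix"` (matrix + JSON sidecar).
#'
#' @param path File path (.vhdr for BrainVision).
#' @param format One of `"brainvision"`, `"edf"`, `"matrix"`.
#' @param expected_srate Optional sampling rate the caller's configuration
#'   assumes; a mismatch with the file is a hard error.
#' @inheritParams read_brainvision
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("matrix", "brainvision", "edf"),
                           montage = NULL, condition = NA_character_, run = 0L,
                           expected_srate = NULL) {
  format <- match.arg(format)
  rec <- switch(format,
         matrix = {
           rec <- read_recording_matrix(path, montage)
           if (!is.na(condition)) rec$condition <- condition
           if (run != 0L) rec$run <- as.integer(run)
           rec
         },
         brainvision = read_brainvision(path, montage, condition, run),
         edf = read_edf(path, montage, condition, run))
  if (!is.null(expected_srate) && abs(rec$srate - expected_srate) > 1e-9)
    stop("sampling rate mismatch: file has ", rec$srate, " Hz, configuration ",
         "expects ", expected_srate, " Hz")
  rec
}
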