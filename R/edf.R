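# Minimal European Data Format (EDF) writer/reader for continuous recordings.
# Signals are stored as 16-bit integers with per-channel physical scaling and
# 1-second data records; the true sample count is kept in the reserved header
# field so the reader can trim record padding. Trial events and channel
# positions travel in plain-text sidecars (TSV), written by generateCohort.

.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param rec an \code{\link{EEGRecording}}.
#' @param path output file path.
#' @param patient_id,recording_id header identification strings.
#' @return \code{path}, invisibly.
#' @export
writeEdf <- function(rec, path, patient_id = "X", recording_id = "synthetic") {
  dat <- eegData(rec)
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nc <- nrow(dat)
  n <- ncol(dat)
  nrec <- ceiling(n / fs)
  physMin <- apply(dat, 1, min)
  physMax <- apply(dat, 1, max)
  pad <- pmax((physMax - physMin) * 0.01, 1e-3)
  physMin <- physMin - pad
  physMax <- physMax + pad
  dmin <- -32767L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * nc
  writeChar(paste0(
    .padField("0", 8), .padField(patient_id, 80), .padField(recording_id, 80),
    .padField("01.01.26", 8), .padField("00.00.00", 8),
    .padField(hdrBytes, 8), .padField(sprintf("NSAMP=%d", n), 44),
    .padField(nrec, 8), .padField(1, 8), .padField(nc, 4)
  ), con, eos = NULL)
  fields <- list(
    vapply(channelLabels(rec), .padField, "", width = 16),
    rep(.padField("synthetic EEG", 80), nc),
    rep(.padField("uV", 8), nc),
    vapply(sprintf("%.6g", physMin), .padField, "", width = 8),
    vapply(sprintf("%.6g", physMax), .padField, "", width = 8),
    rep(.padField(dmin, 8), nc),
    rep(.padField(dmax, 8), nc),
    rep(.padField("none", 80), nc),
    rep(.padField(fs, 8), nc),
    rep(.padField("", 32), nc)
  )
  writeChar(paste(unlist(fields), collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (physMax - physMin)
  padded <- matrix(0, nc, nrec * fs)
  padded[, seq_len(n)] <- dat
  dig <- round((padded - physMin) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file (plus optional sidecars) into an EEGRecording
#'
#' @param path EDF file written by \code{\link{writeEdf}} (or any EDF file
#'   with a common sampling rate across signals and 1-channel-block records).
#' @param events_path optional events TSV sidecar (columns as written by
#'   \code{\link{generateCohort}}).
#' @param channels_path optional channel-position TSV sidecar; when absent,
#'   positions are looked up from the built-in montage.
#' @return an \code{\link{EEGRecording}}.
#' @export
readEdf <- function(path, events_path = NULL, channels_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)           # transducer
  for (i in seq_len(nc)) rd(8)            # physical dim
  pmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nc)) rd(80)           # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed per-signal rates not supported")
  fs <- spr[1] / recDur
  dat <- matrix(0, nc, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = nc * spr[1], size = 2,
                     endian = "little")
    m <- matrix(block, nrow = spr[1], ncol = nc)
    dat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(m)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  dat <- dat * scale + (pmin - dmin * scale)
  if (grepl("^NSAMP=", reserved)) {
    n <- as.integer(sub("^NSAMP=", "", reserved))
    dat <- dat[, seq_len(n), drop = FALSE]
  }
  channels <- if (!is.null(channels_path)) {
    utils::read.delim(channels_path, stringsAsFactors = FALSE)
  } else {
    buildMontage(labels = labels)
  }
  events <- if (!is.null(events_path)) {
    utils::read.delim(events_path, stringsAsFactors = FALSE)
  } else {
    data.frame(trial_id = integer(0), condition = character(0),
               onset_s = numeric(0), change_s = numeric(0))
  }
  newRecording(dat, fs, channels, events)
}
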