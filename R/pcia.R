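# Auditory perturbational complexity index (PCIa): per channel and trial the
# evoked signal is reduced to a binary sequence by thresholding its Hilbert
# amplitude envelope at the envelope's own mean; the binarized rows are
# concatenated into one sequence S whose exhaustive-history Lempel-Ziv word
# count c(S) is normalized by the expected word count of a random string,
# PCIa = c(S) * log2(L) / (L * H(S)), with H(S) the binary entropy of the
# proportion of ones. Random strings calibrate to 1 for any P(1).

#' Binary Shannon entropy of a 0/1 sequence
#'
#' \code{H = -p1 log2(p1) - (1 - p1) log2(1 - p1)} with the convention
#' \code{0 log 0 = 0}; \code{p1} is the empirical proportion of ones.
#'
#' @param s integer/logical vector of 0/1 symbols (or a single probability
#'   via \code{p}).
#' @param p optional: give the probability directly instead of a sequence.
#' @return entropy in bits, in \code{[0, 1]}.
#' @export
binaryEntropy <- function(s = NULL, p = NULL) {
  if (is.null(p)) {
    stopifnot(length(s) >= 1)
    p <- mean(s == 1)
  }
  stopifnot(p >= 0, p <= 1)
  term <- function(q) if (q <= 0) 0 else -q * log2(q)
  term(p) + term(1 - p)
}

#' Hilbert-mean binarization of epoched EEG
#'
#' For each kept trial and each requested channel: the amplitude envelope is
#' computed over the whole epoch (magnitude of the FFT analytic signal, which
#' avoids window-edge artifacts), restricted to the analysis window,
#' resampled to \code{target_rate} (zero-phase decimation), and thresholded
#' at its own mean - strictly greater becomes 1 (with a tiny relative
#' tolerance so constant envelopes binarize to all zeros).
#'
#' @param epochs an \code{\link{EpochArray}}.
#' @param window analysis window \code{c(t0, t1)} seconds relative to the
#'   lock (default \code{c(-0.5, 1.5)}).
#' @param channels channel labels to use.
#' @param target_rate binarization rate in Hz (default 64).
#' @return integer matrix with one row per (trial, channel) pair - channels
#'   in montage order within each trial, trials in chronological order - and
#'   attributes \code{window}, \code{channels}, \code{nTrials}, \code{lock}.
#' @export
binarizeHilbert <- function(epochs, window = c(-0.5, 1.5),
                            channels = channelLabels(epochs),
                            target_rate = 64) {
  chIdx <- match(channels, channelLabels(epochs))
  if (anyNA(chIdx)) stop("channel(s) not present: ",
                         paste(channels[is.na(chIdx)], collapse = ", "))
  keep <- keptIndex(epochs)
  if (!length(keep)) stop("no kept trials")
  tt <- epochTimes(epochs)
  fs <- samplingRate(epochs)
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) stop("target_rate must divide the epoch rate")
  q <- as.integer(round(q))
  sel <- which(tt >= window[1] & tt < window[2])
  if (!length(sel)) stop("analysis window lies outside the epoch")
  rows <- vector("list", length(keep) * length(chIdx))
  r <- 0
  for (tr in keep) {
    for (ch in chIdx) {
      env <- Mod(analyticSignal(epochs@data[tr, ch, ]))
      env <- env[sel]
      if (q > 1) env <- .decimateBy(env, q)
      thr <- mean(env)
      r <- r + 1
      rows[[r]] <- as.integer(env > thr * (1 + 1e-9))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "channels") <- channels
  attr(out, "nTrials") <- length(keep)
  attr(out, "lock") <- epochs@lock
  out
}

#' Normalized Lempel-Ziv complexity of a binary matrix
#'
#' Flattens the matrix row by row into one sequence S and computes
#' \code{PCIa = c(S) * log2(L) / (L * H(S))} with \code{c(S)} the LZ76 word
#' count (\code{\link{lzWordCount}}). When H(S) = 0 (constant sequence) the
#' score is undefined and flagged.
#'
#' @param bin integer matrix of 0/1 (rows are concatenated), or a vector.
#' @param lock,window,channelSet,nTrials provenance fields; taken from the
#'   attributes of \code{\link{binarizeHilbert}} output when present.
#' @return a \code{\link{PCIaScore}}.
#' @export
pciaScore <- function(bin, lock = NULL, window = NULL, channelSet = NULL,
                      nTrials = NULL) {
  if (is.matrix(bin)) {
    lock <- lock %||% attr(bin, "lock")
    window <- window %||% attr(bin, "window")
    channelSet <- channelSet %||% attr(bin, "channels")
    nTrials <- nTrials %||% attr(bin, "nTrials")
    s <- as.integer(t(bin))          # concatenate rows
  } else {
    s <- as.integer(bin)
  }
  if (!length(s)) stop("empty sequence")
  L <- length(s)
  p1 <- mean(s == 1)
  H <- binaryEntropy(p = p1)
  cc <- lzWordCount(s)
  defined <- H > 0
  value <- if (defined) cc * log2(L) / (L * H) else NA_real_
  new("PCIaScore", value = value, wordCount = as.integer(cc),
      length = as.integer(L), p1 = p1, entropy = H, defined = defined,
      lock = lock %||% "onset",
      window = as.numeric(window %||% c(NA_real_, NA_real_)),
      channelSet = as.character(channelSet %||% character(0)),
      nTrials = as.integer(nTrials %||% nrow(as.matrix(bin))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute a subject's PCIa for one lock
#'
#' Binarizes the kept trials of the requested channel cluster over the
#' analysis window and scores the flattened sequence. For the change lock the
#' epochs should already be restricted to the longest change-time condition
#' (3 s), as done by \code{\link{preprocessRecording}}.
#'
#' @param epochs an \code{\link{EpochArray}} (onset- or change-locked).
#' @param window analysis window in seconds (default \code{c(-0.5, 1.5)};
#'   the narrower \code{c(-0.25, 1.25)} variant is available as
#'   \code{window = "narrow"}).
#' @param channel_set channel labels; defaults to the lock-specific
#'   14-channel cluster (\code{\link{pciaChannelSet}}).
#' @param target_rate binarization rate (Hz).
#' @return a \code{\link{PCIaScore}}.
#' @export
computeSubjectPCIa <- function(epochs, window = c(-0.5, 1.5),
                               channel_set = NULL, target_rate = 64) {
  if (identical(window, "narrow")) window <- c(-0.25, 1.25)
  if (is.null(channel_set)) {
    channel_set <- intersect(pciaChannelSet(epochs@lock),
                             channelLabels(epochs))
  }
  if (!length(channel_set)) stop("empty channel set")
  bin <- binarizeHilbert(epochs, window = window, channels = channel_set,
                         target_rate = target_rate)
  pciaScore(bin)
}
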