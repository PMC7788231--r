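# Preprocessing: bad-channel repair -> resampling -> common-average
# reference -> zero-phase filtering -> epoching -> amplitude rejection ->
# median baseline. All stage defaults are the analysis defaults used
# throughout the package (128 Hz, 0.3-30 Hz, +/- 200 uV, median baseline in
# [-0.400, -0.150] s before the lock).

.applyChannels <- function(dat, fun) {
  first <- fun(dat[1, ])
  out <- matrix(0, nrow(dat), length(first))
  out[1, ] <- first
  if (nrow(dat) > 1) {
    for (i in 2:nrow(dat)) out[i, ] <- fun(dat[i, ])
  }
  out
}

#' Resample a recording to a lower rate
#'
#' Zero-phase anti-alias filtering followed by integer-factor decimation.
#' The target rate must divide the current rate. Event times are expressed in
#' seconds and therefore carry over unchanged.
#'
#' @param rec an \code{\link{EEGRecording}}.
#' @param target_rate target rate in Hz (default 128).
#' @return resampled \code{\link{EEGRecording}}.
#' @export
resampleTo <- function(rec, target_rate = 128) {
  fs <- samplingRate(rec)
  if (target_rate > fs) stop("target_rate must not exceed the sampling rate")
  if (target_rate == fs) return(rec)
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) stop("target_rate must divide the sampling rate")
  q <- as.integer(round(q))
  dat <- .applyChannels(eegData(rec), function(x) .decimateBy(x, q))
  newRecording(dat, target_rate, rec@channels, rec@events)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across all scalp channels from every
#' channel, so the per-sample channel mean is zero.
#'
#' @param rec an \code{\link{EEGRecording}} with at least 2 channels.
#' @return re-referenced recording.
#' @export
rereferenceCommonAverage <- function(rec) {
  dat <- eegData(rec)
  if (nrow(dat) < 2) stop("common-average reference requires >= 2 channels")
  avg <- colMeans(dat)
  newRecording(sweep(dat, 2, avg), samplingRate(rec), rec@channels, rec@events)
}

#' Band-pass filter a recording
#'
#' High-pass: Chebyshev type II (default order 15, 40 dB stop-band) at
#' \code{hp_cutoff}; low-pass: Butterworth (default order 4) at
#' \code{lp_cutoff}. Both are applied forward-backward (zero phase) as
#' second-order-section cascades, preserving component latencies.
#'
#' @param rec an \code{\link{EEGRecording}}.
#' @param hp_cutoff,lp_cutoff corner frequencies in Hz (defaults 0.3 and 30).
#' @param hp_order,lp_order filter orders.
#' @param hp_stopband_db Chebyshev II stop-band attenuation in dB.
#' @return filtered recording.
#' @export
bandpassFilter <- function(rec, hp_cutoff = 0.3, lp_cutoff = 30,
                           hp_order = 15, lp_order = 4, hp_stopband_db = 40) {
  fs <- samplingRate(rec)
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < fs / 2)) {
    stop("require 0 < hp_cutoff < lp_cutoff < fs/2")
  }
  hp <- .designFilter(hp_order, hp_cutoff, fs, type = "high",
                      design = "cheby2", Rs = hp_stopband_db)
  lp <- .designFilter(lp_order, lp_cutoff, fs, type = "low", design = "butter")
  dat <- .applyChannels(eegData(rec), function(x) {
    .sosFiltFilt(lp, .sosFiltFilt(hp, x))
  })
  newRecording(dat, fs, rec@channels, rec@events)
}

#' 50 Hz notch filter (optional stage)
#'
#' Zero-phase biquad notch centred at 50 Hz.
#'
#' @param rec an \code{\link{EEGRecording}} sampled above 100 Hz.
#' @param freq notch centre frequency, Hz.
#' @param q quality factor (bandwidth = freq / q).
#' @return filtered recording.
#' @export
notchFilter <- function(rec, freq = 50, q = 25) {
  fs <- samplingRate(rec)
  if (fs <= 2 * freq) stop("sampling rate too low for the notch frequency")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  sos <- matrix(c(b, a), nrow = 1)
  dat <- .applyChannels(eegData(rec), function(x) {
    as.numeric(.sosFiltFiltCpp(sos, x))
  })
  newRecording(dat, fs, rec@channels, rec@events)
}

#' Repair bad channels by inverse-distance-weighted neighbour averaging
#'
#' Each bad channel is replaced by the inverse-distance-weighted average of
#' its good neighbours on the montage graph; good channels are untouched.
#' A simple, sane stand-in for spline-based interpolation.
#'
#' @param rec an \code{\link{EEGRecording}}.
#' @param bad_labels character vector of channel labels to repair.
#' @param radius neighbourhood radius (see \code{\link{channelAdjacency}}).
#' @return repaired recording.
#' @export
repairBadChannels <- function(rec, bad_labels, radius = 0.3) {
  if (length(bad_labels) == 0) return(rec)
  labels <- channelLabels(rec)
  unknown <- setdiff(bad_labels, labels)
  if (length(unknown)) stop("bad_labels not in montage: ",
                            paste(unknown, collapse = ", "))
  if (length(bad_labels) >= length(labels)) stop("all channels marked bad")
  adj <- channelAdjacency(rec@channels, radius = radius)
  dat <- eegData(rec)
  pos <- rec@channels
  for (b in bad_labels) {
    nb <- setdiff(adj[[b]], bad_labels)
    if (length(nb) < 3) stop("channel ", b, " has fewer than 3 good neighbours")
    bi <- match(b, labels)
    ni <- match(nb, labels)
    d <- sqrt((pos$x[ni] - pos$x[bi])^2 + (pos$y[ni] - pos$y[bi])^2)
    w <- (1 / d) / sum(1 / d)
    dat[bi, ] <- as.numeric(w %*% eegData(rec)[ni, , drop = FALSE])
  }
  newRecording(dat, samplingRate(rec), rec@channels, rec@events)
}

#' Extract epochs around a lock event
#'
#' Epochs are half-open windows \code{[-pre_s, +post_s)} around the lock
#' sample (time 0 = lock). \code{lock = "onset"} uses every trial's sound
#' onset; \code{lock = "change"} uses the statistics-change time and therefore
#' excludes sham trials. Trials whose window exceeds the recording bounds are
#' flagged rejected (zero-filled data row) with reason
#' \code{"out_of_bounds"}.
#'
#' @param rec an \code{\link{EEGRecording}} with an event table.
#' @param lock \code{"onset"} or \code{"change"}.
#' @param pre_s,post_s window extent in seconds before/after the lock.
#' @param change_times optional filter: keep only trials with these nominal
#'   change times (used to restrict the change-locked analysis to the 3 s
#'   condition).
#' @return an \code{\link{EpochArray}}.
#' @export
extractEpochs <- function(rec, lock = c("onset", "change"), pre_s = 0.5,
                          post_s = 1.5, change_times = NULL) {
  lock <- match.arg(lock)
  ev <- recordingEvents(rec)
  fs <- samplingRate(rec)
  if (lock == "change") ev <- ev[ev$condition == "change", , drop = FALSE]
  if (!is.null(change_times) && nrow(ev)) {
    ev <- ev[!is.na(ev$change_time) & ev$change_time %in% change_times |
               is.na(ev$change_time) & lock == "onset", , drop = FALSE]
  }
  nPre <- round(pre_s * fs)
  nPost <- round(post_s * fs)
  nSamp <- nPre + nPost
  times <- (seq_len(nSamp) - 1 - nPre) / fs
  nc <- nrow(eegData(rec))
  if (nrow(ev) == 0) {
    return(newEpochArray(array(0, c(0, nc, nSamp)), times, fs, lock,
                         rec@channels,
                         data.frame(trial_id = integer(0),
                                    condition = character(0),
                                    change_time = numeric(0),
                                    kept = logical(0), reason = character(0))))
  }
  lockT <- if (lock == "onset") ev$onset_s else ev$change_s
  lockIdx <- round(lockT * fs) + 1
  lo <- lockIdx - nPre
  hi <- lockIdx + nPost - 1
  inb <- lo >= 1 & hi <= ncol(eegData(rec))
  arr <- array(0, c(nrow(ev), nc, nSamp))
  dat <- eegData(rec)
  for (k in which(inb)) {
    arr[k, , ] <- dat[, lo[k]:hi[k]]
  }
  info <- data.frame(trial_id = ev$trial_id,
                     condition = ev$condition,
                     change_time = if ("change_time" %in% names(ev))
                       ev$change_time else NA_real_,
                     kept = inb,
                     reason = ifelse(inb, "", "out_of_bounds"),
                     stringsAsFactors = FALSE)
  if ("stage_ok" %in% names(ev)) info$stage_ok <- ev$stage_ok
  newEpochArray(arr, times, fs, lock, rec@channels, info)
}

#' Reject epochs containing amplitude artifacts
#'
#' Flags as rejected every trial in which any channel sample exceeds the
#' threshold in absolute value. Already-rejected trials stay rejected.
#'
#' @param epochs an \code{\link{EpochArray}}.
#' @param threshold_uv rejection threshold in microvolts (default 200).
#' @return the \code{\link{EpochArray}} with updated kept/reason metadata.
#' @export
rejectArtifacts <- function(epochs, threshold_uv = 200) {
  stopifnot(threshold_uv > 0)
  info <- epochs@info
  if (nrow(info) == 0) return(epochs)
  mx <- apply(abs(epochs@data), 1, max)
  bad <- mx > threshold_uv & info$kept
  info$kept[bad] <- FALSE
  info$reason[bad] <- "amplitude_artifact"
  newEpochArray(epochs@data, epochs@times, epochs@samplingRate, epochs@lock,
                epochs@channels, info)
}

#' Median baseline correction
#'
#' Per trial and channel, subtracts the median voltage in a pre-lock window
#' (default \code{[-0.400, -0.150]} s). The median is robust to residual
#' outliers in the baseline window.
#'
#' @param epochs an \code{\link{EpochArray}}.
#' @param window baseline window \code{c(t0, t1)} in seconds relative to the
#'   lock; must lie inside the epoch.
#' @return baseline-corrected \code{\link{EpochArray}}.
#' @export
baselineCorrect <- function(epochs, window = c(-0.400, -0.150)) {
  tt <- epochTimes(epochs)
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("baseline window lies outside the epoch")
  dat <- epochs@data
  if (dim(dat)[1] > 0) {
    base <- apply(dat[, , sel, drop = FALSE], c(1, 2), stats::median)
    dat <- dat - array(rep(base, dim(dat)[3]), dim(dat))
  }
  newEpochArray(dat, tt, epochs@samplingRate, epochs@lock, epochs@channels,
                epochs@info)
}

#' Run the full preprocessing chain on a recording
#'
#' Fixed stage order: repair bad channels, resample, common-average
#' reference, band-pass (and optional notch) filtering, epoching around both
#' locks, amplitude rejection, median baseline. The change-locked epochs are
#' restricted to the longest change-time condition by default.
#'
#' @param rec raw \code{\link{EEGRecording}}.
#' @param bad_labels channels to repair before anything else.
#' @param target_rate analysis rate (Hz).
#' @param hp_cutoff,lp_cutoff band-pass corners (Hz).
#' @param notch apply the 50 Hz notch.
#' @param reject_uv rejection threshold (microvolts).
#' @param pre_s,post_s epoch window around each lock (seconds).
#' @param baseline_window pre-lock median baseline window (seconds).
#' @param change_condition change times kept for the change-locked epochs
#'   (default 3 s).
#' @return list with elements \code{onset} and \code{change}
#'   (\code{\link{EpochArray}}s) and \code{recording} (the cleaned
#'   continuous recording).
#' @export
preprocessRecording <- function(rec, bad_labels = character(0),
                                target_rate = 128, hp_cutoff = 0.3,
                                lp_cutoff = 30, notch = FALSE,
                                reject_uv = 200, pre_s = 0.5, post_s = 1.5,
                                baseline_window = c(-0.400, -0.150),
                                change_condition = 3) {
  rec <- repairBadChannels(rec, bad_labels)
  rec <- resampleTo(rec, target_rate)
  rec <- rereferenceCommonAverage(rec)
  rec <- bandpassFilter(rec, hp_cutoff, lp_cutoff)
  if (notch) rec <- notchFilter(rec)
  onset <- baselineCorrect(
    rejectArtifacts(extractEpochs(rec, "onset", pre_s, post_s), reject_uv),
    baseline_window)
  change <- baselineCorrect(
    rejectArtifacts(extractEpochs(rec, "change", pre_s, post_s,
                                  change_times = change_condition), reject_uv),
    baseline_window)
  list(onset = onset, change = change, recording = rec)
}
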