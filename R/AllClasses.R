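#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib auditoryPCI, .registration = TRUE
NULL

#' Continuous multichannel EEG recording
#'
#' A channels-by-samples voltage trace (microvolts) with its sampling rate,
#' a montage table (channel labels and 2-D scalp positions) and an event
#' table describing the auditory trials (one row per trial; columns
#' \code{trial_id}, \code{condition}, \code{onset_s}, \code{change_s},
#' \code{duration_s}, \code{stage_ok}).
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channels data.frame with columns \code{label}, \code{x}, \code{y}.
#' @slot events data.frame of trial events.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channels = "data.frame",
    events = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (!all(c("label", "x", "y") %in% names(object@channels))) {
    msg <- c(msg, "channels needs columns label, x, y")
  } else {
    if (anyDuplicated(object@channels$label)) {
      msg <- c(msg, "channel labels must be unique")
    }
    if (nrow(object@channels) != nrow(object@data)) {
      msg <- c(msg, "nrow(channels) must equal nrow(data)")
    }
  }
  if (nrow(object@data) > 0 && !all(is.finite(object@data))) {
    msg <- c(msg, "data must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched EEG data
#'
#' Trials x channels x samples array sharing one time axis relative to a lock
#' event (stimulus onset or statistics change). Epoch windows are half-open
#' \code{[-pre, +post)}; time 0 is the lock sample. Per-trial metadata records
#' the condition, change time, and a kept/rejected flag with a reason.
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot times numeric vector of sample times in seconds relative to the lock.
#' @slot samplingRate sampling rate in Hz.
#' @slot lock \code{"onset"} or \code{"change"}.
#' @slot channels montage data.frame (label, x, y).
#' @slot info per-trial data.frame with at least \code{trial_id},
#'   \code{condition}, \code{kept}, \code{reason}.
#'
#' @exportClass EpochArray
setClass("EpochArray",
  representation(
    data = "array",
    times = "numeric",
    samplingRate = "numeric",
    lock = "character",
    channels = "data.frame",
    info = "data.frame"
  )
)

setValidity("EpochArray", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be a 3-d array")
  if (length(d) == 3) {
    if (d[3] != length(object@times)) {
      msg <- c(msg, "length(times) must equal dim(data)[3]")
    }
    if (d[2] != nrow(object@channels)) {
      msg <- c(msg, "nrow(channels) must equal dim(data)[2]")
    }
    if (d[1] != nrow(object@info)) {
      msg <- c(msg, "nrow(info) must equal dim(data)[1]")
    }
  }
  if (length(object@times) > 1 && any(diff(object@times) <= 0)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (!object@lock %in% c("onset", "change")) {
    msg <- c(msg, "lock must be 'onset' or 'change'")
  }
  if (nrow(object@info) > 0) {
    need <- c("trial_id", "condition", "kept", "reason")
    if (!all(need %in% names(object@info))) {
      msg <- c(msg, "info needs columns trial_id, condition, kept, reason")
    } else if (any(!object@info$kept & !nzchar(object@info$reason))) {
      msg <- c(msg, "rejected trials must carry a reason")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Auditory perturbational complexity index score
#'
#' The normalized Lempel-Ziv complexity of the Hilbert-binarized evoked EEG:
#' \code{value = c(S) * log2(L) / (L * H(S))}, where \code{c(S)} is the
#' exhaustive-history LZ76 word count of the flattened binary sequence S,
#' \code{L} its length and \code{H(S)} the binary Shannon entropy of the
#' proportion of ones. A score is undefined (value NA, \code{defined} FALSE)
#' when H(S) = 0.
#'
#' @slot value the normalized complexity (unitless, NA when undefined).
#' @slot wordCount LZ76 word count c(S).
#' @slot length L, length of the flattened sequence.
#' @slot p1 empirical probability of a 1.
#' @slot entropy H(S) in bits.
#' @slot defined logical; FALSE when H(S) = 0.
#' @slot lock lock event of the analysis window.
#' @slot window numeric window \code{c(t0, t1)} in seconds relative to lock.
#' @slot channelSet channel labels used.
#' @slot nTrials number of kept trials that entered the sequence.
#'
#' @exportClass PCIaScore
setClass("PCIaScore",
  representation(
    value = "numeric",
    wordCount = "integer",
    length = "integer",
    p1 = "numeric",
    entropy = "numeric",
    defined = "logical",
    lock = "character",
    window = "numeric",
    channelSet = "character",
    nTrials = "integer"
  )
)

setValidity("PCIaScore", function(object) {
  msg <- character(0)
  if (object@length < 1) msg <- c(msg, "length must be >= 1")
  if (object@wordCount < 1) msg <- c(msg, "word count must be >= 1")
  if (!is.na(object@p1) && (object@p1 < 0 || object@p1 > 1)) {
    msg <- c(msg, "p1 must lie in [0, 1]")
  }
  if (object@defined && (!is.finite(object@value) || object@value < 0)) {
    msg <- c(msg, "a defined score must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat(sprintf("  events: %d trials (%d change, %d sham)\n",
              nrow(object@events),
              sum(object@events$condition == "change"),
              sum(object@events$condition == "sham")))
  invisible(object)
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochArray (lock = %s): %d trials x %d channels x %d samples @ %g Hz\n",
              object@lock, d[1], d[2], d[3], object@samplingRate))
  cat(sprintf("  time: [%.3f, %.3f] s; kept: %d / %d\n",
              min(object@times), max(object@times),
              sum(object@info$kept), d[1]))
  invisible(object)
})

setMethod("show", "PCIaScore", function(object) {
  if (object@defined) {
    cat(sprintf("PCIaScore: %.4f (c = %d, L = %d, p1 = %.3f, H = %.3f bits)\n",
                object@value, object@wordCount, object@length,
                object@p1, object@entropy))
  } else {
    cat("PCIaScore: undefined (H(S) = 0)\n")
  }
  cat(sprintf("  lock = %s, window = [%g, %g] s, %d channels, %d trials\n",
              object@lock, object@window[1], object@window[2],
              length(object@channelSet), object@nTrials))
  invisible(object)
})

# ---- accessors ----

#' Accessors for EEG containers
#'
#' @param object an \code{EEGRecording} or \code{EpochArray}.
#' @return \code{channelLabels} returns the character vector of channel
#'   labels; \code{samplingRate} the sampling rate in Hz; \code{eegData} the
#'   underlying numeric matrix/array; \code{recordingEvents} the event table;
#'   \code{epochTimes} the time axis; \code{epochInfo} the per-trial metadata;
#'   \code{keptIndex} the indices of kept (non-rejected) trials;
#'   \code{pciaValue} the numeric value of a \code{PCIaScore}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("recordingEvents", function(object) standardGeneric("recordingEvents"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("epochInfo", function(object) standardGeneric("epochInfo"))
#' @rdname accessors
#' @export
setGeneric("keptIndex", function(object) standardGeneric("keptIndex"))
#' @rdname accessors
#' @export
setGeneric("pciaValue", function(object) standardGeneric("pciaValue"))

#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(object) object@channels$label)
#' @rdname accessors
setMethod("channelLabels", "EpochArray", function(object) object@channels$label)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "EpochArray", function(object) object@samplingRate)
#' @rdname accessors
setMethod("eegData", "EEGRecording", function(object) object@data)
#' @rdname accessors
setMethod("eegData", "EpochArray", function(object) object@data)
#' @rdname accessors
setMethod("recordingEvents", "EEGRecording", function(object) object@events)
#' @rdname accessors
setMethod("epochTimes", "EpochArray", function(object) object@times)
#' @rdname accessors
setMethod("epochInfo", "EpochArray", function(object) object@info)
#' @rdname accessors
setMethod("keptIndex", "EpochArray", function(object) which(object@info$kept))
#' @rdname accessors
setMethod("pciaValue", "PCIaScore", function(object) object@value)

# internal constructors

newRecording <- function(data, samplingRate, channels, events) {
  new("EEGRecording", data = data, samplingRate = samplingRate,
      channels = channels, events = events)
}

newEpochArray <- function(data, times, samplingRate, lock, channels, info) {
  new("EpochArray", data = data, times = times, samplingRate = samplingRate,
      lock = lock, channels = channels, info = info)
}
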