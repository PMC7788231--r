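# shared builders for small in-memory fixtures

emptyEvents <- function() {
  data.frame(trial_id = integer(0), condition = character(0),
             onset_s = numeric(0), change_s = numeric(0))
}

# continuous recording from a channels x samples matrix
toyRecording <- function(dat, fs = 128, labels = NULL, events = emptyEvents()) {
  if (is.null(labels)) labels <- c("Cz", "Pz", "FCz", "CPz")[seq_len(nrow(dat))]
  new("EEGRecording", data = dat, samplingRate = fs,
      channels = buildMontage(labels = labels), events = events)
}

# epochs built directly from an array (trials x channels x samples)
toyEpochs <- function(arr, fs = 128, pre = 0.5, lock = "onset",
                      labels = NULL, condition = "change",
                      change_time = 3) {
  d <- dim(arr)
  if (is.null(labels)) {
    labels <- buildMontage()$label[seq_len(d[2])]
  }
  times <- (seq_len(d[3]) - 1 - round(pre * fs)) / fs
  info <- data.frame(trial_id = seq_len(d[1]),
                     condition = rep_len(condition, d[1]),
                     change_time = change_time,
                     kept = TRUE, reason = "", stringsAsFactors = FALSE)
  new("EpochArray", data = arr, times = times, samplingRate = fs,
      lock = lock, channels = buildMontage(labels = labels), info = info)
}

# gaussian-noise epochs, optionally with a signal added to given channels in
# a post-lock window
noiseEpochs <- function(nTrials, labels, fs = 128, pre = 0.5, post = 1.5,
                        sd = 1, seed = 1, signal = 0,
                        signalChannels = character(0),
                        signalWindow = c(0, 0.3)) {
  set.seed(seed)
  nSamp <- round((pre + post) * fs)
  arr <- array(rnorm(nTrials * length(labels) * nSamp, sd = sd),
               c(nTrials, length(labels), nSamp))
  if (signal != 0 && length(signalChannels)) {
    times <- (seq_len(nSamp) - 1 - round(pre * fs)) / fs
    sIdx <- which(times >= signalWindow[1] & times < signalWindow[2])
    cIdx <- match(signalChannels, labels)
    arr[, cIdx, sIdx] <- arr[, cIdx, sIdx] + signal
  }
  toyEpochs(arr, fs = fs, pre = pre, labels = labels)
}
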