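# Per-subject ERP features: trial- and channel-averaged waveforms, P2 peak
# amplitude/latency (largest interior local maximum), centro-parietal
# positivity area under the curve, and fixed-window peak potentials.

#' Average ERP over kept trials and a channel set
#'
#' Mean over kept trials, then over the listed channels.
#'
#' @param epochs an \code{\link{EpochArray}}.
#' @param labels channel labels to average.
#' @return list with \code{erp} (microvolts), \code{times} (seconds),
#'   \code{nTrials}; NULL (with a warning) when no kept trials remain.
#' @export
averageErp <- function(epochs, labels) {
  chIdx <- match(labels, channelLabels(epochs))
  if (anyNA(chIdx)) {
    stop("channel(s) not present: ",
         paste(labels[is.na(chIdx)], collapse = ", "))
  }
  keep <- keptIndex(epochs)
  if (length(keep) == 0) {
    warning("no kept trials; ERP feature missing")
    return(NULL)
  }
  dat <- epochs@data[keep, chIdx, , drop = FALSE]
  erp <- apply(dat, 3, mean)
  list(erp = erp, times = epochTimes(epochs), nTrials = length(keep))
}

#' Measure the P2 peak
#'
#' Amplitude and latency of the largest interior local maximum of the ERP
#' within the search window (default 0.10-0.35 s). A local maximum is a
#' sample strictly greater than both neighbours; plateaus take their first
#' sample. If the window contains no interior local maximum, the window
#' maximum is returned and flagged \code{no_local_max}.
#'
#' @param erp list from \code{\link{averageErp}} (or any list with \code{erp}
#'   and \code{times}).
#' @param window search window \code{c(t0, t1)} in seconds.
#' @return list: \code{amplitude} (microvolts), \code{latency} (seconds),
#'   \code{flag} (\code{""} or \code{"no_local_max"}).
#' @export
measureP2 <- function(erp, window = c(0.10, 0.35)) {
  sel <- which(erp$times >= window[1] & erp$times <= window[2])
  if (length(sel) < 3) stop("P2 window must contain at least 3 samples")
  x <- erp$erp[sel]
  n <- length(x)
  interior <- 2:(n - 1)
  # strict local maxima, plus the first sample of an interior plateau
  locs <- interior[x[interior] > x[interior - 1] & x[interior] > x[interior + 1]]
  plateau <- interior[x[interior] > x[interior - 1] & x[interior] == x[interior + 1]]
  locs <- sort(unique(c(locs, plateau)))
  if (length(locs)) {
    best <- locs[which.max(x[locs])]
    list(amplitude = x[best], latency = erp$times[sel][best], flag = "")
  } else {
    best <- which.max(x)
    list(amplitude = x[best], latency = erp$times[sel][best],
         flag = "no_local_max")
  }
}

#' Centro-parietal positivity area under the curve
#'
#' Trapezoidal integral of the change-locked ERP over the window (default
#' 0.2-1.0 s after the change), in microvolt-seconds. The normalized mode
#' divides by the window length (mean potential, microvolts).
#'
#' @param erp list from \code{\link{averageErp}}.
#' @param window integration window \code{c(t0, t1)} seconds.
#' @param mode \code{"integral"} (microvolt-seconds, default) or
#'   \code{"normalized"} (divided by the integrated time).
#' @return list: \code{auc}, \code{mode}, \code{window}.
#' @export
measureCppAuc <- function(erp, window = c(0.2, 1.0),
                          mode = c("integral", "normalized")) {
  mode <- match.arg(mode)
  tt <- erp$times
  if (window[1] < min(tt) || window[2] > max(tt)) {
    stop("AUC window lies outside the epoch")
  }
  sel <- which(tt >= window[1] & tt <= window[2])
  x <- erp$erp[sel]
  ts <- tt[sel]
  auc <- sum(diff(ts) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
  if (mode == "normalized") auc <- auc / (ts[length(ts)] - ts[1])
  list(auc = auc, mode = mode, window = window)
}

#' Maximum potential within a fixed window
#'
#' Plain window maximum (closed window); used for the fixed-interval peak
#' potentials entering the CRS-R correlations (onset 0.2-0.3 s, change
#' 0.6-0.8 s).
#'
#' @param erp list from \code{\link{averageErp}}.
#' @param window window \code{c(t0, t1)} seconds.
#' @return peak potential in microvolts.
#' @export
measureWindowPeak <- function(erp, window) {
  tt <- erp$times
  if (window[1] < min(tt) || window[2] > max(tt)) {
    stop("window lies outside the epoch")
  }
  max(erp$erp[tt >= window[1] & tt <= window[2]])
}
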