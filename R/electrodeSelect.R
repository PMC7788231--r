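# Per-subject electrode selection: a paired pre- vs peri-stimulus contrast
# over a 0.3 s window, assessed with a nonparametric cluster-based
# permutation test over channels x time, followed by the 3-electrode
# selection rules (fixed FCz/FC1/FC2 for non-patients, lowest cluster
# p-values for patients).

#' Paired pre/peri-stimulus statistic map
#'
#' For every kept trial, subtracts the time-matched pre-stimulus sample from
#' the corresponding peri-stimulus sample (equal-length windows, default
#' 0.3 s each) and computes a paired t-statistic across trials per channel
#' and post-window time bin.
#'
#' @param epochs onset-locked \code{\link{EpochArray}}.
#' @param pre_window,post_window windows \code{c(t0, t1)} in seconds relative
#'   to the lock; must contain equally many samples.
#' @param channels channel labels to test (default: the 15-electrode central
#'   candidate set present in the montage).
#' @return list with \code{tmap} (channels x time matrix of t-statistics),
#'   \code{diffs} (trials x (channels*time) paired differences),
#'   \code{postMean} (channels x time mean peri-stimulus potential),
#'   \code{channels}, \code{times}, \code{nTrials}.
#' @export
pairedPrePostStat <- function(epochs, pre_window = c(-0.3, 0),
                              post_window = c(0, 0.3),
                              channels = centralCandidateSet()) {
  tt <- epochTimes(epochs)
  fs <- samplingRate(epochs)
  preIdx <- which(tt >= pre_window[1] & tt < pre_window[2])
  postIdx <- which(tt >= post_window[1] & tt < post_window[2])
  if (abs(diff(c(pre_window[2], pre_window[1])) -
            diff(c(post_window[2], post_window[1]))) > 1e-9) {
    stop("pre and post windows must have equal length")
  }
  # sample-grid rounding can make the two half-open windows differ by one
  # bin; trim at the edges farthest from the lock
  nWin <- min(length(preIdx), length(postIdx))
  if (nWin == 0) stop("windows lie outside the epoch")
  preIdx <- utils::tail(preIdx, nWin)
  postIdx <- utils::head(postIdx, nWin)
  chIdx <- match(intersect(channels, channelLabels(epochs)),
                 channelLabels(epochs))
  if (!length(chIdx)) stop("no requested channels present")
  keep <- keptIndex(epochs)
  if (length(keep) < 2) stop("need >= 2 kept trials for a paired statistic")
  dat <- epochs@data[keep, chIdx, , drop = FALSE]
  post <- dat[, , postIdx, drop = FALSE]
  pre <- dat[, , preIdx, drop = FALSE]
  d <- post - pre                                    # trials x ch x time
  n <- dim(d)[1]
  dm <- matrix(d, nrow = n)                          # trials x (ch*time)
  mu <- colMeans(dm)
  sdv <- sqrt((colSums(dm^2) - n * mu^2) / (n - 1))
  tv <- mu / (sdv / sqrt(n))
  tv[sdv == 0] <- 0
  nch <- length(chIdx)
  ntime <- length(postIdx)
  list(tmap = matrix(tv, nch, ntime),
       diffs = dm,
       postMean = matrix(colMeans(matrix(post, nrow = n)), nch, ntime),
       channels = channelLabels(epochs)[chIdx],
       times = tt[postIdx],
       nTrials = n)
}

# connected components over suprathreshold (channel, time) cells; cells are
# connected through channel adjacency at the same time bin and through
# adjacent time bins on the same channel
.clusterMass <- function(tmat, tcrit, adjIdx) {
  nch <- nrow(tmat)
  nt <- ncol(tmat)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- (sgn * tmat) > tcrit
    if (!any(supra)) next
    labelMat <- matrix(0L, nch, nt)
    nextLab <- 0L
    cells <- which(supra, arr.ind = TRUE)
    for (r in seq_len(nrow(cells))) {
      ch <- cells[r, 1]; tb <- cells[r, 2]
      if (labelMat[ch, tb] != 0L) next
      nextLab <- nextLab + 1L
      queue <- list(c(ch, tb))
      labelMat[ch, tb] <- nextLab
      members <- matrix(c(ch, tb), 1)
      while (length(queue)) {
        cell <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        cc <- cell[1]; ct <- cell[2]
        cand <- rbind(
          if (ct > 1) c(cc, ct - 1),
          if (ct < nt) c(cc, ct + 1),
          if (length(adjIdx[[cc]])) cbind(adjIdx[[cc]], ct)
        )
        if (is.null(cand)) next
        for (q in seq_len(nrow(cand))) {
          a <- cand[q, 1]; b <- cand[q, 2]
          if (supra[a, b] && labelMat[a, b] == 0L) {
            labelMat[a, b] <- nextLab
            queue[[length(queue) + 1]] <- c(a, b)
            members <- rbind(members, c(a, b))
          }
        }
      }
      out[[length(out) + 1]] <- list(
        sign = sgn,
        members = members,
        mass = sum(tmat[members])
      )
    }
  }
  out
}

#' Cluster-based permutation test of the pre/peri contrast
#'
#' Forms clusters by thresholding the paired t-map at the two-sided
#' \code{cluster_alpha} quantile of the t distribution, connected through
#' channel adjacency and temporal contiguity; the cluster statistic is the
#' summed t. The null distribution is built from random per-trial exchanges
#' of the pre and post windows (sign flips of the paired difference); each
#' cluster's p-value is \code{(1 + #(null max |mass| >= |mass|)) / (1 +
#' n_perm)}.
#'
#' @param prepost output of \code{\link{pairedPrePostStat}}.
#' @param adjacency channel neighbourhood list (\code{\link{channelAdjacency}}).
#' @param n_perm number of random sign-flip permutations (>= 100).
#' @param cluster_alpha per-sample two-sided cluster-forming alpha.
#' @param seed integer seed for the permutation draws.
#' @return list of class \code{ClusterResult}: \code{clusters} (each with
#'   sign, member channel/time indices, mass, p), \code{tmap},
#'   \code{channels}, \code{times}, \code{electrode_p} (per-channel smallest
#'   positive-cluster p, 1 when in none), \code{postMean}, \code{n_perm}.
#' @export
clusterPermutationTest <- function(prepost, adjacency, n_perm = 1000,
                                   cluster_alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 100)
  if (!length(prepost$channels)) stop("empty candidate channel set")
  n <- prepost$nTrials
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  adjIdx <- lapply(prepost$channels, function(ch) {
    match(intersect(adjacency[[ch]], prepost$channels), prepost$channels)
  })
  obs <- .clusterMass(prepost$tmap, tcrit, adjIdx)
  nullMax <- numeric(n_perm)
  if (length(obs)) {
    D <- prepost$diffs
    ss <- colSums(D^2)
    .withSeed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      sums <- signs %*% D
      for (p in seq_len(n_perm)) {
        mu <- sums[p, ] / n
        sdv <- sqrt(pmax(ss - n * mu^2, 0) / (n - 1))
        tv <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
        tm <- matrix(tv, nrow(prepost$tmap), ncol(prepost$tmap))
        cl <- .clusterMass(tm, tcrit, adjIdx)
        nullMax[p] <- if (length(cl)) {
          max(vapply(cl, function(x) abs(x$mass), 0))
        } else 0
      }
    })
    for (i in seq_along(obs)) {
      obs[[i]]$p <- (1 + sum(nullMax >= abs(obs[[i]]$mass))) / (1 + n_perm)
    }
  }
  ep <- rep(1, length(prepost$channels))
  for (cl in obs) {
    if (cl$sign > 0) {
      chs <- unique(cl$members[, 1])
      ep[chs] <- pmin(ep[chs], cl$p)
    }
  }
  structure(list(clusters = obs, tmap = prepost$tmap,
                 channels = prepost$channels, times = prepost$times,
                 electrode_p = stats::setNames(ep, prepost$channels),
                 postMean = prepost$postMean, n_perm = n_perm),
            class = "ClusterResult")
}

#' Select the three P2 analysis electrodes
#'
#' Non-patients use the fixed consistently-significant set (FCz, FC1, FC2).
#' Patients use the three electrodes with the lowest positive-cluster
#' p-values from the central candidate set, whether or not they reach
#' significance; ties are broken by the larger mean peri-stimulus potential,
#' then by label order.
#'
#' @param cluster_result a \code{ClusterResult} from
#'   \code{\link{clusterPermutationTest}} (its candidate set must cover the
#'   central electrodes).
#' @param subject_kind \code{"control"} or \code{"patient"}.
#' @return list of class \code{ElectrodeSelection}: \code{labels} (3),
#'   \code{p_values} (per candidate electrode), \code{rule}.
#' @export
selectElectrodes <- function(cluster_result, subject_kind = c("control", "patient")) {
  subject_kind <- match.arg(subject_kind)
  cand <- centralCandidateSet()
  missing <- setdiff(cand, cluster_result$channels)
  if (length(missing)) {
    stop("candidate electrodes missing from the tested set: ",
         paste(missing, collapse = ", "))
  }
  pvals <- cluster_result$electrode_p[cand]
  if (subject_kind == "control") {
    labels <- controlP2Set()
    rule <- "common_control_set"
  } else {
    meanPeri <- rowMeans(cluster_result$postMean)[match(cand, cluster_result$channels)]
    ord <- order(pvals, -meanPeri, cand)
    labels <- cand[ord][1:3]
    rule <- "lowest_p_patient"
  }
  structure(list(labels = labels, p_values = pvals, rule = rule),
            class = "ElectrodeSelection")
}
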