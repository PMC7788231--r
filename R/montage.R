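# 64-channel 10-20 montage (BioSemi-style label set) on a schematic 2-D grid.
# Positions are a flattened scalp layout: y runs front (+) to back (-), x left
# (-) to right (+), with 0.2 spacing between neighbouring rows/columns. The
# layout is only used to build the channel neighbourhood graph (cluster
# permutation adjacency, bad-channel repair), not for source modelling.

.montageRows <- list(
  Fp = 0.8, AF = 0.6, F = 0.4, FT = 0.2, FC = 0.2, C = 0.0, TP = -0.2,
  CP = -0.2, P = -0.4, PO = -0.6, O = -0.8, I = -1.0
)

.montage64 <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  pos <- t(vapply(labels, .labelPosition, numeric(2)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}

.labelPosition <- function(label) {
  # T7/T8 sit on the C row at full lateral extent
  if (label %in% c("T7", "T8")) {
    return(c(ifelse(label == "T7", -0.8, 0.8), .montageRows$C))
  }
  m <- regmatches(label, regexec("^([A-Za-z]+)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3) stop("unrecognized channel label: ", label)
  row <- m[2]
  if (!row %in% names(.montageRows)) stop("unrecognized channel label: ", label)
  y <- .montageRows[[row]]
  if (m[3] == "z") return(c(0, y))
  n <- as.integer(m[3])
  x <- 0.2 * ceiling(n / 2) * ifelse(n %% 2 == 1, -1, 1)
  c(x, y)
}

#' Build the EEG channel montage
#'
#' Returns the 64-channel 10-20 montage used throughout the package: channel
#' labels plus schematic 2-D scalp positions suitable for computing the
#' channel neighbourhood graph. The label set contains the 15-electrode
#' central candidate set used for electrode selection and the parietal set
#' (Pz, POz, P1, P2) used for the change-locked response.
#'
#' @param n_channels number of channels; only the full 64-channel montage is
#'   defined.
#' @param labels optional character vector to restrict the montage to a known
#'   subset of labels (used for reduced-channel simulations). Unknown labels
#'   raise an error.
#' @return data.frame with columns \code{label}, \code{x}, \code{y}.
#' @examples
#' mont <- buildMontage()
#' head(mont)
#' @export
buildMontage <- function(n_channels = 64, labels = NULL) {
  full <- .montage64()
  if (!is.null(labels)) {
    unknown <- setdiff(labels, full$label)
    if (length(unknown)) {
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
    }
    out <- full[match(labels, full$label), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (n_channels != 64) {
    stop("only the 64-channel montage is defined; use `labels` for subsets")
  }
  full
}

#' Channel neighbourhood graph from scalp positions
#'
#' Two channels are neighbours when their planar distance is at most
#' \code{radius}. With the default grid spacing (0.2) and radius (0.3) each
#' interior channel has 8 neighbours (rook + diagonal moves).
#'
#' @param montage montage data.frame from \code{\link{buildMontage}}.
#' @param radius neighbourhood radius in montage units.
#' @return named list mapping each label to the character vector of its
#'   neighbours.
#' @export
channelAdjacency <- function(montage, radius = 0.3) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  nb <- lapply(seq_len(nrow(montage)), function(i) {
    montage$label[d[i, ] <= radius & seq_len(nrow(montage)) != i]
  })
  names(nb) <- montage$label
  nb
}

#' Fixed channel sets of the paradigm
#'
#' \code{centralCandidateSet} is the 15-electrode fronto-central/centro-parietal
#' candidate set searched during per-subject electrode selection.
#' \code{controlP2Set} is the fixed 3-electrode set (FCz, FC1, FC2) used for
#' the P2 of non-patient groups. \code{parietalErpSet} is the parietal set
#' (Pz, POz, P1, P2) for the change-locked centro-parietal positivity.
#' \code{pciaChannelSet} returns the default 14-channel cluster used for the
#' complexity analysis around stimulus onset or statistics change; the exact
#' membership is a package default (configurable everywhere it is used).
#'
#' @return character vector of channel labels.
#' @export
centralCandidateSet <- function() {
  c("FC1", "FCz", "FC2", "FC3", "FC4", "C4", "C2", "Cz", "C1", "C3",
    "CP3", "CP1", "CPz", "CP4", "CP2")
}

#' @rdname centralCandidateSet
#' @export
controlP2Set <- function() c("FCz", "FC1", "FC2")

#' @rdname centralCandidateSet
#' @export
parietalErpSet <- function() c("Pz", "POz", "P1", "P2")

#' @rdname centralCandidateSet
#' @param lock \code{"onset"} or \code{"change"}.
#' @export
pciaChannelSet <- function(lock = c("onset", "change")) {
  lock <- match.arg(lock)
  if (lock == "onset") {
    setdiff(centralCandidateSet(), "Cz")
  } else {
    c("CP3", "CP1", "CPz", "CP2", "CP4", "P3", "P1", "Pz", "P2", "P4",
      "PO3", "POz", "PO4", "Oz")
  }
}
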