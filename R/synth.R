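# Synthetic multi-subject EEG generator. Emulates the auditory-texture
# change-detection paradigm: every trial is a texture with a sound onset; on
# change trials the texture statistics change at 0.75, 1.6 or 3 s and the
# sound continues for 2 s after the change; sham trials of matched length
# never change. Group profiles control the injected evoked components
# (fronto-central P2 at onset, centro-parietal positivity after change), the
# background regime (desynchronized broadband vs high-amplitude slow
# stereotyped activity) and the artifact rate.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483629)
}

#' Paradigm specification
#'
#' Trial structure of the auditory-texture change paradigm: change times,
#' post-change sound duration, inter-stimulus-interval range, trial counts and
#' sampling rate.
#'
#' @param change_times change times in seconds (default 0.75, 1.6, 3).
#' @param post_change_duration seconds of sound after the change (default 2).
#' @param isi_range inter-stimulus silence range \code{c(low, high)} seconds.
#' @param n_change_trials_per_time change trials per change time.
#' @param n_sham_trials total sham (no-change) trials.
#' @param sham_times nominal lengths used for sham trials; defaults to
#'   \code{change_times} (controls); the patient preset uses only 3 s.
#' @param sampling_rate acquisition rate in Hz (default 1024).
#' @param stimulus_level_note free-text note (the acoustics are not simulated).
#' @return a \code{ParadigmSpec} list.
#' @examples
#' paradigmPreset("patient")   # 80 x 4 stimuli: 240 change + 80 sham
#' @export
paradigmSpec <- function(change_times = c(0.75, 1.6, 3),
                         post_change_duration = 2,
                         isi_range = c(1, 2),
                         n_change_trials_per_time = 80,
                         n_sham_trials = 80,
                         sham_times = change_times,
                         sampling_rate = 1024,
                         stimulus_level_note = "70 dB SPL (not simulated)") {
  stopifnot(length(isi_range) == 2, isi_range[1] >= 0,
            isi_range[1] <= isi_range[2],
            n_change_trials_per_time >= 0, n_sham_trials >= 0,
            sampling_rate > 0, all(change_times > 0),
            post_change_duration > 0)
  structure(list(change_times = change_times,
                 post_change_duration = post_change_duration,
                 isi_range = isi_range,
                 n_change_trials_per_time = n_change_trials_per_time,
                 n_sham_trials = n_sham_trials,
                 sham_times = sham_times,
                 sampling_rate = sampling_rate,
                 stimulus_level_note = stimulus_level_note),
            class = "ParadigmSpec")
}

#' @rdname paradigmSpec
#' @param kind \code{"patient"} (320 stimuli: 80 per change time + 80 sham,
#'   sham length 3 s), \code{"control_passive"} (240 trials: 40 per change and
#'   no-change condition) or \code{"control_active"} (480 stimuli: 80 per
#'   condition).
#' @param ... overrides passed on to \code{paradigmSpec}.
#' @export
paradigmPreset <- function(kind = c("patient", "control_passive", "control_active"),
                           ...) {
  kind <- match.arg(kind)
  args <- switch(kind,
    patient = list(n_change_trials_per_time = 80, n_sham_trials = 80,
                   sham_times = 3),
    control_passive = list(n_change_trials_per_time = 40, n_sham_trials = 120),
    control_active = list(n_change_trials_per_time = 80, n_sham_trials = 240))
  do.call(paradigmSpec, utils::modifyList(args, list(...)))
}

#' Group profile for the synthetic generator
#'
#' Parameterizes the group-dependent contrasts: mean injected P2 amplitude
#' and latency, mean centro-parietal positivity (CPP) amplitude, background
#' regime, and artifact rate.
#'
#' @param group one of Responding, Passive, AsleepNREM, MCS, UWS.
#' @param p2_amplitude_mean mean P2 amplitude in microvolts (>= 0).
#' @param p2_amplitude_sd trial-to-trial P2 amplitude SD (microvolts).
#' @param p2_latency P2 latency in seconds after sound onset.
#' @param cpp_amplitude_mean mean CPP peak amplitude in microvolts (>= 0);
#'   0 disables the component.
#' @param background_mode \code{"broadband"} (desynchronized 1/f noise) or
#'   \code{"slow_stereotyped"} (high-amplitude 0.5-4 Hz oscillation shared
#'   across channels plus attenuated broadband noise).
#' @param slow_osc_amplitude SD of the slow oscillation in microvolts.
#' @param noise_sd SD of the per-channel broadband noise in microvolts.
#' @param artifact_rate expected artifacts per trial (square-pulse excursions
#'   exceeding the +/- 200 microvolt rejection threshold).
#' @return a \code{GroupProfile} list.
#' @export
groupProfile <- function(group,
                         p2_amplitude_mean = 2,
                         p2_amplitude_sd = 0.5,
                         p2_latency = 0.2,
                         cpp_amplitude_mean = 0,
                         background_mode = c("broadband", "slow_stereotyped"),
                         slow_osc_amplitude = 0,
                         noise_sd = 10,
                         artifact_rate = 0) {
  background_mode <- match.arg(background_mode)
  vals <- c(p2_amplitude_mean, p2_amplitude_sd, p2_latency,
            cpp_amplitude_mean, slow_osc_amplitude, noise_sd, artifact_rate)
  if (!all(is.finite(vals))) stop("profile parameters must be finite")
  stopifnot(p2_amplitude_mean >= 0, cpp_amplitude_mean >= 0,
            artifact_rate >= 0, noise_sd >= 0, slow_osc_amplitude >= 0)
  structure(list(group = group, p2_amplitude_mean = p2_amplitude_mean,
                 p2_amplitude_sd = p2_amplitude_sd, p2_latency = p2_latency,
                 cpp_amplitude_mean = cpp_amplitude_mean,
                 background_mode = background_mode,
                 slow_osc_amplitude = slow_osc_amplitude,
                 noise_sd = noise_sd, artifact_rate = artifact_rate),
            class = "GroupProfile")
}

#' Default group profiles
#'
#' The package defaults encode the contrasts the analysis assumes: a ~2
#' microvolt fronto-central P2 in all non-patient groups, strongly attenuated
#' in patients; a parietal CPP only in awake controls (full size when
#' responding, halved when passive); desynchronized broadband background for
#' the conscious groups and high-amplitude slow stereotyped activity for
#' Asleep-NREM and UWS; artifact rates increasing from controls to UWS.
#'
#' @return named list of \code{GroupProfile}s for the five groups.
#' @export
defaultGroupProfiles <- function() {
  list(
    Responding = groupProfile("Responding", p2_amplitude_mean = 2,
                              cpp_amplitude_mean = 2, background_mode = "broadband",
                              noise_sd = 10, artifact_rate = 0.05),
    Passive = groupProfile("Passive", p2_amplitude_mean = 2,
                           cpp_amplitude_mean = 1, background_mode = "broadband",
                           noise_sd = 10, artifact_rate = 0.05),
    AsleepNREM = groupProfile("AsleepNREM", p2_amplitude_mean = 2,
                              cpp_amplitude_mean = 0,
                              background_mode = "slow_stereotyped",
                              slow_osc_amplitude = 40, noise_sd = 4,
                              artifact_rate = 0.08),
    MCS = groupProfile("MCS", p2_amplitude_mean = 0.6,
                       cpp_amplitude_mean = 0, background_mode = "broadband",
                       noise_sd = 12, artifact_rate = 0.2),
    UWS = groupProfile("UWS", p2_amplitude_mean = 0.4,
                       cpp_amplitude_mean = 0,
                       background_mode = "slow_stereotyped",
                       slow_osc_amplitude = 40, noise_sd = 5,
                       artifact_rate = 0.35)
  )
}

.crsrMax <- c(auditory = 4, visual = 5, motor = 6, oromotor = 3,
              communication = 2, arousal = 3)

#' Subject metadata
#'
#' @param subject_id subject identifier.
#' @param group group label.
#' @param crs_r_subscales named integer vector (auditory, visual, motor,
#'   oromotor, communication, arousal) or NULL for controls.
#' @param diagnosis_at_eeg,latest_diagnosis UWS/MCS/EMCS or NA for controls.
#' @return one-row data.frame (total score is the subscale sum).
#' @export
subjectMeta <- function(subject_id, group, crs_r_subscales = NULL,
                        diagnosis_at_eeg = NA_character_,
                        latest_diagnosis = NA_character_) {
  if (is.null(crs_r_subscales)) {
    sub <- stats::setNames(rep(NA_integer_, 6), names(.crsrMax))
    total <- NA_integer_
  } else {
    stopifnot(all(names(.crsrMax) %in% names(crs_r_subscales)))
    sub <- as.integer(crs_r_subscales[names(.crsrMax)])
    names(sub) <- names(.crsrMax)
    if (any(sub < 0 | sub > .crsrMax)) stop("CRS-R subscale out of range")
    total <- sum(sub)
  }
  out <- data.frame(subject_id = subject_id, group = group,
                    t(sub), crs_r_total = total,
                    diagnosis_at_eeg = diagnosis_at_eeg,
                    latest_diagnosis = latest_diagnosis,
                    stringsAsFactors = FALSE)
  names(out)[3:8] <- paste0("crsr_", names(.crsrMax))
  out
}

# random but clinically plausible subscale draws per group
.sampleSubjectMeta <- function(group, subject_id, seed) {
  .withSeed(seed, {
    if (group %in% c("UWS", "MCS")) {
      if (group == "UWS") {
        sub <- c(auditory = sample(0:1, 1), visual = sample(0:1, 1),
                 motor = sample(0:2, 1), oromotor = sample(0:2, 1),
                 communication = 0L, arousal = sample(0:2, 1))
        dx <- "UWS"
      } else {
        sub <- c(auditory = sample(2:4, 1), visual = sample(2:5, 1),
                 motor = sample(2:6, 1), oromotor = sample(1:3, 1),
                 communication = sample(0:2, 1), arousal = sample(1:3, 1))
        dx <- if (sub["communication"] == 2) "EMCS" else "MCS"
      }
      latest <- if (stats::runif(1) < 0.2) {
        sample(c("UWS", "MCS", "EMCS"), 1)
      } else dx
      subjectMeta(subject_id, group, sub, dx, latest)
    } else {
      subjectMeta(subject_id, group)
    }
  })
}

#' Generate a randomized trial schedule
#'
#' One row per trial, in presentation order, with the sound onset time, the
#' change time (NA for sham trials) and the trial duration. Inter-stimulus
#' intervals are drawn uniformly from the paradigm's ISI range; the trial
#' order is randomized. Reproducible given the seed.
#'
#' @param spec a \code{\link{paradigmSpec}}.
#' @param seed integer seed.
#' @param start_pad silence before the first trial (seconds).
#' @return data.frame with columns \code{trial_id}, \code{condition},
#'   \code{change_time}, \code{duration_s}, \code{onset_s}, \code{change_s},
#'   \code{stage_ok}.
#' @export
generateTrialSchedule <- function(spec, seed, start_pad = 1) {
  stopifnot(inherits(spec, "ParadigmSpec"))
  .withSeed(seed, {
    ct <- rep(spec$change_times, each = spec$n_change_trials_per_time)
    nSham <- spec$n_sham_trials
    shamLen <- if (nSham > 0) {
      rep_len(spec$sham_times, nSham)
    } else numeric(0)
    trials <- data.frame(
      condition = c(rep("change", length(ct)), rep("sham", nSham)),
      change_time = c(ct, rep(NA_real_, nSham)),
      nominal_time = c(ct, shamLen),
      stringsAsFactors = FALSE
    )
    n <- nrow(trials)
    if (n == 0) {
      return(data.frame(trial_id = integer(0), condition = character(0),
                        change_time = numeric(0), duration_s = numeric(0),
                        onset_s = numeric(0), change_s = numeric(0),
                        stage_ok = logical(0)))
    }
    trials <- trials[sample.int(n), , drop = FALSE]
    trials$duration_s <- trials$nominal_time + spec$post_change_duration
    isi <- stats::runif(n, spec$isi_range[1], spec$isi_range[2])
    onset <- start_pad + c(0, cumsum(trials$duration_s[-n] + isi[-n]))
    data.frame(trial_id = seq_len(n), condition = trials$condition,
               change_time = trials$change_time,
               duration_s = trials$duration_s,
               onset_s = onset,
               change_s = onset + trials$change_time,
               stage_ok = TRUE, row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

# FFT-shaped Gaussian noise; computed at a highly composite length >= n
# (mixed-radix FFT stays O(n log n)) and truncated
.shapedNoise <- function(n, fs, shape, sd) {
  if (sd <= 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  a <- shape(f)
  x <- Re(stats::fft(stats::fft(w) * a, inverse = TRUE))[seq_len(n)] / m
  x * sd / stats::sd(x)
}

# 1/f ("pink") noise, flattened below 1 Hz to bound slow drift
.pinkNoise <- function(n, fs, sd) {
  .shapedNoise(n, fs, function(f) {
    a <- 1 / sqrt(pmax(f, 1))
    a[1] <- 0
    a
  }, sd)
}

# narrowband (band Hz) Gaussian noise via FFT masking
.narrowbandNoise <- function(n, fs, band, sd) {
  .shapedNoise(n, fs, function(f) as.numeric(f >= band[1] & f <= band[2]), sd)
}

#' P2 and CPP component waveforms
#'
#' \code{p2Waveform} is a Gaussian bump at the P2 latency. \code{cppWaveform}
#' is the injected centro-parietal positivity: a half-Gaussian ramp rising to
#' its peak 0.65 s after the change, followed by a faster half-Gaussian
#' decay; zero before the change. \code{cppWaveformArea} is the closed-form
#' (Gaussian-integral) area of that waveform over a window, used to validate
#' numerical AUC measures.
#'
#' @param t time in seconds (relative to onset for P2, to change for CPP).
#' @param amplitude peak amplitude, microvolts.
#' @param latency,width P2 peak time and Gaussian SD (seconds).
#' @return waveform values in microvolts.
#' @export
p2Waveform <- function(t, amplitude = 2, latency = 0.2, width = 0.04) {
  amplitude * exp(-(t - latency)^2 / (2 * width^2))
}

#' @rdname p2Waveform
#' @param peak CPP peak time after the change (seconds).
#' @param rise_sd,fall_sd SD of the rising/falling half-Gaussian (seconds).
#' @export
cppWaveform <- function(t, amplitude = 2, peak = 0.65, rise_sd = 0.30,
                        fall_sd = 0.15) {
  s <- ifelse(t <= peak, rise_sd, fall_sd)
  out <- amplitude * exp(-(t - peak)^2 / (2 * s^2))
  out[t < 0] <- 0
  out
}

#' @rdname p2Waveform
#' @param window integration window \code{c(a, b)} in seconds after change.
#' @export
cppWaveformArea <- function(window, amplitude = 2, peak = 0.65,
                            rise_sd = 0.30, fall_sd = 0.15) {
  a <- max(window[1], 0)
  b <- window[2]
  stopifnot(b > a)
  gauss <- function(lo, hi, s) {
    s * sqrt(2 * pi) * (stats::pnorm((hi - peak) / s) - stats::pnorm((lo - peak) / s))
  }
  riseTo <- min(b, peak)
  area <- 0
  if (a < peak) area <- area + gauss(a, riseTo, rise_sd)
  if (b > peak) area <- area + gauss(max(a, peak), b, fall_sd)
  amplitude * area
}

# Gaussian spatial falloff from a seed electrode
.spatialWeights <- function(montage, center, sd = 0.3) {
  i <- match(center, montage$label)
  if (is.na(i)) return(rep(0, nrow(montage)))
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  exp(-d2 / (2 * sd^2))
}

# Evoked components are injected as average-reference topographies: zero
# spatial mean (so the common-average reference leaves them unchanged),
# scaled so the mean weight over the component's measurement electrodes is 1
# - the nominal amplitude is then the amplitude seen at those electrodes.
.componentTopography <- function(montage, center, ref_set, sd = 0.3) {
  w <- .spatialWeights(montage, center, sd)
  if (all(w == 0)) return(w)
  w <- w - mean(w)
  refIdx <- match(intersect(ref_set, montage$label), montage$label)
  ref <- if (length(refIdx)) mean(w[refIdx]) else w[match(center, montage$label)]
  if (!is.finite(ref) || ref <= 0) ref <- max(w)
  w / ref
}

#' Synthesize one subject's continuous EEG recording
#'
#' Builds a continuous recording at the paradigm sampling rate: background
#' activity per the group profile, an injected P2 on fronto-central channels
#' at every sound onset (per-trial amplitude Normal(mean, sd)), an injected
#' CPP on parietal channels after the change (change trials only, when the
#' profile's CPP mean is positive), and square-pulse artifacts of +/-
#' (250-500) microvolts at the profile's rate.
#'
#' @param meta one-row subject metadata (see \code{\link{subjectMeta}}).
#' @param profile a \code{\link{groupProfile}}.
#' @param spec a \code{\link{paradigmSpec}}.
#' @param montage montage data.frame (\code{\link{buildMontage}}).
#' @param seed integer seed; the whole recording is reproducible from it.
#' @return an \code{\link{EEGRecording}}.
#' @export
synthesizeSubject <- function(meta, profile, spec, montage = buildMontage(),
                              seed = 1) {
  stopifnot(inherits(profile, "GroupProfile"), inherits(spec, "ParadigmSpec"))
  sched <- generateTrialSchedule(spec, seed = .deriveSeed(seed, 1))
  fs <- spec$sampling_rate
  endT <- if (nrow(sched)) max(sched$onset_s + sched$duration_s) + 2 else 4
  n <- ceiling(endT * fs)
  nc <- nrow(montage)
  .withSeed(.deriveSeed(seed, 2), {
    dat <- matrix(0, nc, n)
    # background; the slow mode uses a few independent high-amplitude delta
    # (0.5-4 Hz) sources with zero-spatial-mean random loadings, so the
    # stereotyped activity survives the common-average reference
    if (profile$background_mode == "slow_stereotyped") {
      nSrc <- 3
      src <- vapply(seq_len(nSrc),
                    function(i) .narrowbandNoise(n, fs, c(0.5, 4), 1),
                    numeric(n))
      load <- matrix(stats::rnorm(nc * nSrc), nc, nSrc)
      load <- sweep(load, 2, colMeans(load))
      slow <- load %*% t(src)
      rowSd <- sqrt(rowMeans(slow^2))
      rowSd[rowSd == 0] <- 1
      slow <- slow * (profile$slow_osc_amplitude / rowSd)
      for (ch in seq_len(nc)) {
        dat[ch, ] <- slow[ch, ] + .pinkNoise(n, fs, profile$noise_sd)
      }
    } else {
      for (ch in seq_len(nc)) {
        dat[ch, ] <- .pinkNoise(n, fs, profile$noise_sd)
      }
    }
    # evoked components
    wP2 <- .componentTopography(montage, "FCz", controlP2Set())
    wCpp <- .componentTopography(montage, "Pz", parietalErpSet())
    tP2 <- seq(0, 0.5, by = 1 / fs)
    p2base <- p2Waveform(tP2, amplitude = 1, latency = profile$p2_latency)
    for (k in seq_len(nrow(sched))) {
      i0 <- round(sched$onset_s[k] * fs) + 1
      if (profile$p2_amplitude_mean > 0) {
        amp <- stats::rnorm(1, profile$p2_amplitude_mean, profile$p2_amplitude_sd)
        idx <- i0:(i0 + length(p2base) - 1)
        dat[, idx] <- dat[, idx] + outer(wP2, amp * p2base)
      }
      if (profile$cpp_amplitude_mean > 0 && sched$condition[k] == "change") {
        c0 <- round(sched$change_s[k] * fs) + 1
        tC <- seq(0, sched$duration_s[k] - sched$change_time[k] - 1 / fs,
                  by = 1 / fs)
        amp <- max(stats::rnorm(1, profile$cpp_amplitude_mean,
                                profile$cpp_amplitude_mean * 0.15), 0)
        cw <- cppWaveform(tC, amplitude = amp)
        idx <- c0:(c0 + length(cw) - 1)
        dat[, idx] <- dat[, idx] + outer(wCpp, cw)
      }
      # artifacts: square pulses within the trial window
      nArt <- stats::rpois(1, profile$artifact_rate)
      if (nArt > 0) {
        for (a in seq_len(nArt)) {
          t0 <- stats::runif(1, sched$onset_s[k],
                             sched$onset_s[k] + sched$duration_s[k] - 0.1)
          j0 <- round(t0 * fs) + 1
          j1 <- min(j0 + round(0.1 * fs), n)
          amp <- sample(c(-1, 1), 1) * stats::runif(1, 250, 500)
          chs <- sample.int(nc, min(nc, sample(1:4, 1)))
          dat[chs, j0:j1] <- dat[chs, j0:j1] + amp
        }
      }
    }
    newRecording(dat, fs, montage, sched)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Synthesizes one recording per subject across the configured groups and
#' writes an on-disk dataset bundle: per-subject EDF recordings with a
#' channel-position sidecar (TSV), per-subject event tables (TSV), a subject
#' metadata table (CSV) and a JSON manifest recording every seed and
#' parameter, so that any subject can be regenerated independently.
#'
#' @param config cohort configuration, see \code{\link{demoCohortConfig}};
#'   must contain \code{group_sizes} (named list/vector) and may override
#'   \code{profiles}, trial counts and \code{sampling_rate}.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generateCohort <- function(config, seed, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  config <- .normalizeCohortConfig(config)
  profiles <- config$profiles
  montage <- buildMontage(labels = config$channels)
  subjects <- list()
  manifest <- list(master_seed = seed, config = config, subjects = list())
  idx <- 0
  for (g in names(config$group_sizes)) {
    ng <- config$group_sizes[[g]]
    if (ng <= 0) next
    for (i in seq_len(ng)) {
      idx <- idx + 1
      sid <- sprintf("%s_%02d", g, i)
      sseed <- .deriveSeed(seed, idx)
      meta <- .sampleSubjectMeta(g, sid, .deriveSeed(sseed, 99))
      spec <- .specForGroup(g, config)
      rec <- synthesizeSubject(meta, profiles[[g]], spec, montage, seed = sseed)
      edf <- file.path(outdir, paste0(sid, ".edf"))
      writeEdf(rec, edf)
      evf <- file.path(outdir, paste0(sid, "_events.tsv"))
      ev <- recordingEvents(rec)
      ev$lock <- "onset"
      utils::write.table(
        ev[, c("trial_id", "lock", "onset_s", "change_s", "condition",
               "change_time", "duration_s", "stage_ok")],
        evf, sep = "\t", row.names = FALSE, quote = FALSE)
      chf <- file.path(outdir, paste0(sid, "_channels.tsv"))
      utils::write.table(rec@channels, chf, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      subjects[[idx]] <- meta
      manifest$subjects[[sid]] <- list(
        subject_id = sid, group = g, seed = sseed,
        edf = basename(edf), events = basename(evf), channels = basename(chf))
    }
  }
  subjTab <- if (length(subjects)) do.call(rbind, subjects) else
    subjectMeta("none", "none")[0, ]
  utils::write.csv(subjTab, file.path(outdir, "subjects.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

.specForGroup <- function(group, config) {
  kind <- if (group %in% c("MCS", "UWS")) "patient"
          else if (group == "Responding") "control_active"
          else "control_passive"
  args <- list(kind, sampling_rate = config$sampling_rate)
  # trial-count overrides are optional; the presets carry the study defaults
  if (!is.null(config$n_change_trials_per_time)) {
    args$n_change_trials_per_time <- config$n_change_trials_per_time
  }
  if (!is.null(config$n_sham_trials)) args$n_sham_trials <- config$n_sham_trials
  do.call(paradigmPreset, args)
}

.normalizeCohortConfig <- function(config) {
  stopifnot(is.list(config), !is.null(config$group_sizes))
  defaults <- list(sampling_rate = 1024)
  config <- utils::modifyList(defaults, config)
  prof <- defaultGroupProfiles()
  if (!is.null(config$profiles)) {
    for (g in names(config$profiles)) {
      ov <- config$profiles[[g]]
      if (inherits(ov, "GroupProfile")) prof[[g]] <- ov
      else prof[[g]] <- do.call(groupProfile,
                                utils::modifyList(unclass(prof[[g]]), ov))
    }
  }
  config$profiles <- prof
  if (is.null(config$channels)) config$channels <- buildMontage()$label
  config$group_sizes <- as.list(config$group_sizes)
  config
}

#' Cohort configurations
#'
#' \code{defaultCohortConfig} mirrors the study's group sizes (12 Responding,
#' 12 Passive, 15 Asleep-NREM, 12 MCS, 12 UWS) at the full per-group trial
#' counts. \code{demoCohortConfig} is a small cohort (4 subjects per group,
#' 40 trials each) that runs in minutes.
#'
#' @return a config list for \code{\link{generateCohort}} /
#'   \code{\link{runPipeline}}.
#' @export
defaultCohortConfig <- function() {
  list(group_sizes = list(Responding = 12, Passive = 12, AsleepNREM = 15,
                          MCS = 12, UWS = 12),
       sampling_rate = 1024)
}

#' @rdname defaultCohortConfig
#' @export
demoCohortConfig <- function() {
  list(group_sizes = list(Responding = 4, Passive = 4, AsleepNREM = 4,
                          MCS = 4, UWS = 4),
       n_change_trials_per_time = 8, n_sham_trials = 16,
       sampling_rate = 1024)
}
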