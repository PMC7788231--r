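test_that("trial schedules reproduce the paradigm's stimulus counts", {
  pat <- generateTrialSchedule(paradigmPreset("patient"), seed = 1)
  expect_equal(nrow(pat), 320)
  expect_equal(sum(pat$condition == "change"), 240)
  expect_equal(sum(pat$condition == "sham"), 80)
  # patient sham trials all use the 3 s nominal length
  expect_true(all(pat$duration_s[pat$condition == "sham"] == 5))

  ctl <- generateTrialSchedule(paradigmPreset("control_passive"), seed = 1)
  expect_equal(nrow(ctl), 240)
  expect_equal(sum(ctl$condition == "change"), 120)
  expect_equal(sum(ctl$condition == "sham"), 120)

  act <- generateTrialSchedule(paradigmPreset("control_active"), seed = 2)
  expect_equal(nrow(act), 480)
})

test_that("schedules are deterministic and respect the ISI range", {
  spec <- paradigmPreset("control_passive", n_change_trials_per_time = 5,
                         n_sham_trials = 5)
  s1 <- generateTrialSchedule(spec, seed = 7)
  s2 <- generateTrialSchedule(spec, seed = 7)
  expect_identical(s1, s2)
  s3 <- generateTrialSchedule(spec, seed = 8)
  expect_false(identical(s1$onset_s, s3$onset_s))
  gaps <- s1$onset_s[-1] - (s1$onset_s[-nrow(s1)] + s1$duration_s[-nrow(s1)])
  expect_true(all(gaps >= 1 - 1e-9 & gaps <= 2 + 1e-9))
  cts <- s1$change_s[s1$condition == "change"] -
    s1$onset_s[s1$condition == "change"]
  expect_true(all(vapply(cts, function(x)
    min(abs(x - c(0.75, 1.6, 3))) < 1e-9, NA)))
})

test_that("synthesized recordings are reproducible and finite", {
  spec <- paradigmPreset("patient", n_change_trials_per_time = 2,
                         n_sham_trials = 2, sampling_rate = 256)
  mont <- buildMontage(labels = c("FCz", "FC1", "FC2", "Cz", "Pz", "POz"))
  prof <- defaultGroupProfiles()$UWS
  meta <- subjectMeta("u1", "UWS")
  r1 <- synthesizeSubject(meta, prof, spec, mont, seed = 3)
  r2 <- synthesizeSubject(meta, prof, spec, mont, seed = 3)
  expect_identical(eegData(r1), eegData(r2))
  expect_true(all(is.finite(eegData(r1))))
  expect_error(synthesizeSubject(meta, groupProfile("UWS", noise_sd = NaN),
                                 spec, mont, seed = 1), "finite")
})

test_that("the injected P2 appears as a fronto-central peak near 0.2 s", {
  spec <- paradigmPreset("control_passive", n_change_trials_per_time = 70,
                         n_sham_trials = 0, sampling_rate = 256)
  mont <- buildMontage(labels = c(centralCandidateSet(), "Fz", "Pz", "POz"))
  prof <- groupProfile("Responding", p2_amplitude_mean = 2,
                       cpp_amplitude_mean = 0, noise_sd = 10,
                       artifact_rate = 0)
  rec <- synthesizeSubject(subjectMeta("r1", "Responding"), prof, spec, mont,
                           seed = 5)
  ep <- extractEpochs(rec, "onset", pre_s = 0.5, post_s = 1.0)
  erp <- averageErp(ep, controlP2Set())
  expect_gte(erp$nTrials, 200)
  pk <- measureP2(erp)
  expect_lt(abs(pk$latency - 0.2), 0.03)
  expect_gt(pk$amplitude, 1)
})

test_that("zero artifact rate yields zero rejections; rate increases them", {
  spec <- paradigmPreset("patient", n_change_trials_per_time = 6,
                         n_sham_trials = 6, sampling_rate = 256)
  mont <- buildMontage(labels = c("FCz", "Cz", "CPz", "Pz"))
  clean <- groupProfile("MCS", artifact_rate = 0, noise_sd = 8)
  noisy <- groupProfile("MCS", artifact_rate = 2, noise_sd = 8)
  rc <- synthesizeSubject(subjectMeta("a", "MCS"), clean, spec, mont, seed = 9)
  rn <- synthesizeSubject(subjectMeta("b", "MCS"), noisy, spec, mont, seed = 9)
  nRej <- function(r) {
    ep <- rejectArtifacts(extractEpochs(r, "onset", 0.3, 1.0), 200)
    sum(!epochInfo(ep)$kept)
  }
  expect_equal(nRej(rc), 0)
  expect_gt(nRej(rn), 0)
})

test_that("UWS subjects without an injected CPP show no parietal response", {
  spec <- paradigmPreset("patient", n_change_trials_per_time = 6,
                         n_sham_trials = 0, change_times = 3, sham_times = 3,
                         sampling_rate = 256)
  mont <- buildMontage(labels = c(parietalErpSet(), "CPz", "Cz", "FCz"))
  prof <- groupProfile("UWS", p2_amplitude_mean = 0, cpp_amplitude_mean = 0,
                       background_mode = "slow_stereotyped",
                       slow_osc_amplitude = 30, noise_sd = 5,
                       artifact_rate = 0)
  aucs <- vapply(1:6, function(i) {
    rec <- synthesizeSubject(subjectMeta("u", "UWS"), prof, spec, mont,
                             seed = 40 + i)
    ep <- baselineCorrect(extractEpochs(rec, "change", 0.5, 1.5))
    measureCppAuc(averageErp(ep, parietalErpSet()))$auc
  }, 0)
  expect_gt(t.test(aucs)$p.value, 0.01)
})

test_that("cohort generation writes a complete, regenerable bundle", {
  cfg <- list(group_sizes = list(MCS = 2, UWS = 1),
              n_change_trials_per_time = 1, n_sham_trials = 1,
              sampling_rate = 256,
              channels = c("FCz", "FC1", "FC2", "Cz", "Pz"))
  d1 <- withr::local_tempdir()
  man <- generateCohort(cfg, seed = 11, outdir = d1)
  expect_length(man$subjects, 3)
  expect_true(file.exists(file.path(d1, "subjects.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  subj <- read.csv(file.path(d1, "subjects.csv"))
  expect_equal(nrow(subj), 3)
  expect_equal(subj$crs_r_total,
               rowSums(subj[, grep("^crsr_", names(subj))]))
  # regeneration with the same master seed is byte-identical
  d2 <- withr::local_tempdir()
  generateCohort(cfg, seed = 11, outdir = d2)
  for (f in c("MCS_01_events.tsv", "subjects.csv", "MCS_01.edf")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  # empty cohort: manifest but no subjects, no error
  d3 <- withr::local_tempdir()
  man0 <- generateCohort(list(group_sizes = list(MCS = 0)), seed = 1,
                         outdir = d3)
  expect_length(man0$subjects, 0)
})

test_that("the study-scale default config covers 63 subjects in 5 groups", {
  cfg <- defaultCohortConfig()
  expect_equal(sum(unlist(cfg$group_sizes)), 63)
  expect_length(cfg$group_sizes, 5)
  expect_equal(cfg$group_sizes$AsleepNREM, 15)
})

test_that("subject metadata enforces CRS-R subscale structure", {
  m <- subjectMeta("p1", "MCS",
                   c(auditory = 3, visual = 4, motor = 5, oromotor = 2,
                     communication = 1, arousal = 2), "MCS", "MCS")
  expect_equal(m$crs_r_total, 17)
  expect_error(subjectMeta("p2", "MCS",
                           c(auditory = 5, visual = 0, motor = 0,
                             oromotor = 0, communication = 0, arousal = 0)),
               "range")
})
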