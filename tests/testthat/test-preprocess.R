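test_that("resampling preserves duration and pass-band amplitude", {
  fs <- 1024
  n <- fs * 10
  tt <- (0:(n - 1)) / fs
  rec <- toyRecording(matrix(sin(2 * pi * 5 * tt), 1), fs = fs,
                      labels = "Cz")
  out <- resampleTo(rec, 128)
  expect_equal(samplingRate(out), 128)
  expect_equal(ncol(eegData(out)), 1280)
  x <- eegData(out)[1, ]
  mid <- 200:1000                        # away from edges
  expect_lt(abs(sqrt(mean(x[mid]^2)) / sqrt(0.5) - 1), 0.01)
  # identity when target equals current rate
  expect_identical(eegData(resampleTo(rec, fs)), eegData(rec))
  expect_error(resampleTo(rec, 2048), "exceed")
  expect_error(resampleTo(rec, 100), "divide")
})

test_that("common-average reference zeroes the channel mean and is idempotent", {
  set.seed(1)
  rec <- toyRecording(matrix(rnorm(4 * 500), 4), labels = c("Cz", "Pz", "FCz", "CPz"))
  out <- rereferenceCommonAverage(rec)
  expect_lt(max(abs(colMeans(eegData(out)))), 1e-9)
  out2 <- rereferenceCommonAverage(out)
  expect_equal(eegData(out2), eegData(out), tolerance = 1e-12)
  # symmetric two-channel input is already average-referenced
  two <- toyRecording(matrix(c(1, -1), 2, 100), labels = c("Cz", "Pz"))
  expect_equal(eegData(rereferenceCommonAverage(two)), eegData(two))
  expect_error(rereferenceCommonAverage(toyRecording(matrix(0, 1, 10),
                                                     labels = "Cz")),
               ">= 2 channels")
})

test_that("band-pass removes DC, keeps 10 Hz and attenuates 50 Hz by >= 20 dB", {
  fs <- 128
  n <- fs * 30
  tt <- (0:(n - 1)) / fs
  mid <- (5 * fs):(25 * fs)
  run <- function(x) eegData(bandpassFilter(toyRecording(matrix(x, 1),
                                                         fs = fs,
                                                         labels = "Cz")))[1, ]
  dc <- run(rep(100, n))
  expect_lt(mean(abs(dc[mid])), 1)
  g10 <- sqrt(mean(run(sin(2 * pi * 10 * tt))[mid]^2)) / sqrt(0.5)
  expect_lt(abs(g10 - 1), 0.05)
  g50 <- sqrt(mean(run(sin(2 * pi * 50 * tt))[mid]^2)) / sqrt(0.5)
  expect_lt(g50, 10^(-20 / 20))
  expect_error(bandpassFilter(toyRecording(matrix(0, 1, 10), labels = "Cz"),
                              hp_cutoff = 40, lp_cutoff = 30), "hp_cutoff")
})

test_that("high-pass and low-pass sections match the signal package designs", {
  skip_if_not_installed("signal")
  fs <- 128
  f <- c(0.5, 2, 10, 25, 40, 60)
  mine <- auditoryPCI:::.designFilter(4, 30, fs, "low", "butter")
  ref <- signal::butter(4, 30 / (fs / 2))
  expect_equal(Mod(auditoryPCI:::.sosFreqResponse(mine, f, fs)),
               Mod(signal::freqz(ref$b, ref$a, 2 * pi * f / fs)$h),
               tolerance = 1e-9)
  mch <- auditoryPCI:::.designFilter(5, 2, fs, "high", "cheby2", Rs = 40)
  rch <- signal::cheby2(5, 40, 2 / (fs / 2), "high")
  expect_equal(Mod(auditoryPCI:::.sosFreqResponse(mch, f, fs)),
               Mod(signal::freqz(rch$b, rch$a, 2 * pi * f / fs)$h),
               tolerance = 1e-7)
})

test_that("notch removes 50 Hz, spares 10 Hz and maps zero to zero", {
  fs <- 256
  n <- fs * 20
  tt <- (0:(n - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  run <- function(x) eegData(notchFilter(toyRecording(matrix(x, 1), fs = fs,
                                                      labels = "Cz")))[1, ]
  r50 <- sqrt(mean(run(sin(2 * pi * 50 * tt))[mid]^2)) / sqrt(0.5)
  expect_lt(r50, 0.1)
  r10 <- sqrt(mean(run(sin(2 * pi * 10 * tt))[mid]^2)) / sqrt(0.5)
  expect_lt(abs(r10 - 1), 0.05)
  expect_equal(run(rep(0, n)), rep(0, n))
})

test_that("bad-channel repair averages neighbours and bounds variance", {
  labels <- c("Cz", "FCz", "CPz", "C1", "C2")
  # identical constant neighbours -> repaired value equals that constant
  dat <- rbind(rep(99, 200), matrix(5, 4, 200))
  rec <- toyRecording(dat, labels = labels)
  rep1 <- repairBadChannels(rec, "Cz")
  expect_equal(eegData(rep1)[1, ], rep(5, 200))
  expect_equal(eegData(rep1)[-1, ], dat[-1, ])
  # empty bad set is the identity
  expect_identical(eegData(repairBadChannels(rec, character(0))), dat)
  # repaired variance never exceeds the largest neighbour variance
  set.seed(42)
  for (i in 1:5) {
    datR <- matrix(rnorm(5 * 300, sd = runif(1, 0.5, 3)), 5, 300)
    recR <- toyRecording(datR, labels = labels)
    out <- repairBadChannels(recR, "Cz")
    expect_lte(var(eegData(out)[1, ]), max(apply(datR[-1, ], 1, var)))
  }
  expect_error(repairBadChannels(rec, labels), "all channels")
  expect_error(repairBadChannels(rec, "XX1"), "not in montage")
})

test_that("epoch extraction yields the documented shapes and drop reasons", {
  fs <- 128
  ev <- data.frame(trial_id = 1:4,
                   condition = c("change", "change", "sham", "change"),
                   change_time = c(3, 3, NA, 3),
                   onset_s = c(0.1, 2, 8, 14),
                   change_s = c(3.1, 5, NA, 17),
                   stage_ok = TRUE)
  rec <- toyRecording(matrix(rnorm(2 * fs * 25), 2), fs = fs,
                      labels = c("Cz", "Pz"), events = ev)
  epOn <- extractEpochs(rec, "onset", pre_s = 0.5, post_s = 1.5)
  expect_equal(dim(eegData(epOn)), c(4, 2, 256))
  expect_equal(epochTimes(epOn)[round(0.5 * fs) + 1], 0)
  info <- epochInfo(epOn)
  expect_false(info$kept[1])                    # onset at 0.1 s, pre = 0.5
  expect_equal(info$reason[1], "out_of_bounds")
  # change lock excludes sham trials
  epCh <- extractEpochs(rec, "change", pre_s = 0.5, post_s = 1.5)
  expect_equal(nrow(epochInfo(epCh)), 3)
  expect_false("sham" %in% epochInfo(epCh)$condition)
  # no matching events -> empty array, not an error
  ep0 <- extractEpochs(toyRecording(matrix(0, 2, 100), labels = c("Cz", "Pz")),
                       "change")
  expect_equal(dim(eegData(ep0))[1], 0)
})

test_that("amplitude rejection flags excursions and is monotone in threshold", {
  arr <- array(rnorm(6 * 2 * 64), c(6, 2, 64))
  arr[2, 1, 10] <- 250
  arr[5, 2, 30] <- -300
  ep <- toyEpochs(arr, labels = c("Cz", "Pz"))
  out <- rejectArtifacts(ep, 200)
  expect_equal(which(!epochInfo(out)$kept), c(2L, 5L))
  expect_equal(unique(epochInfo(out)$reason[!epochInfo(out)$kept]),
               "amplitude_artifact")
  expect_true(all(epochInfo(rejectArtifacts(ep, Inf))$kept))
  # kept sets are nested as the threshold decreases
  kept <- lapply(c(400, 200, 100, 3), function(th)
    which(epochInfo(rejectArtifacts(ep, th))$kept))
  for (i in 2:length(kept)) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("median baseline zeroes the window median and resists outliers", {
  fs <- 128
  arr <- array(7, c(2, 1, 256))
  ep <- toyEpochs(arr, labels = "Cz")
  out <- baselineCorrect(ep)
  expect_equal(as.numeric(eegData(out)), rep(0, length(arr)))
  # random input: window median is exactly zero afterwards
  set.seed(3)
  arrR <- array(rnorm(3 * 2 * 256, 5), c(3, 2, 256))
  epR <- toyEpochs(arrR, labels = c("Cz", "Pz"))
  outR <- baselineCorrect(epR)
  tt <- epochTimes(outR)
  sel <- tt >= -0.4 & tt <= -0.15
  meds <- apply(eegData(outR)[, , sel, drop = FALSE], c(1, 2), median)
  expect_equal(max(abs(meds)), 0)
  # one 300 uV outlier among ~flat baseline samples barely moves the median
  arrO <- array(0, c(1, 1, 256))
  arrO[1, 1, 20] <- 300                         # inside the baseline window
  epO <- toyEpochs(arrO, labels = "Cz")
  outO <- baselineCorrect(epO)
  expect_equal(eegData(outO)[1, 1, 256], 0)     # correction was ~0
  expect_error(baselineCorrect(ep, window = c(-9, -8)), "outside")
})

test_that("the preprocessing chain is deterministic and keeps the CAR invariant", {
  spec <- paradigmPreset("patient", n_change_trials_per_time = 2,
                         n_sham_trials = 1, sampling_rate = 256)
  mont <- buildMontage(labels = c("FCz", "FC1", "FC2", "Cz", "CPz", "Pz"))
  rec <- synthesizeSubject(subjectMeta("s", "MCS"),
                           defaultGroupProfiles()$MCS, spec, mont, seed = 21)
  p1 <- preprocessRecording(rec)
  p2 <- preprocessRecording(rec)
  expect_identical(eegData(p1$onset), eegData(p2$onset))
  # linear filtering preserves the zero channel mean
  expect_lt(max(abs(colMeans(eegData(p1$recording)))), 1e-9)
})
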