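test_that("binary entropy follows the closed form with 0 log 0 = 0", {
  expect_equal(binaryEntropy(p = 0.5), 1)
  expect_equal(binaryEntropy(p = 0), 0)
  expect_equal(binaryEntropy(p = 1), 0)
  h011 <- -0.11 * log2(0.11) - 0.89 * log2(0.89)
  expect_equal(binaryEntropy(p = 0.11), h011)
  expect_equal(binaryEntropy(p = 0.11), binaryEntropy(p = 0.89))
  expect_equal(binaryEntropy(c(0L, 1L, 1L, 0L)), 1)
})

test_that("LZ76 word count matches the hand-checked small cases", {
  expect_equal(lzWordCount(0L), 1)
  expect_equal(lzWordCount(rep(0L, 1000)), lzOracle(rep(0L, 1000)))
  expect_equal(lzWordCount(rep(0L, 1000)), 2)
  expect_error(lzWordCount(c(0L, 2L)), "binary")
  expect_error(lzWordCount(integer(0)), "length")
})

test_that("LZ76 equals the brute-force exhaustive-history parser", {
  set.seed(99)
  for (i in 1:300) {
    L <- sample(1:64, 1)
    p <- runif(1, 0.05, 0.95)
    s <- as.integer(runif(L) < p)
    expect_equal(lzWordCount(s), lzOracle(s))
  }
  # structured strings too
  for (s in list(rep(c(0L, 1L), 20), c(rep(0L, 30), rep(1L, 30)),
                 rep(c(0L, 0L, 1L), 15))) {
    expect_equal(lzWordCount(s), lzOracle(s))
  }
})

test_that("the random-string word count approaches the normalization asymptote", {
  set.seed(7)
  s <- as.integer(runif(1e4) < 0.5)
  cc <- lzWordCount(s)
  expect_lt(abs(cc / (length(s) / log2(length(s))) - 1), 0.05)
})

test_that("the normalized score calibrates to 1 on random strings and collapses on periodic ones", {
  set.seed(11)
  v5 <- pciaValue(pciaScore(as.integer(runif(2e4) < 0.5)))
  v2 <- pciaValue(pciaScore(as.integer(runif(2e4) < 0.2)))
  expect_lt(abs(v5 - 1), 0.07)
  expect_lt(abs(v2 - 1), 0.07)
  per <- pciaValue(pciaScore(rep(c(0L, 1L), 5000)))
  expect_lt(per, 0.05)
  # H = 0 sequences are flagged undefined
  sc0 <- pciaScore(matrix(0L, 2, 50))
  expect_false(sc0@defined)
  expect_true(is.na(pciaValue(sc0)))
})

test_that("a constant-envelope sinusoid binarizes to all zeros", {
  fs <- 128
  nSamp <- 256
  tt <- (seq_len(nSamp) - 1 - 64) / fs
  arr <- array(0, c(1, 1, nSamp))
  arr[1, 1, ] <- sin(2 * pi * 10 * (0:(nSamp - 1)) / fs)  # 20 whole periods
  ep <- toyEpochs(arr, labels = "Cz")
  bin <- binarizeHilbert(ep, window = c(-0.5, 1.5), channels = "Cz")
  expect_equal(dim(bin), c(1, 128))                        # 2 s at 64 Hz
  expect_true(all(bin == 0))
})

test_that("an amplitude-modulated burst yields roughly half ones", {
  fs <- 128
  nSamp <- 256
  x <- sin(2 * pi * 20 * (0:(nSamp - 1)) / fs)
  x[1:128] <- 0.05 * x[1:128]                # low-amplitude first half
  arr <- array(x, c(1, 1, nSamp))
  ep <- toyEpochs(arr, labels = "Cz")
  bin <- binarizeHilbert(ep, window = c(-0.5, 1.5), channels = "Cz")
  expect_gt(mean(bin), 0.35)
  expect_lt(mean(bin), 0.6)
  expect_true(all(bin[1:55] == 0))           # silent half stays below the mean
})

test_that("the score is invariant to global amplitude scaling", {
  set.seed(5)
  arr <- array(rnorm(2 * 2 * 256), c(2, 2, 256))
  ep1 <- toyEpochs(arr, labels = c("Cz", "Pz"))
  ep2 <- toyEpochs(arr * 137.5, labels = c("Cz", "Pz"))
  s1 <- pciaScore(binarizeHilbert(ep1))
  s2 <- pciaScore(binarizeHilbert(ep2))
  expect_equal(pciaValue(s1), pciaValue(s2))
})

test_that("a single noise row reduces computeSubjectPCIa to pciaScore", {
  set.seed(6)
  arr <- array(rnorm(1 * 1 * 256), c(1, 1, 256))
  ep <- toyEpochs(arr, labels = "Cz")
  direct <- pciaScore(binarizeHilbert(ep, channels = "Cz"))
  via <- computeSubjectPCIa(ep, channel_set = "Cz")
  expect_equal(pciaValue(via), pciaValue(direct))
  expect_equal(via@wordCount, direct@wordCount)
  expect_error(computeSubjectPCIa(ep, channel_set = character(0)), "empty")
})

test_that("duplicated trials never exceed the diversity of independent trials", {
  set.seed(8)
  worse <- 0
  for (i in 1:10) {
    one <- array(rnorm(1 * 1 * 256), c(1, 1, 256))
    dup <- array(c(one, one), c(2, 1, 256))
    ind <- array(rnorm(2 * 1 * 256), c(2, 1, 256))
    sDup <- pciaValue(pciaScore(binarizeHilbert(toyEpochs(dup, labels = "Cz"))))
    sInd <- pciaValue(pciaScore(binarizeHilbert(toyEpochs(ind, labels = "Cz"))))
    if (sDup > sInd + 1e-9) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
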