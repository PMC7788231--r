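test_that("groupCompare recovers a constructed 3-pooled-SD separation", {
  set.seed(1)
  xa <- rnorm(12)
  xb <- xa + 3 * sd(xa)                 # pooled SD equals sd(xa) exactly
  d <- data.frame(v = c(xa, xb), group = rep(c("A", "B"), each = 12))
  gc <- groupCompare(d, "v")
  expect_lt(gc$omnibus$p, 0.001)
  expect_equal(gc$pairwise$cohens_d, -3, tolerance = 1e-9)
  expect_lt(gc$pairwise$p_adj, 0.001)
  expect_gte(gc$pairwise$p_adj, gc$pairwise$p_raw)
})

test_that("null pairwise comparisons keep their nominal size", {
  set.seed(2)
  hits <- 0
  for (i in 1:200) {
    d <- data.frame(v = rnorm(24), group = rep(c("A", "B"), each = 12))
    gc <- groupCompare(d, "v", posthoc = "ranksum_holm")
    if (gc$pairwise$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0)
  expect_lte(hits / 200, 0.10)          # ~5% +/- Monte-Carlo noise
})

test_that("a group symmetric about zero has a well-calibrated signed-rank test", {
  set.seed(3)
  ps <- vapply(1:200, function(i) {
    d <- data.frame(v = c(rnorm(15), rnorm(15, 2)),
                    group = rep(c("A", "B"), each = 15))
    groupCompare(d, "v")$vs_zero[["A"]]
  }, 0)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
  # degenerate all-identical values are flagged
  dd <- data.frame(v = rep(1, 8), group = rep(c("A", "B"), each = 4))
  gcd <- groupCompare(dd, "v")
  expect_true(gcd$degenerate)
})

test_that("Kruskal-Wallis p-values are uniform under the five-group null", {
  set.seed(4)
  ps <- vapply(1:500, function(i) {
    d <- data.frame(v = rnorm(40), group = rep(letters[1:5], each = 8))
    groupCompare(d, "v")$omnibus$p
  }, 0)
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.08)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("correlations behave on exact, monotone and independent data", {
  x <- seq(-2, 2, length.out = 20)
  d <- data.frame(f = x, crs_r_total = 2 * x)
  expect_equal(correlateWithCrsr(d, "f")$r, 1)
  expect_equal(correlateWithCrsr(d, "f", method = "spearman")$r, 1)
  dexp <- data.frame(f = x, crs_r_total = exp(x))
  expect_equal(correlateWithCrsr(dexp, "f", method = "spearman")$r, 1)
  expect_lt(correlateWithCrsr(dexp, "f", method = "pearson")$r, 1)
  set.seed(5)
  dn <- data.frame(f = rnorm(200), crs_r_total = rnorm(200))
  expect_lt(abs(correlateWithCrsr(dn, "f")$r), 0.2)
  dz <- data.frame(f = rep(1, 10), crs_r_total = 1:10)
  expect_identical(correlateWithCrsr(dz, "f")$flag, "zero_variance")
  expect_error(correlateWithCrsr(dn[1:3, ], "f"), ">= 4")
})

test_that("the linear discriminant matches the closed-form Fisher direction", {
  set.seed(6)
  n <- 200
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  ch <- chol(S)
  x0 <- matrix(rnorm(n * 2), n) %*% ch
  x1 <- sweep(matrix(rnorm(n * 2), n) %*% ch, 2, c(2, 1), "+")
  X <- rbind(x0, x1)
  y <- rep(c("a", "b"), each = n)
  m <- fitLda(X, y, shrinkage = 0)
  # undo the internal standardization to compare on the raw scale
  wRaw <- m$weights / m$scale
  # independent oracle: pooled sample covariance and mean difference
  Sp <- ((n - 1) * cov(x0) + (n - 1) * cov(x1)) / (2 * n - 2)
  wRef <- solve(Sp, colMeans(x1) - colMeans(x0))
  cosang <- sum(wRaw * wRef) / sqrt(sum(wRaw^2) * sum(wRef^2))
  expect_gt(cosang, 0.9999)
})

test_that("fitLda agrees with MASS::lda posteriors at zero shrinkage", {
  skip_if_not_installed("MASS")
  set.seed(7)
  X <- rbind(matrix(rnorm(36), 12), matrix(rnorm(36, 1), 12))
  colnames(X) <- c("f1", "f2", "f3")
  y <- rep(c("UWS", "MCS"), each = 12)
  m <- fitLda(X, y, shrinkage = 0)
  p <- predict(m, X)
  ref <- MASS::lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  pr <- predict(ref, X)
  expect_equal(p$score, unname(pr$posterior[, m$levels[2]]),
               tolerance = 1e-8)
  expect_equal(as.character(p$class), as.character(pr$class))
})

test_that("degenerate and separable training sets behave as expected", {
  set.seed(8)
  Xs <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
  ys <- rep(c("a", "b"), each = 10)
  m <- fitLda(Xs, ys)
  expect_equal(mean(predict(m, Xs)$class == ys), 1)
  expect_error(fitLda(Xs[1:11, ], ys[1:11]), ">= 2 members")
  # identical class distributions: near-chance LOOCV accuracy
  di <- data.frame(f1 = rnorm(40), f2 = rnorm(40),
                   group = rep(c("a", "b"), 20))
  r <- loocvClassify(di, features = c("f1", "f2"))
  expect_gte(r$accuracy, 0.2)
  expect_lte(r$accuracy, 0.8)
})

test_that("LOOCV is deterministic and its confusion matrix conserves counts", {
  X <- data.frame(f = c(-2, -1.5, 1.5, 2, -1.8, 1.8),
                  group = c("a", "a", "b", "b", "a", "b"))
  r1 <- loocvClassify(X, features = "f")
  r2 <- loocvClassify(X, features = "f")
  expect_identical(r1$table$score, r2$table$score)
  expect_equal(r1$accuracy, 1)
  expect_true(all(r1$table$score >= 0 & r1$table$score <= 1))
  cm <- confusionCounts(r1)
  expect_equal(sum(cm), 6)
  expect_equal(unname(diag(cm)), c(3, 3))
  # all predicted one class -> a single nonzero column
  tab <- data.frame(true = c("a", "a", "b"), predicted = rep("a", 3))
  cm2 <- confusionCounts(tab)
  expect_equal(unname(colSums(cm2)), c(3, 0))
  expect_error(loocvClassify(X[1:3, ], features = "f"), ">= 4")
})

test_that("shuffled labels drive LOOCV accuracy to the 50% base rate", {
  set.seed(9)
  d <- data.frame(p2_amplitude = c(rnorm(8), rnorm(8, 2)),
                  pcia_onset = c(rnorm(8), rnorm(8, 1)),
                  pcia_change = c(rnorm(8), rnorm(8, 2)),
                  group = rep(c("UWS", "MCS"), each = 8))
  sh <- shuffledLabelControl(d, n_shuffles = 100, seed = 10)
  expect_lt(abs(sh$mean_accuracy - 0.5), 0.06)
  # determinism under the seed
  sh2 <- shuffledLabelControl(d, n_shuffles = 100, seed = 10)
  expect_identical(sh$accuracies, sh2$accuracies)
})
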