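# Group-level statistics and the consciousness-state classifier. Omnibus
# comparisons use Kruskal-Wallis; pairwise post-hoc tests are rank-based with
# either a Tukey-style studentized-range adjustment on mean ranks (the
# behaviour of multiple-comparison procedures applied to Kruskal-Wallis
# output) or rank-sum tests with Holm adjustment. Effect sizes are Cohen's d
# from the pooled SD. The classifier is a pooled-covariance linear
# discriminant with optional diagonal shrinkage, evaluated by leave-one-out
# cross-validation with the class-membership score thresholded at 0.5.

#' Compare a feature across groups
#'
#' Kruskal-Wallis omnibus test, pairwise post-hoc comparisons with
#' multiple-comparison adjustment, Cohen's d (pooled SD, first group minus
#' second), and a one-sample Wilcoxon signed-rank test against zero per
#' group.
#'
#' @param data data.frame of per-subject features.
#' @param feature name of the feature column.
#' @param group name of the grouping column (default \code{"group"}).
#' @param posthoc \code{"tukey_rank"}: studentized-range test on mean ranks
#'   (adjusted); \code{"ranksum_holm"}: pairwise Wilcoxon rank-sum with Holm
#'   adjustment.
#' @return list of class \code{GroupComparison}: \code{omnibus}
#'   (Kruskal-Wallis statistic, df, p), \code{pairwise} (data.frame: groups,
#'   raw and adjusted p, Cohen's d), \code{vs_zero} (per-group signed-rank p),
#'   \code{degenerate} flag.
#' @export
groupCompare <- function(data, feature, group = "group",
                         posthoc = c("tukey_rank", "ranksum_holm")) {
  posthoc <- match.arg(posthoc)
  x <- data[[feature]]
  g <- factor(data[[group]])
  ok <- is.finite(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 subjects each")
  }
  degenerate <- stats::var(x) == 0
  omni <- if (degenerate) {
    list(statistic = NA_real_, df = nlevels(g) - 1, p = NA_real_)
  } else {
    kw <- stats::kruskal.test(x, g)
    list(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p = kw$p.value)
  }
  lev <- levels(g)
  k <- length(lev)
  N <- length(x)
  rk <- rank(x)
  meanRank <- tapply(rk, g, mean)
  nPer <- table(g)
  # tie correction for the rank-variance term
  ties <- table(rk)
  tieAdj <- 1 - sum(ties^3 - ties) / (N^3 - N)
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   p_raw = NA_real_, p_adj = NA_real_, cohens_d = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    xa <- x[g == a]; xb <- x[g == b]
    if (!degenerate) {
      pw$p_raw[i] <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    }
    sp <- sqrt(((length(xa) - 1) * stats::var(xa) +
                  (length(xb) - 1) * stats::var(xb)) /
                 (length(xa) + length(xb) - 2))
    pw$cohens_d[i] <- if (sp > 0) (mean(xa) - mean(xb)) / sp else NA_real_
  }
  if (!degenerate) {
    if (posthoc == "tukey_rank") {
      for (i in seq_len(ncol(pairs))) {
        a <- pairs[1, i]; b <- pairs[2, i]
        se <- sqrt(tieAdj * N * (N + 1) / 12 * (1 / nPer[a] + 1 / nPer[b]))
        qstat <- abs(meanRank[a] - meanRank[b]) / se * sqrt(2)
        pw$p_adj[i] <- stats::ptukey(qstat, nmeans = k, df = Inf,
                                     lower.tail = FALSE)
      }
    } else {
      pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
    }
    pw$p_adj <- pmax(pw$p_adj, pw$p_raw, na.rm = TRUE)
  }
  vz <- vapply(lev, function(l) {
    xi <- x[g == l]
    if (all(xi == 0)) return(1)
    suppressWarnings(stats::wilcox.test(xi, mu = 0)$p.value)
  }, 0)
  structure(list(feature = feature, omnibus = omni, pairwise = pw,
                 vs_zero = stats::setNames(vz, lev), degenerate = degenerate,
                 posthoc = posthoc),
            class = "GroupComparison")
}

#' Correlate a feature with a CRS-R score
#'
#' @param data data.frame of per-subject features.
#' @param feature feature column name.
#' @param crsr CRS-R column name (e.g. \code{"crs_r_total"}).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list: \code{r}, \code{p}, \code{n}, \code{method};
#'   undefined (\code{r} NA, flagged) when either variable has zero variance.
#' @export
correlateWithCrsr <- function(data, feature, crsr = "crs_r_total",
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- data[[feature]]
  y <- data[[crsr]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), method = method,
                flag = "zero_variance"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method, flag = "")
}

#' Fit a linear discriminant classifier
#'
#' Two-class LDA on standardized features with a pooled covariance that can
#' be shrunk toward its diagonal: \code{S(lambda) = (1 - lambda) S + lambda
#' diag(S)}. \code{shrinkage = "auto"} picks lambda by leave-one-out
#' cross-validation on the training data over a small grid. The score is the
#' posterior probability of the second class level (equal priors), in
#' \code{[0, 1]}, thresholded at 0.5 for prediction.
#'
#' @param x numeric matrix (subjects x features).
#' @param y two-level factor (or coercible) of class labels.
#' @param shrinkage numeric in \code{[0, 1]} or \code{"auto"}.
#' @return object of class \code{ldaModel} with \code{weights}, \code{bias},
#'   scaling info, class levels and the chosen lambda.
#' @export
fitLda <- function(x, y, shrinkage = 0) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) stop("fitLda requires exactly 2 classes")
  if (any(table(y) < 2)) stop("each class needs >= 2 members")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  if (identical(shrinkage, "auto")) {
    grid <- c(0, 0.1, 0.25, 0.5, 1)
    acc <- vapply(grid, function(l) {
      pred <- vapply(seq_len(nrow(xs)), function(i) {
        yi <- droplevels(y[-i])
        if (nlevels(yi) < 2 || any(table(yi) < 2)) return(NA_character_)
        m <- .ldaCore(xs[-i, , drop = FALSE], y[-i], l)
        as.character(.ldaPredict(m, xs[i, , drop = FALSE])$class)
      }, "")
      mean(pred == as.character(y), na.rm = TRUE)
    }, 0)
    lambda <- grid[which.max(acc)]
  } else {
    lambda <- shrinkage
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  }
  m <- .ldaCore(xs, y, lambda)
  m$center <- ctr
  m$scale <- scl
  m$lambda <- lambda
  m
}

.ldaCore <- function(xs, y, lambda) {
  lev <- levels(y)
  m0 <- colMeans(xs[y == lev[1], , drop = FALSE])
  m1 <- colMeans(xs[y == lev[2], , drop = FALSE])
  n0 <- sum(y == lev[1]); n1 <- sum(y == lev[2])
  c0 <- stats::cov(xs[y == lev[1], , drop = FALSE])
  c1 <- stats::cov(xs[y == lev[2], , drop = FALSE])
  S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  S <- (1 - lambda) * S + lambda * diag(diag(S), nrow(S))
  S <- S + diag(1e-10, nrow(S))
  w <- solve(S, m1 - m0)
  structure(list(weights = w, mid = (m0 + m1) / 2, levels = lev,
                 center = rep(0, length(w)), scale = rep(1, length(w))),
            class = "ldaModel")
}

.ldaPredict <- function(model, xs) {
  logit <- as.numeric((xs - matrix(model$mid, nrow(xs), length(model$mid),
                                   byrow = TRUE)) %*% model$weights)
  score <- stats::plogis(logit)
  cls <- factor(ifelse(score > 0.5, model$levels[2], model$levels[1]),
                levels = model$levels)
  list(score = score, class = cls)
}

#' Predict from a fitted LDA model
#'
#' @param object an \code{ldaModel} from \code{\link{fitLda}}.
#' @param newdata numeric matrix of features (subjects x features).
#' @param ... unused.
#' @return list with \code{score} (class-membership probability of the
#'   second level, in \code{[0, 1]}) and \code{class} (threshold 0.5).
#' @export
predict.ldaModel <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center,
              scale = object$scale)
  .ldaPredict(object, xs)
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is scored by a linear discriminant trained on all other
#' subjects (default feature set: P2 amplitude plus PCIa at onset and at
#' change). Folds whose training set degenerates to a single class are
#' flagged and excluded from the accuracy.
#'
#' @param data data.frame of per-subject features and labels.
#' @param features feature column names.
#' @param label label column name.
#' @param shrinkage passed to \code{\link{fitLda}}.
#' @return list of class \code{ClassificationResult}: \code{table}
#'   (per-subject score in \code{[0, 1]}, predicted and true class),
#'   \code{accuracy}, \code{confusion}, \code{features}, \code{cv} =
#'   \code{"loocv"}.
#' @export
loocvClassify <- function(data,
                          features = c("p2_amplitude", "pcia_onset", "pcia_change"),
                          label = "group", shrinkage = 0) {
  x <- as.matrix(data[, features, drop = FALSE])
  y <- factor(data[[label]])
  n <- nrow(x)
  if (n < 4) stop("need >= 4 subjects for leave-one-out evaluation")
  if (nlevels(y) != 2) stop("binary classification requires 2 classes")
  score <- rep(NA_real_, n)
  pred <- rep(NA_character_, n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2 || any(table(yi) < 2)) {
      flagged[i] <- TRUE
      next
    }
    m <- fitLda(x[-i, , drop = FALSE], y[-i], shrinkage = shrinkage)
    p <- predict.ldaModel(m, x[i, , drop = FALSE])
    score[i] <- p$score
    pred[i] <- as.character(p$class)
  }
  ok <- !flagged
  tab <- data.frame(subject = seq_len(n), score = score,
                    predicted = pred, true = as.character(y),
                    flagged = flagged, stringsAsFactors = FALSE)
  if ("subject_id" %in% names(data)) tab$subject <- data$subject_id
  acc <- mean(pred[ok] == as.character(y)[ok])
  structure(list(table = tab, accuracy = acc,
                 confusion = confusionCounts(tab),
                 features = features, cv = "loocv", shrinkage = shrinkage),
            class = "ClassificationResult")
}

#' Confusion matrix of a classification result
#'
#' Counts per (true, predicted) cell; marginals sum to the number of
#' classified subjects.
#'
#' @param results a \code{ClassificationResult} or its \code{table}
#'   data.frame (columns \code{true}, \code{predicted}).
#' @return integer matrix, rows = true class, columns = predicted class.
#' @export
confusionCounts <- function(results) {
  tab <- if (inherits(results, "ClassificationResult")) results$table else results
  tab <- tab[!is.na(tab$predicted), , drop = FALSE]
  lev <- sort(unique(c(tab$true, tab$predicted)))
  table(factor(tab$true, levels = lev),
        factor(tab$predicted, levels = lev),
        dnn = c("true", "predicted"))
}

#' Shuffled-label control of the LOOCV classifier
#'
#' Randomly permutes the class labels and reruns the full leave-one-out
#' evaluation, \code{n_shuffles} times; a sound cross-validation scheme must
#' land at the majority-class base rate (50\% for balanced classes).
#'
#' @param data,features,label,shrinkage as in \code{\link{loocvClassify}}.
#' @param n_shuffles number of label permutations.
#' @param seed integer seed.
#' @return list: \code{mean_accuracy}, \code{accuracies}.
#' @export
shuffledLabelControl <- function(data, features = c("p2_amplitude",
                                                    "pcia_onset", "pcia_change"),
                                 label = "group", n_shuffles = 200,
                                 shrinkage = 0, seed = 1) {
  acc <- numeric(n_shuffles)
  .withSeed(seed, {
    for (s in seq_len(n_shuffles)) {
      shuffled <- data
      shuffled[[label]] <- sample(data[[label]])
      acc[s] <- loocvClassify(shuffled, features, label,
                              shrinkage = shrinkage)$accuracy
    }
  })
  list(mean_accuracy = mean(acc), accuracies = acc)
}
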