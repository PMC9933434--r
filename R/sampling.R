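# Farthest point sampling for structure selection, and evaluation scores
# (MAE, squared Pearson correlation) with k-fold cross-validation.

#' Farthest point sampling
#'
#' Greedy maximin selection: starting from \code{startIndex}, each new index
#' maximizes the minimum Euclidean distance to the already-selected set.
#' Deterministic; ties are broken by the lowest index.
#'
#' @param X numeric matrix, one feature vector per row (e.g. MM potentials).
#' @param k number of points to select (<= nrow(X)).
#' @param startIndex index of the first selected point (default 1).
#' @return Integer vector of k selected row indices, in selection order.
#' @export
farthestPointSampling <- function(X, k, startIndex = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of points")
  stopifnot(k >= 1, startIndex >= 1, startIndex <= n)
  selected <- integer(k)
  selected[1] <- as.integer(startIndex)
  if (k == 1) return(selected)
  minDist <- crossDist(X, X[startIndex, , drop = FALSE])[, 1]
  for (step in 2:k) {
    minDist[selected[seq_len(step - 1)]] <- -Inf
    nxt <- which.max(minDist)   # which.max returns the first (lowest) index
    selected[step] <- nxt
    minDist <- pmin(minDist, crossDist(X, X[nxt, , drop = FALSE])[, 1])
  }
  selected
}

#' Mean absolute error
#'
#' @param pred,target numeric vectors of equal length.
#' @return (1/N) sum |pred - target|, >= 0.
#' @export
maeScore <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  mean(abs(pred - target))
}

#' Squared Pearson correlation coefficient
#'
#' Symmetric in its arguments and invariant to affine rescaling of either;
#' in [0, 1].
#'
#' @param pred,target numeric vectors of equal length.
#' @return r^2 in [0, 1].
#' @export
rSquaredScore <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  if (stats::sd(pred) == 0 || stats::sd(target) == 0) {
    stop("undefined score: zero variance in an input vector")
  }
  stats::cor(pred, target)^2
}

#' k-fold cross-validation of a trainer, with optional learning curve
#'
#' Folds are a seeded random partition with sizes differing by at most one.
#' In learning-curve mode, the training subsets drawn at each size are
#' nested (smaller inside larger) for variance reduction.
#'
#' @param trainer function(trainIdx, testIdx) returning numeric predictions
#'   for \code{testIdx}; closes over the data.
#' @param targets numeric target vector (defines n).
#' @param nFolds number of folds (default 5).
#' @param seed integer seed; same seed gives identical folds.
#' @param sizes NULL for plain CV, or a vector of training-set sizes for a
#'   learning curve (each size is cross-validated on the same folds,
#'   subsampling the training portion of each fold).
#' @return data.frame with one row per (size x) fold: columns size, fold,
#'   mae, r2; attribute \code{summary} holds per-size mean and 2*sd bands.
#' @export
crossValidate <- function(trainer, targets, nFolds = 5, seed = 1,
                          sizes = NULL) {
  n <- length(targets)
  stopifnot(nFolds >= 2, nFolds <= n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  foldId <- sample(rep(seq_len(nFolds), length.out = n))
  if (is.null(sizes)) sizes <- NA_integer_
  rows <- list()
  for (s in sizes) {
    for (f in seq_len(nFolds)) {
      trainIdx <- which(foldId != f)
      testIdx <- which(foldId == f)
      if (!is.na(s)) {
        if (s > length(trainIdx)) {
          stop("training size ", s, " exceeds fold training portion")
        }
        # nested subsets: a seeded permutation per fold, truncated per size
        set.seed((as.integer(seed) + 7919L * f) %% .Machine$integer.max)
        trainIdx <- trainIdx[sample.int(length(trainIdx))][seq_len(s)]
      }
      pred <- trainer(trainIdx, testIdx)
      rows[[length(rows) + 1]] <- data.frame(
        size = if (is.na(s)) length(trainIdx) else s, fold = f,
        mae = maeScore(pred, targets[testIdx]),
        r2 = rSquaredScore(pred, targets[testIdx]))
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$size), function(d) {
    data.frame(size = d$size[1],
               maeMean = mean(d$mae), maeBand = 2 * stats::sd(d$mae),
               r2Mean = mean(d$r2), r2Band = 2 * stats::sd(d$r2))
  }))
  agg <- agg[order(agg$size), , drop = FALSE]
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
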