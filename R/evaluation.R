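#' Masked root-mean-squared error
#'
#' RMSE between truth and imputation computed only over the evaluation
#' mask (the entries that were hidden); values elsewhere are ignored.
#'
#' @param truth,imputed numeric D x T matrices.
#' @param evalMask numeric D x T 0/1 matrix, 1 = score this entry.
#' @return nonnegative scalar.
#' @examples
#' maskedRMSE(matrix(0, 1, 2), matrix(c(1, 3), 1), matrix(1, 1, 2)) # sqrt(5)
#' @export
maskedRMSE <- function(truth, imputed, evalMask) {
  if (!identical(dim(truth), dim(imputed)) ||
    !identical(dim(truth), dim(evalMask))) {
    stop("truth, imputed and evalMask must have identical dimensions")
  }
  idx <- evalMask == 1
  if (!any(idx)) stop("evaluation mask selects no entries")
  sqrt(mean((truth[idx] - imputed[idx])^2))
}

#' Baseline imputers
#'
#' Reference fills for comparison: `"mean"` replaces missing entries
#' with the per-feature observed mean; `"forward_fill"` carries the last
#' observed value forward (entries before a feature's first observation
#' are back-filled from it); `"zero"` writes 0 (the marginal mean in
#' standardized units).  Observed entries are never altered.  A feature
#' with no observations at all falls back to 0.
#'
#' @param series An [IncompleteSeries-class].
#' @param method one of `"mean"`, `"forward_fill"`, `"zero"`.
#' @return a completed [IncompleteSeries-class] (mask all ones).
#' @export
baselineImpute <- function(series, method = c("mean", "forward_fill", "zero")) {
  method <- match.arg(method)
  v <- seriesValues(series)
  m <- seriesMask(series)
  d <- nrow(v)
  tt <- ncol(v)
  out <- v
  if (method == "zero") {
    out[m == 0] <- 0
  } else if (method == "mean") {
    mu <- rowMeans(v, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (f in seq_len(d)) out[f, m[f, ] == 0] <- mu[f]
  } else {
    for (f in seq_len(d)) {
      obs <- which(m[f, ] == 1)
      if (!length(obs)) {
        out[f, ] <- 0
        next
      }
      last <- v[f, obs[1L]] # back-fill before the first observation
      for (i in seq_len(tt)) {
        if (m[f, i] == 1) last <- v[f, i] else out[f, i] <- last
      }
    }
  }
  new("IncompleteSeries",
    values = out, mask = matrix(1, d, tt),
    timestamps = seriesTimestamps(series),
    featureNames = featureNames(series)
  )
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive is scored above a randomly chosen negative, with ties
#' counted one half.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @return scalar in [0, 1].
#' @examples
#' aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
aucScore <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores) # average ranks: ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' GRU classifier on completed sequences
#'
#' The downstream evaluation model: a single-layer plain GRU (no
#' temporal decay — completed data has no missingness, so decay is
#' undefined) read out through a logistic unit on the final hidden
#' state, trained with Adam on cross-entropy.  Inputs are standardized
#' internally using the training split.  Deterministic given `seed`.
#'
#' @param trainData,testData lists of completed
#'   [IncompleteSeries-class] objects (no missing entries).
#' @param trainLabels 0/1 vector, one label per training sequence.
#' @param hiddenSize recurrent hidden size (default 16).
#' @param epochs training epochs (default 30).
#' @param learningRate Adam learning rate (default 0.01).
#' @param batchSize sequences per gradient step (default 8).
#' @param seed integer RNG seed (default 1).
#' @return numeric vector of scores in (0, 1), one per test sequence.
#' @seealso [aucScore()]
#' @export
downstreamClassifier <- function(trainData, trainLabels, testData,
                                 hiddenSize = 16, epochs = 30,
                                 learningRate = 0.01, batchSize = 8,
                                 seed = 1) {
  if (length(trainData) != length(trainLabels)) {
    stop("trainLabels must have one entry per training sequence")
  }
  y <- as.numeric(trainLabels)
  std <- standardizeDataset(trainData)
  tr <- lapply(std$dataset, seriesValues)
  te <- lapply(testData, function(s) {
    (seriesValues(s) - std$center) / std$scale
  })
  d <- nrow(tr[[1L]])
  h <- as.integer(hiddenSize)
  set.seed(seed)
  cell <- .plist_random(d, h)
  w <- stats::rnorm(h, sd = 1 / sqrt(h))
  b <- 0
  opt <- .adam_init(list(cell = cell, w = w, b = b))
  n <- length(tr)

  fwd_last <- function(X, want_cache = FALSE) {
    zl <- matrix(0, d, ncol(X)) # zero lags: plain GRU
    cache <- .grui_fwd_cache(X, zl, cell, seq_len(ncol(X)))
    if (want_cache) cache else cache$H[, ncol(X)]
  }

  for (epoch in seq_len(epochs)) {
    order <- sample.int(n)
    for (start in seq(1L, n, by = batchSize)) {
      batch <- order[start:min(start + batchSize - 1L, n)]
      gc_sum <- NULL
      gw <- 0 * w
      gb <- 0
      for (i in batch) {
        X <- tr[[i]]
        cache <- fwd_last(X, want_cache = TRUE)
        hT <- cache$H[, ncol(X)]
        p <- .sigmoid(sum(w * hT) + b)
        dlogit <- p - y[i]
        gw <- gw + dlogit * hT
        gb <- gb + dlogit
        dH <- matrix(0, h, ncol(X))
        dH[, ncol(X)] <- dlogit * w
        bk <- .grui_bwd(dH, cache, cell)
        gc_sum <- .grad_add(gc_sum, bk$grads)
      }
      k <- length(batch)
      upd <- .adam_step(
        list(cell = cell, w = w, b = b),
        list(cell = .grad_scale(gc_sum, 1 / k), w = gw / k, b = gb / k),
        opt, learningRate
      )
      cell <- upd$params$cell
      w <- upd$params$w
      b <- upd$params$b
      opt <- upd$opt
    }
  }
  vapply(te, function(X) .sigmoid(sum(w * fwd_last(X)) + b), numeric(1),
    USE.NAMES = FALSE
  )
}
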