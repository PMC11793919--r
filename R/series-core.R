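#' Binary observation mask
#'
#' Builds the mask matrix M from a value matrix: `M[d, i] = 1` where
#' `values[d, i]` is a finite observation and 0 where it is missing
#' (`NA`/`NaN`).
#'
#' @param values numeric D x T matrix, missing entries `NA`.
#' @return numeric D x T matrix of 0/1.
#' @examples
#' buildMask(matrix(c(2, NA, 5), 1))
#' @export
buildMask <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("values must have at least one feature and one timestep")
  }
  m <- matrix(as.numeric(is.finite(values)), nrow(values), ncol(values))
  dimnames(m) <- dimnames(values)
  m
}

.check_lag_args <- function(mask, timestamps) {
  mask <- as.matrix(mask)
  if (length(timestamps) != ncol(mask)) {
    stop(sprintf(
      "timestamps length (%d) must equal the number of timesteps (%d)",
      length(timestamps), ncol(mask)
    ))
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  mask
}

#' Forward time-lag matrix
#'
#' For each feature d and time index i, the elapsed time since feature d
#' was last observed, accumulated across runs of missing values:
#' 0 at i = 1; `t_i - t_{i-1}` when the feature was observed at i-1;
#' otherwise the previous lag plus `t_i - t_{i-1}`.  Note the recursion
#' looks at the mask of the *previous* step, so the lag at an observed
#' position can still exceed one sampling interval.
#'
#' @param mask numeric D x T matrix of 0/1 (see [buildMask()]).
#' @param timestamps numeric vector of length T, strictly increasing.
#' @return numeric D x T matrix of nonnegative lags.
#' @seealso [backwardTimeLag()], [timeLags()]
#' @examples
#' m <- rbind(c(1, 0, 0, 1, 1), c(1, 1, 0, 0, 0), c(0, 1, 0, 1, 1))
#' forwardTimeLag(m, c(0, 3, 5, 8, 12))
#' @export
forwardTimeLag <- function(mask, timestamps) {
  mask <- .check_lag_args(mask, timestamps)
  d <- nrow(mask)
  tt <- ncol(mask)
  lag <- matrix(0, d, tt)
  if (tt > 1L) {
    gaps <- diff(timestamps)
    for (i in 2:tt) {
      gi <- gaps[i - 1L]
      lag[, i] <- ifelse(mask[, i - 1L] == 1, gi, lag[, i - 1L] + gi)
    }
  }
  lag
}

#' Backward time-lag matrix
#'
#' Mirror image of [forwardTimeLag()]: time until the next observation
#' of each feature, accumulated backwards across missing runs, with base
#' case 0 at i = T.
#'
#' @inheritParams forwardTimeLag
#' @return numeric D x T matrix of nonnegative lags.
#' @examples
#' m <- rbind(c(1, 0, 0, 1, 1), c(1, 1, 0, 0, 0), c(0, 1, 0, 1, 1))
#' backwardTimeLag(m, c(0, 3, 5, 8, 12))
#' @export
backwardTimeLag <- function(mask, timestamps) {
  mask <- .check_lag_args(mask, timestamps)
  d <- nrow(mask)
  tt <- ncol(mask)
  lag <- matrix(0, d, tt)
  if (tt > 1L) {
    gaps <- diff(timestamps)
    for (i in (tt - 1L):1L) {
      gi <- gaps[i]
      lag[, i] <- ifelse(mask[, i + 1L] == 1, gi, lag[, i + 1L] + gi)
    }
  }
  lag
}

#' Both time-lag matrices of a series
#'
#' @param x An [IncompleteSeries-class] object.
#' @return A [TimeLagPair-class] with the forward and backward lag
#'   matrices.
#' @rdname timeLags
#' @examples
#' s <- IncompleteSeries(matrix(c(1, NA, 3), 1), timestamps = c(0, 2, 5))
#' timeLags(s)
#' @export
setMethod("timeLags", "IncompleteSeries", function(x) {
  new("TimeLagPair",
    deltaF = forwardTimeLag(x@mask, x@timestamps),
    deltaB = backwardTimeLag(x@mask, x@timestamps)
  )
})

#' Reverse the time axis of a series
#'
#' Reverses the column order of values and mask and reflects the
#' timestamps so they remain strictly increasing and start at 0:
#' `t'_j = t_T - t_{T+1-j}`.  Applying it twice restores the original
#' series.  Used internally by the backward recurrent pass.
#'
#' @param x An [IncompleteSeries-class] object.
#' @return The time-reversed [IncompleteSeries-class].
#' @rdname reverseTime
#' @examples
#' s <- IncompleteSeries(matrix(1:3, 1), timestamps = c(0, 3, 5))
#' seriesTimestamps(reverseTime(s))  # 0 2 5
#' @export
setMethod("reverseTime", "IncompleteSeries", function(x) {
  tt <- ncol(x@values)
  idx <- tt:1L
  ts <- x@timestamps
  new("IncompleteSeries",
    values = x@values[, idx, drop = FALSE],
    mask = x@mask[, idx, drop = FALSE],
    timestamps = ts[tt] - ts[idx],
    featureNames = x@featureNames
  )
})

#' Standardize a dataset of incomplete series
#'
#' Z-scores every feature using the mean and population (1/n) standard
#' deviation of its *observed* entries pooled across all sequences.
#' Masks and timestamps are untouched.  A feature with constant
#' observed values gets scale 1
#' (so it maps to all zeros rather than dividing by zero).  The returned
#' transform lets imputed output be mapped back to original units with
#' [unstandardizeValues()].
#'
#' @param dataset a list of [IncompleteSeries-class] objects sharing the
#'   same features, or a single series.
#' @return A list with elements `dataset` (standardized series),
#'   `center` and `scale` (named numeric vectors of length D).
#' @examples
#' s <- IncompleteSeries(matrix(c(2, NA, 4), 1))
#' standardizeDataset(list(s))$center
#' @export
standardizeDataset <- function(dataset) {
  if (is(dataset, "IncompleteSeries")) dataset <- list(dataset)
  stopifnot(length(dataset) >= 1L)
  d <- nFeatures(dataset[[1L]])
  fn <- featureNames(dataset[[1L]])
  allv <- do.call(cbind, lapply(dataset, seriesValues))
  n_obs <- rowSums(is.finite(allv))
  if (any(n_obs == 0L)) {
    stop(
      "feature(s) with no observed entries in the whole dataset: ",
      paste(fn[n_obs == 0L], collapse = ", ")
    )
  }
  center <- rowMeans(allv, na.rm = TRUE)
  scale <- sqrt(rowMeans((allv - center)^2, na.rm = TRUE))
  scale[!is.finite(scale) | scale == 0] <- 1
  names(center) <- names(scale) <- fn
  out <- lapply(dataset, function(s) {
    v <- (seriesValues(s) - center) / scale
    new("IncompleteSeries",
      values = v, mask = seriesMask(s),
      timestamps = seriesTimestamps(s), featureNames = featureNames(s)
    )
  })
  list(dataset = out, center = center, scale = scale)
}

#' Map standardized values back to original units
#'
#' @param values numeric D x T matrix in standardized units.
#' @param transform list with `center` and `scale` as returned by
#'   [standardizeDataset()].
#' @return numeric D x T matrix in original units.
#' @export
unstandardizeValues <- function(values, transform) {
  values * transform$scale + transform$center
}
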