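#' Incomplete multivariate time series
#'
#' Container for one irregularly sampled multivariate sequence with
#' missing entries.  Values are stored features-by-time (D x T) with
#' `NA` as the missing sentinel; the binary mask has a 1 exactly where a
#' value is observed; timestamps are strictly increasing and start at 0.
#'
#' @slot values numeric D x T matrix, `NA` where missing.
#' @slot mask numeric D x T matrix of 0/1, 1 = observed.
#' @slot timestamps numeric vector of length T, strictly increasing,
#'   first element 0, in arbitrary time units.
#' @slot featureNames character vector of length D.
#'
#' @seealso [IncompleteSeries()] for construction, [timeLags()],
#'   [reverseTime()], [standardizeDataset()]
#' @export
setClass("IncompleteSeries",
  representation(
    values = "matrix",
    mask = "matrix",
    timestamps = "numeric",
    featureNames = "character"
  )
)

setValidity("IncompleteSeries", function(object) {
  v <- object@values
  m <- object@mask
  ts <- object@timestamps
  msgs <- character()
  if (nrow(v) < 1L || ncol(v) < 1L) {
    msgs <- c(msgs, "values must have at least 1 feature and 1 timestep")
  }
  if (!identical(dim(v), dim(m))) {
    msgs <- c(msgs, "mask and values dimensions differ")
  } else {
    if (!all(m %in% c(0, 1))) {
      msgs <- c(msgs, "mask entries must be 0 or 1")
    } else if (!all((m == 1) == is.finite(v))) {
      msgs <- c(msgs, "mask must be 1 exactly where values are finite and 0 where NA")
    }
  }
  if (length(ts) != ncol(v)) {
    msgs <- c(msgs, "timestamps length must equal the number of timesteps")
  } else {
    if (length(ts) >= 1L && !isTRUE(all.equal(ts[1L], 0))) {
      msgs <- c(msgs, "timestamps must start at 0")
    }
    if (length(ts) > 1L && any(diff(ts) <= 0)) {
      msgs <- c(msgs, "timestamps must be strictly increasing")
    }
  }
  if (length(object@featureNames) != nrow(v)) {
    msgs <- c(msgs, "featureNames length must equal the number of features")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an incomplete series
#'
#' @param values numeric D x T matrix with `NA` marking missing entries.
#' @param timestamps optional numeric vector of length T; strictly
#'   increasing, first element 0.  Defaults to unit spacing
#'   `0, 1, ..., T-1` when the data carry no explicit time axis.
#' @param featureNames optional character vector of length D; defaults
#'   to the rownames of `values` or `"V1", "V2", ...`.
#' @return An [IncompleteSeries-class] object.
#' @examples
#' x <- matrix(c(2, NA, NA, 5, 9,
#'               3, 8, NA, NA, NA,
#'               NA, 6, NA, 10, 1), nrow = 3, byrow = TRUE)
#' s <- IncompleteSeries(x, timestamps = c(0, 3, 5, 8, 12))
#' seriesMask(s)
#' @export
IncompleteSeries <- function(values, timestamps = NULL, featureNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(timestamps)) {
    timestamps <- seq_len(ncol(values)) - 1
  }
  if (is.null(featureNames)) {
    featureNames <- rownames(values)
    if (is.null(featureNames)) {
      featureNames <- paste0("V", seq_len(nrow(values)))
    }
  }
  new("IncompleteSeries",
    values = values,
    mask = buildMask(values),
    timestamps = as.numeric(timestamps),
    featureNames = as.character(featureNames)
  )
}

#' @rdname series-accessors
#' @export
setMethod("seriesValues", "IncompleteSeries", function(x) x@values)

#' @rdname series-accessors
#' @export
setMethod("seriesMask", "IncompleteSeries", function(x) x@mask)

#' @rdname series-accessors
#' @export
setMethod("seriesTimestamps", "IncompleteSeries", function(x) x@timestamps)

#' @rdname series-accessors
#' @export
setMethod("featureNames", "IncompleteSeries", function(x) x@featureNames)

#' @rdname series-dims
#' @export
setMethod("nFeatures", "IncompleteSeries", function(x) nrow(x@values))

#' @rdname series-dims
#' @export
setMethod("nTimesteps", "IncompleteSeries", function(x) ncol(x@values))

setMethod("show", "IncompleteSeries", function(object) {
  d <- nrow(object@values)
  tt <- ncol(object@values)
  obs <- sum(object@mask)
  cat(sprintf(
    "IncompleteSeries: %d feature%s x %d timestep%s\n",
    d, if (d == 1L) "" else "s", tt, if (tt == 1L) "" else "s"
  ))
  cat(sprintf(
    "  observed: %d/%d entries (%.1f%% missing)\n",
    obs, d * tt, 100 * (1 - obs / (d * tt))
  ))
  cat(sprintf(
    "  time span: [%g, %g]\n",
    object@timestamps[1L], object@timestamps[tt]
  ))
  invisible(object)
})

#' Forward/backward time-lag pair
#'
#' Holds the forward time-lag matrix (elapsed time since the most recent
#' observation of each feature) and the backward time-lag matrix (time
#' until the next observation), both D x T.
#'
#' @slot deltaF numeric D x T matrix, nonnegative; column 1 is zero.
#' @slot deltaB numeric D x T matrix, nonnegative; column T is zero.
#' @seealso [timeLags()], [forwardTimeLag()], [backwardTimeLag()]
#' @export
setClass("TimeLagPair",
  representation(deltaF = "matrix", deltaB = "matrix")
)

setValidity("TimeLagPair", function(object) {
  f <- object@deltaF
  b <- object@deltaB
  msgs <- character()
  if (!identical(dim(f), dim(b))) {
    msgs <- c(msgs, "deltaF and deltaB dimensions differ")
  }
  if (any(f < 0) || any(b < 0)) {
    msgs <- c(msgs, "time lags must be nonnegative")
  }
  if (ncol(f) >= 1L && any(f[, 1L] != 0)) {
    msgs <- c(msgs, "deltaF column 1 must be zero")
  }
  if (ncol(b) >= 1L && any(b[, ncol(b)] != 0)) {
    msgs <- c(msgs, "deltaB last column must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TimeLagPair", function(object) {
  cat(sprintf(
    "TimeLagPair: %d x %d, max forward lag %g, max backward lag %g\n",
    nrow(object@deltaF), ncol(object@deltaF),
    max(object@deltaF), max(object@deltaB)
  ))
  invisible(object)
})

#' @describeIn TimeLagPair-class forward lag matrix accessor.
#' @param x A `TimeLagPair`.
#' @export
deltaF <- function(x) x@deltaF

#' @describeIn TimeLagPair-class backward lag matrix accessor.
#' @export
deltaB <- function(x) x@deltaB
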