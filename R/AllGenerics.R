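#' @import methods
NULL

#' Accessors for incomplete time series
#'
#' Extract the value matrix (features x timesteps, missing entries `NA`),
#' the binary mask (1 = observed, 0 = missing), the timestamp vector, or
#' the feature names of an [IncompleteSeries-class] object.
#'
#' @param x An `IncompleteSeries` object.
#' @return `seriesValues` and `seriesMask` return a D x T matrix;
#'   `seriesTimestamps` a numeric vector of length T; `featureNames` a
#'   character vector of length D.
#' @aliases seriesValues seriesMask seriesTimestamps featureNames
#' @seealso [IncompleteSeries()]
#' @name series-accessors
#' @examples
#' s <- IncompleteSeries(matrix(c(1, NA, 3, 4), 2, 2))
#' seriesValues(s)
#' seriesMask(s)
NULL

#' @rdname series-accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname series-accessors
#' @export
setGeneric("seriesMask", function(x) standardGeneric("seriesMask"))

#' @rdname series-accessors
#' @export
setGeneric("seriesTimestamps", function(x) standardGeneric("seriesTimestamps"))

#' @rdname series-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Number of features / timesteps
#'
#' @param x An `IncompleteSeries` object.
#' @return An integer scalar.
#' @aliases nFeatures nTimesteps
#' @name series-dims
NULL

#' @rdname series-dims
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname series-dims
#' @export
setGeneric("nTimesteps", function(x) standardGeneric("nTimesteps"))

#' @rdname reverseTime
#' @export
setGeneric("reverseTime", function(x) standardGeneric("reverseTime"))

#' @rdname timeLags
#' @export
setGeneric("timeLags", function(x) standardGeneric("timeLags"))
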