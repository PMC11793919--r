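#' Read one series from a wide CSV
#'
#' Expects one row per timestamp and one column per feature; empty cells
#' are missing.  A column named `time` (case-insensitive), when present,
#' supplies the timestamps and is re-zeroed to start at 0; otherwise
#' unit spacing is assumed.
#'
#' @param path path to a CSV file.
#' @return An [IncompleteSeries-class] object.
#' @seealso [writeSeriesCSV()], [readSeriesDataset()]
#' @export
readSeriesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L) stop("no rows in ", path)
  cn <- names(df)
  tcol <- which(tolower(cn) == "time")
  if (length(tcol) > 1L) stop("multiple time columns in ", path)
  if (length(tcol) == 1L) {
    ts <- as.numeric(df[[tcol]])
    ts <- ts - ts[1L]
    df <- df[, -tcol, drop = FALSE]
  } else {
    ts <- seq_len(nrow(df)) - 1
  }
  if (ncol(df) < 1L) stop("no feature columns in ", path)
  v <- t(as.matrix(df))
  storage.mode(v) <- "double"
  IncompleteSeries(v, timestamps = ts, featureNames = names(df))
}

#' Write one series to a wide CSV
#'
#' Inverse of [readSeriesCSV()]: first column `time`, one column per
#' feature, missing entries written as empty cells.
#'
#' @param x An [IncompleteSeries-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeriesCSV <- function(x, path) {
  df <- data.frame(time = seriesTimestamps(x), t(seriesValues(x)),
    check.names = FALSE
  )
  names(df) <- c("time", featureNames(x))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a multi-sequence dataset
#'
#' Two dialects are supported.  A *directory* is read as one wide CSV
#' per sequence (alphabetical order).  A *file* is read as a long CSV
#' with a sequence-id column (default `sequence`); each id's rows form
#' one sequence, in file order, with the same wide layout otherwise.
#'
#' @param path directory of per-sequence CSVs, or a long CSV file.
#' @param idColumn name of the sequence-id column in the long dialect.
#' @return A named list of [IncompleteSeries-class] objects.
#' @export
readSeriesDataset <- function(path, idColumn = "sequence") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no .csv files in directory ", path)
    out <- lapply(files, readSeriesCSV)
    names(out) <- sub("\\.csv$", "", basename(files))
    return(out)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!idColumn %in% names(df)) {
    stop(
      "long CSV must contain a '", idColumn, "' column; found: ",
      paste(names(df), collapse = ", ")
    )
  }
  ids <- unique(df[[idColumn]])
  out <- lapply(ids, function(id) {
    sub <- df[df[[idColumn]] == id, setdiff(names(df), idColumn),
      drop = FALSE
    ]
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    utils::write.csv(sub, tmp, row.names = FALSE, na = "")
    readSeriesCSV(tmp)
  })
  names(out) <- as.character(ids)
  out
}

#' Write a multi-sequence dataset
#'
#' @param dataset named list of [IncompleteSeries-class] objects.
#' @param path output directory (created if absent); one
#'   `<name>.csv` per sequence.
#' @return `path`, invisibly.
#' @export
writeSeriesDataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nm <- names(dataset)
  if (is.null(nm)) nm <- sprintf("seq%03d", seq_along(dataset))
  for (i in seq_along(dataset)) {
    writeSeriesCSV(dataset[[i]], file.path(path, paste0(nm[i], ".csv")))
  }
  invisible(path)
}
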