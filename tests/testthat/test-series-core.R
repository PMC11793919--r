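test_that("mask construction flags observed entries and rejects empties", {
  m <- buildMask(example_values())
  expect_identical(m, rbind(
    c(1, 0, 0, 1, 1),
    c(1, 1, 0, 0, 0),
    c(0, 1, 0, 1, 1)
  ))
  expect_identical(buildMask(matrix(1:6 / 2, 2, 3)), matrix(1, 2, 3))
  expect_identical(
    buildMask(matrix(NA_real_, 1, 4)),
    matrix(0, 1, 4)
  )
  expect_error(buildMask(matrix(numeric(), 0, 0)), "at least one")
})

test_that("forward and backward lags reproduce the worked example", {
  lg <- timeLags(example_series())
  expect_identical(deltaF(lg), rbind(
    c(0, 3, 5, 8, 4),
    c(0, 3, 2, 5, 9),
    c(0, 3, 2, 5, 4)
  ))
  expect_identical(deltaB(lg), rbind(
    c(8, 5, 3, 4, 0),
    c(3, 9, 7, 4, 0),
    c(3, 5, 3, 4, 0)
  ))
})

test_that("fully observed masks give consecutive-gap lags", {
  expect_equal(
    forwardTimeLag(matrix(1, 2, 3), c(0, 1, 2)),
    rbind(c(0, 1, 1), c(0, 1, 1))
  )
  expect_equal(
    backwardTimeLag(matrix(1, 2, 3), c(0, 2, 5)),
    rbind(c(2, 3, 0), c(2, 3, 0))
  )
})

test_that("lag construction validates its arguments", {
  expect_error(forwardTimeLag(matrix(1, 2, 3), c(0, 1)), "length")
  expect_error(forwardTimeLag(matrix(1, 1, 3), c(0, 2, 2)), "increasing")
  expect_error(backwardTimeLag(matrix(1, 1, 3), c(0, 3, 1)), "increasing")
})

# Independent oracle: the per-entry recursion written out directly.
naive_forward_lag <- function(mask, ts) {
  d <- nrow(mask)
  tt <- ncol(mask)
  out <- matrix(0, d, tt)
  for (f in seq_len(d)) {
    for (i in seq_len(tt)) {
      if (i == 1) {
        out[f, i] <- 0
      } else if (mask[f, i - 1] == 1) {
        out[f, i] <- ts[i] - ts[i - 1]
      } else {
        out[f, i] <- out[f, i - 1] + ts[i] - ts[i - 1]
      }
    }
  }
  out
}

test_that("forward lag matches a step-by-step recursion oracle", {
  set.seed(101)
  for (k in 1:20) {
    m <- matrix(rbinom(32, 1, 0.5), 4, 8)
    ts <- c(0, cumsum(sample(1:4, 7, replace = TRUE)))
    expect_equal(forwardTimeLag(m, ts), naive_forward_lag(m, ts))
  }
})

test_that("backward lag is the time-reversal of the forward lag", {
  set.seed(202)
  for (k in 1:200) {
    d <- sample(1:5, 1)
    tt <- sample(1:10, 1)
    m <- matrix(rbinom(d * tt, 1, runif(1, 0.2, 0.9)), d, tt)
    ts <- if (tt == 1) 0 else c(0, cumsum(0.1 + rexp(tt - 1)))
    rev_ts <- ts[tt] - rev(ts)
    rev_m <- m[, tt:1, drop = FALSE]
    oracle <- forwardTimeLag(rev_m, rev_ts)[, tt:1, drop = FALSE]
    expect_equal(backwardTimeLag(m, ts), oracle)
  }
})

test_that("lags are nonnegative, span-bounded, and shift-invariant", {
  set.seed(303)
  for (k in 1:25) {
    s <- random_series()
    lg <- timeLags(s)
    span <- max(seriesTimestamps(s))
    expect_true(all(deltaF(lg) >= 0) && all(deltaF(lg) <= span))
    expect_true(all(deltaB(lg) >= 0) && all(deltaB(lg) <= span))
    # adding a constant to all timestamps and re-zeroing changes nothing
    ts2 <- seriesTimestamps(s) + 5
    ts2 <- ts2 - ts2[1]
    expect_equal(forwardTimeLag(seriesMask(s), ts2), deltaF(lg))
    expect_equal(backwardTimeLag(seriesMask(s), ts2), deltaB(lg))
  }
})

test_that("time reversal reflects timestamps and is an involution", {
  s <- example_series()
  r <- reverseTime(s)
  expect_equal(seriesTimestamps(r), c(0, 4, 7, 9, 12))
  expect_equal(seriesValues(r), example_values()[, 5:1])
  rr <- reverseTime(r)
  expect_equal(seriesValues(rr), seriesValues(s))
  expect_equal(seriesTimestamps(rr), seriesTimestamps(s))
  s1 <- IncompleteSeries(matrix(3.5, 1, 1))
  expect_equal(seriesValues(reverseTime(s1)), seriesValues(s1))
})

test_that("series validity catches malformed objects", {
  expect_error(
    IncompleteSeries(matrix(1:4, 2), timestamps = c(1, 2)),
    "start at 0"
  )
  expect_error(
    IncompleteSeries(matrix(1:4, 2), timestamps = c(0, 0)),
    "strictly increasing"
  )
  expect_error(
    new("IncompleteSeries",
      values = matrix(c(1, NA), 1), mask = matrix(c(1, 1), 1),
      timestamps = c(0, 1), featureNames = "a"
    ),
    "mask"
  )
})

test_that("standardization z-scores observed entries and round-trips", {
  s <- IncompleteSeries(matrix(c(2, NA, 4), 1))
  std <- standardizeDataset(list(s))
  v <- seriesValues(std$dataset[[1]])
  expect_equal(v[is.finite(v)], c(-1, 1))
  expect_equal(unname(std$center), 3)
  # constant feature: no division error, all zeros
  sc <- IncompleteSeries(matrix(c(5, 5, NA), 1))
  stdc <- standardizeDataset(list(sc))
  expect_equal(
    seriesValues(stdc$dataset[[1]])[1, 1:2],
    c(0, 0)
  )
  # round trip
  set.seed(404)
  ds <- replicate(3, random_series(), simplify = FALSE)
  std2 <- standardizeDataset(ds)
  back <- unstandardizeValues(
    seriesValues(std2$dataset[[2]]), std2[c("center", "scale")]
  )
  orig <- seriesValues(ds[[2]])
  expect_lt(max(abs(back[is.finite(orig)] - orig[is.finite(orig)])), 1e-10)
})

test_that("standardization names a feature with no observations", {
  s <- IncompleteSeries(
    matrix(c(1, 2, NA, NA), 2, byrow = TRUE),
    featureNames = c("hr", "bp")
  )
  expect_error(standardizeDataset(list(s)), "bp")
})

test_that("wide CSV round-trips values, mask and timestamps", {
  s <- example_series()
  path <- tempfile(fileext = ".csv")
  writeSeriesCSV(s, path)
  s2 <- readSeriesCSV(path)
  expect_equal(seriesValues(s2), seriesValues(s), ignore_attr = TRUE)
  expect_equal(seriesTimestamps(s2), seriesTimestamps(s))
  expect_equal(seriesMask(s2), seriesMask(s), ignore_attr = TRUE)
  unlink(path)
})

test_that("dataset IO supports directory and long-CSV dialects", {
  set.seed(505)
  ds <- list(a = random_series(2, 5), b = random_series(2, 7))
  dir <- tempfile()
  writeSeriesDataset(ds, dir)
  ds2 <- readSeriesDataset(dir)
  expect_named(ds2, c("a", "b"))
  expect_equal(seriesValues(ds2$b), seriesValues(ds$b), ignore_attr = TRUE)
  # long dialect
  long <- do.call(rbind, lapply(names(ds), function(nm) {
    data.frame(
      sequence = nm, time = seriesTimestamps(ds[[nm]]),
      t(seriesValues(ds[[nm]]))
    )
  }))
  lpath <- tempfile(fileext = ".csv")
  write.csv(long, lpath, row.names = FALSE, na = "")
  ds3 <- readSeriesDataset(lpath)
  expect_equal(seriesValues(ds3$a), seriesValues(ds$a), ignore_attr = TRUE)
  expect_equal(seriesTimestamps(ds3$b), seriesTimestamps(ds$b))
  unlink(c(lpath, dir), recursive = TRUE)
})
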