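# Shared fixtures, built in code.

# The 3-feature, 5-timestep incomplete matrix with timestamps
# (0, 3, 5, 8, 12) used throughout as a small worked example.
example_values <- function() {
  matrix(c(
    2, NA, NA, 5, 9,
    3, 8, NA, NA, NA,
    NA, 6, NA, 10, 1
  ), nrow = 3, byrow = TRUE)
}

example_timestamps <- function() c(0, 3, 5, 8, 12)

example_series <- function() {
  IncompleteSeries(example_values(), timestamps = example_timestamps())
}

# Random incomplete series with at least one observation per feature.
random_series <- function(d = 4, tt = 8, missing_rate = 0.3,
                          irregular = TRUE) {
  repeat {
    v <- matrix(rnorm(d * tt), d, tt)
    drop_idx <- runif(d * tt) < missing_rate
    v[drop_idx] <- NA_real_
    if (all(rowSums(is.finite(v)) >= 1)) break
  }
  ts <- if (irregular) {
    c(0, cumsum(0.1 + rexp(tt - 1)))
  } else {
    seq_len(tt) - 1
  }
  IncompleteSeries(v, timestamps = ts)
}

# Tiny seeded dataset for pipeline tests.
tiny_dataset <- function(n = 4, d = 3, tt = 12, rate = 0.25, seed = 7) {
  sim <- generateComplete(simConfig(
    nSequences = n, nFeatures = d, nTimesteps = tt, seed = seed
  ))
  applyMissingness(sim, rate, seed = seed + 1L)
}

# Small training configuration for fast tests; any trainConfig()
# argument can be overridden.
tiny_config <- function(...) {
  defaults <- list(
    hiddenSize = 6, batchSize = 2, learningRate = 0.01,
    pretrainEpochs = 1, epochs = 1, refineIterations = 0, seed = 11
  )
  do.call(trainConfig, utils::modifyList(defaults, list(...)))
}
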