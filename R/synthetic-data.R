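#' Synthetic-data configuration
#'
#' Parameters of the synthetic study system: a stationary first-order
#' vector autoregression, VAR(1), with exchangeable cross-feature
#' innovation correlation, an optional sinusoidal seasonal component on
#' the last feature, and (optionally) irregular sampling times drawn as
#' cumulative sums of shifted-exponential gaps.
#'
#' @slot nSequences number of sequences.
#' @slot nFeatures number of features D.
#' @slot nTimesteps number of timesteps T per sequence.
#' @slot arCoefficient AR(1) coefficient, in (-1, 1) for stationarity.
#' @slot crossCorr exchangeable innovation correlation, in [0, 1].
#' @slot noiseSd innovation standard deviation, positive.
#' @slot seasonalAmplitude amplitude of the sinusoid added to the last
#'   feature (only when D >= 2; 0 disables it).
#' @slot seasonalPeriod period of the sinusoid in time units.
#' @slot irregular logical; irregular sampling times when TRUE.
#' @slot missingRate default missing rate for [applyMissingness()].
#' @slot labelRule numeric length-D logistic weights for
#'   [generateLabels()] (may be empty).
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [generateComplete()]
#' @export
setClass("SimConfig",
  representation(
    nSequences = "integer",
    nFeatures = "integer",
    nTimesteps = "integer",
    arCoefficient = "numeric",
    crossCorr = "numeric",
    noiseSd = "numeric",
    seasonalAmplitude = "numeric",
    seasonalPeriod = "numeric",
    irregular = "logical",
    missingRate = "numeric",
    labelRule = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nSequences < 1L) msgs <- c(msgs, "nSequences must be >= 1")
  if (object@nFeatures < 1L) msgs <- c(msgs, "nFeatures must be >= 1")
  if (object@nTimesteps < 1L) msgs <- c(msgs, "nTimesteps must be >= 1")
  if (abs(object@arCoefficient) >= 1) {
    msgs <- c(msgs, "arCoefficient must lie in (-1, 1) for stationarity")
  }
  if (object@crossCorr < 0 || object@crossCorr > 1) {
    msgs <- c(msgs, "crossCorr must lie in [0, 1]")
  }
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be positive")
  if (object@seasonalAmplitude < 0) {
    msgs <- c(msgs, "seasonalAmplitude must be >= 0")
  }
  if (object@seasonalPeriod <= 0) {
    msgs <- c(msgs, "seasonalPeriod must be positive")
  }
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msgs <- c(msgs, "missingRate must lie in [0, 1)")
  }
  if (length(object@labelRule) &&
    length(object@labelRule) != object@nFeatures) {
    msgs <- c(msgs, "labelRule must have length nFeatures")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0(
      "SimConfig: %d sequences, %d features x %d timesteps\n",
      "  VAR(1) a = %.2f, cross-corr %.2f, innovation sd %.2f, %s sampling\n"
    ),
    object@nSequences, object@nFeatures, object@nTimesteps,
    object@arCoefficient, object@crossCorr, object@noiseSd,
    if (object@irregular) "irregular" else "unit-spaced"
  ))
  invisible(object)
})

#' Create a synthetic-data configuration
#'
#' @param nSequences,nFeatures,nTimesteps dataset dimensions.
#' @param arCoefficient AR(1) coefficient in (-1, 1) (default 0.8:
#'   strong temporal autocorrelation, the regime where recurrent
#'   imputation has signal to exploit).
#' @param crossCorr exchangeable innovation correlation (default 0.3).
#' @param noiseSd innovation standard deviation (default 1).
#' @param seasonalAmplitude sinusoid amplitude on the last feature when
#'   D >= 2 (default 0.5).
#' @param seasonalPeriod sinusoid period in time units (default 12).
#' @param irregular irregular sampling times (default TRUE).
#' @param missingRate default MCAR rate (default 0.2).
#' @param labelRule optional logistic weight vector of length D.
#' @param seed integer RNG seed (default 1).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nSequences = 20, nFeatures = 5, nTimesteps = 48,
                      arCoefficient = 0.8, crossCorr = 0.3, noiseSd = 1,
                      seasonalAmplitude = 0.5, seasonalPeriod = 12,
                      irregular = TRUE, missingRate = 0.2,
                      labelRule = numeric(), seed = 1) {
  new("SimConfig",
    nSequences = as.integer(nSequences),
    nFeatures = as.integer(nFeatures),
    nTimesteps = as.integer(nTimesteps),
    arCoefficient = as.numeric(arCoefficient),
    crossCorr = as.numeric(crossCorr),
    noiseSd = as.numeric(noiseSd),
    seasonalAmplitude = as.numeric(seasonalAmplitude),
    seasonalPeriod = as.numeric(seasonalPeriod),
    irregular = isTRUE(irregular),
    missingRate = as.numeric(missingRate),
    labelRule = as.numeric(labelRule),
    seed = as.integer(seed)
  )
}

# minimum gap of the shifted-exponential sampling-time model
.MIN_GAP <- 0.1

#' Generate fully observed synthetic series
#'
#' Each sequence follows a latent VAR(1), `x_t = a x_{t-1} + e_t`, with
#' innovations `e_t ~ N(0, Sigma)` where `Sigma` has exchangeable
#' correlation `crossCorr` and standard deviation `noiseSd`; the first
#' state is drawn from the stationary distribution.  When D >= 2 and
#' `seasonalAmplitude > 0`, a sinusoid of the configured period is added
#' to the last feature.  Irregular timestamps are cumulative sums of
#' `0.1 + Exp(mean 0.9)` gaps (strictly increasing, mean spacing 1);
#' otherwise unit spacing is used.  The whole draw is a pure function of
#' `config@seed`.
#'
#' @param config A [SimConfig-class] object.
#' @return named list of fully observed [IncompleteSeries-class]
#'   objects.
#' @export
generateComplete <- function(config) {
  validObject(config)
  set.seed(config@seed)
  d <- config@nFeatures
  tt <- config@nTimesteps
  a <- config@arCoefficient
  Sigma <- config@noiseSd^2 *
    ((1 - config@crossCorr) * diag(d) + config@crossCorr * matrix(1, d, d))
  L <- chol(Sigma) # upper triangular; t(L) %*% z gives N(0, Sigma)
  out <- vector("list", config@nSequences)
  for (s in seq_len(config@nSequences)) {
    ts <- if (config@irregular) {
      c(0, cumsum(.MIN_GAP + stats::rexp(tt - 1, rate = 1 / (1 - .MIN_GAP))))
    } else {
      seq_len(tt) - 1
    }
    x <- matrix(0, d, tt)
    x[, 1L] <- drop(crossprod(L, stats::rnorm(d))) / sqrt(1 - a^2)
    if (tt > 1L) {
      for (i in 2:tt) {
        x[, i] <- a * x[, i - 1L] + drop(crossprod(L, stats::rnorm(d)))
      }
    }
    if (d >= 2L && config@seasonalAmplitude > 0) {
      x[d, ] <- x[d, ] +
        config@seasonalAmplitude * sin(2 * pi * ts / config@seasonalPeriod)
    }
    out[[s]] <- IncompleteSeries(x, timestamps = ts)
  }
  names(out) <- sprintf("seq%03d", seq_len(config@nSequences))
  out
}

#' Remove entries at random, keeping the ground truth
#'
#' Masks each entry independently with probability `rate` (MCAR), or in
#' geometric bursts (`mechanism = "burst"`) whose stationary missing
#' fraction equals `rate` — the bursty variant stresses the accumulation
#' of time lags across consecutive missing values.  A sequence whose
#' draw would leave some feature entirely unobserved is redrawn (up to
#' 200 tries, after which one randomly chosen entry per empty feature is
#' put back).
#'
#' @param dataset list of fully observed [IncompleteSeries-class]
#'   objects.
#' @param rate missing rate in [0, 1).
#' @param seed integer RNG seed.
#' @param mechanism `"mcar"` (default) or `"burst"`.
#' @param meanBurst mean run length of missing bursts (burst mechanism).
#' @return list with `dataset` (incomplete series), `truth` (list of
#'   the original value matrices) and `evalMask` (list of 0/1 matrices,
#'   1 = entry removed, i.e. the held-out positions to score).
#' @export
applyMissingness <- function(dataset, rate, seed = 1,
                             mechanism = c("mcar", "burst"),
                             meanBurst = 3) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  set.seed(seed)
  inc <- vector("list", length(dataset))
  truth <- vector("list", length(dataset))
  emask <- vector("list", length(dataset))
  for (s in seq_along(dataset)) {
    v <- seriesValues(dataset[[s]])
    d <- nrow(v)
    tt <- ncol(v)
    for (try in seq_len(200L)) {
      rm_mask <- .draw_removal(d, tt, rate, mechanism, meanBurst)
      if (all(rowSums(1 - rm_mask) >= 1)) break
    }
    bad <- which(rowSums(1 - rm_mask) < 1)
    for (f in bad) rm_mask[f, sample.int(tt, 1L)] <- 0
    vv <- v
    vv[rm_mask == 1] <- NA_real_
    inc[[s]] <- new("IncompleteSeries",
      values = vv, mask = 1 - rm_mask,
      timestamps = seriesTimestamps(dataset[[s]]),
      featureNames = featureNames(dataset[[s]])
    )
    truth[[s]] <- v
    emask[[s]] <- rm_mask
  }
  names(inc) <- names(truth) <- names(emask) <- names(dataset)
  list(dataset = inc, truth = truth, evalMask = emask)
}

.draw_removal <- function(d, tt, rate, mechanism, meanBurst) {
  if (mechanism == "mcar" || rate == 0) {
    return(matrix(stats::rbinom(d * tt, 1L, rate), d, tt))
  }
  # two-state Markov chain per feature; missing runs ~ Geometric with
  # mean meanBurst; stationary missing fraction = rate
  p_exit <- 1 / meanBurst
  p_enter <- min(1, rate * p_exit / (1 - rate))
  m <- matrix(0L, d, tt)
  for (f in seq_len(d)) {
    state <- stats::rbinom(1L, 1L, rate)
    m[f, 1L] <- state
    if (tt > 1L) {
      for (i in 2:tt) {
        p <- if (state == 1L) 1 - p_exit else p_enter
        state <- stats::rbinom(1L, 1L, p)
        m[f, i] <- state
      }
    }
  }
  m
}

#' Generate binary labels from per-feature means
#'
#' `label ~ Bernoulli(sigmoid(w' m + e))` where `m` holds the
#' per-feature means over time of one sequence and `e ~ N(0, 0.5^2)`.
#' With zero weights labels are Bernoulli(0.5); a huge weight on a
#' feature with a consistent mean saturates the sigmoid.
#'
#' @param dataset list of [IncompleteSeries-class] objects (means are
#'   taken over observed entries).
#' @param labelRule numeric weight vector of length D.
#' @param seed integer RNG seed.
#' @param noiseSd latent noise standard deviation (default 0.5).
#' @return integer vector of 0/1 labels, one per sequence.
#' @export
generateLabels <- function(dataset, labelRule, seed = 1, noiseSd = 0.5) {
  if (!length(dataset)) stop("dataset must be nonempty")
  d <- nFeatures(dataset[[1L]])
  if (length(labelRule) != d) {
    stop(sprintf(
      "labelRule length (%d) must equal the number of features (%d)",
      length(labelRule), d
    ))
  }
  set.seed(seed)
  vapply(dataset, function(s) {
    m <- rowMeans(seriesValues(s), na.rm = TRUE)
    eta <- sum(labelRule * m) + stats::rnorm(1L, sd = noiseSd)
    stats::rbinom(1L, 1L, stats::plogis(eta))
  }, integer(1), USE.NAMES = FALSE)
}
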