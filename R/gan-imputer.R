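#' Generator and discriminator networks
#'
#' Both networks are (bi)directional GRUI stacks with a per-timestep
#' affine projection.  The generator projects the combined hidden state
#' to D outputs (one imputed value per feature); the discriminator
#' projects to D raw critic scores (one per feature per timestep, so it
#' discriminates at the granularity of the mask).  Internally the cells
#' and projections are stored as plain lists of numeric arrays; use
#' [generatorParams()] / [discriminatorParams()] to obtain
#' [GRUIParams-class] views.
#'
#' @slot generator list with elements `f`, `b` (GRUI cell parameter
#'   lists; `b` is NULL in unidirectional mode) and `proj` (affine map
#'   H -> D).
#' @slot discriminator same structure as `generator` (its `b` follows
#'   the same direction mode).
#' @slot direction `"uni"` or `"bi"`.
#' @slot hiddenSize,inputSize integer sizes.
#' @seealso [imputerNets()], [tbigainTrain()], [tbigainImpute()]
#' @export
setClass("ImputerNets",
  representation(
    generator = "list",
    discriminator = "list",
    direction = "character",
    hiddenSize = "integer",
    inputSize = "integer"
  )
)

setValidity("ImputerNets", function(object) {
  msgs <- character()
  if (!object@direction %in% c("uni", "bi")) {
    msgs <- c(msgs, "direction must be 'uni' or 'bi'")
  }
  d <- object@inputSize
  h <- object@hiddenSize
  for (side in c("generator", "discriminator")) {
    net <- slot(object, side)
    if (!all(c("f", "proj") %in% names(net))) {
      msgs <- c(msgs, sprintf("%s must contain 'f' and 'proj'", side))
      next
    }
    if (object@direction == "bi" && is.null(net$b)) {
      msgs <- c(msgs, sprintf("%s lacks a backward cell in 'bi' mode", side))
    }
    if (!identical(dim(net$proj$W), c(as.integer(d), as.integer(h)))) {
      msgs <- c(msgs, sprintf("%s projection must be %d x %d", side, d, h))
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ImputerNets", function(object) {
  cat(sprintf(
    "ImputerNets: %sdirectional GRUI, input %d, hidden %d\n",
    if (object@direction == "bi") "bi" else "uni",
    object@inputSize, object@hiddenSize
  ))
  invisible(object)
})

#' Initialize imputer networks
#'
#' @param inputSize number of features D.
#' @param hiddenSize recurrent hidden size H.
#' @param direction `"bi"` (default) or `"uni"`.
#' @return An [ImputerNets-class] object with randomly initialized
#'   weights (uses the current RNG state).
#' @export
imputerNets <- function(inputSize, hiddenSize, direction = c("bi", "uni")) {
  direction <- match.arg(direction)
  bi <- direction == "bi"
  new("ImputerNets",
    generator = .net_new(inputSize, hiddenSize, inputSize, bi),
    discriminator = .net_new(inputSize, hiddenSize, inputSize, bi),
    direction = direction,
    hiddenSize = as.integer(hiddenSize),
    inputSize = as.integer(inputSize)
  )
}

#' @describeIn ImputerNets-class generator cell parameters as
#'   [GRUIParams-class] (list of `forward` and possibly `backward`).
#' @param x An `ImputerNets` object.
#' @export
generatorParams <- function(x) {
  out <- list(forward = .l2p(x@generator$f))
  if (!is.null(x@generator$b)) out$backward <- .l2p(x@generator$b)
  out
}

#' @describeIn ImputerNets-class discriminator cell parameters as
#'   [GRUIParams-class].
#' @export
discriminatorParams <- function(x) {
  out <- list(forward = .l2p(x@discriminator$f))
  if (!is.null(x@discriminator$b)) out$backward <- .l2p(x@discriminator$b)
  out
}

#' Training configuration
#'
#' Hyperparameters of the adversarial imputer.  Defaults follow the
#' reference configuration for clinical time series: batch size 128,
#' hidden size 64, reconstruction weight `lambdaRecon = 0.15`, learning
#' rate 0.001, 5 pretraining epochs, 30 adversarial epochs, and 400
#' noise-refinement iterations per sequence at imputation time.
#'
#' @slot batchSize sequences per gradient step.
#' @slot hiddenSize recurrent hidden size of both networks.
#' @slot lambdaRecon weight of the reconstruction loss in the generator
#'   objective `L_G = L_adv + lambda * L_R`.
#' @slot learningRate Adam learning rate for both networks.
#' @slot pretrainEpochs generator-only reconstruction epochs.
#' @slot epochs adversarial training epochs.
#' @slot refineIterations gradient steps of per-sequence noise
#'   refinement at imputation time (0 disables refinement).
#' @slot divergence adversarial loss name (see
#'   [availableDivergences()]).
#' @slot direction `"bi"` or `"uni"`.
#' @slot seed integer seed controlling all randomness.
#' @slot dStepsPerGStep discriminator updates per generator update
#'   (5 is conventional for the Wasserstein critic, 1 otherwise).
#' @slot noiseSd standard deviation of the Gaussian noise filling
#'   missing slots of the generator input.
#' @seealso [trainConfig()]
#' @export
setClass("TrainConfig",
  representation(
    batchSize = "integer",
    hiddenSize = "integer",
    lambdaRecon = "numeric",
    learningRate = "numeric",
    pretrainEpochs = "integer",
    epochs = "integer",
    refineIterations = "integer",
    divergence = "character",
    direction = "character",
    seed = "integer",
    dStepsPerGStep = "integer",
    noiseSd = "numeric"
  )
)

setValidity("TrainConfig", function(object) {
  msgs <- character()
  counts <- c(
    "batchSize", "hiddenSize", "pretrainEpochs", "epochs",
    "refineIterations", "dStepsPerGStep"
  )
  for (nm in counts) {
    if (slot(object, nm) < 0L) msgs <- c(msgs, paste(nm, "must be >= 0"))
  }
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@hiddenSize < 1L) msgs <- c(msgs, "hiddenSize must be >= 1")
  if (object@lambdaRecon < 0) msgs <- c(msgs, "lambdaRecon must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (!object@direction %in% c("uni", "bi")) {
    msgs <- c(msgs, "direction must be 'uni' or 'bi'")
  }
  if (!object@divergence %in% names(.DIV_REGISTRY)) {
    msgs <- c(msgs, paste0(
      "unknown divergence '", object@divergence, "'; available: ",
      paste(names(.DIV_REGISTRY), collapse = ", ")
    ))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    paste0(
      "TrainConfig: %s GRUI, divergence '%s'\n",
      "  batch %d, hidden %d, lambda %.3g, lr %.3g\n",
      "  %d pretrain + %d adversarial epochs, %d refine iterations, seed %d\n"
    ),
    object@direction, object@divergence,
    object@batchSize, object@hiddenSize, object@lambdaRecon,
    object@learningRate, object@pretrainEpochs, object@epochs,
    object@refineIterations, object@seed
  ))
  invisible(object)
})

#' Create a training configuration
#'
#' @param batchSize sequences per gradient step (default 128).
#' @param hiddenSize recurrent hidden size (default 64).
#' @param lambdaRecon reconstruction weight (default 0.15).
#' @param learningRate Adam learning rate (default 0.001).
#' @param pretrainEpochs generator-only epochs (default 5).
#' @param epochs adversarial epochs (default 30).
#' @param refineIterations noise-refinement steps (default 400).
#' @param divergence adversarial loss (default `"forward_kl"`).
#' @param direction `"bi"` (default) or `"uni"`.
#' @param seed integer RNG seed (default 1).
#' @param dStepsPerGStep discriminator steps per generator step;
#'   defaults to 5 for the Wasserstein critic and 1 otherwise.
#' @param noiseSd noise standard deviation for missing slots
#'   (default 0.01).
#' @return A [TrainConfig-class] object.
#' @examples
#' trainConfig(divergence = "js", epochs = 10)
#' @export
trainConfig <- function(batchSize = 128, hiddenSize = 64,
                        lambdaRecon = 0.15, learningRate = 0.001,
                        pretrainEpochs = 5, epochs = 30,
                        refineIterations = 400,
                        divergence = "forward_kl",
                        direction = c("bi", "uni"), seed = 1,
                        dStepsPerGStep = NULL, noiseSd = 0.01) {
  direction <- match.arg(direction)
  if (is.null(dStepsPerGStep)) {
    dStepsPerGStep <- if (identical(divergence, "wasserstein")) 5L else 1L
  }
  new("TrainConfig",
    batchSize = as.integer(batchSize),
    hiddenSize = as.integer(hiddenSize),
    lambdaRecon = as.numeric(lambdaRecon),
    learningRate = as.numeric(learningRate),
    pretrainEpochs = as.integer(pretrainEpochs),
    epochs = as.integer(epochs),
    refineIterations = as.integer(refineIterations),
    divergence = divergence,
    direction = direction,
    seed = as.integer(seed),
    dStepsPerGStep = as.integer(dStepsPerGStep),
    noiseSd = as.numeric(noiseSd)
  )
}

#' Compose the generator input
#'
#' `M * X + (1 - M) * Z`: observed entries of X pass through untouched,
#' missing slots are filled from the noise matrix.  Missing entries of
#' `X` (`NA`) contribute nothing because they are multiplied by a zero
#' mask.
#'
#' @param X numeric D x T data matrix (`NA` allowed where `M` is 0).
#' @param M numeric D x T binary mask.
#' @param Z numeric D x T noise matrix.
#' @return numeric D x T composed matrix.
#' @export
composeInput <- function(X, M, Z) {
  if (!identical(dim(X), dim(M)) || !identical(dim(X), dim(Z))) {
    stop("X, M and Z must have identical dimensions")
  }
  X0 <- X
  X0[M == 0] <- 0
  M * X0 + (1 - M) * Z
}

#' Run the generator over one series
#'
#' Feeds the composed input (see [composeInput()]) through the
#' (bi)directional GRUI with the series' forward/backward time lags and
#' projects every combined hidden state to D outputs, yielding the full
#' generated matrix `Ghat = G(X, M, Z, delta)`.
#'
#' @param series An [IncompleteSeries-class] (typically standardized).
#' @param Z numeric D x T noise matrix.
#' @param nets An [ImputerNets-class] object.
#' @return numeric D x T generated matrix.
#' @export
generatorForward <- function(series, Z, nets) {
  if (nFeatures(series) != nets@inputSize) {
    stop(sprintf(
      "series has %d features but nets expect %d",
      nFeatures(series), nets@inputSize
    ))
  }
  lag <- timeLags(series)
  Xin <- composeInput(seriesValues(series), seriesMask(series), Z)
  .net_forward(Xin, lag@deltaF, lag@deltaB, nets@generator)
}

#' Run the discriminator over a completed matrix
#'
#' Produces one raw critic score per feature per timestep (D x T); the
#' "real" expectation in the adversarial objective averages scores at
#' observed positions of the completed matrix, the "fake" expectation at
#' imputed positions.
#'
#' @param Xhat numeric D x T completed matrix (no missing entries).
#' @param lagPair A [TimeLagPair-class] for the underlying series.
#' @param nets An [ImputerNets-class] object.
#' @return numeric D x T raw score matrix.
#' @export
discriminatorForward <- function(Xhat, lagPair, nets) {
  .net_forward(Xhat, lagPair@deltaF, lagPair@deltaB, nets@discriminator)
}

#' Assemble the completed matrix
#'
#' `Xhat = M * X + (1 - M) * Ghat`: observed entries come from the
#' data, missing slots from the generator.  Wherever `M = 1` the output
#' equals `X` exactly.
#'
#' @param X numeric D x T data matrix (`NA` allowed where `M` is 0).
#' @param M numeric D x T binary mask.
#' @param Ghat numeric D x T generated matrix.
#' @return numeric D x T completed matrix.
#' @export
assembleImputed <- function(X, M, Ghat) {
  if (!identical(dim(X), dim(M)) || !identical(dim(X), dim(Ghat))) {
    stop("X, M and Ghat must have identical dimensions")
  }
  X0 <- X
  X0[M == 0] <- 0
  M * X0 + (1 - M) * Ghat
}

#' Masked reconstruction loss
#'
#' Mean squared error between data and generator output over observed
#' entries only: `||X * M - Ghat * M||^2 / sum(M)`.  Zero exactly when
#' the generator matches every observed entry; defined as 0 (with a
#' warning) when nothing is observed.
#'
#' @param X numeric D x T data matrix.
#' @param M numeric D x T binary mask.
#' @param Ghat numeric D x T generated matrix.
#' @return nonnegative scalar.
#' @export
reconstructionLoss <- function(X, M, Ghat) {
  if (!identical(dim(X), dim(M)) || !identical(dim(X), dim(Ghat))) {
    stop("X, M and Ghat must have identical dimensions")
  }
  n_obs <- sum(M)
  if (n_obs == 0) {
    warning("no observed entries; reconstruction loss defined as 0")
    return(0)
  }
  d <- (X - Ghat) * M
  sum(d[M == 1]^2) / n_obs
}

#' Generator objective
#'
#' `L_G = L_adv + lambda * L_R`, the weighted sum of the adversarial
#' loss and the reconstruction loss.
#'
#' @param adv scalar adversarial loss (see [generatorAdvLoss()]).
#' @param recon scalar reconstruction loss (see
#'   [reconstructionLoss()]).
#' @param lambdaRecon nonnegative weight.
#' @return scalar objective.
#' @export
generatorLoss <- function(adv, recon, lambdaRecon) {
  adv + lambdaRecon * recon
}
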