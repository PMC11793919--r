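#' Refine the imputation noise for one sequence
#'
#' Holding the trained network weights fixed, gradient-descends the
#' noise entries that fill the missing slots of the generator input so
#' that the generator's output (a) reconstructs the observed entries
#' well and (b) earns high discriminator scores at the imputed slots:
#' the objective is `L_R + 0.1 * (-mean fake score)`.  Steps use plain
#' gradient descent with a backtracking step size: a step is accepted
#' only if the reconstruction component does not increase, so that
#' component is nonincreasing across accepted iterations.
#'
#' @param series An [IncompleteSeries-class] in model (standardized)
#'   units.
#' @param nets A trained [ImputerNets-class].
#' @param config A [TrainConfig-class]; `refineIterations` gradient
#'   evaluations are performed (0 returns the input noise unchanged);
#'   the initial step size is `learningRate`.
#' @param Z optional starting D x T noise matrix; when `NULL` it is
#'   drawn from `N(0, noiseSd^2)` after seeding the RNG with
#'   `config@seed`, making the call deterministic.
#' @return the refined D x T noise matrix.
#' @seealso [tbigainImpute()]
#' @export
refineNoise <- function(series, nets, config, Z = NULL) {
  sq <- .prep_sequence(series)
  if (is.null(Z)) {
    set.seed(config@seed)
    Z <- .draw_noise(sq$D, sq$TT, config@noiseSd)
  }
  if (!identical(dim(Z), dim(sq$X))) {
    stop("Z must match the series dimensions")
  }
  if (config@refineIterations == 0L || sq$n_mis == 0 || sq$n_obs == 0) {
    return(Z)
  }
  gen <- nets@generator
  disc <- nets@discriminator
  # backtracking step size: start at the training rate, shrink on any
  # step that worsens reconstruction, grow gently on accepted steps.
  # Steps stay small on purpose: noise at a missing slot also feeds the
  # direct input->output path of that same slot, and large noise moves
  # exploit it at the expense of the imputation.
  lr <- config@learningRate
  lr_cap <- config@learningRate * 10
  ADV_W <- 0.1

  fwd_of <- function(Z) {
    Xin <- composeInput(sq$X, sq$M, Z)
    .net_forward(Xin, sq$dF, sq$dB, gen, want_cache = TRUE)
  }

  fwdG <- fwd_of(Z)
  cur_recon <- reconstructionLoss(sq$X, sq$M, fwdG$out)
  for (iter in seq_len(config@refineIterations)) {
    Ghat <- fwdG$out
    dGhat <- if (sq$n_obs > 0) 2 * sq$M * (Ghat - sq$X0) / sq$n_obs else 0 * Ghat
    Xhat <- sq$M * sq$X0 + (1 - sq$M) * Ghat
    fwdD <- .net_forward(Xhat, sq$dF, sq$dB, disc, want_cache = TRUE)
    dS <- matrix(0, sq$D, sq$TT)
    dS[sq$M == 0] <- -ADV_W / sq$n_mis # d of ADV_W * (-mean fake)
    bkD <- .net_backward(dS, fwdD, disc)
    dGhat <- dGhat + bkD$dX * (1 - sq$M)
    bkG <- .net_backward(dGhat, fwdG, gen)
    dZ <- bkG$dX * (1 - sq$M)
    cand <- Z - lr * dZ
    fwd_cand <- fwd_of(cand)
    cand_recon <- reconstructionLoss(sq$X, sq$M, fwd_cand$out)
    if (cand_recon <= cur_recon + 1e-12) {
      Z <- cand
      fwdG <- fwd_cand
      cur_recon <- cand_recon
      lr <- min(lr * 1.1, lr_cap)
    } else {
      lr <- lr / 2
    }
  }
  Z
}

#' Impute a dataset with trained networks
#'
#' Per sequence: draw (and optionally refine) the noise, run the
#' generator, and assemble `Xhat = M * X + (1 - M) * Ghat`, then map
#' back to original units with the stored standardization transform.
#' Observed entries are preserved exactly by construction; every output
#' entry is finite.
#'
#' @param dataset list of [IncompleteSeries-class] objects in model
#'   (standardized) units.
#' @param nets A trained [ImputerNets-class].
#' @param config A [TrainConfig-class]; `refineIterations > 0` enables
#'   per-sequence noise refinement.
#' @param transform standardization transform (list with `center`,
#'   `scale`) as returned by [standardizeDataset()]; the default
#'   identity transform leaves values in model units.
#' @return list of completed [IncompleteSeries-class] objects (mask all
#'   ones) in original units.
#' @seealso [imputeDataset()] for the one-call pipeline.
#' @export
tbigainImpute <- function(dataset, nets, config,
                          transform = list(center = 0, scale = 1)) {
  if (is(dataset, "IncompleteSeries")) dataset <- list(dataset)
  out <- vector("list", length(dataset))
  names(out) <- names(dataset)
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    if (nFeatures(s) != nets@inputSize) {
      stop(sprintf(
        "sequence %d has %d features but nets expect %d",
        i, nFeatures(s), nets@inputSize
      ))
    }
    sq <- .prep_sequence(s)
    set.seed((config@seed + 7919L * i) %% .Machine$integer.max)
    Z <- .draw_noise(sq$D, sq$TT, config@noiseSd)
    if (config@refineIterations > 0L) {
      Z <- refineNoise(s, nets, config, Z = Z)
    }
    Ghat <- generatorForward(s, Z, nets)
    Xhat <- assembleImputed(sq$X, sq$M, Ghat)
    v <- unstandardizeValues(Xhat, transform)
    out[[i]] <- new("IncompleteSeries",
      values = v,
      mask = matrix(1, sq$D, sq$TT),
      timestamps = seriesTimestamps(s),
      featureNames = featureNames(s)
    )
  }
  out
}

#' One-call train-and-impute pipeline
#'
#' Standardizes the dataset, trains the adversarial imputer, imputes
#' every sequence, and maps the result back to original units.
#'
#' @param dataset list of [IncompleteSeries-class] objects in original
#'   units.
#' @param config A [TrainConfig-class].
#' @return list with `completed` (list of completed series in original
#'   units), `nets`, `history`, and `transform`.
#' @examples
#' \donttest{
#' sim <- generateComplete(simConfig(nSequences = 4, nFeatures = 3,
#'                                   nTimesteps = 16, seed = 1))
#' inc <- applyMissingness(sim, rate = 0.2, seed = 2)
#' cfg <- trainConfig(hiddenSize = 8, batchSize = 2, pretrainEpochs = 1,
#'                    epochs = 1, refineIterations = 0, seed = 3)
#' res <- imputeDataset(inc$dataset, cfg)
#' }
#' @export
imputeDataset <- function(dataset, config) {
  std <- standardizeDataset(dataset)
  fit <- tbigainTrain(std$dataset, config)
  completed <- tbigainImpute(
    std$dataset, fit$nets, config,
    transform = std[c("center", "scale")]
  )
  list(
    completed = completed, nets = fit$nets, history = fit$history,
    transform = std[c("center", "scale")]
  )
}
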