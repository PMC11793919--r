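.draw_noise <- function(d, tt, sd) {
  matrix(stats::rnorm(d * tt, sd = sd), d, tt)
}

# Precompute per-sequence arrays used repeatedly during training.
.prep_sequence <- function(s) {
  X <- seriesValues(s)
  M <- seriesMask(s)
  X0 <- X
  X0[M == 0] <- 0
  lag <- timeLags(s)
  list(
    X = X, M = M, X0 = X0,
    dF = lag@deltaF, dB = lag@deltaB,
    n_obs = sum(M), n_mis = sum(1 - M),
    D = nrow(X), TT = ncol(X)
  )
}

# Batches bucketed by sequence length so no padding ever enters the
# recurrent math; order within buckets is shuffled by the caller.
.make_batches <- function(lens, order, batchSize) {
  out <- list()
  for (len in unique(lens[order])) {
    idx <- order[lens[order] == len]
    starts <- seq(1L, length(idx), by = batchSize)
    for (s in starts) {
      out[[length(out) + 1L]] <- idx[s:min(s + batchSize - 1L, length(idx))]
    }
  }
  out
}

.WGAN_CLIP <- 0.01

#' Train the adversarial imputer
#'
#' Two phases.  (1) Pretraining: the generator alone is trained for
#' `pretrainEpochs` epochs to minimize the masked reconstruction loss.
#' (2) Adversarial training: per batch, the discriminator takes
#' `dStepsPerGStep` gradient steps maximizing the variational
#' f-divergence objective (real scores are taken at observed positions
#' of the completed matrix, fake scores at imputed positions), then the
#' generator takes one step minimizing
#' `L_adv + lambdaRecon * L_R`.  Both networks use Adam; the
#' Wasserstein critic's weights are clipped to `[-0.01, 0.01]` after
#' each discriminator update.  The whole run is a deterministic function
#' of `config@seed`.
#'
#' @param dataset list of [IncompleteSeries-class] objects (standardize
#'   first; see [standardizeDataset()]).
#' @param config A [TrainConfig-class] object.
#' @return list with `nets` (trained [ImputerNets-class]) and `history`
#'   (data.frame with one row per epoch: `phase`, `epoch`, `loss_d`,
#'   `loss_adv`, `loss_recon`).
#' @seealso [tbigainImpute()], [imputeDataset()]
#' @export
tbigainTrain <- function(dataset, config) {
  if (is(dataset, "IncompleteSeries")) dataset <- list(dataset)
  if (!length(dataset)) stop("dataset must contain at least one sequence")
  d_in <- nFeatures(dataset[[1L]])
  spec <- getDivergence(config@divergence)
  set.seed(config@seed)
  nets <- imputerNets(d_in, config@hiddenSize, config@direction)
  gen <- nets@generator
  disc <- nets@discriminator
  optG <- .adam_init(gen)
  optD <- .adam_init(disc)
  seqs <- lapply(dataset, .prep_sequence)
  lens <- vapply(seqs, `[[`, integer(1), "TT")
  n <- length(seqs)
  lr <- config@learningRate
  lam <- config@lambdaRecon
  hist_rows <- list()

  recon_grad <- function(sq, Ghat) {
    if (sq$n_obs == 0) {
      return(0 * Ghat)
    }
    2 * sq$M * (Ghat - sq$X0) / sq$n_obs
  }

  # ---- phase 1: generator-only reconstruction pretraining -----------
  for (epoch in seq_len(config@pretrainEpochs)) {
    order <- sample.int(n)
    ep_recon <- 0
    for (batch in .make_batches(lens, order, config@batchSize)) {
      gsum <- NULL
      for (i in batch) {
        sq <- seqs[[i]]
        Z <- .draw_noise(sq$D, sq$TT, config@noiseSd)
        Xin <- composeInput(sq$X, sq$M, Z)
        fwd <- .net_forward(Xin, sq$dF, sq$dB, gen, want_cache = TRUE)
        ep_recon <- ep_recon + reconstructionLoss(sq$X, sq$M, fwd$out)
        bk <- .net_backward(recon_grad(sq, fwd$out), fwd, gen)
        gsum <- .grad_add(gsum, bk$grads)
      }
      upd <- .adam_step(gen, .grad_scale(gsum, 1 / length(batch)), optG, lr)
      gen <- upd$params
      optG <- upd$opt
    }
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      phase = "pretrain", epoch = epoch,
      loss_d = NA_real_, loss_adv = NA_real_, loss_recon = ep_recon / n
    )
  }

  # ---- phase 2: adversarial training --------------------------------
  for (epoch in seq_len(config@epochs)) {
    order <- sample.int(n)
    ep_d <- ep_adv <- ep_recon <- 0
    n_d <- n_adv <- 0L
    for (batch in .make_batches(lens, order, config@batchSize)) {
      # discriminator step(s): maximize L_D (descend its negation)
      for (k in seq_len(config@dStepsPerGStep)) {
        gsum <- NULL
        used <- 0L
        for (i in batch) {
          sq <- seqs[[i]]
          if (sq$n_mis == 0 || sq$n_obs == 0) next
          Z <- .draw_noise(sq$D, sq$TT, config@noiseSd)
          Xin <- composeInput(sq$X, sq$M, Z)
          Ghat <- .net_forward(Xin, sq$dF, sq$dB, gen)
          Xhat <- sq$M * sq$X0 + (1 - sq$M) * Ghat
          fwdD <- .net_forward(Xhat, sq$dF, sq$dB, disc, want_cache = TRUE)
          S <- fwdD$out
          real <- S[sq$M == 1]
          fake <- S[sq$M == 0]
          if (k == 1L) {
            ep_d <- ep_d + discriminatorLoss(real, fake, spec)
            n_d <- n_d + 1L
          }
          dsc <- .d_disc_scores(real, fake, spec)
          dS <- matrix(0, sq$D, sq$TT)
          dS[sq$M == 1] <- -dsc$dReal # negate: maximize via descent
          dS[sq$M == 0] <- -dsc$dFake
          bk <- .net_backward(dS, fwdD, disc)
          gsum <- .grad_add(gsum, bk$grads)
          used <- used + 1L
        }
        if (used > 0L) {
          upd <- .adam_step(disc, .grad_scale(gsum, 1 / used), optD, lr)
          disc <- upd$params
          optD <- upd$opt
          if (spec@critic) disc <- .clip_params(disc, .WGAN_CLIP)
        }
      }
      # generator step: minimize L_adv + lambda * L_R
      gsum <- NULL
      for (i in batch) {
        sq <- seqs[[i]]
        Z <- .draw_noise(sq$D, sq$TT, config@noiseSd)
        Xin <- composeInput(sq$X, sq$M, Z)
        fwdG <- .net_forward(Xin, sq$dF, sq$dB, gen, want_cache = TRUE)
        Ghat <- fwdG$out
        ep_recon <- ep_recon + reconstructionLoss(sq$X, sq$M, Ghat)
        dGhat <- lam * recon_grad(sq, Ghat)
        if (sq$n_mis > 0) {
          Xhat <- sq$M * sq$X0 + (1 - sq$M) * Ghat
          fwdD <- .net_forward(Xhat, sq$dF, sq$dB, disc, want_cache = TRUE)
          fake <- fwdD$out[sq$M == 0]
          ep_adv <- ep_adv + generatorAdvLoss(fake, spec)
          n_adv <- n_adv + 1L
          dS <- matrix(0, sq$D, sq$TT)
          dS[sq$M == 0] <- .d_gen_fake_scores(fake, spec)
          bkD <- .net_backward(dS, fwdD, disc)
          dGhat <- dGhat + bkD$dX * (1 - sq$M)
        }
        bkG <- .net_backward(dGhat, fwdG, gen)
        gsum <- .grad_add(gsum, bkG$grads)
      }
      upd <- .adam_step(gen, .grad_scale(gsum, 1 / length(batch)), optG, lr)
      gen <- upd$params
      optG <- upd$opt
    }
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      phase = "adversarial", epoch = epoch,
      loss_d = if (n_d) ep_d / n_d else NA_real_,
      loss_adv = if (n_adv) ep_adv / n_adv else NA_real_,
      loss_recon = ep_recon / n
    )
  }

  nets@generator <- gen
  nets@discriminator <- disc
  validObject(nets)
  history <- if (length(hist_rows)) {
    do.call(rbind, hist_rows)
  } else {
    data.frame(
      phase = character(), epoch = integer(), loss_d = numeric(),
      loss_adv = numeric(), loss_recon = numeric()
    )
  }
  list(nets = nets, history = history)
}
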