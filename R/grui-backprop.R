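# Internal reverse-mode machinery for GRUI training.
#
# Parameters travel through the hot path as plain lists of numeric
# arrays (".plist"); the exported GRUIParams S4 class is converted at
# the boundary.  The forward pass caches every intermediate needed by
# backpropagation-through-time; the backward pass returns both the
# parameter gradients and the gradient with respect to the inputs (the
# latter is what lets generator gradients flow through the frozen
# discriminator, and noise refinement flow through the generator).

.p2l <- function(p) {
  list(
    Wr = p@Wr, Wh = p@Wh, Wz = p@Wz,
    br = p@br, bh = p@bh, bz = p@bz,
    Wbeta = p@Wbeta, bbeta = p@bbeta,
    H = p@hiddenSize, D = p@inputSize
  )
}

.l2p <- function(l) {
  new("GRUIParams",
    Wr = l$Wr, Wh = l$Wh, Wz = l$Wz,
    br = as.numeric(l$br), bh = as.numeric(l$bh), bz = as.numeric(l$bz),
    Wbeta = l$Wbeta, bbeta = as.numeric(l$bbeta),
    hiddenSize = as.integer(l$H), inputSize = as.integer(l$D)
  )
}

.plist_zero_grads <- function(l) {
  list(
    Wr = 0 * l$Wr, Wh = 0 * l$Wh, Wz = 0 * l$Wz,
    br = 0 * l$br, bh = 0 * l$bh, bz = 0 * l$bz,
    Wbeta = 0 * l$Wbeta, bbeta = 0 * l$bbeta
  )
}

.plist_random <- function(inputSize, hiddenSize) {
  .p2l(gruiParams(inputSize, hiddenSize))
}

# Forward pass over the sequence in processing order `ord` (1..T for a
# forward cell, T..1 for a backward cell), caching intermediates.
# X: D x T inputs; lags: D x T time lags read at the processed step.
.grui_fwd_cache <- function(X, lags, pl, ord) {
  H <- pl$H
  tt <- ncol(X)
  HS <- matrix(0, H, tt) # output states, natural time positions
  BETA <- matrix(0, H, tt)
  PREI <- matrix(0, H, tt) # indicator: decay pre-activation in (0, clip)
  HB <- matrix(0, H, tt)
  RG <- matrix(0, H, tt)
  HT <- matrix(0, H, tt)
  ZG <- matrix(0, H, tt)
  HPREV <- matrix(0, H, tt)
  h <- numeric(H)
  for (t in ord) {
    x <- X[, t]
    pre <- drop(pl$Wbeta %*% lags[, t]) + pl$bbeta
    beta <- exp(-pmin(pmax(pre, 0), .DECAY_CLIP))
    hb <- h * beta
    xh <- c(x, hb)
    r <- .sigmoid(drop(pl$Wr %*% xh) + pl$br)
    htl <- tanh(drop(pl$Wh %*% c(x, r * hb)) + pl$bh)
    z <- .sigmoid(drop(pl$Wz %*% xh) + pl$bz)
    hnew <- (1 - z) * hb + z * htl
    HPREV[, t] <- h
    BETA[, t] <- beta
    PREI[, t] <- as.numeric(pre > 0 & pre < .DECAY_CLIP)
    HB[, t] <- hb
    RG[, t] <- r
    HT[, t] <- htl
    ZG[, t] <- z
    HS[, t] <- hnew
    h <- hnew
  }
  list(
    H = HS, X = X, lags = lags, ord = ord,
    BETA = BETA, PREI = PREI, HB = HB, R = RG, HT = HT, Z = ZG,
    HPREV = HPREV
  )
}

# Backward pass.  dH: H x T gradient w.r.t. each cached output state
# (natural time positions).  Returns parameter gradients and dX.
.grui_bwd <- function(dH, cache, pl) {
  D <- pl$D
  H <- pl$H
  ord <- cache$ord
  tt <- length(ord)
  g <- .plist_zero_grads(pl)
  dX <- matrix(0, D, ncol(cache$X))
  idx_x <- seq_len(D)
  idx_h <- D + seq_len(H)
  carry <- numeric(H)
  for (k in rev(seq_len(tt))) {
    t <- ord[k]
    dh <- dH[, t] + carry
    hb <- cache$HB[, t]
    r <- cache$R[, t]
    htl <- cache$HT[, t]
    z <- cache$Z[, t]
    beta <- cache$BETA[, t]
    hprev <- cache$HPREV[, t]
    x <- cache$X[, t]
    xh <- c(x, hb)

    dz_pre <- dh * (htl - hb) * z * (1 - z)
    dht_pre <- dh * z * (1 - htl * htl)
    dhb <- dh * (1 - z)

    g$Wz <- g$Wz + tcrossprod(dz_pre, xh)
    g$bz <- g$bz + dz_pre
    back <- drop(crossprod(pl$Wz, dz_pre))
    dX[, t] <- dX[, t] + back[idx_x]
    dhb <- dhb + back[idx_h]

    g$Wh <- g$Wh + tcrossprod(dht_pre, c(x, r * hb))
    g$bh <- g$bh + dht_pre
    back <- drop(crossprod(pl$Wh, dht_pre))
    dX[, t] <- dX[, t] + back[idx_x]
    drhb <- back[idx_h]
    dr <- drhb * hb
    dhb <- dhb + drhb * r

    dr_pre <- dr * r * (1 - r)
    g$Wr <- g$Wr + tcrossprod(dr_pre, xh)
    g$br <- g$br + dr_pre
    back <- drop(crossprod(pl$Wr, dr_pre))
    dX[, t] <- dX[, t] + back[idx_x]
    dhb <- dhb + back[idx_h]

    dhprev <- dhb * beta
    dbeta <- dhb * hprev
    dpre <- -dbeta * beta * cache$PREI[, t]
    g$Wbeta <- g$Wbeta + tcrossprod(dpre, cache$lags[, t])
    g$bbeta <- g$bbeta + dpre
    carry <- dhprev
  }
  list(grads = g, dX = dX)
}

# --- recurrent network (one or two cells + per-timestep projection) ---

# net: list(f = plist, b = plist or NULL, proj = list(W = Dout x H, b))
# Forward: hidden trajectory (mean of directions when bidirectional)
# projected per timestep to Dout outputs.
.net_forward <- function(X, dF, dB, net, want_cache = FALSE) {
  tt <- ncol(X)
  ordf <- seq_len(tt)
  cf <- .grui_fwd_cache(X, dF, net$f, ordf)
  if (!is.null(net$b)) {
    cb <- .grui_fwd_cache(X, dB, net$b, rev(ordf))
    Hc <- (cf$H + cb$H) / 2
  } else {
    cb <- NULL
    Hc <- cf$H
  }
  out <- net$proj$W %*% Hc + net$proj$b
  if (!want_cache) {
    return(out)
  }
  list(out = out, Hc = Hc, cf = cf, cb = cb)
}

# Backward from dOut (Dout x T) through projection and cell(s).
.net_backward <- function(dOut, fwd, net) {
  gproj <- list(
    W = tcrossprod(dOut, fwd$Hc),
    b = rowSums(dOut)
  )
  dHc <- crossprod(net$proj$W, dOut)
  if (!is.null(net$b)) {
    bf <- .grui_bwd(dHc / 2, fwd$cf, net$f)
    bb <- .grui_bwd(dHc / 2, fwd$cb, net$b)
    list(
      grads = list(f = bf$grads, b = bb$grads, proj = gproj),
      dX = bf$dX + bb$dX
    )
  } else {
    bf <- .grui_bwd(dHc, fwd$cf, net$f)
    list(grads = list(f = bf$grads, b = NULL, proj = gproj), dX = bf$dX)
  }
}

.net_new <- function(inputSize, hiddenSize, outSize, bidirectional) {
  list(
    f = .plist_random(inputSize, hiddenSize),
    b = if (bidirectional) .plist_random(inputSize, hiddenSize) else NULL,
    proj = list(
      W = matrix(stats::rnorm(outSize * hiddenSize, sd = 1 / sqrt(hiddenSize)),
        outSize, hiddenSize
      ),
      b = numeric(outSize)
    )
  )
}
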