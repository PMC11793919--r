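#' Parameters of a GRUI cell
#'
#' A gated recurrent unit for imputation (GRUI) in concatenated form:
#' the reset, candidate and update transforms each act on the
#' concatenation `[x_t, h]` of the current input and the (decayed)
#' previous hidden state, so each weight matrix is H x (D_in + H).  The
#' decay map `W_beta` (H x D_in) turns the time-lag vector into the
#' hidden-sized decay exponent.
#'
#' @slot Wr,Wh,Wz numeric H x (D_in + H) gate weight matrices.
#' @slot br,bh,bz numeric length-H gate biases.
#' @slot Wbeta numeric H x D_in decay weight matrix.
#' @slot bbeta numeric length-H decay bias.
#' @slot hiddenSize,inputSize integer sizes H and D_in.
#' @seealso [gruiParams()], [gruiStep()], [decayVector()]
#' @export
setClass("GRUIParams",
  representation(
    Wr = "matrix", Wh = "matrix", Wz = "matrix",
    br = "numeric", bh = "numeric", bz = "numeric",
    Wbeta = "matrix", bbeta = "numeric",
    hiddenSize = "integer", inputSize = "integer"
  )
)

setValidity("GRUIParams", function(object) {
  h <- object@hiddenSize
  d <- object@inputSize
  msgs <- character()
  for (nm in c("Wr", "Wh", "Wz")) {
    w <- slot(object, nm)
    if (!identical(dim(w), c(as.integer(h), as.integer(d + h)))) {
      msgs <- c(msgs, sprintf("%s must be %d x %d", nm, h, d + h))
    }
  }
  if (!identical(dim(object@Wbeta), c(as.integer(h), as.integer(d)))) {
    msgs <- c(msgs, sprintf("Wbeta must be %d x %d", h, d))
  }
  for (nm in c("br", "bh", "bz", "bbeta")) {
    if (length(slot(object, nm)) != h) {
      msgs <- c(msgs, sprintf("%s must have length %d", nm, h))
    }
  }
  all_fin <- all(
    is.finite(object@Wr), is.finite(object@Wh), is.finite(object@Wz),
    is.finite(object@Wbeta), is.finite(object@br), is.finite(object@bh),
    is.finite(object@bz), is.finite(object@bbeta)
  )
  if (!all_fin) msgs <- c(msgs, "all parameter entries must be finite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GRUIParams", function(object) {
  cat(sprintf(
    "GRUIParams: input %d -> hidden %d (%d parameters)\n",
    object@inputSize, object@hiddenSize, .n_params(object)
  ))
  invisible(object)
})

.n_params <- function(p) {
  3L * length(p@Wr) + 3L * length(p@br) + length(p@Wbeta) + length(p@bbeta)
}

#' Create (randomly initialized) GRUI parameters
#'
#' Gate weights are drawn i.i.d. normal with standard deviation
#' `1/sqrt(inputSize + hiddenSize)` (Glorot-style scaling) and biases
#' start at zero.  Decay weights are drawn small and positive
#' (uniform on \[0, 0.1\]) rather than zero: the decay pre-activation
#' passes through a rectifier, so starting exactly at the kink would
#' freeze the decay map at 1 with no gradient.
#'
#' @param inputSize input dimension D_in.
#' @param hiddenSize hidden dimension H.
#' @param init `"random"` (default) or `"zero"`.
#' @return A [GRUIParams-class] object.  Uses the current RNG state.
#' @export
gruiParams <- function(inputSize, hiddenSize, init = c("random", "zero")) {
  init <- match.arg(init)
  d <- as.integer(inputSize)
  h <- as.integer(hiddenSize)
  gate <- function() {
    if (init == "zero") {
      matrix(0, h, d + h)
    } else {
      matrix(stats::rnorm(h * (d + h), sd = 1 / sqrt(d + h)), h, d + h)
    }
  }
  wb <- if (init == "zero") {
    matrix(0, h, d)
  } else {
    matrix(stats::runif(h * d, 0, 0.1), h, d)
  }
  new("GRUIParams",
    Wr = gate(), Wh = gate(), Wz = gate(),
    br = numeric(h), bh = numeric(h), bz = numeric(h),
    Wbeta = wb, bbeta = numeric(h),
    hiddenSize = h, inputSize = d
  )
}

.sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# Pre-activation of the decay is clipped at +50 before exp so beta never
# underflows to exactly 0 (exp(-50) ~ 2e-22; documented floor 1e-20).
.DECAY_CLIP <- 50

#' Temporal decay vector
#'
#' `beta_t = exp(-max(0, W_beta delta_t + b_beta))`, the elementwise
#' attenuation applied to the previous hidden state.  Every component
#' lies in (0, 1]; a component equals 1 exactly when its pre-activation
#' is nonpositive (no decay for freshly observed features).
#'
#' @param delta numeric length-D_in vector of nonnegative time lags.
#' @param params A [GRUIParams-class] object.
#' @return numeric length-H vector in (0, 1].
#' @export
decayVector <- function(delta, params) {
  if (length(delta) != params@inputSize) {
    stop(sprintf(
      "delta length (%d) must equal inputSize (%d)",
      length(delta), params@inputSize
    ))
  }
  pre <- drop(params@Wbeta %*% delta) + params@bbeta
  exp(-pmin(pmax(pre, 0), .DECAY_CLIP))
}

#' One step of a plain GRU
#'
#' Standard gated recurrent unit update in concatenated form:
#' `R = sigma(Wr[x, h] + br)`, `Htilde = tanh(Wh[x, R * h] + bh)`,
#' `Z = sigma(Wz[x, h] + bz)`, `H = (1 - Z) * h + Z * Htilde`.
#' Equivalent to [gruiStep()] with decay fixed at 1.
#'
#' @param x numeric length-D_in input vector.
#' @param hPrev numeric length-H previous hidden state.
#' @param params A [GRUIParams-class] object.
#' @return numeric length-H new hidden state.
#' @export
gruStep <- function(x, hPrev, params) {
  .grui_core(x, hPrev, rep(1, params@hiddenSize), params)
}

#' One step of the decay-modified GRU (GRUI)
#'
#' The previous hidden state is first attenuated elementwise by the
#' decay vector `beta_t` computed from the time lags (see
#' [decayVector()]); the standard GRU gates then act on the decayed
#' state, and the convex combination in the update uses the decayed
#' state as well.
#'
#' @param x numeric length-D_in input vector.
#' @param hPrev numeric length-H previous hidden state.
#' @param delta numeric length-D_in nonnegative time-lag vector.
#' @param params A [GRUIParams-class] object.
#' @return numeric length-H new hidden state.
#' @export
gruiStep <- function(x, hPrev, delta, params) {
  if (any(delta < 0)) stop("time lags must be nonnegative")
  .grui_core(x, hPrev, decayVector(delta, params), params)
}

.grui_core <- function(x, hPrev, beta, params) {
  if (length(x) != params@inputSize) stop("x length must equal inputSize")
  if (length(hPrev) != params@hiddenSize) {
    stop("hPrev length must equal hiddenSize")
  }
  hb <- hPrev * beta
  xh <- c(x, hb)
  r <- .sigmoid(drop(params@Wr %*% xh) + params@br)
  ht <- tanh(drop(params@Wh %*% c(x, r * hb)) + params@bh)
  z <- .sigmoid(drop(params@Wz %*% xh) + params@bz)
  (1 - z) * hb + z * ht
}

#' Run a GRUI over a sequence in one direction
#'
#' Forward: iterates t = 1..T from a zero initial state using the
#' forward lags.  Backward: iterates t = T..1 from a zero state beyond
#' the last step using the backward lags.  Hidden states are returned in
#' natural time order (column t is the state computed at step t) in both
#' cases.
#'
#' @param inputs numeric D_in x T matrix, one input vector per column.
#' @param lags numeric D_in x T matrix of time lags (forward lags for
#'   `direction = "forward"`, backward lags for `"backward"`).
#' @param params A [GRUIParams-class] object.
#' @param direction `"forward"` or `"backward"`.
#' @return numeric H x T matrix of hidden states.
#' @seealso [runBidirectional()]
#' @export
runDirection <- function(inputs, lags, params,
                         direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  inputs <- as.matrix(inputs)
  lags <- as.matrix(lags)
  if (!identical(dim(inputs), dim(lags))) {
    stop("inputs and lags must have identical dimensions")
  }
  tt <- ncol(inputs)
  ord <- if (direction == "forward") seq_len(tt) else rev(seq_len(tt))
  hs <- matrix(0, params@hiddenSize, tt)
  h <- numeric(params@hiddenSize)
  for (t in ord) {
    h <- gruiStep(inputs[, t], h, lags[, t], params)
    hs[, t] <- h
  }
  hs
}

#' Bidirectional GRUI hidden states
#'
#' Runs an independent forward cell (with the forward lags) and backward
#' cell (with the backward lags) over the sequence and returns the
#' elementwise mean of the two trajectories,
#' `H_t = (H^f_t + H^b_t) / 2`.
#'
#' @param inputs numeric D_in x T matrix.
#' @param deltaF,deltaB numeric D_in x T forward/backward lag matrices.
#' @param paramsF,paramsB [GRUIParams-class] for the two directions.
#' @return numeric H x T matrix of combined hidden states.
#' @export
runBidirectional <- function(inputs, deltaF, deltaB, paramsF, paramsB) {
  if (paramsF@hiddenSize != paramsB@hiddenSize) {
    stop("forward and backward cells must share the hidden size")
  }
  hf <- runDirection(inputs, deltaF, paramsF, "forward")
  hb <- runDirection(inputs, deltaB, paramsB, "backward")
  (hf + hb) / 2
}
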