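# Internal Adam optimizer over nested lists of numeric arrays.
# Beta1 = 0.5, beta2 = 0.9: the low-momentum variant customary for
# adversarial training.
#
# Parameter structures are nested lists whose trainable leaves are
# double arrays; integer leaves (layer sizes) are passed through
# untouched, which is why the leaf test is is.double, not is.numeric.

.ADAM_B1 <- 0.5
.ADAM_B2 <- 0.9
.ADAM_EPS <- 1e-8

.is_param <- function(x) is.double(x)

.adam_init <- function(params) {
  walk <- function(p) {
    if (is.null(p)) {
      return(NULL)
    }
    if (.is_param(p)) {
      return(list(m = 0 * p, v = 0 * p))
    }
    if (is.list(p)) {
      return(lapply(p, walk))
    }
    NULL
  }
  list(state = walk(params), t = 0L)
}

# Returns list(params = updated params, opt = updated optimizer).
# Entries of `grads` that are NULL (e.g. absent backward cell) are
# skipped; non-double leaves of `params` pass through unchanged.
.adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - .ADAM_B1^opt$t
  bc2 <- 1 - .ADAM_B2^opt$t
  walk <- function(p, g, s) {
    if (is.null(p) || is.null(g)) {
      return(list(p = p, s = s))
    }
    if (.is_param(p)) {
      s$m <- .ADAM_B1 * s$m + (1 - .ADAM_B1) * g
      s$v <- .ADAM_B2 * s$v + (1 - .ADAM_B2) * g * g
      p <- p - lr * (s$m / bc1) / (sqrt(s$v / bc2) + .ADAM_EPS)
      return(list(p = p, s = s))
    }
    if (is.list(p)) {
      for (nm in names(p)) {
        res <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- res$p
        s[[nm]] <- res$s
      }
    }
    list(p = p, s = s)
  }
  res <- walk(params, grads, opt$state)
  opt$state <- res$s
  list(params = res$p, opt = opt)
}

# Sum two gradient structures of identical shape (NULLs propagate).
.grad_add <- function(a, b) {
  if (is.null(a)) {
    return(b)
  }
  if (is.null(b)) {
    return(a)
  }
  if (.is_param(a)) {
    return(a + b)
  }
  out <- a
  for (nm in names(a)) out[[nm]] <- .grad_add(a[[nm]], b[[nm]])
  out
}

# Scale a gradient structure by a scalar.
.grad_scale <- function(g, s) {
  if (is.null(g)) {
    return(NULL)
  }
  if (.is_param(g)) {
    return(g * s)
  }
  lapply(g, .grad_scale, s = s)
}

# Clip every trainable leaf into [-radius, radius] (Wasserstein critic).
.clip_params <- function(p, radius) {
  if (is.null(p)) {
    return(NULL)
  }
  if (.is_param(p)) {
    return(pmin(pmax(p, -radius), radius))
  }
  if (is.list(p)) {
    for (nm in names(p)) p[[nm]] <- .clip_params(p[[nm]], radius)
  }
  p
}
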