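setClassUnion("functionOrNULL", c("function", "NULL"))

#' An f-divergence specification
#'
#' Bundles everything adversarial training needs for one divergence: the
#' convex generator function `f` (with `f(1) = 0`), its Fenchel
#' conjugate `f*`, the critic output activation `g_f` that maps raw
#' network outputs into the domain of `f*`, the derivatives used by
#' backpropagation, and the conjugate domain bounds.  The Wasserstein
#' entry is not an f-divergence; it is flagged `critic = TRUE` and uses
#' an identity activation with a weight-clipped (Lipschitz) critic and
#' plain mean-difference losses.
#'
#' @slot name divergence name.
#' @slot f generator function (NULL for Wasserstein).
#' @slot fStar Fenchel conjugate `f*(t) = sup_u {ut - f(u)}`.
#' @slot fStarPrime derivative of `fStar`.
#' @slot gf critic output activation.
#' @slot gfPrime derivative of `gf`.
#' @slot tMin,tMax open-interval domain bounds of `fStar`.
#' @slot critic logical; TRUE for the Wasserstein special case.
#' @seealso [getDivergence()], [conjugate()], [discriminatorLoss()]
#' @export
setClass("DivergenceSpec",
  representation(
    name = "character",
    f = "functionOrNULL",
    fStar = "functionOrNULL",
    fStarPrime = "functionOrNULL",
    gf = "function",
    gfPrime = "function",
    tMin = "numeric",
    tMax = "numeric",
    critic = "logical"
  )
)

setMethod("show", "DivergenceSpec", function(object) {
  if (object@critic) {
    cat(sprintf(
      "DivergenceSpec '%s' (clipped-weight critic, identity activation)\n",
      object@name
    ))
  } else {
    cat(sprintf(
      "DivergenceSpec '%s': conjugate domain (%g, %g)\n",
      object@name, object@tMin, object@tMax
    ))
  }
  invisible(object)
})

# exp with the argument clamped at +/-30 (numerical guard used inside
# every activation/conjugate below).
.cexp <- function(x) exp(pmin(pmax(x, -30), 30))

# interior margin applied when evaluating f* at a finite domain boundary
.FSTAR_EPS <- 1e-7

.make_registry <- function() {
  list(
    forward_kl = new("DivergenceSpec",
      name = "forward_kl",
      f = function(u) ifelse(u == 0, 0, u * log(u)),
      fStar = function(t) .cexp(t - 1),
      fStarPrime = function(t) .cexp(t - 1),
      gf = function(v) v,
      gfPrime = function(v) rep(1, length(v)),
      tMin = -Inf, tMax = Inf, critic = FALSE
    ),
    reverse_kl = new("DivergenceSpec",
      name = "reverse_kl",
      f = function(u) -log(u),
      fStar = function(t) {
        t <- pmin(t, -.FSTAR_EPS)
        -1 - log(-t)
      },
      fStarPrime = function(t) {
        t <- pmin(t, -.FSTAR_EPS)
        -1 / t
      },
      gf = function(v) -.cexp(v),
      gfPrime = function(v) -.cexp(v),
      tMin = -Inf, tMax = 0, critic = FALSE
    ),
    js = new("DivergenceSpec",
      name = "js",
      f = function(u) {
        ifelse(u == 0, log(2), u * log(u) - (u + 1) * log((u + 1) / 2))
      },
      fStar = function(t) {
        t <- pmin(t, log(2) - .FSTAR_EPS)
        -log(2 - exp(t))
      },
      fStarPrime = function(t) {
        t <- pmin(t, log(2) - .FSTAR_EPS)
        exp(t) / (2 - exp(t))
      },
      # log(2) - log(1 + exp(-v)), written stably; range (-Inf, log 2)
      gf = function(v) {
        log(2) - ifelse(v > 0, log1p(.cexp(-v)), -v + log1p(.cexp(v)))
      },
      gfPrime = function(v) .sigmoid(-v),
      tMin = -Inf, tMax = log(2), critic = FALSE
    ),
    # Pearson chi-squared: f is convex on the whole real line, so its
    # conjugate t^2/4 + t holds for every t and the identity activation
    # needs no domain guard.
    pearson = new("DivergenceSpec",
      name = "pearson",
      f = function(u) (u - 1)^2,
      fStar = function(t) t^2 / 4 + t,
      fStarPrime = function(t) t / 2 + 1,
      gf = function(v) v,
      gfPrime = function(v) rep(1, length(v)),
      tMin = -Inf, tMax = Inf, critic = FALSE
    ),
    wasserstein = new("DivergenceSpec",
      name = "wasserstein",
      f = NULL, fStar = NULL, fStarPrime = NULL,
      gf = function(v) v,
      gfPrime = function(v) rep(1, length(v)),
      tMin = -Inf, tMax = Inf, critic = TRUE
    )
  )
}

.DIV_REGISTRY <- .make_registry()

#' Look up a divergence by name
#'
#' @param name one of `"forward_kl"`, `"reverse_kl"`, `"js"`,
#'   `"pearson"`, `"wasserstein"`.
#' @return A [DivergenceSpec-class] object.
#' @examples
#' getDivergence("pearson")
#' @export
getDivergence <- function(name) {
  spec <- .DIV_REGISTRY[[name]]
  if (is.null(spec)) {
    stop(
      "unknown divergence '", name, "'; available: ",
      paste(names(.DIV_REGISTRY), collapse = ", ")
    )
  }
  spec
}

#' Names of all registered divergences
#' @return character vector.
#' @export
availableDivergences <- function() names(.DIV_REGISTRY)

.check_domain <- function(spec, t, what = "t") {
  bad <- t <= spec@tMin | t >= spec@tMax
  if (any(bad)) {
    stop(sprintf(
      "%s outside the conjugate domain (%g, %g) of '%s': %s",
      what, spec@tMin, spec@tMax, spec@name,
      paste(utils::head(signif(t[bad], 4), 3), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Evaluate the Fenchel conjugate
#'
#' `f*(t) = sup_u {ut - f(u)}`, convex in `t`.  Errors when `t` falls
#' outside the divergence's conjugate domain (for example `t >= log 2`
#' for Jensen-Shannon, `t >= 0` for reverse KL).
#'
#' @param spec A [DivergenceSpec-class].
#' @param t numeric vector of evaluation points.
#' @return numeric vector `f*(t)`.
#' @examples
#' conjugate(getDivergence("pearson"), 0) # 0
#' @export
conjugate <- function(spec, t) {
  if (spec@critic) {
    stop("'", spec@name, "' is critic-based and has no conjugate here")
  }
  .check_domain(spec, t)
  spec@fStar(t)
}

#' Discriminator objective
#'
#' The variational f-divergence objective the discriminator *maximizes*:
#' `mean(g_f(real)) - mean(f*(g_f(fake)))` over raw critic outputs; for
#' the Wasserstein critic, `mean(real) - mean(fake)`.  The training loop
#' implements maximization as minimizing the negation.
#'
#' @param realScores,fakeScores numeric vectors of raw critic outputs at
#'   observed ("real") and imputed ("fake") positions.
#' @param spec A [DivergenceSpec-class].
#' @return scalar objective value.
#' @export
discriminatorLoss <- function(realScores, fakeScores, spec) {
  if (!length(realScores) || !length(fakeScores)) {
    stop("score vectors must be nonempty")
  }
  if (spec@critic) {
    return(mean(realScores) - mean(fakeScores))
  }
  mean(spec@gf(realScores)) - mean(spec@fStar(spec@gf(fakeScores)))
}

#' Generator adversarial loss
#'
#' `-mean(f*(g_f(fake)))` (minimized by the generator); for the
#' Wasserstein critic, `-mean(fake)`.
#'
#' @param fakeScores numeric vector of raw critic outputs at imputed
#'   positions.
#' @param spec A [DivergenceSpec-class].
#' @return scalar loss.
#' @export
generatorAdvLoss <- function(fakeScores, spec) {
  if (!length(fakeScores)) stop("score vector must be nonempty")
  if (spec@critic) {
    return(-mean(fakeScores))
  }
  -mean(spec@fStar(spec@gf(fakeScores)))
}

#' Empirical variational lower bound on an f-divergence
#'
#' `mean_P[T(x)] - mean_Q[f*(T(x))]` for a critic function `T` whose
#' outputs already lie in the conjugate domain.  For any critic this
#' under-estimates `D_f(P || Q)` in expectation; the bound is tight at
#' the optimal critic `T*(x) = f'(p(x)/q(x))`.
#'
#' @param samplesP,samplesQ numeric vectors of samples from P and Q.
#' @param critic a vectorized function sample -> real (already in the
#'   domain of `f*`; apply `spec@gf` yourself if starting from raw
#'   scores).
#' @param spec A [DivergenceSpec-class].
#' @return scalar estimate of the lower bound.
#' @export
estimateDivergence <- function(samplesP, samplesQ, critic, spec) {
  tp <- critic(samplesP)
  tq <- critic(samplesQ)
  if (!all(is.finite(tp)) || !all(is.finite(tq))) {
    stop("critic produced non-finite values")
  }
  if (spec@critic) {
    return(mean(tp) - mean(tq))
  }
  .check_domain(spec, tq, "critic output")
  .check_domain(spec, tp, "critic output")
  mean(tp) - mean(spec@fStar(tq))
}

# --- gradients used by the training loop (internal) -------------------

# d(discriminator objective)/d(raw scores); the trainer negates these
# to perform maximization by gradient descent.
.d_disc_scores <- function(realScores, fakeScores, spec) {
  nr <- length(realScores)
  nf <- length(fakeScores)
  if (spec@critic) {
    return(list(
      dReal = rep(1 / nr, nr),
      dFake = rep(-1 / nf, nf)
    ))
  }
  list(
    dReal = spec@gfPrime(realScores) / nr,
    dFake = -spec@fStarPrime(spec@gf(fakeScores)) *
      spec@gfPrime(fakeScores) / nf
  )
}

# d(generator adversarial loss)/d(raw fake scores)
.d_gen_fake_scores <- function(fakeScores, spec) {
  nf <- length(fakeScores)
  if (spec@critic) {
    return(rep(-1 / nf, nf))
  }
  -spec@fStarPrime(spec@gf(fakeScores)) * spec@gfPrime(fakeScores) / nf
}
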