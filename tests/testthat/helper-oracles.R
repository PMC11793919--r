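# Independent conjugate oracle: numerical supremum of u*t - f(u) over a
# dense grid refined by golden-section search.  The KL/JS family is
# defined on u > 0 (log-spaced grid); the Pearson generator is convex on
# the whole real line and its textbook conjugate is taken over all of
# it, so its grid is linear and two-sided.
numeric_conjugate <- function(f, t, domain = c("positive", "real")) {
  domain <- match.arg(domain)
  obj <- function(u) u * t - f(u)
  grid <- if (domain == "positive") {
    exp(seq(log(1e-8), log(60), length.out = 4000))
  } else {
    seq(-100, 100, length.out = 4000)
  }
  best <- grid[which.max(obj(grid))]
  span <- if (domain == "positive") c(best / 3, best * 3) else best + c(-1, 1)
  stats::optimize(obj, span, maximum = TRUE, tol = 1e-12)$objective
}

conjugate_domain_of <- function(name) {
  if (name == "pearson") "real" else "positive"
}
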