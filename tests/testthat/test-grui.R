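# Hand-set 1-dimensional parameters for scalar oracles.
scalar_params <- function(wr = 0.3, ur = -0.2, wh = 0.5, uh = 0.4,
                          wz = -0.1, uz = 0.6, br = 0.1, bh = -0.3,
                          bz = 0.2, wb = 0.7, bb = -0.1) {
  new("GRUIParams",
    Wr = matrix(c(wr, ur), 1), Wh = matrix(c(wh, uh), 1),
    Wz = matrix(c(wz, uz), 1),
    br = br, bh = bh, bz = bz,
    Wbeta = matrix(wb, 1, 1), bbeta = bb,
    hiddenSize = 1L, inputSize = 1L
  )
}

sig <- function(x) 1 / (1 + exp(-x))

test_that("decay vector is exp(-relu(.)), in (0,1], 1 iff pre <= 0", {
  set.seed(1)
  p <- gruiParams(3, 4)
  p@Wbeta <- matrix(0, 4, 3)
  p@bbeta <- rep(0, 4)
  expect_equal(decayVector(c(5, 2, 9), p), rep(1, 4))
  ps <- scalar_params(wb = 1, bb = 0)
  expect_equal(decayVector(log(2), ps), 0.5)
  # scalar-loop oracle on random parameters
  for (k in 1:30) {
    p <- gruiParams(3, 4)
    p@Wbeta <- matrix(rnorm(12), 4, 3)
    p@bbeta <- rnorm(4)
    delta <- abs(rnorm(3))
    b <- decayVector(delta, p)
    oracle <- vapply(1:4, function(i) {
      pre <- sum(p@Wbeta[i, ] * delta) + p@bbeta[i]
      exp(-max(0, pre))
    }, numeric(1))
    expect_equal(b, oracle, tolerance = 1e-12)
    expect_true(all(b > 0 & b <= 1))
    pre <- drop(p@Wbeta %*% delta) + p@bbeta
    expect_identical(b == 1, pre <= 0)
  }
  expect_error(decayVector(c(1, 2), p), "inputSize")
})

test_that("decay never underflows to zero at extreme lags", {
  ps <- scalar_params(wb = 1, bb = 0)
  expect_gt(decayVector(1e9, ps), 1e-22)
})

test_that("plain GRU step follows the gate equations", {
  pz <- gruiParams(1, 1, init = "zero")
  expect_equal(gruStep(0.7, 0, pz), 0) # tanh(0) * sigma(0) with h = 0
  # closed update gate keeps the previous state
  pz2 <- pz
  pz2@bz <- -30
  expect_equal(gruStep(0.7, 0.4, pz2), 0.4, tolerance = 1e-10)
  # scalar arithmetic oracle
  p <- scalar_params()
  x <- 0.8
  h <- -0.5
  r <- sig(0.3 * x + (-0.2) * h + 0.1)
  htl <- tanh(0.5 * x + 0.4 * (r * h) - 0.3)
  z <- sig(-0.1 * x + 0.6 * h + 0.2)
  expect_equal(gruStep(x, h, p), (1 - z) * h + z * htl, tolerance = 1e-12)
})

test_that("GRUI step decays the previous state then gates it", {
  # beta = 1 reduction: nonpositive pre-activation makes GRUI = GRU
  p <- scalar_params(wb = -1, bb = 0)
  x <- 0.3
  h <- 0.9
  expect_equal(gruiStep(x, h, delta = 2, p), gruStep(x, h, p))
  # zero state: decay acts only on h, so delta is irrelevant
  expect_equal(gruiStep(x, 0, delta = 5, p), gruiStep(x, 0, delta = 0.1, p))
  expect_error(gruiStep(x, h, delta = -1, p), "nonnegative")
  # full scalar oracle through all four equations with delta = 1
  p2 <- scalar_params()
  beta <- exp(-max(0, 0.7 * 1 - 0.1))
  hb <- h * beta
  r <- sig(0.3 * x + (-0.2) * hb + 0.1)
  htl <- tanh(0.5 * x + 0.4 * (r * hb) - 0.3)
  z <- sig(-0.1 * x + 0.6 * hb + 0.2)
  expect_equal(gruiStep(x, h, 1, p2), (1 - z) * hb + z * htl,
    tolerance = 1e-12
  )
})

test_that("GRUI trajectory reduces to GRU when decay is inactive", {
  set.seed(42)
  for (k in 1:100) {
    d <- sample(1:3, 1)
    h <- sample(1:5, 1)
    tt <- sample(1:7, 1)
    p <- gruiParams(d, h)
    p@Wbeta <- -abs(p@Wbeta) - 0.01 # pre-activation < 0 for delta >= 0
    p@bbeta <- -abs(rnorm(h))
    X <- matrix(rnorm(d * tt), d, tt)
    lags <- matrix(abs(rnorm(d * tt)), d, tt)
    hs <- runDirection(X, lags, p, "forward")
    hcur <- numeric(h)
    for (t in seq_len(tt)) {
      hcur <- gruStep(X[, t], hcur, p)
      expect_equal(hs[, t], hcur, tolerance = 1e-12)
    }
  }
})

test_that("directional runs match loop and time-reversal oracles", {
  set.seed(7)
  d <- 3
  h <- 4
  tt <- 6
  p <- gruiParams(d, h)
  s <- random_series(d, tt, 0.3)
  lg <- timeLags(s)
  X <- matrix(rnorm(d * tt), d, tt)
  # T = 1: both directions equal one step from the zero state
  p1 <- gruiParams(d, h)
  x1 <- matrix(rnorm(d), d, 1)
  l1 <- matrix(0, d, 1)
  one <- gruiStep(x1[, 1], numeric(h), l1[, 1], p1)
  expect_equal(runDirection(x1, l1, p1, "forward")[, 1], one)
  expect_equal(runDirection(x1, l1, p1, "backward")[, 1], one)
  # forward pass = plain loop of steps
  hs <- runDirection(X, deltaF(lg), p, "forward")
  hcur <- numeric(h)
  for (t in seq_len(tt)) {
    hcur <- gruiStep(X[, t], hcur, deltaF(lg)[, t], p)
  }
  expect_equal(hs[, tt], hcur)
  # backward pass = forward pass on the time-reversed problem
  hb <- runDirection(X, deltaB(lg), p, "backward")
  rs <- reverseTime(s)
  lg_r <- timeLags(rs)
  hf_rev <- runDirection(X[, tt:1], deltaF(lg_r), p, "forward")
  expect_equal(hb, hf_rev[, tt:1], tolerance = 1e-12)
})

test_that("bidirectional states are the mean of the two directions", {
  set.seed(8)
  d <- 2
  h <- 3
  tt <- 5
  pf <- gruiParams(d, h)
  pb <- gruiParams(d, h)
  X <- matrix(rnorm(d * tt), d, tt)
  dF <- matrix(abs(rnorm(d * tt)), d, tt)
  dB <- matrix(abs(rnorm(d * tt)), d, tt)
  expect_equal(
    runBidirectional(X, dF, dB, pf, pb),
    (runDirection(X, dF, pf, "forward") +
      runDirection(X, dB, pb, "backward")) / 2
  )
  # zero backward cell contributes zero states
  pz <- gruiParams(d, h, init = "zero")
  expect_equal(
    runBidirectional(X, dF, dB, pf, pz),
    runDirection(X, dF, pf, "forward") / 2
  )
  # T = 1 with identical parameters: mean of two equal vectors
  x1 <- matrix(rnorm(d), d, 1)
  l0 <- matrix(0, d, 1)
  expect_equal(
    runBidirectional(x1, l0, l0, pf, pf)[, 1],
    runDirection(x1, l0, pf, "forward")[, 1]
  )
  pbig <- gruiParams(d, h + 1)
  expect_error(runBidirectional(X, dF, dB, pf, pbig), "hidden size")
})

test_that("hidden states stay inside (-1, 1) from a zero start", {
  set.seed(9)
  for (k in 1:20) {
    d <- sample(1:4, 1)
    h <- sample(1:6, 1)
    tt <- sample(1:15, 1)
    p <- gruiParams(d, h)
    X <- matrix(rnorm(d * tt, sd = 3), d, tt)
    lags <- matrix(abs(rnorm(d * tt)), d, tt)
    hs <- runDirection(X, lags, p, "forward")
    expect_true(all(abs(hs) < 1))
  }
})

test_that("decay is nonincreasing in lags under nonnegative weights", {
  set.seed(10)
  p <- gruiParams(2, 3)
  p@Wbeta <- abs(p@Wbeta)
  for (k in 1:20) {
    delta <- abs(rnorm(2))
    bump <- c(abs(rnorm(1)), 0)
    expect_true(all(decayVector(delta + bump, p) <= decayVector(delta, p)))
  }
})

test_that("reverse-mode gradients match central finite differences", {
  set.seed(11)
  d <- 3
  h <- 4
  tt <- 5
  net <- tbigain:::.net_new(d, h, d, bidirectional = TRUE)
  X <- matrix(rnorm(d * tt), d, tt)
  dF <- matrix(abs(rnorm(d * tt)), d, tt)
  dB <- matrix(abs(rnorm(d * tt)), d, tt)
  tgt <- matrix(rnorm(d * tt), d, tt)
  loss_of <- function(net, X) {
    sum((tbigain:::.net_forward(X, dF, dB, net) - tgt)^2)
  }
  fwd <- tbigain:::.net_forward(X, dF, dB, net, want_cache = TRUE)
  bk <- tbigain:::.net_backward(2 * (fwd$out - tgt), fwd, net)
  eps <- 1e-6
  leaves <- list(
    c("f", "Wr"), c("f", "Wh"), c("f", "Wz"), c("f", "br"),
    c("f", "Wbeta"), c("f", "bbeta"), c("b", "Wh"), c("b", "Wbeta"),
    c("proj", "W"), c("proj", "b")
  )
  for (leaf in leaves) {
    g <- bk$grads[[leaf[1]]][[leaf[2]]]
    for (rep in 1:3) {
      i <- sample(length(g), 1)
      up <- net
      up[[leaf[1]]][[leaf[2]]][i] <- up[[leaf[1]]][[leaf[2]]][i] + eps
      dn <- net
      dn[[leaf[1]]][[leaf[2]]][i] <- dn[[leaf[1]]][[leaf[2]]][i] - eps
      num <- (loss_of(up, X) - loss_of(dn, X)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
  # gradient with respect to the inputs
  for (rep in 1:5) {
    i <- sample(length(X), 1)
    Xu <- X
    Xu[i] <- Xu[i] + eps
    Xd <- X
    Xd[i] <- Xd[i] - eps
    num <- (loss_of(net, Xu) - loss_of(net, Xd)) / (2 * eps)
    expect_equal(bk$dX[i], num, tolerance = 1e-5)
  }
})
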