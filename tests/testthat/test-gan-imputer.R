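test_that("input composition blends observed data with noise", {
  X <- matrix(c(1, NA, NA, 4), 2, byrow = TRUE)
  M <- buildMask(X)
  Z <- matrix(c(9, 8, 7, 6), 2, byrow = TRUE)
  expect_equal(composeInput(X, M, Z), matrix(c(1, 8, 7, 4), 2, byrow = TRUE))
  expect_equal(composeInput(Z, matrix(1, 2, 2), 0 * Z), Z)
  expect_equal(composeInput(Z, matrix(0, 2, 2), Z + 1), Z + 1)
  expect_error(composeInput(X, M, matrix(0, 3, 2)), "dimensions")
})

test_that("completed matrix keeps every observed entry exactly", {
  X <- matrix(c(1, NA, NA, 4), 2, byrow = TRUE)
  M <- buildMask(X)
  G <- matrix(c(9, 8, 7, 6), 2, byrow = TRUE)
  xh <- assembleImputed(X, M, G)
  expect_equal(xh, matrix(c(1, 8, 7, 4), 2, byrow = TRUE))
  expect_equal(assembleImputed(G, matrix(1, 2, 2), 0 * G), G)
  expect_equal(assembleImputed(X, matrix(0, 2, 2), G), G)
})

test_that("reconstruction loss is observed-mean squared error", {
  X <- matrix(c(1, 2), 1)
  M <- matrix(c(1, 1), 1)
  expect_equal(reconstructionLoss(X, M, matrix(c(2, 4), 1)), 2.5)
  expect_equal(reconstructionLoss(X, M, X), 0)
  expect_warning(
    out <- reconstructionLoss(X, matrix(0, 1, 2), X),
    "no observed"
  )
  expect_equal(out, 0)
  # values outside the mask are ignored entirely
  Xm <- matrix(c(1, NA), 1)
  expect_equal(reconstructionLoss(Xm, buildMask(Xm), matrix(c(1, 99), 1)), 0)
})

test_that("generator objective is adversarial plus weighted recon", {
  expect_equal(generatorLoss(-1, 2, 0.15), -0.7)
  expect_equal(generatorLoss(-1, 2, 0), -1)
  expect_equal(generatorLoss(-0.3, 0, 0.15), -0.3)
})

test_that("generator forward pass composes cells and projection", {
  set.seed(30)
  s <- random_series(3, 6, 0.3)
  Z <- matrix(rnorm(18, sd = 0.01), 3, 6)
  # zero weights: output is the projection bias at every timestep
  nets0 <- imputerNets(3, 4)
  nets0@generator$f <- tbigain:::.p2l(gruiParams(3, 4, init = "zero"))
  nets0@generator$b <- tbigain:::.p2l(gruiParams(3, 4, init = "zero"))
  nets0@generator$proj$W[] <- 0
  nets0@generator$proj$b <- c(1, 2, 3)
  expect_equal(
    generatorForward(s, Z, nets0),
    matrix(c(1, 2, 3), 3, 6)
  )
  # unidirectional mode = forward-only run + projection
  nets1 <- imputerNets(3, 4, direction = "uni")
  g <- generatorForward(s, Z, nets1)
  lg <- timeLags(s)
  Xin <- composeInput(seriesValues(s), seriesMask(s), Z)
  hf <- runDirection(Xin, deltaF(lg), tbigain:::.l2p(nets1@generator$f),
    "forward"
  )
  expect_equal(g, nets1@generator$proj$W %*% hf + nets1@generator$proj$b)
  # pure function of its inputs
  expect_identical(g, generatorForward(s, Z, nets1))
  # feature mismatch is caught
  expect_error(generatorForward(random_series(2, 6), Z[1:2, ], nets1), "features")
})

test_that("discriminator scores have one entry per feature and timestep", {
  set.seed(31)
  s <- random_series(3, 5, 0.4)
  nets <- imputerNets(3, 4)
  Xhat <- matrix(rnorm(15), 3, 5)
  S <- discriminatorForward(Xhat, timeLags(s), nets)
  expect_identical(dim(S), c(3L, 5L))
  expect_true(all(is.finite(S)))
})

test_that("training runs both phases with consistent bookkeeping", {
  dat <- tiny_dataset()
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(pretrainEpochs = 2, epochs = 2)
  fit <- tbigainTrain(std$dataset, cfg)
  h <- fit$history
  expect_equal(nrow(h), 4)
  expect_equal(h$phase, rep(c("pretrain", "adversarial"), each = 2))
  expect_true(all(is.na(h$loss_d[1:2])))
  expect_true(all(is.finite(h$loss_d[3:4])))
  expect_true(all(is.finite(h$loss_recon)))
  expect_s4_class(fit$nets, "ImputerNets")
})

test_that("training is reproducible from the seed alone", {
  dat <- tiny_dataset()
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(pretrainEpochs = 1, epochs = 1)
  f1 <- tbigainTrain(std$dataset, cfg)
  f2 <- tbigainTrain(std$dataset, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  expect_equal(f1$nets@generator, f2$nets@generator, tolerance = 1e-12)
  cfg2 <- cfg
  cfg2@seed <- 99L
  f3 <- tbigainTrain(std$dataset, cfg2)
  expect_false(isTRUE(all.equal(f1$history$loss_recon, f3$history$loss_recon)))
})

test_that("pretraining reduces the reconstruction loss on AR data", {
  dat <- tiny_dataset(n = 6, tt = 16)
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(pretrainEpochs = 6, epochs = 0)
  fit <- tbigainTrain(std$dataset, cfg)
  lr <- fit$history$loss_recon
  expect_lt(lr[length(lr)], lr[1])
})

test_that("unidirectional Wasserstein mode degenerates to the antecedent architecture", {
  dat <- tiny_dataset()
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(divergence = "wasserstein", direction = "uni")
  expect_equal(cfg@dStepsPerGStep, 5L)
  fit <- tbigainTrain(std$dataset, cfg)
  # backward cells absent; critic weights clipped to the WGAN radius
  expect_null(fit$nets@generator$b)
  expect_null(fit$nets@discriminator$b)
  expect_lte(max(abs(fit$nets@discriminator$f$Wr)), 0.01)
  expect_lte(max(abs(fit$nets@discriminator$proj$W)), 0.01)
  # critic loss is the plain mean difference
  expect_equal(
    discriminatorLoss(c(2, 4), c(1, 3), getDivergence("wasserstein")), 1
  )
})

test_that("noise refinement is optional, deterministic and monotone", {
  set.seed(33)
  dat <- tiny_dataset()
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(pretrainEpochs = 2, epochs = 1)
  fit <- tbigainTrain(std$dataset, cfg)
  s <- std$dataset[[1]]
  cfg0 <- cfg
  cfg0@refineIterations <- 0L
  Z0 <- matrix(rnorm(length(seriesValues(s)), sd = 0.01), nrow = nFeatures(s))
  expect_identical(refineNoise(s, fit$nets, cfg0, Z = Z0), Z0)
  cfg2 <- cfg
  cfg2@refineIterations <- 15L
  r1 <- refineNoise(s, fit$nets, cfg2)
  r2 <- refineNoise(s, fit$nets, cfg2)
  expect_identical(r1, r2) # seeded determinism
  # the reconstruction component never increases across refinement
  recon_of <- function(Z) {
    reconstructionLoss(
      seriesValues(s), seriesMask(s),
      generatorForward(s, Z, fit$nets)
    )
  }
  expect_lte(recon_of(refineNoise(s, fit$nets, cfg2, Z = Z0)), recon_of(Z0))
  # observed noise slots are untouched
  expect_equal(r1[seriesMask(s) == 1], refineNoise(s, fit$nets, cfg2)[seriesMask(s) == 1])
})

test_that("imputation preserves observed values and fills everything", {
  dat <- tiny_dataset(n = 3, d = 3, tt = 10, rate = 0.4)
  std <- standardizeDataset(dat$dataset)
  cfg <- tiny_config(refineIterations = 3)
  fit <- tbigainTrain(std$dataset, cfg)
  comp <- tbigainImpute(std$dataset, fit$nets, cfg,
    transform = std[c("center", "scale")]
  )
  for (i in seq_along(comp)) {
    v <- seriesValues(comp[[i]])
    expect_true(all(is.finite(v)))
    orig <- seriesValues(dat$dataset[[i]])
    obs <- seriesMask(dat$dataset[[i]]) == 1
    expect_lt(max(abs(v[obs] - orig[obs])), 1e-10)
  }
  # fully observed sequence comes back unchanged
  full <- IncompleteSeries(matrix(rnorm(9), 3, 3))
  std_full <- (seriesValues(full) - std$center) / std$scale
  sfull <- IncompleteSeries(std_full)
  out <- tbigainImpute(list(sfull), fit$nets, cfg,
    transform = std[c("center", "scale")]
  )
  expect_equal(seriesValues(out[[1]]), seriesValues(full), tolerance = 1e-10)
  # seeded end-to-end reproducibility
  c2 <- tbigainImpute(std$dataset, fit$nets, cfg,
    transform = std[c("center", "scale")]
  )
  expect_identical(
    seriesValues(comp[[1]]), seriesValues(c2[[1]])
  )
  expect_error(
    tbigainImpute(list(random_series(5, 4)), fit$nets, cfg),
    "features"
  )
})

test_that("checkpoints round-trip the trained networks", {
  set.seed(34)
  nets <- imputerNets(3, 4)
  path <- tempfile(fileext = ".json")
  saveImputerNets(nets, path)
  nets2 <- loadImputerNets(path)
  expect_equal(nets2@generator, nets@generator, tolerance = 1e-12)
  expect_equal(nets2@discriminator, nets@discriminator, tolerance = 1e-12)
  expect_identical(nets2@direction, nets@direction)
  s <- random_series(3, 5)
  Z <- matrix(0, 3, 5)
  expect_equal(generatorForward(s, Z, nets2), generatorForward(s, Z, nets))
  unlink(path)
})
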