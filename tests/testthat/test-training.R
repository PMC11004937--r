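smallSetup <- function(seed = 1L) {
  spec <- syntheticSpec(imageSize = 128, cellSize = 32, mapping = "invert",
                        seed = seed)
  ds <- generateDataset(spec)
  grid <- partitionRegions(c(128, 128), 64, overlap = 32, patchSize = 32)
  list(pair = ds$pairs[[1]], grid = grid)
}

test_that("the learning-rate schedule matches the reference recipe", {
  cfg <- trainConfig()
  expect_identical(lrAtEpoch(10, cfg), 2e-4)
  expect_identical(lrAtEpoch(40, cfg), 2e-4)
  expect_equal(lrAtEpoch(60, cfg), 1e-4)
  expect_identical(lrAtEpoch(80, cfg), 0)
  expect_error(lrAtEpoch(81, cfg), class = "regiongan_contract_error")
  expect_error(lrAtEpoch(-1, cfg), class = "regiongan_contract_error")
  expect_error(trainConfig(epochs = 10, decayStart = 12),
               class = "regiongan_contract_error")
  # constant-rate configuration for short runs
  cfg2 <- trainConfig(epochs = 4, decayStart = 5)
  expect_identical(lrAtEpoch(4, cfg2), 2e-4)
})

test_that("initialisation follows the prescribed schemes", {
  set.seed(60)
  b <- buildNetworks(1, 1, N = 4, preset = "small")  # wide enough to test
  collect <- function(net, what) {
    out <- list()
    for (l in net$layers) {
      if (l$type == "conv") out <- c(out, list(l[[what]]))
      if (l$type == "residual")
        out <- c(out, list(l$conv1[[what]], l$conv2[[what]]))
      if (l$type == "dense") out <- c(out, list(l[[what]]))
    }
    out
  }
  # every bias in every network is exactly zero
  for (net in list(b@ES, b@ET, b@ESh, b@USh, b@US, b@UT, b@DS, b@DT))
    expect_true(all(vapply(collect(net, "b"),
                           function(x) all(x == 0), logical(1))))
  # discriminator weights ~ Normal(0, 0.02): pooled moments within 3 sigma
  dw <- unlist(collect(b@DS, "W"))
  n <- length(dw)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(dw)), 3 * 0.02 / sqrt(n))
  expect_lt(abs(sd(dw) - 0.02), 3 * 0.02 / sqrt(2 * n))
  # generator layers: Kaiming fan-in variance 2/fanIn within 10%
  for (l in b@ES$layers) {
    if (l$type != "conv") next
    expect_lt(abs(var(as.numeric(l$W)) - 2 / nrow(l$W)) / (2 / nrow(l$W)),
              0.1)
  }
})

test_that("a discriminator step decreases Ld on its own batch", {
  su <- smallSetup(2)
  wins <- 0L
  for (trial in 1:20) {
    set.seed(trial + 300)
    b <- buildNetworks(1, 1, nRegions(su$grid), preset = "tiny",
                       widthBase = 2)
    dist <- uniformSamplingDistribution(sourceImage(su$pair), su$grid)
    batch <- RegionGAN:::drawBatch(list(su$pair), list(dist), su$grid,
                                   32L, 2L)
    st <- list(DS = RegionGAN:::adamInit(b@DS),
               DT = RegionGAN:::adamInit(b@DT))
    before <- RegionGAN:::discStep(b, st$DS, st$DT, batch, lr = 0)$CEd
    stepped <- RegionGAN:::discStep(b, st$DS, st$DT, batch, lr = 5e-4)
    after <- RegionGAN:::discStep(stepped$bundle, stepped$stDS, stepped$stDT,
                                  batch, lr = 0)$CEd
    if (after < before) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("short training runs are finite, logged, and seed-deterministic", {
  su <- smallSetup(3)
  cfg <- trainConfig(epochs = 2, iterPerEpoch = 5, batchSize = 1,
                     decayStart = 3, seed = 11, patchSize = 32)
  fit1 <- trainModel(su$pair, su$grid, cfg)
  expect_identical(nrow(fit1$history), 10L)
  expect_true(all(is.finite(as.matrix(fit1$history[, c(
    "Lg", "Ld", "CEg", "CEd", "Lcycle", "Lrec")]))))
  expect_true(all(fit1$history$lr == 2e-4))
  fit2 <- trainModel(su$pair, su$grid, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$bundle, fit2$bundle)
})

test_that("resuming from a checkpoint reproduces the trajectory", {
  su <- smallSetup(4)
  ckdir <- tempfile(); dir.create(ckdir)
  cfg <- trainConfig(epochs = 2, iterPerEpoch = 4, batchSize = 1,
                     decayStart = 3, seed = 21, patchSize = 32,
                     checkpointEvery = 1, checkpointDir = ckdir)
  full <- trainModel(su$pair, su$grid, cfg)
  ck <- file.path(ckdir, "checkpoint_epoch001.rds")
  expect_true(file.exists(ck))
  resumed <- trainModel(su$pair, su$grid, cfg, resumeFrom = ck)
  expect_equal(resumed$history, full$history)
  expect_equal(resumed$bundle, full$bundle)
})

test_that("sampled region labels over an epoch follow P", {
  # uniform-P fixture: statistically identical regions
  spec <- syntheticSpec(imageSize = 128, cellSize = 16, mapping = "identity",
                        seed = 31)
  ds <- generateDataset(spec)
  grid <- partitionRegions(c(128, 128), 64, overlap = 32, patchSize = 32)
  dist <- uniformSamplingDistribution(sourceImage(ds$pairs[[1]]), grid)
  set.seed(32)
  ks <- vapply(1:2000, function(i)
    samplePatchPair(sourceImage(ds$pairs[[1]]), targetImage(ds$pairs[[1]]),
                    grid, dist, 32L)$region, integer(1))
  ct <- tabulate(ks, nRegions(grid))
  expect_gt(chisq.test(ct, p = samplingProbs(dist))$p.value, 0.01)
})
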