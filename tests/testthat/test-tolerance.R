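test_that("pearsonCorrelation matches closed forms and flags degeneracy", {
  u <- c(1, 2, 3, 5, 4)
  expect_equal(pearsonCorrelation(u, u), 1)
  expect_equal(pearsonCorrelation(u, -u), -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 4)), 0.981981,
               tolerance = 1e-5)
  expect_error(pearsonCorrelation(1:3, 1:4),
               class = "regiongan_contract_error")
  r <- pearsonCorrelation(c(1, 1, 1), c(1, 2, 3))
  expect_identical(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
})

test_that("the built-in descriptor is deterministic with fixed length", {
  p1 <- rimg(24, 24, seed = 4)
  expect_identical(defaultFeatureDescriptor(p1), defaultFeatureDescriptor(p1))
  expect_length(defaultFeatureDescriptor(p1), 80L)
  expect_length(defaultFeatureDescriptor(rimg(100, 60, seed = 5)), 80L)
  expect_length(defaultFeatureDescriptor(rimg(16, 16, 3L, seed = 6)), 80L)
  expect_error(defaultFeatureDescriptor(rimg(7, 20, seed = 7)),
               class = "regiongan_contract_error")
})

test_that("descriptor separates perturbed copies from independent textures", {
  # correlation(noisy copy) should beat correlation(independent texture)
  set.seed(8)
  wins <- 0L
  for (i in 1:100) {
    base <- renderPatch <- RegionGAN:::renderTexture(c(32L, 32L), 16L,
                                                     i, i + 1L)
    noisy <- pmin(pmax(base + rnorm(length(base), 0, 0.02), 0), 1)
    other <- RegionGAN:::renderTexture(c(32L, 32L), 16L, i + 5000L,
                                       i + 5001L)
    f0 <- defaultFeatureDescriptor(base)
    cSame <- pearsonCorrelation(f0, defaultFeatureDescriptor(noisy))
    cOther <- pearsonCorrelation(f0, defaultFeatureDescriptor(other))
    if (cSame > cOther) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("tolerance search honours forced and degenerate configurations", {
  src <- rimg(64, 64, seed = 9); tgt <- rimg(64, 64, seed = 10)
  cfg <- toleranceSearchConfig(32, 32, numSampling = 4, seed = 1)
  r <- optimizeTolerance(src, tgt, cfg)
  expect_identical(r$tolerance, 32L)
  expect_length(r$objective, 1L)

  expect_error(
    optimizeTolerance(src, tgt, toleranceSearchConfig(32, 128,
                                                      numSampling = 2)),
    class = "regiongan_geometry_error")
  expect_error(toleranceSearchConfig(64, 32),
               class = "regiongan_contract_error")
  # memory floor: a lower bound implying too many regions is rejected
  expect_error(
    optimizeTolerance(src, tgt,
                      toleranceSearchConfig(2, 32, numSampling = 2,
                                            headCap = 16L)),
    class = "regiongan_contract_error")
})

test_that("stationary identical textures select the largest candidate", {
  img <- RegionGAN:::renderTexture(c(128L, 128L), 8L, 21L, 22L)
  img <- array(img, c(dim(img), 1L))
  cfg <- toleranceSearchConfig(16, 64, numSampling = 12, seed = 2)
  r <- optimizeTolerance(img, img, cfg)
  # matched positions on identical images: every correlation is ~1, the
  # curve is flat, and the tie band returns the largest candidate
  expect_identical(r$tolerance, 64L)
  expect_true(all(abs(r$objective - cfg$numSampling) < 0.05 * cfg$numSampling))
})

test_that("search is deterministic, bounded, and plug-compatible", {
  pr <- makeToleranceValidationPair(c(128L, 128L), 16L, seed = 31L)
  cfg <- toleranceSearchConfig(8, 64, numSampling = 6, seed = 5)
  r1 <- optimizeTolerance(pr$source, pr$target, cfg)
  r2 <- optimizeTolerance(pr$source, pr$target, cfg)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$objective) <= cfg$numSampling))
  expect_length(r1$objective, length(r1$candidates))

  # swapping the extractor preserves the contract
  meanSd <- function(patch) c(mean(patch), stats::sd(patch), range(patch))
  cfg2 <- toleranceSearchConfig(8, 64, numSampling = 6, seed = 5,
                                featureExtractor = meanSd)
  r3 <- optimizeTolerance(pr$source, pr$target, cfg2)
  expect_length(r3$objective, length(r1$candidates))
  expect_false(identical(r3$objective, r1$objective))
})
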