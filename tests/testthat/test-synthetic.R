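test_that("the identity configuration delivers the ground truth exactly", {
  spec <- syntheticSpec(imageSize = 96, cellSize = 16, mapping = "invert",
                        misalignment = 0, noiseSd = 0, seed = 5)
  ds <- generateDataset(spec)
  expect_identical(targetImage(ds$pairs[[1]]), ds$groundTruth[[1]])
  # same seed: byte-identical dataset
  ds2 <- generateDataset(spec)
  expect_identical(ds, ds2)
})

test_that("appearance mappings are invertible", {
  spec <- syntheticSpec(imageSize = 64, cellSize = 16, seed = 6)
  for (m in c("invert", "gamma", "invertMix2", "gammaMix2", "invertMix3",
              "identity")) {
    sp <- syntheticSpec(imageSize = 64, cellSize = 16, mapping = m, seed = 6)
    ds <- generateDataset(sp)
    rec <- invertAppearanceMapping(ds$groundTruth[[1]], m)
    expect_lt(max(abs(rec - sourceImage(ds$pairs[[1]]))), 1e-6)
  }
})

test_that("patch misalignment displaces by d and permutes pixels", {
  img <- rimg(128, 128, seed = 7)
  set.seed(8)
  out0 <- applyMisalignment(img, 0, 16)
  expect_identical(out0$image, img)
  expect_true(all(out0$manifest$vy == 0 & out0$manifest$vx == 0))

  set.seed(9)
  out <- applyMisalignment(img, 32, 16)
  moved <- out$manifest$vy != 0 | out$manifest$vx != 0
  expect_gt(mean(moved), 0.5)
  norms <- sqrt(out$manifest$vy[moved]^2 + out$manifest$vx[moved]^2)
  expect_true(all(abs(norms - 32) <= 0.5))
  # swaps permute pixels: multisets agree
  expect_identical(sort(as.numeric(out$image)), sort(as.numeric(img)))
  expect_false(identical(out$image, img))

  expect_error(applyMisalignment(img, 8, 16),
               class = "regiongan_geometry_error")
  expect_error(applyMisalignment(rimg(20, 20, seed = 1), 400, 16),
               class = "regiongan_geometry_error")
  expect_error(syntheticSpec(imageSize = 64, misalignment = 64), "half")
})

test_that("the dataset records displacement norms matching the spec", {
  spec <- syntheticSpec(imageSize = 768, cellSize = 64, mapping = "invert",
                        misalignment = 256, misalignGrid = 64, seed = 10)
  ds <- generateDataset(spec)
  man <- ds$manifest$images[[1]]$displacements
  moved <- man$vy != 0 | man$vx != 0
  expect_gt(sum(moved), 0)
  norms <- sqrt(man$vy[moved]^2 + man$vx[moved]^2)
  expect_true(all(abs(norms - 256) <= 0.5))
})

test_that("alignment degrades monotonically with the displacement distance", {
  # fine-grained displacement so similarity degrades gradually; the sweep
  # skips distances near the fibre wavelength (8-16 px at this cell size),
  # where quasi-periodic textures partially re-align
  vals <- vapply(c(0, 4, 8, 32), function(d) {
    spec <- syntheticSpec(imageSize = 256, cellSize = 32, mapping = "invert",
                          misalignment = d, misalignGrid = 4L, seed = 11)
    ds <- generateDataset(spec)
    suppressWarnings(msSSIM(ds$groundTruth[[1]],
                            targetImage(ds$pairs[[1]])))
  }, numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) <= 0.02))  # nonincreasing up to estimator noise
})

test_that("noise and affine jitter degrade the delivered target only", {
  spec <- syntheticSpec(imageSize = 96, cellSize = 16, mapping = "invert",
                        affineJitter = c(3, 0.02, 0.01), noiseSd = 0.05,
                        seed = 12)
  ds <- generateDataset(spec)
  gt <- ds$groundTruth[[1]]
  delivered <- targetImage(ds$pairs[[1]])
  expect_gt(mean(abs(gt - delivered)), 0.01)
  expect_false(isTRUE(all.equal(gt, delivered)))
  aff <- ds$manifest$images[[1]]$affine
  expect_true(all(abs(aff[1:2]) <= 3) && abs(aff[3]) <= 0.02)
})

test_that("the scale-validation pair is reproducible with displaced detail", {
  pr1 <- makeToleranceValidationPair(c(128L, 128L), 32L, seed = 13L)
  pr2 <- makeToleranceValidationPair(c(128L, 128L), 32L, seed = 13L)
  expect_identical(pr1, pr2)
  moved <- pr1$displacements$vy != 0 | pr1$displacements$vx != 0
  expect_gt(mean(moved), 0.5)
  expect_false(identical(pr1$source, pr1$target))
})
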