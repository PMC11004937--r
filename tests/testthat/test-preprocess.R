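test_that("intensity scaling normalises, clips spikes, and reports", {
  # constant image: degenerate passthrough rescaled to 0
  r0 <- intensityScale(matrix(5, 10, 10))
  expect_true(r0$degenerate)
  expect_true(all(r0$image == 0))

  # bulk uniform values plus bright spikes: spikes saturate at 1
  set.seed(20)
  v <- c(runif(1e6), rep(10, 100))
  img <- matrix(sample(v), 10001, 100)
  r <- intensityScale(img)
  expect_false(r$degenerate)
  expect_true(all(r$image >= 0 & r$image <= 1))
  # the clip value sits in the top 0.1% neighbourhood of the uniform bulk
  expect_gt(r$clip, 0.99)
  expect_lte(r$clip, 10)
  expect_true(all(r$image[img == 10] == 1))
  expect_false(is.na(r$threshold))
  expect_false(is.na(r$fence))

  # monotone nondecreasing mapping
  o <- order(as.numeric(img))
  expect_true(all(diff(as.numeric(r$image)[o]) >= 0))

  # near-idempotent on an already-scaled image
  r2 <- intensityScale(r$image)
  expect_lt(max(abs(r2$image - r$image)), 1e-6)
})

test_that("Sobel-Feldman channels follow the kernel arithmetic", {
  cst <- sobelChannels(matrix(0.3, 8, 8))
  expect_identical(dim(cst), c(8L, 8L, 3L))
  expect_true(all(cst[, , 2] == 0.5))
  expect_true(all(cst[, , 3] == 0.5))

  # horizontal ramp with unit pixel step: interior Gx = 8, Gy = 0
  ramp <- matrix(rep(0:7, each = 8), 8, 8)  # column j has value j - 1
  raw <- sobelChannels(ramp, scale = FALSE)
  expect_true(all(raw[2:7, 2:7, 2] == 8))
  expect_true(all(raw[2:7, 2:7, 3] == 0))

  s <- sobelChannels(rimg(12, 9, seed = 21))
  expect_identical(dim(s), c(12L, 9L, 3L))
  expect_error(sobelChannels(rimg(8, 8, 3L, seed = 22)),
               class = "regiongan_contract_error")
  expect_error(sobelChannels(matrix(0, 2, 5)),
               class = "regiongan_contract_error")
})

test_that("point-based affine estimation recovers exact transforms", {
  set.seed(23)
  src <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  r0 <- affineFromPoints(src, src)
  expect_lt(max(abs(r0$affine - cbind(diag(2), c(0, 0)))), 1e-12)

  A <- matrix(c(1.2, 0.1, -0.2, 0.9, 5, -3), 2, 3)
  dst <- t(A %*% t(cbind(src, 1)))
  r <- affineFromPoints(src, dst)
  expect_lt(max(abs(r$affine - A)), 1e-10)
  expect_lt(r$rmse, 1e-10)

  # exact correspondences of any size >= 3 have ~zero residual
  for (n in c(3, 5, 20)) {
    srcN <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    dstN <- t(A %*% t(cbind(srcN, 1)))
    expect_lt(affineFromPoints(srcN, dstN)$rmse, 1e-10)
  }

  coll <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(affineFromPoints(coll, coll),
               class = "regiongan_geometry_error")
  expect_error(affineFromPoints(src[1:2, ], src[1:2, ]),
               class = "regiongan_geometry_error")
})

test_that("local affine refinement maximises Pearson correlation", {
  tgt <- RegionGAN:::renderTexture(c(96L, 96L), 24L, 41L, 42L)
  tgt <- array(tgt, c(dim(tgt), 1L))
  patch <- tgt[33:64, 33:64, , drop = FALSE]
  initAt <- function(dx, dy) matrix(c(1, 0, 0, 1, 32 + dx, 32 + dy), 2, 3)

  aligned <- refineLocalAffine(patch, tgt, initAt(0, 0))
  expect_gte(aligned$correlation, 0.999)
  expect_lt(max(abs(aligned$params[1:2])), 1)

  # known shift within the search range is recovered to within a pixel
  shifted <- refineLocalAffine(patch, tgt, initAt(-5, 3))
  expect_gte(shifted$correlation, 0.95)
  expect_lt(abs(shifted$params[1] - 5), 1)
  expect_lt(abs(shifted$params[2] + 3), 1)

  # refinement never falls below the initial correlation
  expect_gte(shifted$correlation, shifted$initCorrelation)

  expect_error(refineLocalAffine(array(0.5, c(16, 16, 1)), tgt, initAt(0, 0)),
               class = "regiongan_degenerate_error")
  expect_warning(refineLocalAffine(patch, tgt,
                                   matrix(c(1, 0, 0, 1, 90, 90), 2, 3)),
                 "clamped")
})
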