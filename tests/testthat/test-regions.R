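test_that("partition covers exactly with row-major regions", {
  g <- partitionRegions(c(1024, 1024), 512)
  expect_equal(nRegions(g), 4L)
  expect_equal(unname(regionRects(g)),
               matrix(c(0L, 0L, 512L, 512L,
                        0L, 512L, 512L, 1024L,
                        512L, 0L, 1024L, 512L,
                        512L, 512L, 1024L, 1024L),
                      4, 4, byrow = TRUE))

  # boundary regions truncate at the edge
  g2 <- partitionRegions(c(1000, 1000), 512)
  expect_equal(nRegions(g2), 4L)
  r <- regionRects(g2)
  expect_equal(unname(r[4, ]), c(512L, 512L, 1000L, 1000L))
  expect_equal(r[4, "row1"] - r[4, "row0"], c(row1 = 488L))

  # identity case
  g3 <- partitionRegions(c(512, 512), 512)
  expect_equal(nRegions(g3), 1L)
  expect_equal(unname(regionRects(g3)[1, ]), c(0L, 0L, 512L, 512L))
})

test_that("partition rejects images too small for one patch", {
  expect_error(partitionRegions(c(16, 128), 16, overlap = 16, patchSize = 32),
               class = "regiongan_geometry_error")
  expect_error(partitionRegions(c(100, 100), 200),
               class = "regiongan_geometry_error")
  expect_error(partitionRegions(c(64, 64), 32, overlap = 0, patchSize = 48),
               class = "regiongan_contract_error")
})

test_that("coverage and exclusivity hold over random geometries", {
  set.seed(42)
  for (i in 1:25) {
    H <- sample(20:200, 1); W <- sample(20:200, 1)
    tol <- sample(5:min(H, W), 1)
    g <- partitionRegions(c(H, W), tol, overlap = 8, patchSize = 4)
    # validity already asserts single coverage; re-check independently
    owner <- matrix(0L, H, W)
    r <- regionRects(g)
    for (k in seq_len(nrow(r)))
      owner[(r[k, 1] + 1):r[k, 3], (r[k, 2] + 1):r[k, 4]] <-
        owner[(r[k, 1] + 1):r[k, 3], (r[k, 2] + 1):r[k, 4]] + 1L
    expect_true(all(owner == 1L))
    expect_equal(nrow(r), ceiling(H / tol) * ceiling(W / tol))
  }
})

test_that("hand-computed sampling cases give the expected P", {
  g <- tinyGrid()
  # four distinct constant regions, source == target
  img <- constantBlockImage(c(0.1, 0.3, 0.5, 0.7))
  d <- computeSamplingDistribution(img, img, g, bins = 64)
  expect_equal(samplingScores(d), rep(1, 4))
  expect_equal(samplingProbs(d), rep(1 / 4, 4))

  # three regions share a value, the fourth is rare
  img2 <- constantBlockImage(c(0.1, 0.1, 0.1, 0.7))
  d2 <- computeSamplingDistribution(img2, img2, g, bins = 64)
  expect_equal(samplingScores(d2), c(1 / 3, 1 / 3, 1 / 3, 1))
  expect_equal(samplingProbs(d2), c(1 / 6, 1 / 6, 1 / 6, 1 / 2))
})

test_that("Q and P match a brute-force evaluation of the formulas", {
  set.seed(7)
  for (i in 1:20) {
    H <- sample(c(8L, 12L, 16L), 1); tol <- sample(c(4L, 8L), 1)
    if (tol > H) tol <- H
    g <- partitionRegions(c(H, H), tol, overlap = 0, patchSize = 4)
    src <- array(round(runif(H * H), 2), c(H, H, 1))
    tgt <- array(round(runif(H * H), 2), c(H, H, 1))
    d <- computeSamplingDistribution(src, tgt, g, bins = 64)
    bf <- bruteForceQP(src, tgt, g, bins = 64)
    expect_lt(max(abs(samplingScores(d) - bf$Q)), 1e-12)
    expect_lt(max(abs(samplingProbs(d) - bf$P)), 1e-12)
  }
})

test_that("P is uniform when regions are statistically identical", {
  g <- tinyGrid()
  img <- constantBlockImage(rep(0.4, 4))
  d <- computeSamplingDistribution(img, img, g, bins = 16)
  expect_identical(samplingProbs(d), rep(1 / 4, 4))
  # fuzz: P is a distribution for arbitrary images
  set.seed(11)
  for (i in 1:10) {
    src <- rimg(8, 8, seed = i); tgt <- rimg(8, 8, seed = i + 100)
    g8 <- partitionRegions(c(8, 8), 4, overlap = 0, patchSize = 4)
    d <- computeSamplingDistribution(src, tgt, g8, bins = 32)
    expect_true(all(samplingProbs(d) >= 0))
    expect_lt(abs(sum(samplingProbs(d)) - 1), 1e-9)
  }
})

test_that("all-zero scores raise the degenerate error and uniform fallback works", {
  g <- tinyGrid()
  src <- constantBlockImage(c(0.1, 0.3, 0.5, 0.7))
  src[1, 1] <- 0.11; src[1, 3] <- 0.31; src[3, 1] <- 0.51; src[3, 3] <- 0.71
  tgt <- 1 - src  # every region perfectly anti-correlated
  expect_error(computeSamplingDistribution(src, tgt, g, bins = 8),
               class = "regiongan_degenerate_error")
  u <- uniformSamplingDistribution(src, g, bins = 8)
  expect_equal(samplingProbs(u), rep(1 / 4, 4))
})

test_that("patch sampling respects the categorical distribution and geometry", {
  g <- partitionRegions(c(32, 32), 16, overlap = 4, patchSize = 8)
  src <- rimg(32, 32, seed = 1); tgt <- rimg(32, 32, seed = 2)
  H <- matrix(1 / 8, 4, 8)
  oneHotP <- new("SamplingDistribution", H = H, Q = c(0, 0, 1, 0),
                 P = c(0, 0, 1, 0))
  set.seed(3)
  for (i in 1:20) {
    draw <- samplePatchPair(src, tgt, g, oneHotP, 8)
    expect_identical(draw$region, 3L)
    expect_identical(dim(draw$source), c(8L, 8L, 1L))
    expect_identical(dim(draw$target), c(8L, 8L, 1L))
  }

  # identical seeds give identical draw sequences
  unif <- new("SamplingDistribution", H = H, Q = rep(1, 4), P = rep(1 / 4, 4))
  seqOf <- function() {
    set.seed(99)
    lapply(1:10, function(i) samplePatchPair(src, tgt, g, unif, 8))
  }
  expect_identical(seqOf(), seqOf())

  # empirical frequencies within 3-sigma binomial bounds of P
  p <- c(0.1, 0.2, 0.3, 0.4)
  dist <- new("SamplingDistribution", H = H, Q = p, P = p)
  set.seed(5)
  n <- 4000
  ks <- vapply(seq_len(n), function(i)
    samplePatchPair(src, tgt, g, dist, 8)$region, integer(1))
  freq <- tabulate(ks, 4) / n
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n)))
})

test_that("grid and distribution serialise to a JSON report", {
  g <- tinyGrid()
  img <- constantBlockImage(c(0.1, 0.3, 0.5, 0.7))
  d <- computeSamplingDistribution(img, img, g, bins = 16)
  js <- gridReport(g, d)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(parsed$regions), 4L)
  expect_equal(parsed$regions[[1]]$class, 0L)
  expect_equal(unlist(parsed$P), rep(0.25, 4))
  f <- tempfile(fileext = ".json")
  gridReport(g, d, f)
  expect_true(file.exists(f))
})
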