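# Shared fixtures: tiny images and bundles built in code at test time.

# deterministic random image
rimg <- function(h, w, c = 1L, seed = 1L) {
  set.seed(seed)
  array(stats::runif(h * w * c), c(h, w, c))
}

# four-region grid over a 4x4 image with 2x2 constant blocks
constantBlockImage <- function(values) {
  img <- matrix(0, 4, 4)
  img[1:2, 1:2] <- values[1]; img[1:2, 3:4] <- values[2]
  img[3:4, 1:2] <- values[3]; img[3:4, 3:4] <- values[4]
  img
}

tinyGrid <- function() partitionRegions(c(4, 4), 2, overlap = 0, patchSize = 2)

# straight-line reimplementation of the printed sampling-rule formulas,
# independent of the package internals (same histogram convention: B equal
# bins on [0, 1], clamped)
bruteForceQP <- function(source, target, grid, bins = 64L) {
  N <- nRegions(grid)
  rects <- regionRects(grid)
  H <- matrix(0, N, bins)
  corr <- numeric(N)
  for (i in seq_len(N)) {
    r <- rects[i, ]
    sv <- as.numeric(source[(r[1] + 1):r[3], (r[2] + 1):r[4], , drop = FALSE])
    tv <- as.numeric(target[(r[1] + 1):r[3], (r[2] + 1):r[4], , drop = FALSE])
    corr[i] <- if (sd(sv) == 0 || sd(tv) == 0) 0 else
      sum((sv - mean(sv)) * (tv - mean(tv))) /
        (sqrt(sum((sv - mean(sv))^2)) * sqrt(sum((tv - mean(tv))^2)))
    idx <- pmin(pmax(floor(sv * bins) + 1, 1), bins)
    for (b in idx) H[i, b] <- H[i, b] + 1
    H[i, ] <- H[i, ] / sum(H[i, ])
  }
  Q <- numeric(N)
  for (i in seq_len(N)) {
    den <- 0
    for (j in seq_len(N)) den <- den + sum(H[i, ] * H[j, ])
    Q[i] <- (1 + corr[i]) / den
  }
  list(Q = Q, P = Q / sum(Q))
}

# tiny network bundle for structural and loss tests
tinyBundle <- function(N = 4L, cs = 1L, ct = 1L, seed = 1L, widthBase = 2L) {
  set.seed(seed)
  buildNetworks(cs, ct, N, preset = "tiny", widthBase = widthBase)
}

# bundle whose discriminators output the uniform distribution: zero weights
# give zero logits everywhere, hence uniform softmax at every location
uniformDiscBundle <- function(N = 3L, seed = 1L) {
  b <- tinyBundle(N = N, seed = seed)
  zero <- function(net) {
    for (i in seq_along(net$layers)) {
      l <- net$layers[[i]]
      if (l$type == "conv") { l$W[] <- 0; l$b[] <- 0 }
      if (l$type == "residual") {
        l$conv1$W[] <- 0; l$conv1$b[] <- 0
        l$conv2$W[] <- 0; l$conv2$b[] <- 0
      }
      net$layers[[i]] <- l
    }
    net
  }
  b@DS <- zero(b@DS)
  b@DT <- zero(b@DT)
  b
}
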