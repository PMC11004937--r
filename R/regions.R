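#' Partition an image into tolerance-sized regions
#'
#' Divides the image plane into N mutually exclusive square regions of side
#' \code{tolerance} laid out in row-major spatial order; boundary regions are
#' truncated at the image edge so that the partition covers the image exactly,
#' with no padding pixels. Each region is also expanded by \code{overlap}
#' pixels on every side (clipped to the image bounds) to form the rectangle
#' from which training patches are cropped, so that features are partially
#' shared between neighbouring regions.
#'
#' @param imageShape integer(2), image height and width in pixels.
#' @param tolerance integer(1), region side length in pixels.
#' @param overlap integer(1), expansion margin in pixels. Default 64.
#' @param patchSize integer(1), training patch side; every expanded region
#'   must accommodate it.
#' @return a [RegionGrid-class] with \code{ceiling(H / tolerance) *
#'   ceiling(W / tolerance)} regions.
#' @examples
#' g <- partitionRegions(c(1024, 1024), tolerance = 512)
#' nRegions(g)  # 4
#' @export
partitionRegions <- function(imageShape, tolerance, overlap = 64L,
                             patchSize = 64L) {
  imageShape <- as.integer(imageShape)
  tolerance <- as.integer(tolerance)
  overlap <- as.integer(overlap)
  patchSize <- as.integer(patchSize)
  if (tolerance < 1L) stopContract("tolerance must be >= 1")
  if (overlap < 0L) stopContract("overlap must be >= 0")
  if (patchSize > tolerance + 2L * overlap)
    stopContract("patch size %d exceeds tolerance + 2*overlap = %d",
                 patchSize, tolerance + 2L * overlap)
  H <- imageShape[1]; W <- imageShape[2]
  if (H < tolerance || W < tolerance)
    stopGeometry("image (%d x %d) is smaller than one tolerance region (%d)",
                 H, W, tolerance)
  nr <- ceiling(H / tolerance); nc <- ceiling(W / tolerance)
  regions <- matrix(0L, nr * nc, 4L)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      regions[k, ] <- c((i - 1L) * tolerance, (j - 1L) * tolerance,
                        min(i * tolerance, H), min(j * tolerance, W))
    }
  }
  expanded <- cbind(pmax(regions[, 1] - overlap, 0L),
                    pmax(regions[, 2] - overlap, 0L),
                    pmin(regions[, 3] + overlap, H),
                    pmin(regions[, 4] + overlap, W))
  small <- which(expanded[, 3] - expanded[, 1] < patchSize |
                 expanded[, 4] - expanded[, 2] < patchSize)
  if (length(small)) {
    bad <- expanded[small[1], ]
    dimname <- if (bad[3] - bad[1] < patchSize) "height" else "width"
    stopGeometry(
      "expanded region %d has %s %d < patch size %d; image too small for one patch",
      small[1], dimname,
      min(bad[3] - bad[1], bad[4] - bad[2]), patchSize)
  }
  new("RegionGrid", imageShape = imageShape, tolerance = tolerance,
      overlap = overlap, patchSize = patchSize,
      regions = regions, expanded = expanded)
}

# Pearson correlation of a region's source and target pixel vectors.
# Different channel counts are reduced to channel means first; constant
# vectors yield 0 (a constant region is no evidence either way).
regionPearson <- function(sPix, tPix) {
  if (length(sPix) != length(tPix)) {
    stopContract("source/target pixel vectors differ in length")
  }
  if (stats::sd(sPix) == 0 || stats::sd(tPix) == 0) return(0)
  stats::cor(sPix, tPix)
}

regionPixelVector <- function(img, rect, channels) {
  px <- cropRect(img, rect)
  if (dim(px)[3] != channels) px <- apply(px, c(1, 2), mean)
  as.numeric(px)
}

# Histogram over `bins` equal-width bins spanning `range`; values clamped
# into the outer bins; normalised to sum 1.
normalisedHistogram <- function(values, bins, range) {
  idx <- floor((values - range[1]) / diff(range) * bins) + 1
  idx <- pmin(pmax(idx, 1), bins)
  h <- tabulate(idx, nbins = bins)
  h / sum(h)
}

#' Compute the global patch-sampling distribution
#'
#' For each region i of the grid, the score
#' \deqn{Q_i = \frac{1 + \mathrm{cor}(S_i, T_i)}{\sum_{j=1}^N H_i \cdot H_j}}
#' combines the Pearson correlation of the region's source and target pixel
#' vectors (the better the two domains agree locally, the more the region is
#' trained) with the summed dot products of its normalised pixel histogram
#' \eqn{H_i} against all regions' histograms (the rarer the region's intensity
#' distribution, the more it is trained). Sampling probabilities are
#' \eqn{P_i = Q_i / \sum_j Q_j}.
#'
#' A region whose source or target pixels are constant has undefined Pearson
#' correlation; it is defined as 0 here. When source and target channel counts
#' differ, the correlation is computed on per-pixel channel means.
#'
#' @param source,target matrices or (H, W, C) arrays sharing the grid's
#'   spatial shape.
#' @param grid a [RegionGrid-class].
#' @param bins number of histogram bins B (default 64).
#' @param histogramFrom which pixels feed the histograms: the source image
#'   (default, since sampling selects translation inputs), the target image,
#'   or both concatenated.
#' @param range declared intensity range spanned by the histogram bins.
#' @return a [SamplingDistribution-class].
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), each = 8), 4, 4)
#' g <- partitionRegions(c(4, 4), 2, overlap = 0, patchSize = 2)
#' computeSamplingDistribution(img, img, g, bins = 8)
#' @export
computeSamplingDistribution <- function(source, target, grid, bins = 64L,
                                        histogramFrom = c("source", "target",
                                                          "joint"),
                                        range = c(0, 1)) {
  histogramFrom <- match.arg(histogramFrom)
  source <- asImageArray(source, "source")
  target <- asImageArray(target, "target")
  if (any(dim(source)[1:2] != grid@imageShape) ||
      any(dim(target)[1:2] != grid@imageShape))
    stopContract("source/target spatial shape must match the grid")
  if (bins < 2L) stopContract("bins must be >= 2")
  N <- nRegions(grid)
  cs <- dim(source)[3]; ct <- dim(target)[3]
  ch <- if (cs == ct) cs else 1L
  H <- matrix(0, N, bins)
  corr <- numeric(N)
  for (i in seq_len(N)) {
    rect <- grid@regions[i, ]
    sPix <- regionPixelVector(source, rect, ch)
    tPix <- regionPixelVector(target, rect, ch)
    corr[i] <- regionPearson(sPix, tPix)
    hv <- switch(histogramFrom,
                 source = as.numeric(cropRect(source, rect)),
                 target = as.numeric(cropRect(target, rect)),
                 joint = c(as.numeric(cropRect(source, rect)),
                           as.numeric(cropRect(target, rect))))
    H[i, ] <- normalisedHistogram(hv, bins, range)
  }
  denom <- as.numeric(H %*% colSums(H))  # sum_j Hi . Hj for each i
  Q <- (1 + corr) / denom
  if (all(Q == 0))
    stopDegenerate(paste0(
      "all region scores are zero (every region perfectly anti-correlated); ",
      "fall back to uniform sampling probabilities 1/N"))
  new("SamplingDistribution", H = H, Q = Q, P = Q / sum(Q))
}

#' Uniform sampling distribution over a grid's regions
#'
#' The fallback distribution when every region score is zero (which requires
#' a Pearson correlation of exactly -1 in every region, e.g. two perfectly
#' anti-correlated stains): all regions are sampled with probability 1/N.
#' Histograms are still computed from the image for reporting.
#'
#' @param source source image conforming to the grid.
#' @param grid a [RegionGrid-class].
#' @param bins histogram bins.
#' @param range declared intensity range.
#' @return a [SamplingDistribution-class] with uniform P.
#' @export
uniformSamplingDistribution <- function(source, grid, bins = 64L,
                                        range = c(0, 1)) {
  source <- asImageArray(source, "source")
  N <- nRegions(grid)
  H <- t(vapply(seq_len(N), function(i)
    normalisedHistogram(as.numeric(cropRect(source, grid@regions[i, ])),
                        bins, range), numeric(bins)))
  new("SamplingDistribution", H = H, Q = rep(1 / N, N), P = rep(1 / N, N))
}

#' Draw a source/target training patch pair
#'
#' A region index is drawn from the categorical distribution P of the global
#' sampling rule; a source patch and a target patch of side \code{patchSize}
#' are then cropped at independent uniform positions inside the region's
#' overlap-expanded rectangle. Positions are independent because within a
#' region the translation is learned without pixelwise registration.
#'
#' Uses the current R random number generator state; call \code{set.seed()}
#' beforehand for reproducible draws.
#'
#' @param source,target images conforming to the grid.
#' @param grid a [RegionGrid-class].
#' @param dist a [SamplingDistribution-class] matching the grid.
#' @param patchSize patch side in pixels; defaults to the grid's patch size.
#' @return list with elements \code{source}, \code{target} (patch arrays) and
#'   \code{region} (the 1-based region index).
#' @export
samplePatchPair <- function(source, target, grid, dist,
                            patchSize = grid@patchSize) {
  N <- nRegions(grid)
  if (length(dist@P) != N)
    stopContract("distribution has %d regions but grid has %d",
                 length(dist@P), N)
  source <- asImageArray(source, "source")
  target <- asImageArray(target, "target")
  k <- sample.int(N, 1L, prob = dist@P)
  e <- grid@expanded[k, ]
  maxR <- e[3] - patchSize; maxC <- e[4] - patchSize
  if (maxR < e[1] || maxC < e[2])
    stopGeometry("patch size %d does not fit expanded region %d", patchSize, k)
  crop1 <- function(img) {
    r0 <- e[1] + sample.int(maxR - e[1] + 1L, 1L) - 1L
    c0 <- e[2] + sample.int(maxC - e[2] + 1L, 1L) - 1L
    img[(r0 + 1L):(r0 + patchSize), (c0 + 1L):(c0 + patchSize), , drop = FALSE]
  }
  list(source = crop1(source), target = crop1(target), region = k)
}

#' Serialise a grid and sampling distribution to a JSON report
#'
#' Writes the region rectangles (0-based half-open coordinates with 0-based
#' class labels), the scores Q and the probabilities P.
#'
#' @param grid a [RegionGrid-class].
#' @param dist optional [SamplingDistribution-class].
#' @param file path to write; with \code{NULL} the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
gridReport <- function(grid, dist = NULL, file = NULL) {
  rects <- regionRects(grid)
  rep <- list(
    image_shape = as.integer(grid@imageShape),
    tolerance = grid@tolerance,
    overlap = grid@overlap,
    patch_size = grid@patchSize,
    regions = lapply(seq_len(nrow(rects)), function(i)
      list(class = i - 1L, row0 = rects[i, 1], col0 = rects[i, 2],
           row1 = rects[i, 3], col1 = rects[i, 4]))
  )
  if (!is.null(dist)) {
    rep$Q <- dist@Q
    rep$P <- dist@P
  }
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
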