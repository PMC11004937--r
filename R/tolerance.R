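#' Pearson correlation with a degenerate-input flag
#'
#' Standard Pearson correlation coefficient of two equal-length vectors.
#' If either vector is constant the coefficient is undefined; 0 is returned
#' with attribute \code{degenerate = TRUE} so that callers can count how many
#' comparisons carried no information.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return numeric(1) in [-1, 1], possibly with attribute \code{degenerate}.
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(1, 2, 4))  # 0.98198
#' @export
pearsonCorrelation <- function(u, v) {
  if (length(u) != length(v))
    stopContract("vectors differ in length (%d vs %d)", length(u), length(v))
  if (length(u) < 2L) stopContract("vectors must have length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(u, v)
}

# Average-pool an (H, W) matrix onto a g x g grid of block means.
blockMeans <- function(m, g = 8L) {
  ri <- floor((seq_len(nrow(m)) - 1L) * g / nrow(m)) + 1L
  ci <- floor((seq_len(ncol(m)) - 1L) * g / ncol(m)) + 1L
  sums <- rowsum(m, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- outer(tabulate(ri, g), tabulate(ci, g))
  sums / cnt
}

#' Built-in patch feature descriptor
#'
#' The default feature extractor for the tolerance search: a fixed-length
#' (80-element) descriptor of an image patch, concatenating an 8 x 8 grid of
#' block-mean intensities with a 16-bin gradient-orientation histogram
#' (magnitude-weighted). Each of the two blocks is standardised to zero mean
#' and unit variance within the descriptor, so that correlations between
#' descriptors compare the shape of the intensity layout and of the
#' orientation profile rather than the blocks' arbitrary offsets.
#' Multi-channel patches are reduced to their per-pixel channel mean first so
#' that descriptors from domains with different channel counts remain
#' comparable. The descriptor is deterministic and its length does not depend
#' on the patch size.
#'
#' A pretrained embedding model can be substituted through the
#' \code{featureExtractor} field of [toleranceSearchConfig()]; any function
#' mapping a patch to a fixed-length numeric vector satisfies the contract.
#'
#' @param patch a matrix or (H, W, C) array with both sides >= 8.
#' @return numeric(80).
#' @export
defaultFeatureDescriptor <- function(patch) {
  patch <- asImageArray(patch, "patch")
  d <- dim(patch)
  if (d[1] < 8L || d[2] < 8L)
    stopContract("patch must be at least 8 x 8 pixels (got %d x %d)",
                 d[1], d[2])
  m <- if (d[3] == 1L) patch[, , 1] else apply(patch, c(1, 2), mean)
  grid <- as.numeric(blockMeans(m, 8L))
  gx <- m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]
  gy <- m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  hist <- numeric(16L)
  if (sum(mag) > 0) {
    ori <- atan2(gy, gx)  # (-pi, pi]
    bin <- pmin(floor((ori + pi) / (2 * pi) * 16) + 1L, 16L)
    hist <- vapply(seq_len(16L), function(b) sum(mag[bin == b]), numeric(1))
    hist <- hist / sum(hist)
  }
  standardiseBlock <- function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }
  c(standardiseBlock(grid), standardiseBlock(hist))
}

#' Configuration of the tolerance-size search
#'
#' @param lowerBound,upperBound candidate tolerance range in pixels. The
#'   lower bound enforces the memory floor: the discriminator head width
#'   N + 1 implied by \code{lowerBound} must stay below \code{headCap}.
#' @param step \code{"multiplicative"} (default; candidates
#'   \code{lowerBound * stepFactor^k}) or \code{"additive"} (candidates
#'   \code{seq(lowerBound, upperBound, by = stepAdd)}).
#' @param stepFactor multiplicative factor (default 2).
#' @param stepAdd additive step in pixels (used when \code{step = "additive"}).
#' @param numSampling number of random crop pairs scored per candidate.
#' @param cropPositions \code{"matched"} (default): the source and target
#'   crops of a draw share one random position, so the objective measures at
#'   which scale roughly aligned domains agree; \code{"independent"}: the two
#'   positions are drawn separately.
#' @param featureExtractor function mapping a patch to a fixed-length numeric
#'   vector; default [defaultFeatureDescriptor()].
#' @param seed RNG seed making the search deterministic.
#' @param headCap maximum admissible discriminator head width N + 1.
#' @return a list of class \code{toleranceSearchConfig}.
#' @export
toleranceSearchConfig <- function(lowerBound, upperBound,
                                  step = c("multiplicative", "additive"),
                                  stepFactor = 2, stepAdd = NULL,
                                  numSampling = 20L,
                                  cropPositions = c("matched", "independent"),
                                  featureExtractor = defaultFeatureDescriptor,
                                  seed = 1L, headCap = 4096L) {
  step <- match.arg(step)
  cropPositions <- match.arg(cropPositions)
  if (lowerBound > upperBound)
    stopContract("lowerBound must be <= upperBound")
  if (numSampling < 1L) stopContract("numSampling must be >= 1")
  if (step == "additive" && is.null(stepAdd))
    stopContract("additive stepping requires stepAdd")
  structure(list(lowerBound = as.integer(lowerBound),
                 upperBound = as.integer(upperBound), step = step,
                 stepFactor = stepFactor, stepAdd = stepAdd,
                 numSampling = as.integer(numSampling),
                 cropPositions = cropPositions,
                 featureExtractor = featureExtractor,
                 seed = as.integer(seed), headCap = as.integer(headCap)),
            class = "toleranceSearchConfig")
}

toleranceCandidates <- function(cfg) {
  if (cfg$step == "multiplicative") {
    out <- integer()
    tol <- cfg$lowerBound
    while (tol <= cfg$upperBound) {
      out <- c(out, as.integer(tol))
      tol <- tol * cfg$stepFactor
    }
    out
  } else {
    as.integer(seq(cfg$lowerBound, cfg$upperBound, by = cfg$stepAdd))
  }
}

randomCrop <- function(img, side) {
  d <- dim(img)
  r0 <- sample.int(d[1] - side + 1L, 1L) - 1L
  c0 <- sample.int(d[2] - side + 1L, 1L) - 1L
  img[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), , drop = FALSE]
}

#' Automatic selection of the tolerance size
#'
#' For each candidate tolerance, \code{numSampling} source crops and target
#' crops of that side are drawn at independent uniform positions, each crop is
#' mapped to a feature vector, and the objective is the sum over draws of the
#' Pearson correlation between the source-crop and target-crop features. The
#' candidate maximising the objective is returned; the assumption is that the
#' two domains share feature patterns at the scale of a region, so the
#' correlation peaks near the scale at which source and target statistics
#' agree. Candidates whose objective lies within 1% of the maximum form a tie
#' band and the largest of them is returned, since a larger tolerance means
#' fewer regions and a smaller discriminator head.
#'
#' @param source,target single images or lists of images (a roughly paired
#'   dataset); with lists the objective is summed over pairs.
#' @param cfg a [toleranceSearchConfig()].
#' @return list with \code{tolerance} (the selected size), \code{candidates},
#'   \code{objective} (the full curve), and \code{degenerateFraction} (share
#'   of crop pairs with undefined correlation).
#' @export
optimizeTolerance <- function(source, target, cfg) {
  if (!inherits(cfg, "toleranceSearchConfig"))
    stopContract("cfg must be a toleranceSearchConfig")
  if (!is.list(source)) source <- list(source)
  if (!is.list(target)) target <- list(target)
  source <- lapply(source, asImageArray, what = "source")
  target <- lapply(target, asImageArray, what = "target")
  minSide <- min(vapply(c(source, target),
                        function(x) min(dim(x)[1:2]), numeric(1)))
  if (cfg$upperBound > minSide)
    stopGeometry("upperBound %d exceeds the smallest image side %d",
                 cfg$upperBound, minSide)
  maxShape <- sapply(source, function(x) dim(x)[1:2])
  Nlow <- max(ceiling(maxShape[1, ] / cfg$lowerBound) *
              ceiling(maxShape[2, ] / cfg$lowerBound))
  if (Nlow + 1L > cfg$headCap)
    stopContract(paste0(
      "lowerBound %d implies a discriminator head of %d nodes, above the ",
      "cap of %d; raise the lower bound"), cfg$lowerBound, Nlow + 1L,
      cfg$headCap)
  candidates <- toleranceCandidates(cfg)
  set.seed(cfg$seed)
  objective <- numeric(length(candidates))
  nDegen <- 0L; nTotal <- 0L
  for (ci in seq_along(candidates)) {
    tol <- candidates[ci]
    obj <- 0
    for (p in seq_along(source)) {
      for (i in seq_len(cfg$numSampling)) {
        if (cfg$cropPositions == "matched") {
          ds <- dim(source[[p]])
          r0 <- sample.int(ds[1] - tol + 1L, 1L) - 1L
          c0 <- sample.int(ds[2] - tol + 1L, 1L) - 1L
          cs <- source[[p]][(r0 + 1L):(r0 + tol), (c0 + 1L):(c0 + tol), ,
                            drop = FALSE]
          ct <- target[[p]][(r0 + 1L):(r0 + tol), (c0 + 1L):(c0 + tol), ,
                            drop = FALSE]
        } else {
          cs <- randomCrop(source[[p]], tol)
          ct <- randomCrop(target[[p]], tol)
        }
        fs <- cfg$featureExtractor(cs)
        ft <- cfg$featureExtractor(ct)
        r <- pearsonCorrelation(fs, ft)
        nTotal <- nTotal + 1L
        if (isTRUE(attr(r, "degenerate"))) nDegen <- nDegen + 1L
        obj <- obj + as.numeric(r)
      }
    }
    objective[ci] <- obj
  }
  if (nDegen == nTotal)
    stopDegenerate("every sampled crop pair had undefined correlation")
  mx <- max(objective)
  band <- if (mx == 0) objective == 0 else objective >= mx - 0.01 * abs(mx)
  list(tolerance = max(candidates[band]), candidates = candidates,
       objective = objective, degenerateFraction = nDegen / nTotal)
}

#' Write a tolerance-search report
#'
#' @param result the list returned by [optimizeTolerance()].
#' @param file path of the JSON report; \code{NULL} returns the string.
#' @return the JSON string, invisibly when written.
#' @export
toleranceReport <- function(result, file = NULL) {
  js <- jsonlite::toJSON(
    list(candidates = result$candidates, objective = result$objective,
         tolerance = result$tolerance,
         degenerate_fraction = result$degenerateFraction),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
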