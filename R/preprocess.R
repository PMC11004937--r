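#' Intensity scaling with background estimation
#'
#' Normalises a raw microscopy image to [0, 1]. Otsu's method estimates the
#' threshold separating background noise from signal; the sub-threshold
#' (background) pixels are characterised by an interquartile-range rule whose
#' upper fence Q3 + 1.5 IQR is recorded as the background ceiling (diagnostic
#' only, not applied destructively). The top 0.1% of pixel values are
#' saturated and the remaining values are linearly rescaled so the clip value
#' maps to 1 and the minimum to 0. The mapping is monotone nondecreasing.
#'
#' @param image matrix or (H, W, C) array, any intensity range.
#' @return list with \code{image} (scaled array in [0, 1]), \code{threshold}
#'   (Otsu), \code{fence} (IQR upper fence of the background), \code{clip}
#'   (99.9th percentile) and \code{degenerate} (TRUE for a constant input,
#'   which is returned rescaled to 0).
#' @export
intensityScale <- function(image) {
  image <- asImageArray(image, "image")
  v <- as.numeric(image)
  if (length(unique(v)) < 2L) {
    return(list(image = array(0, dim(image)), threshold = NA_real_,
                fence = NA_real_, clip = NA_real_, degenerate = TRUE))
  }
  rng <- range(v)
  thr <- EBImage::otsu(matrix(v, ncol = 1L), range = rng, levels = 256L)
  bg <- v[v < thr]
  fence <- if (length(bg) >= 4L) {
    q <- stats::quantile(bg, c(0.25, 0.75), names = FALSE)
    q[2] + 1.5 * (q[2] - q[1])
  } else NA_real_
  clip <- stats::quantile(v, 0.999, names = FALSE)
  lo <- rng[1]
  if (clip <= lo) clip <- rng[2]  # safeguard for near-constant images
  scaled <- (pmin(image, clip) - lo) / (clip - lo)
  list(image = scaled, threshold = thr, fence = fence, clip = clip,
       degenerate = FALSE)
}

#' Sobel-Feldman gradient channels
#'
#' Expands a single-channel image into three channels: the original image and
#' its two Sobel-Feldman derivatives. Derivatives are computed with the 3 x 3
#' kernels on an edge-replicated image (so the output keeps the input's
#' size), and scaled symmetrically about zero: the raw derivative range of
#' +/- 8 times the input intensity range is mapped linearly onto [0, 1] with
#' zero gradient at mid-range (0.5; 128 on an 8-bit scale), saturating at the
#' extremes.
#'
#' @param image single-channel matrix or (H, W, 1) array with sides >= 3.
#' @param scale logical; with \code{FALSE} the raw unscaled derivatives are
#'   returned instead.
#' @return (H, W, 3) array: original, Gx, Gy.
#' @export
sobelChannels <- function(image, scale = TRUE) {
  image <- asImageArray(image, "image")
  if (dim(image)[3] != 1L)
    stopContract("sobelChannels expects a single-channel image")
  if (any(dim(image)[1:2] < 3L))
    stopContract("image sides must be >= 3")
  m <- image[, , 1]
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  ky <- t(kx)                                          # d/dy (rows)
  padded <- m[c(1, seq_len(nrow(m)), nrow(m)), c(1, seq_len(ncol(m)), ncol(m))]
  gx <- conv2_valid(padded, kx)
  gy <- conv2_valid(padded, ky)
  if (!scale) return(array(c(m, gx, gy), c(dim(m), 3L)))
  R <- diff(range(m))
  if (R == 0) {
    gx[] <- 0.5; gy[] <- 0.5
  } else {
    gx <- pmin(pmax((gx + 8 * R) / (16 * R), 0), 1)
    gy <- pmin(pmax((gy + 8 * R) / (16 * R), 0), 1)
  }
  array(c(m, gx, gy), c(dim(m), 3L))
}

#' Least-squares affine from corresponding points
#'
#' Estimates the 2 x 3 affine transform minimising the summed squared
#' residuals of \code{dst ~ A \%*\% c(x, y, 1)} over >= 3 non-collinear point
#' correspondences, as used for coarse registration from manually or
#' automatically matched landmarks.
#'
#' @param src,dst numeric matrices (n x 2) of (x, y) coordinates.
#' @return list with \code{affine} (2 x 3 matrix \code{[a b tx; c d ty]}),
#'   \code{residuals} (n x 2) and \code{rmse}.
#' @export
affineFromPoints <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L)
    stopContract("src and dst must be n x 2 matrices of equal n")
  if (nrow(src) < 3L)
    stopGeometry("at least 3 point pairs are required")
  X <- cbind(src, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stopGeometry("points are collinear (rank-deficient design)")
  coef <- qr.coef(qrX, dst)       # 3 x 2
  A <- t(coef)                    # 2 x 3: [a b tx; c d ty]
  fitted <- X %*% coef
  res <- dst - fitted
  list(affine = A, residuals = res, rmse = sqrt(mean(res^2)))
}

#' Warp an image with a 2 x 3 affine
#'
#' Each output pixel (x, y) (0-based, x = column) samples the input bilinearly
#' at \code{A \%*\% c(x, y, 1)}; samples outside the input are clamped to the
#' nearest edge pixel.
#'
#' @param image matrix or (H, W, C) array.
#' @param A 2 x 3 affine matrix.
#' @param outSize integer(2) output (height, width); default the input size.
#' @return warped array.
#' @export
warpAffine <- function(image, A, outSize = NULL) {
  image <- asImageArray(image, "image")
  if (is.null(outSize)) outSize <- dim(image)[1:2]
  warp_affine(image, A, as.integer(outSize[1]), as.integer(outSize[2]))
}

composeParamAffine <- function(init, p, centre) {
  # perturbation in the patch frame: rotate/scale/shear about the centre,
  # then translate; composed with the initial placement
  # [x'; y'] = R * S * Sh * (x - cx, y - cy) + (cx + tx, cy + ty)
  cs <- cos(p[4]); sn <- sin(p[4])
  S <- exp(p[3])
  Sh <- matrix(c(1, 0, p[5], 1), 2, 2)
  RS <- S * matrix(c(cs, sn, -sn, cs), 2, 2) %*% Sh
  tvec <- c(centre[1] + p[1], centre[2] + p[2]) - RS %*% centre
  P <- cbind(RS, tvec)
  # compose: init o P (apply P in patch coords, then init)
  A <- init[, 1:2] %*% P
  A[, 3] <- A[, 3] + init[, 3]
  A
}

#' Refine a local affine by maximising Pearson correlation
#'
#' Gradient-free coordinate-wise pattern search over translation, scale,
#' rotation and shear, starting from an initial affine that places the source
#' patch inside the target image. At every step the candidate affine samples
#' a window from the target (bilinear, edge-clamped) and the Pearson
#' correlation with the source patch is evaluated; only improvements are
#' accepted and step sizes shrink geometrically, so the returned correlation
#' is never below that of the initial affine and the search is deterministic.
#'
#' @param srcPatch non-constant patch array.
#' @param target target image array.
#' @param init 2 x 3 affine mapping patch coordinates to target coordinates.
#' @param searchCfg list of search ranges and controls: \code{maxShift} (px),
#'   \code{maxRot} (radians), \code{maxLogScale}, \code{maxShear},
#'   \code{tol} (minimum step, px) and \code{maxIter}.
#' @return list with \code{affine}, \code{correlation},
#'   \code{initCorrelation} and \code{params} (tx, ty, logScale, rot, shear).
#' @export
refineLocalAffine <- function(srcPatch, target, init,
                              searchCfg = list(maxShift = 8, maxRot = 0.1,
                                               maxLogScale = 0.1,
                                               maxShear = 0.1, tol = 0.05,
                                               maxIter = 400)) {
  srcPatch <- asImageArray(srcPatch, "srcPatch")
  target <- asImageArray(target, "target")
  if (stats::sd(as.numeric(srcPatch)) == 0)
    stopDegenerate("constant source patch: correlation undefined")
  d <- dim(srcPatch)
  centre <- c((d[2] - 1) / 2, (d[1] - 1) / 2)  # (x, y)
  corners <- rbind(c(0, 0, 1), c(d[2] - 1, 0, 1), c(0, d[1] - 1, 1),
                   c(d[2] - 1, d[1] - 1, 1))
  mapped <- corners %*% t(init)
  if (any(mapped[, 1] < 0) || any(mapped[, 2] < 0) ||
      any(mapped[, 1] > dim(target)[2] - 1) ||
      any(mapped[, 2] > dim(target)[1] - 1))
    warning("initial window extends beyond the target; samples are clamped")
  objective <- function(p) {
    A <- composeParamAffine(init, p, centre)
    win <- warp_affine(target, A, d[1], d[2])
    sdw <- stats::sd(as.numeric(win))
    if (sdw == 0) return(-1)
    stats::cor(as.numeric(srcPatch), as.numeric(win))
  }
  lim <- c(searchCfg$maxShift, searchCfg$maxShift, searchCfg$maxLogScale,
           searchCfg$maxRot, searchCfg$maxShear)
  p <- numeric(5)
  steps <- lim / 2
  steps[steps == 0] <- .Machine$double.eps
  best <- objective(p)
  init_corr <- best
  it <- 0L
  while (it < searchCfg$maxIter && steps[1] >= searchCfg$tol / 4) {
    improved <- FALSE
    for (j in seq_len(5)) {
      if (lim[j] == 0) next
      for (sgn in c(1, -1)) {
        cand <- p
        cand[j] <- max(min(cand[j] + sgn * steps[j], lim[j]), -lim[j])
        if (cand[j] == p[j]) next
        val <- objective(cand)
        it <- it + 1L
        if (val > best) {
          best <- val; p <- cand; improved <- TRUE
        }
      }
    }
    if (!improved) steps <- steps / 2
  }
  list(affine = composeParamAffine(init, p, centre), correlation = best,
       initCorrelation = init_corr, params = p)
}
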