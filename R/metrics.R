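# Image-quality metrics: multiscale structural similarity and PSNR.

gaussianKernel <- function(size = 11L, sigma = 1.5) {
  r <- (seq_len(size) - (size + 1) / 2)
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Single-scale SSIM on one channel; returns mean luminance*cs and mean cs.
ssimChannel <- function(x, y, dataRange, k) {
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mx <- conv2_valid(x, k); my <- conv2_valid(y, k)
  mx2 <- mx * mx; my2 <- my * my; mxy <- mx * my
  sx2 <- conv2_valid(x * x, k) - mx2
  sy2 <- conv2_valid(y * y, k) - my2
  sxy <- conv2_valid(x * y, k) - mxy
  lum <- (2 * mxy + C1) / (mx2 + my2 + C1)
  cs <- (2 * sxy + C2) / (sx2 + sy2 + C2)
  c(ssim = mean(lum * cs), cs = mean(cs))
}

downsample2 <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  (m[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(2, W, 2), drop = FALSE]) / 4
}

#' Multiscale structural similarity (MS-SSIM)
#'
#' The standard five-scale formulation with an 11 x 11 Gaussian window
#' (sigma 1.5) and the canonical scale weights (0.0448, 0.2856, 0.3001,
#' 0.2363, 0.1333): contrast-structure terms are accumulated over the coarser
#' scales (dyadic average-pool downsampling) and combined with the luminance
#' term at the coarsest scale, each raised to its weight. Images whose sides
#' cannot support five scales (below 161 pixels) use the largest feasible
#' number of scales with renormalised weights, with a warning. Negative
#' contrast-structure means are clamped at 0, keeping the index in [0, 1].
#' Multi-channel images are averaged over channels.
#'
#' @param x,y images (matrix or (H, W, C) array) of equal shape.
#' @param dataRange intensity range spanned by the data (1 for [0, 1] images,
#'   255 for 8-bit).
#' @return numeric(1) in [0, 1].
#' @export
msSSIM <- function(x, y, dataRange = 1) {
  x <- asImageArray(x, "x"); y <- asImageArray(y, "y")
  if (!identical(dim(x), dim(y)))
    stopContract("images must share dimensions")
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  minSide <- min(dim(x)[1:2])
  M <- min(5L, max(1L, floor(log2((minSide - 1) / 10)) + 1L))
  if (M < 5L)
    warning(sprintf("image sides support only %d of 5 MS-SSIM scales", M))
  w <- weights[seq_len(M)] / sum(weights[seq_len(M)])
  k <- gaussianKernel()
  nc <- dim(x)[3]
  perChannel <- vapply(seq_len(nc), function(ch) {
    cx <- x[, , ch]; cy <- y[, , ch]
    val <- 1
    for (s in seq_len(M)) {
      st <- ssimChannel(cx, cy, dataRange, k)
      if (s < M) {
        val <- val * max(st["cs"], 0)^w[s]
        cx <- downsample2(cx); cy <- downsample2(cy)
      } else {
        val <- val * max(st["ssim"], 0)^w[s]
      }
    }
    val
  }, numeric(1))
  mean(perChannel)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(R^2 / MSE)} in decibels; identical images return
#' \code{Inf}.
#'
#' @inheritParams msSSIM
#' @return numeric(1) in dB.
#' @export
psnr <- function(x, y, dataRange = 1) {
  x <- asImageArray(x, "x"); y <- asImageArray(y, "y")
  if (!identical(dim(x), dim(y)))
    stopContract("images must share dimensions")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' Quantify a translated image against its reference
#'
#' @inheritParams msSSIM
#' @return named numeric(2): \code{ms_ssim} in [0, 1] and \code{psnr} in dB
#'   (\code{Inf} for identical images).
#' @export
imageMetrics <- function(x, y, dataRange = 1) {
  c(ms_ssim = msSSIM(x, y, dataRange), psnr = psnr(x, y, dataRange))
}
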