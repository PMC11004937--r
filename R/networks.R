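#' Build the translation networks
#'
#' Constructs the two generators and two discriminators. Each generator is an
#' encoder (convolutional stem, one stride-2 downsampling, residual blocks)
#' projecting the input into a latent space shared between the domains, and a
#' mirrored decoder (residual blocks, nearest-neighbour upsampling,
#' convolutional head with a sigmoid output in [0, 1]). Each discriminator is
#' a stride-2 convolution stack followed by global average pooling and a
#' softmax layer of exactly N + 1 nodes: one real class per region plus a
#' single node to which all fake generated patches are assigned.
#'
#' Weights are initialised as by [initWeights()]; call \code{set.seed()} first
#' for reproducible construction.
#'
#' @param sourceChannels,targetChannels channel counts of the two domains.
#' @param N number of regions bound to the discriminator heads.
#' @param preset \code{"tiny"} (base width 4, for tests and desk-scale runs),
#'   \code{"small"} (width 16) or \code{"full"} (width 64, more residual
#'   blocks).
#' @param widthBase overrides the preset's base channel width.
#' @param nRes number of residual blocks in each encoder/decoder.
#' @param headCap maximum admissible head width N + 1; exceeding it raises an
#'   error pointing at the tolerance lower bound.
#' @return a [NetworkBundle-class].
#' @examples
#' set.seed(1)
#' b <- buildNetworks(1, 1, N = 4, preset = "tiny")
#' nRegions(b)  # 4
#' @export
buildNetworks <- function(sourceChannels, targetChannels, N,
                          preset = c("small", "tiny", "full"),
                          widthBase = NULL, nRes = NULL, headCap = 4096L) {
  preset <- match.arg(preset)
  if (N < 1L) stopContract("N must be >= 1")
  if (sourceChannels < 1L || targetChannels < 1L)
    stopContract("channel counts must be >= 1")
  if (N + 1L > headCap)
    stopContract(paste0(
      "N + 1 = %d exceeds the discriminator head cap %d; increase the ",
      "tolerance lower bound so that fewer regions are formed"),
      N + 1L, headCap)
  w <- if (!is.null(widthBase)) as.integer(widthBase) else
    switch(preset, tiny = 4L, small = 16L, full = 64L)
  nr <- if (!is.null(nRes)) as.integer(nRes) else
    switch(preset, tiny = 1L, small = 2L, full = 5L)
  makeStem <- function(cin) {
    list(layers = list(convLayer(cin, w, 3L, 1L, "relu"),
                       convLayer(w, 2L * w, 3L, 2L, "relu")))
  }
  makeResStack <- function() {
    list(layers = lapply(seq_len(nr), function(i) residualLayer(2L * w)))
  }
  makeHead <- function(cout) {
    list(layers = list(
      list(type = "upsample2"),
      convLayer(2L * w, w, 3L, 1L, "relu"),
      convLayer(w, cout, 3L, 1L, "sigmoid")))
  }
  # fully convolutional (N+1)-way classifier: stride-2 stack ending in a
  # 1x1 convolution to an (N+1)-channel logit map; class probabilities are
  # the per-location softmaxes averaged over locations, so the classifier
  # judges local style everywhere in the patch rather than one global code
  makeDiscriminator <- function(cin) {
    list(layers = list(
      convLayer(cin, w, 4L, 2L, "lrelu"),
      convLayer(w, 2L * w, 4L, 2L, "lrelu"),
      convLayer(2L * w, 4L * w, 4L, 2L, "lrelu"),
      convLayer(4L * w, N + 1L, 1L, 1L, "linear")))
  }
  bundle <- new("NetworkBundle",
    ES = makeStem(sourceChannels), ET = makeStem(targetChannels),
    ESh = makeResStack(), USh = makeResStack(),
    US = makeHead(sourceChannels), UT = makeHead(targetChannels),
    DS = makeDiscriminator(sourceChannels),
    DT = makeDiscriminator(targetChannels),
    N = as.integer(N), sourceChannels = as.integer(sourceChannels),
    targetChannels = as.integer(targetChannels),
    config = list(preset = preset, widthBase = w, nRes = nr,
                  headCap = as.integer(headCap)))
  initWeights(bundle)
}

#' Initialise bundle weights
#'
#' Discriminator weights are drawn from Normal(0, 0.02); generator (encoder
#' and decoder) weights use Kaiming fan-in initialisation, preserving the
#' magnitude of the activation variance in the forward pass; every bias is
#' set exactly to 0. Uses the current RNG state.
#'
#' @param bundle a [NetworkBundle-class].
#' @return the bundle with freshly initialised weights.
#' @export
initWeights <- function(bundle) {
  bundle@ES <- initNetWeights(bundle@ES, "kaiming")
  bundle@ET <- initNetWeights(bundle@ET, "kaiming")
  bundle@ESh <- initNetWeights(bundle@ESh, "kaiming")
  bundle@USh <- initNetWeights(bundle@USh, "kaiming")
  bundle@US <- initNetWeights(bundle@US, "kaiming")
  bundle@UT <- initNetWeights(bundle@UT, "kaiming")
  bundle@DS <- initNetWeights(bundle@DS, "normal")
  bundle@DT <- initNetWeights(bundle@DT, "normal")
  bundle
}

# Pad an image with edge replication so both sides are even; returns the
# padded image and the original size.
padToEven <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L) x <- x[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (d[2] %% 2L) x <- x[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  list(x = x, size = d[1:2])
}

#' Apply a generator to an image
#'
#' Translation source to target runs \code{UT(ES(x))}; target to source runs
#' \code{US(ET(x))}. Odd-sized inputs are edge-padded to even sides for the
#' stride-2 stage and cropped back, so the output always has the input's
#' spatial size and the opposite domain's channel count.
#'
#' @param bundle a [NetworkBundle-class].
#' @param x image array (H x W x C) in [0, 1].
#' @param direction \code{"st"} (source to target, default) or \code{"ts"}.
#' @return the translated image array.
#' @export
applyGenerator <- function(bundle, x, direction = c("st", "ts")) {
  direction <- match.arg(direction)
  x <- asImageArray(x, "input")
  p <- padToEven(x)
  stem <- if (direction == "st") bundle@ES else bundle@ET
  head <- if (direction == "st") bundle@UT else bundle@US
  z <- netForward(bundle@ESh, netForward(stem, p$x)$out)$out
  y <- netForward(head, netForward(bundle@USh, z)$out)$out
  y[seq_len(p$size[1]), seq_len(p$size[2]), , drop = FALSE]
}

#' Encode an image into the shared latent space
#'
#' @param bundle a [NetworkBundle-class].
#' @param x image array.
#' @param domain \code{"source"} or \code{"target"}.
#' @return latent array; both encoders produce identically shaped latents for
#'   same-shaped inputs (the shared-latent contract).
#' @export
encodeImage <- function(bundle, x, domain = c("source", "target")) {
  domain <- match.arg(domain)
  x <- asImageArray(x, "input")
  stem <- if (domain == "source") bundle@ES else bundle@ET
  netForward(bundle@ESh, netForward(stem, padToEven(x)$x)$out)$out
}

#' Discriminator class probabilities
#'
#' The discriminator produces an (N+1)-channel logit map; each spatial
#' location is softmax-normalised and the locations are averaged, yielding
#' one probability vector per patch.
#'
#' @param bundle a [NetworkBundle-class].
#' @param x patch array.
#' @param domain which discriminator: \code{"source"} (DS) or
#'   \code{"target"} (DT).
#' @return numeric(N + 1) probability vector; entries sum to 1. Classes
#'   1..N are the real-region classes, class N + 1 is the combined fake class.
#' @export
discriminatorProbs <- function(bundle, x, domain = c("source", "target")) {
  domain <- match.arg(domain)
  x <- asImageArray(x, "patch")
  net <- if (domain == "source") bundle@DS else bundle@DT
  pmap <- softmaxMap(netForward(net, x)$out)
  apply(pmap, 3, mean)
}

#' Receptive-field radius of a generator pass
#'
#' Radius, in input pixels, of the full encoder + decoder receptive field:
#' each convolution adds \code{(k \%/\% 2) * currentStride}, downsampling
#' doubles the stride, upsampling halves it. \code{\link{translateTiled}}
#' uses this as the default tile halo, so tiled and whole-image outputs
#' agree away from image borders.
#'
#' @param bundle a \code{NetworkBundle}.
#' @return integer(1) radius in pixels.
#' @export
generatorReceptiveRadius <- function(bundle) {
  radius <- 0; strideNow <- 1
  walk <- function(net) {
    for (l in net$layers) {
      if (l$type == "conv") {
        radius <<- radius + (l$k %/% 2) * strideNow
        strideNow <<- strideNow * l$stride
      } else if (l$type == "residual") {
        radius <<- radius + 2 * strideNow  # two 3x3 convolutions
      } else if (l$type == "upsample2") {
        strideNow <<- strideNow / 2
      }
    }
  }
  walk(bundle@ES)
  walk(bundle@ESh)
  walk(bundle@USh)
  walk(bundle@UT)
  as.integer(ceiling(radius))
}
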