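#' @import methods
NULL

#' RegionGrid: partition of an image into tolerance-sized regions
#'
#' A \code{RegionGrid} records the partition of an image plane into N mutually
#' exclusive, jointly covering, axis-aligned square regions of side
#' \code{tolerance} (boundary regions are truncated at the image edge), plus
#' the \code{overlap} margin by which each region is expanded before patches
#' are cropped from it. Region indices follow row-major spatial order starting
#' at 1 (R convention; serialised reports use 0-based class labels).
#'
#' Rectangles are stored half-open in 0-based pixel coordinates:
#' \code{regions[i, ] = c(row0, col0, row1, col1)} covers pixel rows
#' \code{row0 .. row1 - 1} and columns \code{col0 .. col1 - 1}.
#'
#' @slot imageShape integer(2), image height and width in pixels.
#' @slot tolerance integer(1), region side length in pixels.
#' @slot overlap integer(1), expansion margin in pixels (default 64).
#' @slot patchSize integer(1), side of the training patches the expanded
#'   regions must accommodate.
#' @slot regions integer matrix (N x 4) of half-open rectangles as above.
#' @slot expanded integer matrix (N x 4), the overlap-expanded rectangles
#'   clipped to the image bounds.
#'
#' @seealso [partitionRegions()], [computeSamplingDistribution()]
#' @exportClass RegionGrid
setClass("RegionGrid",
  representation(
    imageShape = "integer",
    tolerance  = "integer",
    overlap    = "integer",
    patchSize  = "integer",
    regions    = "matrix",
    expanded   = "matrix"
  )
)

setValidity("RegionGrid", function(object) {
  msg <- character()
  H <- object@imageShape[1]; W <- object@imageShape[2]
  R <- object@regions
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be two positive integers")
  if (object@tolerance < 1L) msg <- c(msg, "tolerance must be >= 1")
  if (ncol(R) != 4L) msg <- c(msg, "regions must have 4 columns")
  if (length(msg)) return(msg)
  # exclusivity + exact coverage via an integer ownership mask
  owner <- matrix(0L, H, W)
  for (i in seq_len(nrow(R))) {
    rows <- (R[i, 1] + 1L):R[i, 3]
    cols <- (R[i, 2] + 1L):R[i, 4]
    owner[rows, cols] <- owner[rows, cols] + 1L
  }
  if (any(owner != 1L))
    msg <- c(msg, "regions must cover the image exactly once")
  # expanded rectangles must accommodate the patch size
  E <- object@expanded
  if (nrow(E) != nrow(R)) msg <- c(msg, "expanded/regions row mismatch")
  else {
    side1 <- E[, 3] - E[, 1]; side2 <- E[, 4] - E[, 2]
    if (any(side1 < object@patchSize) || any(side2 < object@patchSize))
      msg <- c(msg, "every expanded region must fit the patch size")
  }
  if (length(msg)) msg else TRUE
})

#' SamplingDistribution: the global patch-sampling rule
#'
#' Per-region normalised histograms \eqn{H_i}, scores
#' \eqn{Q_i = (1 + \rho_i) / \sum_j H_i \cdot H_j} (with \eqn{\rho_i} the
#' Pearson correlation of the region's source and target pixels) and sampling
#' probabilities \eqn{P_i = Q_i / \sum_j Q_j}. Regions with high source-target
#' correlation and rare pixel histograms are sampled more often.
#'
#' @slot H numeric matrix (N x B) of normalised per-region histograms; each
#'   row sums to 1.
#' @slot Q numeric(N), nonnegative region scores.
#' @slot P numeric(N), sampling probabilities summing to 1.
#'
#' @seealso [computeSamplingDistribution()], [samplePatchPair()]
#' @exportClass SamplingDistribution
setClass("SamplingDistribution",
  representation(H = "matrix", Q = "numeric", P = "numeric")
)

setValidity("SamplingDistribution", function(object) {
  msg <- character()
  if (any(object@H < 0)) msg <- c(msg, "histogram entries must be >= 0")
  if (any(abs(rowSums(object@H) - 1) > 1e-9))
    msg <- c(msg, "each histogram row must sum to 1")
  if (any(object@Q < 0)) msg <- c(msg, "Q scores must be >= 0")
  if (any(object@P < 0)) msg <- c(msg, "P must be >= 0")
  if (abs(sum(object@P) - 1) > 1e-9) msg <- c(msg, "P must sum to 1")
  if (length(object@Q) != nrow(object@H) ||
      length(object@P) != nrow(object@H))
    msg <- c(msg, "H, Q, P must agree on the number of regions")
  if (length(msg)) msg else TRUE
})

#' ImagePair: a source/target image pair sharing a coordinate frame
#'
#' Both images are numeric arrays of shape (H, W, C) with intensities in the
#' declared range (after [intensityScale()] this is [0, 1]). The two images
#' must share their spatial shape; channel counts may differ.
#'
#' @slot source numeric array (H x W x Cs).
#' @slot target numeric array (H x W x Ct).
#' @slot range numeric(2), declared intensity range of both images.
#' @exportClass ImagePair
setClass("ImagePair",
  representation(source = "array", target = "array", range = "numeric")
)

setValidity("ImagePair", function(object) {
  ds <- dim(object@source); dt <- dim(object@target)
  msg <- character()
  if (length(ds) != 3L || length(dt) != 3L)
    msg <- c(msg, "source and target must be (H, W, C) arrays")
  else if (any(ds[1:2] != dt[1:2]))
    msg <- c(msg, "source and target must share spatial dimensions")
  if (length(object@range) != 2L || diff(object@range) <= 0)
    msg <- c(msg, "range must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' NetworkBundle: generators and region-aware discriminators
#'
#' The translation model: encoders \code{ES}/\code{ET} projecting either
#' domain into a shared latent space, decoders \code{US}/\code{UT} mapping the
#' latent back to each domain, and discriminators \code{DS}/\code{DT} whose
#' final layer has N + 1 nodes (one real class per region plus a single
#' combined fake class). Translation source to target is \code{UT(ES(x))};
#' target to source is \code{US(ET(x))}.
#'
#' Networks are stored as internal layer lists; use [applyGenerator()],
#' [discriminatorProbs()], [translateTiled()] and the loss functions to
#' interact with them rather than touching slots.
#'
#' The latent space is genuinely shared: the residual blocks at the deep end
#' of both encoders (\code{ESh}) and at the entry of both decoders
#' (\code{USh}) have one set of weights used by both domains, so
#' \code{ES = ESh o stem_S}, \code{UT = head_T o USh}, and so on.
#'
#' @slot ES,ET encoder stems; \code{ESh} the shared encoder tail.
#' @slot US,UT decoder heads; \code{USh} the shared decoder entry.
#' @slot DS,DT discriminators.
#' @slot N integer(1), number of regions bound at construction.
#' @slot sourceChannels,targetChannels integer(1).
#' @slot config list of architecture settings (widths, kernel sizes, head cap).
#' @exportClass NetworkBundle
setClass("NetworkBundle",
  representation(
    ES = "list", ET = "list", ESh = "list", USh = "list",
    US = "list", UT = "list",
    DS = "list", DT = "list",
    N = "integer", sourceChannels = "integer", targetChannels = "integer",
    config = "list"
  )
)

#' SyntheticSpec: parameters of the roughly-paired fixture generator
#'
#' Describes a procedural microscopy-like dataset: a grid of texture cells
#' (elliptical "nuclei" blobs or oriented fibres with per-cell parameter
#' jitter), a named invertible appearance mapping from source to target,
#' a global affine jitter, a per-patch displacement of fixed Euclidean norm
#' \code{d} (emulating patch-level mispairing at a known distance), and
#' additive Gaussian noise degrading the SNR.
#'
#' @slot imageSize integer(2), height and width.
#' @slot cellSize integer(1), texture grid cell side in pixels; the scale at
#'   which region statistics vary.
#' @slot mapping character(1), appearance mapping name
#'   ("invert", "gamma", "invertMix2", "gammaMix2", "invertMix3",
#'   "identity").
#' @slot misalignment numeric(1), Euclidean patch displacement d in pixels.
#' @slot misalignGrid integer(1), side of the displaced patches.
#' @slot misalignMode character(1), \code{"swap"} (disjoint patch swaps,
#'   preserving the pixel multiset) or \code{"smooth"} (a smooth displacement
#'   field with norm d at the patch anchors, seam-free like a deformed
#'   adjacent section).
#' @slot affineJitter numeric(3), maximum |shift| (px), |rotation| (radians)
#'   and |log-scale| of the global affine jitter.
#' @slot noiseSd numeric(1), additive Gaussian noise SD on the delivered
#'   target.
#' @slot sourceNoiseSd numeric(1), additive Gaussian noise SD on the source
#'   (emulating a low-SNR acquisition whose clean counterpart is the target).
#' @slot seed integer(1).
#' @seealso [syntheticSpec()], [generateDataset()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    imageSize = "integer", cellSize = "integer", mapping = "character",
    misalignment = "numeric", misalignGrid = "integer",
    misalignMode = "character",
    affineJitter = "numeric", noiseSd = "numeric",
    sourceNoiseSd = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@misalignment < 0) msg <- c(msg, "misalignment d must be >= 0")
  if (object@misalignment > min(object@imageSize) / 2)
    msg <- c(msg, "misalignment d must be at most half the image side")
  if (!object@mapping %in% c("invert", "gamma", "invertMix2", "gammaMix2",
                             "invertMix3", "identity"))
    msg <- c(msg, "unknown appearance mapping")
  if (!object@misalignMode %in% c("swap", "smooth"))
    msg <- c(msg, "misalignMode must be 'swap' or 'smooth'")
  if (object@noiseSd < 0 || object@sourceNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})
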