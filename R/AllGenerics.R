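#' @include AllClasses.R
NULL

#' Number of regions
#'
#' @param x a [RegionGrid-class] or [NetworkBundle-class].
#' @return integer(1), the region count N.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname nRegions
#' @export
setMethod("nRegions", "RegionGrid", function(x) nrow(x@regions))

#' @rdname nRegions
#' @export
setMethod("nRegions", "NetworkBundle", function(x) x@N)

#' Region rectangles of a grid
#'
#' @param x a [RegionGrid-class].
#' @param expanded logical; return the overlap-expanded rectangles instead of
#'   the exclusive partition.
#' @return integer matrix (N x 4) of half-open 0-based rectangles
#'   \code{(row0, col0, row1, col1)}.
#' @export
setGeneric("regionRects", function(x, expanded = FALSE)
  standardGeneric("regionRects"))

#' @rdname regionRects
#' @export
setMethod("regionRects", "RegionGrid", function(x, expanded = FALSE) {
  r <- if (expanded) x@expanded else x@regions
  colnames(r) <- c("row0", "col0", "row1", "col1")
  r
})

#' Tolerance size of a grid
#' @param x a [RegionGrid-class].
#' @return integer(1), the region side length in pixels.
#' @export
setGeneric("toleranceSize", function(x) standardGeneric("toleranceSize"))

#' @rdname toleranceSize
#' @export
setMethod("toleranceSize", "RegionGrid", function(x) x@tolerance)

#' Sampling probabilities and scores
#'
#' @param x a [SamplingDistribution-class].
#' @return numeric(N).
#' @export
setGeneric("samplingProbs", function(x) standardGeneric("samplingProbs"))

#' @rdname samplingProbs
#' @export
setMethod("samplingProbs", "SamplingDistribution", function(x) x@P)

#' @rdname samplingProbs
#' @export
setGeneric("samplingScores", function(x) standardGeneric("samplingScores"))

#' @rdname samplingProbs
#' @export
setMethod("samplingScores", "SamplingDistribution", function(x) x@Q)

#' Source / target image accessors
#' @param x an [ImagePair-class].
#' @return numeric array (H x W x C).
#' @export
setGeneric("sourceImage", function(x) standardGeneric("sourceImage"))

#' @rdname sourceImage
#' @export
setMethod("sourceImage", "ImagePair", function(x) x@source)

#' @rdname sourceImage
#' @export
setGeneric("targetImage", function(x) standardGeneric("targetImage"))

#' @rdname sourceImage
#' @export
setMethod("targetImage", "ImagePair", function(x) x@target)

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf(
    "RegionGrid: %d x %d image, tolerance %d px, overlap %d px, N = %d\n",
    object@imageShape[1], object@imageShape[2],
    object@tolerance, object@overlap, nrow(object@regions)))
})

setMethod("show", "SamplingDistribution", function(object) {
  cat(sprintf("SamplingDistribution over %d regions (%d histogram bins)\n",
              nrow(object@H), ncol(object@H)))
  cat("  P:", paste(sprintf("%.4f", object@P), collapse = " "), "\n")
})

setMethod("show", "ImagePair", function(object) {
  ds <- dim(object@source); dt <- dim(object@target)
  cat(sprintf("ImagePair: %d x %d, source %d channel(s), target %d channel(s)\n",
              ds[1], ds[2], ds[3], dt[3]))
})

setMethod("show", "NetworkBundle", function(object) {
  cat(sprintf(
    "NetworkBundle: %d -> %d channels, N = %d regions (head width %d)\n",
    object@sourceChannels, object@targetChannels, object@N, object@N + 1L))
  cat(sprintf("  base width %d, %d parameters\n", object@config$widthBase,
              bundleParameterCount(object)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d, cell %d px, mapping '%s', d = %g px, noise %g\n",
    object@imageSize[1], object@imageSize[2], object@cellSize,
    object@mapping, object@misalignment, object@noiseSd))
})
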