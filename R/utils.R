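# Internal helpers: condition constructors and image coercion.

stopGeometry <- function(fmt, ...) {
  stop(structure(class = c("regiongan_geometry_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stopContract <- function(fmt, ...) {
  stop(structure(class = c("regiongan_contract_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stopDegenerate <- function(fmt, ...) {
  stop(structure(class = c("regiongan_degenerate_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Coerce a matrix or (H, W, C) array to a 3-D numeric array.
asImageArray <- function(x, what = "image") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stopContract("%s must be a matrix or an (H, W, C) array", what)
  storage.mode(x) <- "double"
  x
}

# Crop a half-open 0-based rectangle from an (H, W, C) array.
cropRect <- function(img, rect) {
  img[(rect[1] + 1L):rect[3], (rect[2] + 1L):rect[4], , drop = FALSE]
}

#' Construct an ImagePair
#'
#' @param source,target matrices or (H, W, C) arrays sharing spatial shape.
#' @param range declared intensity range (default c(0, 1)).
#' @return an [ImagePair-class].
#' @export
imagePair <- function(source, target, range = c(0, 1)) {
  new("ImagePair", source = asImageArray(source, "source"),
      target = asImageArray(target, "target"), range = as.numeric(range))
}
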