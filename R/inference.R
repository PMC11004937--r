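#' Translate a full-size image by overlapped tiling
#'
#' Applies a patch-trained generator to an arbitrarily large image. The image
#' is covered by tiles extended by a \code{halo} margin on every side; after
#' translation only each tile's central core is written to the output, so
#' every output pixel lies at least \code{halo} pixels away from the border of
#' the tile that produced it. With a halo at least the generator's
#' receptive-field radius (the default, computed from the architecture), the
#' tiled result matches a whole-image pass away from the image borders. Tile
#' origins are kept at even offsets so the stride-2 encoder sees every tile in
#' the same phase as the whole image.
#'
#' @param image image array (any size).
#' @param bundle a [NetworkBundle-class].
#' @param direction \code{"st"} or \code{"ts"}.
#' @param tile tile side in pixels (default 128); must be at least
#'   \code{2 * halo + 1}.
#' @param halo overlap margin in pixels; default the generator's
#'   receptive-field radius, rounded up to even.
#' @return translated image with the input's spatial size and the opposite
#'   domain's channel count.
#' @export
translateTiled <- function(image, bundle, direction = c("st", "ts"),
                           tile = 128L, halo = NULL) {
  direction <- match.arg(direction)
  image <- asImageArray(image, "image")
  if (is.null(halo)) halo <- generatorReceptiveRadius(bundle)
  halo <- as.integer(ceiling(halo / 2) * 2)
  tile <- as.integer(tile)
  if (tile < 2L * halo + 1L)
    stopContract("tile (%d) must be >= 2*halo + 1 = %d", tile, 2L * halo + 1L)
  d0 <- dim(image)
  if (d0[1] <= tile && d0[2] <= tile)
    return(applyGenerator(bundle, image, direction))
  p <- padToEven(image)
  x <- p$x
  d <- dim(x)
  outC <- if (direction == "st") bundle@targetChannels else
    bundle@sourceChannels
  out <- array(0, c(d[1], d[2], outC))
  step <- tile - 2L * halo
  step <- max(2L, 2L * (step %/% 2L))
  r0s <- seq.int(0L, d[1] - 1L, by = step)
  c0s <- seq.int(0L, d[2] - 1L, by = step)
  for (r0 in r0s) {
    coreH <- min(step, d[1] - r0)
    tr0 <- max(r0 - halo, 0L)
    tr1 <- min(r0 + coreH + halo, d[1])
    for (c0 in c0s) {
      coreW <- min(step, d[2] - c0)
      tc0 <- max(c0 - halo, 0L)
      tc1 <- min(c0 + coreW + halo, d[2])
      tileIn <- x[(tr0 + 1L):tr1, (tc0 + 1L):tc1, , drop = FALSE]
      tileOut <- applyGenerator(bundle, tileIn, direction)
      out[(r0 + 1L):(r0 + coreH), (c0 + 1L):(c0 + coreW), ] <-
        tileOut[(r0 - tr0 + 1L):(r0 - tr0 + coreH),
                (c0 - tc0 + 1L):(c0 - tc0 + coreW), , drop = FALSE]
    }
  }
  out[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
}
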