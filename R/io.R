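#' Read a microscopy image from TIFF or PNG
#'
#' @param path file path ending in .tif/.tiff or .png.
#' @return numeric (H, W, C) array with intensities as stored (TIFF/PNG
#'   loaders return [0, 1] for integer-typed files).
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stopContract("no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopContract("unsupported image format '.%s' (use TIFF or PNG)", ext))
  asImageArray(img, path)
}

#' Write a microscopy image to TIFF or PNG
#'
#' Intensities are clamped to [0, 1] before writing.
#'
#' @param image matrix or (H, W, C) array.
#' @param path destination ending in .tif/.tiff or .png.
#' @return the path, invisibly.
#' @export
writeImageFile <- function(image, path) {
  image <- pmin(pmax(asImageArray(image, "image"), 0), 1)
  if (dim(image)[3] == 1L) image <- image[, , 1]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    png = png::writePNG(image, path),
    stopContract("unsupported image format '.%s' (use TIFF or PNG)", ext))
  invisible(path)
}

readImageFolder <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stopContract("no TIFF/PNG images under %s", path)
    lapply(files, readImageFile)
  } else {
    list(readImageFile(path))
  }
}
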