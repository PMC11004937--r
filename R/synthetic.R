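#' Specify a synthetic roughly-paired dataset
#'
#' @param imageSize integer(2) or integer(1), image height and width.
#' @param cellSize texture grid cell side in pixels; region statistics vary at
#'   this scale.
#' @param mapping appearance mapping name: \code{"invert"} (single channel,
#'   t = 1 - s), \code{"gamma"} (t = s^0.45), \code{"invertMix2"} (1-channel
#'   source to 2-channel target (1 - s, 0.25 + 0.5 s); the channels have
#'   deliberately distinct marginal ranges so the channel assignment is
#'   identifiable from image statistics alone), \code{"gammaMix2"}
#'   (1-channel source to 2-channel target (s^0.45, 0.25 + 0.5 s); both
#'   channels increase with s, so no sign-flipped or permuted solution
#'   competes with the intended mapping — the best-posed choice for small
#'   adversarial training fixtures), \code{"invertMix3"} (1-channel
#'   source to 3-channel target with monotone channel mixing, exercising the
#'   gradient-channel path) or \code{"identity"}. All mappings are invertible.
#' @param misalignment Euclidean displacement d (pixels) applied to the
#'   delivered target patches; 0 keeps the pair pixelwise aligned.
#' @param misalignGrid side of the displaced patches (the anchor spacing in
#'   smooth mode); defaults to \code{min(cellSize, floor(d))} for d > 0. In
#'   swap mode it must be <= d, since disjoint patch swaps need displacements
#'   of at least one patch side.
#' @param misalignMode \code{"swap"}: patches exchange content pairwise
#'   (exactly distance d, pixel multiset preserved, but with hard seams);
#'   \code{"smooth"} (default): a smooth displacement field interpolated
#'   from per-anchor random directions of norm d, emulating the seam-free
#'   local misregistration of e.g. an adjacent tissue section.
#' @param affineJitter numeric(3): maximum absolute global shift (px),
#'   rotation (radians) and log-scale of the affine jitter applied to the
#'   delivered target. \code{c(0, 0, 0)} disables it.
#' @param noiseSd additive Gaussian noise SD degrading the delivered target's
#'   SNR.
#' @param sourceNoiseSd additive Gaussian noise SD degrading the source
#'   acquisition; with a noisy source and a clean target the dataset poses a
#'   restoration task (the ground-truth target stays noise-free).
#' @param seed RNG seed; the dataset is a pure function of the spec.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(imageSize = c(256L, 256L), cellSize = 32L,
                          mapping = "invert", misalignment = 0,
                          misalignGrid = NULL,
                          misalignMode = c("smooth", "swap"),
                          affineJitter = c(0, 0, 0),
                          noiseSd = 0, sourceNoiseSd = 0, seed = 1L) {
  misalignMode <- match.arg(misalignMode)
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  if (is.null(misalignGrid))
    misalignGrid <- if (misalignment > 0)
      min(cellSize, floor(misalignment)) else cellSize
  new("SyntheticSpec", imageSize = as.integer(imageSize),
      cellSize = as.integer(cellSize), mapping = mapping,
      misalignment = as.numeric(misalignment),
      misalignGrid = as.integer(misalignGrid), misalignMode = misalignMode,
      affineJitter = as.numeric(affineJitter), noiseSd = as.numeric(noiseSd),
      sourceNoiseSd = as.numeric(sourceNoiseSd), seed = as.integer(seed))
}

# Render one procedural texture image: a grid of cells, each either a blob
# field ("nuclei") or an oriented fibre pattern, with per-cell parameter
# jitter. Layout parameters (family, base intensity, fibre orientation,
# blob count) come from layoutSeed; sub-cell detail (blob positions, fibre
# phase) from detailSeed, so detail can be re-drawn while cell-level
# statistics stay fixed.
renderTexture <- function(imageSize, cellSize, layoutSeed, detailSeed) {
  H <- imageSize[1]; W <- imageSize[2]; g <- cellSize
  nr <- ceiling(H / g); nc <- ceiling(W / g)
  set.seed(layoutSeed)
  fam <- matrix(stats::runif(nr * nc) < 0.5, nr, nc)
  base <- matrix(stats::runif(nr * nc, 0.15, 0.45), nr, nc)
  nBlob <- matrix(sample(3:6, nr * nc, TRUE), nr, nc)
  blobInt <- matrix(stats::runif(nr * nc, 0.65, 0.95), nr, nc)
  ori <- matrix(stats::runif(nr * nc, 0, pi), nr, nc)
  wav <- matrix(stats::runif(nr * nc, g / 4, g / 2), nr, nc)
  amp <- matrix(stats::runif(nr * nc, 0.15, 0.3), nr, nc)
  set.seed(detailSeed)
  img <- matrix(0, H, W)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * g; c0 <- (j - 1L) * g
      rows <- (r0 + 1L):min(r0 + g, H)
      cols <- (c0 + 1L):min(c0 + g, W)
      ch <- length(rows); cw <- length(cols)
      yy <- matrix(seq_len(ch), ch, cw)
      xx <- matrix(seq_len(cw), ch, cw, byrow = TRUE)
      cell <- matrix(base[i, j], ch, cw)
      if (fam[i, j]) {
        for (b in seq_len(nBlob[i, j])) {
          cx <- stats::runif(1, 1, cw); cy <- stats::runif(1, 1, ch)
          rx <- stats::runif(1, g / 10, g / 5)
          ry <- stats::runif(1, g / 10, g / 5)
          d2 <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2
          cell <- cell + blobInt[i, j] * exp(-3 * d2)
        }
      } else {
        phase <- stats::runif(1, 0, 2 * pi)
        th <- ori[i, j]
        cell <- cell + amp[i, j] *
          sin(2 * pi * (xx * cos(th) + yy * sin(th)) / wav[i, j] + phase)
      }
      img[rows, cols] <- cell
    }
  }
  # compress into [0.05, 0.95]: real microscopy rarely saturates, and hard
  # 0/1 plateaus are unreachable for a sigmoid-output generator
  0.05 + 0.9 * pmin(pmax(img, 0), 1)
}

applyAppearanceMapping <- function(source, mapping) {
  s <- source[, , 1]
  switch(mapping,
    identity = array(s, c(dim(s), 1L)),
    invert = array(1 - s, c(dim(s), 1L)),
    gamma = array(s^0.45, c(dim(s), 1L)),
    # the second channel's narrow range makes the channel assignment
    # identifiable from marginal statistics (no permuted solution)
    invertMix2 = array(c(1 - s, 0.25 + 0.5 * s), c(dim(s), 2L)),
    # both channels increase with s, so the latent orientations the two
    # domain stems learn agree and no sign-flipped solution competes
    gammaMix2 = array(c(s^0.45, 0.25 + 0.5 * s), c(dim(s), 2L)),
    invertMix3 = array(c(1 - s, s^0.7, 0.3 + 0.4 * s), c(dim(s), 3L)),
    stopContract("unknown appearance mapping '%s'", mapping))
}

#' Invert an appearance mapping
#'
#' Recovers the source intensity image from a ground-truth target generated
#' by [generateDataset()]'s appearance mapping (exactly, up to numerical
#' precision).
#'
#' @param target target image array.
#' @param mapping the mapping name used to generate it.
#' @return (H, W, 1) source intensity array.
#' @export
invertAppearanceMapping <- function(target, mapping) {
  target <- asImageArray(target, "target")
  switch(mapping,
    identity = target[, , 1, drop = FALSE],
    invert = 1 - target[, , 1, drop = FALSE],
    gamma = target[, , 1, drop = FALSE]^(1 / 0.45),
    invertMix2 = 1 - target[, , 1, drop = FALSE],
    gammaMix2 = (target[, , 2, drop = FALSE] - 0.25) / 0.5,
    invertMix3 = 1 - target[, , 1, drop = FALSE],
    stopContract("unknown appearance mapping '%s'", mapping))
}

#' Displace image patches at a fixed Euclidean distance
#'
#' Emulates patch-level mispairing: grid patches of side \code{grid} are
#' swapped pairwise with content at Euclidean distance \code{d} in a
#' uniformly random direction (directions whose displaced patch would leave
#' the image, overlap the patch itself, or overlap already-displaced content
#' are resampled). Because every move is a swap of two disjoint rectangles,
#' the output pixel multiset equals the input's. Patches for which no
#' admissible partner remains (crowding near the end of the pass) stay in
#' place and are recorded with a zero vector.
#'
#' Uses the current RNG state.
#'
#' @param image image array.
#' @param d displacement norm in pixels (>= grid for d > 0, so that swapped
#'   rectangles can be disjoint).
#' @param grid patch side in pixels.
#' @return list with \code{image} and \code{manifest}, a data.frame of patch
#'   origins and displacement vectors \code{(vy, vx)} (norm within 0.5 of d
#'   for displaced patches).
#' @export
applyMisalignment <- function(image, d, grid) {
  image <- asImageArray(image, "image")
  H <- dim(image)[1]; W <- dim(image)[2]
  g <- as.integer(grid)
  if (d < 0) stopContract("d must be >= 0")
  nr <- H %/% g; nc <- W %/% g
  if (nr < 1L || nc < 1L)
    stopGeometry("image (%d x %d) smaller than one %d px patch", H, W, g)
  origins <- expand.grid(r = (seq_len(nr) - 1L) * g,
                         c = (seq_len(nc) - 1L) * g)
  if (d == 0) {
    manifest <- data.frame(row0 = origins$r, col0 = origins$c, vy = 0, vx = 0)
    return(list(image = image, manifest = manifest))
  }
  if (d < g)
    stopGeometry(
      "displacement d = %g is smaller than the patch side %d: no disjoint swap exists",
      d, g)
  # feasibility on an empty image: some in-bounds disjoint displacement must
  # exist for the worst-placed patch
  if (d > sqrt((H - g)^2 + (W - g)^2))
    stopGeometry("displacement d = %g exceeds the image diagonal span", d)
  touched <- matrix(FALSE, H, W)
  man <- data.frame(row0 = origins$r, col0 = origins$c, vy = 0, vx = 0)
  order_ <- sample.int(nrow(origins))
  # displacement vectors aligned to the patch grid swap whole patches and
  # leave the rest of the grid intact, so they are preferred when d admits
  # them; otherwise arbitrary directions are sampled
  span <- ceiling((d + 0.5) / g)
  cand <- expand.grid(i = -span:span, j = -span:span) * g
  cand <- cand[abs(sqrt(cand$i^2 + cand$j^2) - d) <= 0.5 &
               pmax(abs(cand$i), abs(cand$j)) >= g, , drop = FALSE]
  gridAligned <- nrow(cand) > 0L
  for (idx in order_) {
    r0 <- origins$r[idx]; c0 <- origins$c[idx]
    if (any(touched[(r0 + 1L):(r0 + g), (c0 + 1L):(c0 + g)])) next
    placed <- FALSE
    tries <- if (gridAligned) sample.int(nrow(cand)) else seq_len(400L)
    for (try in tries) {
      if (gridAligned) {
        vy <- cand$i[try]; vx <- cand$j[try]
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        vy <- round(d * sin(th)); vx <- round(d * cos(th))
        if (abs(sqrt(vy^2 + vx^2) - d) > 0.5) next
      }
      r1 <- r0 + vy; c1 <- c0 + vx
      if (r1 < 0 || c1 < 0 || r1 + g > H || c1 + g > W) next
      if (max(abs(vy), abs(vx)) < g) next  # rectangles would overlap
      if (any(touched[(r1 + 1L):(r1 + g), (c1 + 1L):(c1 + g)])) next
      tmp <- image[(r0 + 1L):(r0 + g), (c0 + 1L):(c0 + g), , drop = FALSE]
      image[(r0 + 1L):(r0 + g), (c0 + 1L):(c0 + g), ] <-
        image[(r1 + 1L):(r1 + g), (c1 + 1L):(c1 + g), , drop = FALSE]
      image[(r1 + 1L):(r1 + g), (c1 + 1L):(c1 + g), ] <- tmp
      touched[(r0 + 1L):(r0 + g), (c0 + 1L):(c0 + g)] <- TRUE
      touched[(r1 + 1L):(r1 + g), (c1 + 1L):(c1 + g)] <- TRUE
      man$vy[idx] <- vy; man$vx[idx] <- vx
      partner <- which(man$row0 == r1 & man$col0 == c1)
      if (length(partner) == 1L) {
        man$vy[partner] <- -vy; man$vx[partner] <- -vx
      }
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  list(image = image, manifest = man)
}

#' Displace an image along a smooth random field
#'
#' Seam-free counterpart of [applyMisalignment()]: random unit directions are
#' drawn on a lattice of anchors spaced \code{grid} pixels apart, scaled to
#' norm \code{d}, bilinearly interpolated to a dense displacement field, and
#' the image is resampled at \code{x + v(x)} (edge-clamped). Every anchor
#' displacement has Euclidean norm exactly d; between anchors the norm can
#' only shrink, so the field emulates the smoothly varying misregistration of
#' roughly paired acquisitions without introducing stitch artifacts.
#'
#' Uses the current RNG state.
#'
#' @param image image array.
#' @param d anchor displacement norm in pixels.
#' @param grid anchor spacing in pixels.
#' @return list with \code{image} and \code{manifest} (anchor positions and
#'   displacement vectors).
#' @export
applySmoothMisalignment <- function(image, d, grid) {
  image <- asImageArray(image, "image")
  H <- dim(image)[1]; W <- dim(image)[2]
  g <- as.integer(grid)
  if (d < 0) stopContract("d must be >= 0")
  if (d == 0) {
    return(list(image = image,
                manifest = data.frame(row = numeric(0), col = numeric(0),
                                      vy = numeric(0), vx = numeric(0))))
  }
  ar <- unique(c(seq(0, H - 1, by = g), H - 1))
  ac <- unique(c(seq(0, W - 1, by = g), W - 1))
  th <- matrix(stats::runif(length(ar) * length(ac), 0, 2 * pi),
               length(ar), length(ac))
  vyA <- d * sin(th); vxA <- d * cos(th)
  # dense field by separable bilinear weights
  rIdx <- pmin(findInterval(0:(H - 1), ar, rightmost.closed = TRUE),
               length(ar) - 1L)
  cIdx <- pmin(findInterval(0:(W - 1), ac, rightmost.closed = TRUE),
               length(ac) - 1L)
  fr <- (0:(H - 1) - ar[rIdx]) / (ar[rIdx + 1L] - ar[rIdx])
  fc <- (0:(W - 1) - ac[cIdx]) / (ac[cIdx + 1L] - ac[cIdx])
  bilerp <- function(A) {
    A00 <- A[cbind(rep(rIdx, W), rep(cIdx, each = H))]
    A10 <- A[cbind(rep(rIdx + 1L, W), rep(cIdx, each = H))]
    A01 <- A[cbind(rep(rIdx, W), rep(cIdx + 1L, each = H))]
    A11 <- A[cbind(rep(rIdx + 1L, W), rep(cIdx + 1L, each = H))]
    wr <- rep(fr, W); wc <- rep(fc, each = H)
    matrix((1 - wr) * (1 - wc) * A00 + wr * (1 - wc) * A10 +
           (1 - wr) * wc * A01 + wr * wc * A11, H, W)
  }
  vy <- bilerp(vyA); vx <- bilerp(vxA)
  sy <- pmin(pmax(matrix(0:(H - 1), H, W) + vy, 0), H - 1)
  sx <- pmin(pmax(matrix(0:(W - 1), H, W, byrow = TRUE) + vx, 0), W - 1)
  out <- array(0, dim(image))
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- sy - y0; fx <- sx - x0
  for (ch in seq_len(dim(image)[3])) {
    m <- image[, , ch]
    out[, , ch] <-
      (1 - fy) * ((1 - fx) * m[cbind(c(y0) + 1, c(x0) + 1)] +
                  fx * m[cbind(c(y0) + 1, c(x1) + 1)]) +
      fy * ((1 - fx) * m[cbind(c(y1) + 1, c(x0) + 1)] +
            fx * m[cbind(c(y1) + 1, c(x1) + 1)])
  }
  man <- data.frame(row = rep(ar, times = length(ac)),
                    col = rep(ac, each = length(ar)),
                    vy = as.numeric(vyA), vx = as.numeric(vxA))
  list(image = out, manifest = man)
}

#' Generate a roughly paired synthetic dataset
#'
#' Source images are procedural textures (elliptical blob fields and oriented
#' fibres on a cell grid, emulating nuclei/stroma heterogeneity); the
#' ground-truth target is the appearance mapping of the source; the delivered
#' target additionally receives a global affine jitter, per-patch displacement
#' of Euclidean norm \code{misalignment} and additive Gaussian noise, in that
#' order. With zero jitter, displacement and noise the delivered target equals
#' the ground truth exactly. The manifest records the seed, the affine jitter
#' parameters and every patch displacement vector, and the whole dataset is a
#' deterministic function of the spec.
#'
#' @param spec a [syntheticSpec()].
#' @param nImages number of image pairs.
#' @return list with \code{pairs} (list of [ImagePair-class] of source and
#'   delivered target), \code{groundTruth} (list of aligned target arrays) and
#'   \code{manifest}.
#' @export
generateDataset <- function(spec, nImages = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  pairs <- vector("list", nImages)
  gts <- vector("list", nImages)
  mans <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    layoutSeed <- spec@seed + 1000L * (i - 1L)
    src <- array(renderTexture(spec@imageSize, spec@cellSize, layoutSeed,
                               layoutSeed + 1L),
                 c(spec@imageSize, 1L))
    gt <- applyAppearanceMapping(src, spec@mapping)
    delivered <- gt
    set.seed(layoutSeed + 2L)
    if (spec@sourceNoiseSd > 0) {
      src <- pmin(pmax(src + array(stats::rnorm(length(src), 0,
                                                spec@sourceNoiseSd),
                                   dim(src)), 0), 1)
    }
    aff <- c(sx = 0, sy = 0, rot = 0, logScale = 0)
    if (any(spec@affineJitter != 0)) {
      aff <- c(sx = stats::runif(1, -1, 1) * spec@affineJitter[1],
               sy = stats::runif(1, -1, 1) * spec@affineJitter[1],
               rot = stats::runif(1, -1, 1) * spec@affineJitter[2],
               logScale = stats::runif(1, -1, 1) * spec@affineJitter[3])
      ctr <- rev(spec@imageSize - 1) / 2  # (x, y)
      cs <- cos(aff[3]); sn <- sin(aff[3]); sc <- exp(aff[4])
      R <- sc * matrix(c(cs, sn, -sn, cs), 2, 2)
      A <- cbind(R, ctr + aff[1:2] - R %*% ctr)
      delivered <- warpAffine(delivered, A)
    }
    dman <- NULL
    if (spec@misalignment > 0) {
      mis <- if (spec@misalignMode == "swap")
        applyMisalignment(delivered, spec@misalignment, spec@misalignGrid)
      else
        applySmoothMisalignment(delivered, spec@misalignment,
                                spec@misalignGrid)
      delivered <- mis$image
      dman <- mis$manifest
    }
    if (spec@noiseSd > 0) {
      delivered <- delivered +
        array(stats::rnorm(length(delivered), 0, spec@noiseSd),
              dim(delivered))
      delivered <- pmin(pmax(delivered, 0), 1)
    }
    pairs[[i]] <- imagePair(src, delivered)
    gts[[i]] <- gt
    mans[[i]] <- list(image = i, layoutSeed = layoutSeed,
                      affine = aff, displacements = dman)
  }
  list(pairs = pairs, groundTruth = gts,
       manifest = list(spec = list(imageSize = spec@imageSize,
                                   cellSize = spec@cellSize,
                                   mapping = spec@mapping,
                                   misalignment = spec@misalignment,
                                   misalignGrid = spec@misalignGrid,
                                   misalignMode = spec@misalignMode,
                                   affineJitter = spec@affineJitter,
                                   noiseSd = spec@noiseSd,
                                   sourceNoiseSd = spec@sourceNoiseSd,
                                   seed = spec@seed),
                       images = mans))
}

#' Construct a scale-validation image pair
#'
#' A source/target pair that agrees at the texture-cell scale c but not below
#' or far above it, for validating the automatic tolerance-size search. The
#' target starts as a copy of the source and is degraded in two opposite
#' directions: its content is displaced patchwise at a Euclidean distance of
#' c/8 (pixel-level mispairing, which destroys correspondence for regions
#' smaller than about a cell), and a smooth illumination ramp is added to the
#' target only (the macro-scale intensity drift that differs between
#' modalities, which dominates the structure of regions several times the
#' cell size). Matched-position feature correlation is therefore low for
#' crops well below c, maximal around c, and decays for crops well above c.
#'
#' @param imageSize integer(2) or (1), image size.
#' @param cellSize texture cell side c in pixels.
#' @param seed RNG seed.
#' @param rampAmplitude peak-to-peak amplitude of the target-only
#'   illumination ramp (default 0.8).
#' @return list with \code{source} and \code{target} (H, W, 1) arrays and
#'   \code{displacements}, the patch-displacement manifest.
#' @export
makeToleranceValidationPair <- function(imageSize = c(256L, 256L),
                                        cellSize = 32L, seed = 1L,
                                        rampAmplitude = 0.8) {
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  src <- array(renderTexture(imageSize, cellSize, seed, seed + 1L),
               c(imageSize, 1L))
  set.seed(seed + 2L)
  delta <- max(cellSize %/% 8L, 4L)
  mis <- applyMisalignment(src, d = delta, grid = delta)
  tgt <- mis$image
  ramp <- matrix(seq(-rampAmplitude / 2, rampAmplitude / 2,
                     length.out = imageSize[2]),
                 imageSize[1], imageSize[2], byrow = TRUE)
  tgt[, , 1] <- pmin(pmax(tgt[, , 1] + ramp, 0), 1)
  list(source = src, target = tgt, displacements = mis$manifest)
}
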