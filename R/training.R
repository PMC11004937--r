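#' Training configuration
#'
#' Defaults follow the reference training recipe: batch size 2, 80 epochs,
#' Adam with base learning rate 0.0002 held fixed through epoch 40 and then
#' decayed linearly to 0 at epoch 80, loss weights
#' \eqn{\lambda_1 = \lambda_2 = 10}.
#'
#' @param epochs total number of epochs (>= 1).
#' @param iterPerEpoch iterations per epoch; default
#'   \code{ceiling(image area / patch area)} summed over the training pairs.
#' @param batchSize patches per iteration (default 2).
#' @param baseLr Adam base learning rate (default 0.0002).
#' @param decayStart first epoch of the linear decay (default 41); use
#'   \code{epochs + 1} for a constant learning rate.
#' @param seed RNG seed for the whole run.
#' @param patchSize training patch side in pixels (default 64).
#' @param weights a [lossWeights()] list.
#' @param checkpointEvery write a checkpoint every this many epochs
#'   (0 disables checkpointing).
#' @param checkpointDir directory for checkpoint files.
#' @return list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 80L, iterPerEpoch = NULL, batchSize = 2L,
                        baseLr = 2e-4, decayStart = 41L, seed = 1L,
                        patchSize = 64L, weights = lossWeights(),
                        checkpointEvery = 0L, checkpointDir = NULL) {
  if (epochs < 1L) stopContract("epochs must be >= 1")
  if (batchSize < 1L) stopContract("batchSize must be >= 1")
  if (baseLr <= 0) stopContract("baseLr must be > 0")
  if (decayStart > epochs + 1L)
    stopContract("decayStart must be <= epochs + 1")
  structure(list(epochs = as.integer(epochs),
                 iterPerEpoch = if (is.null(iterPerEpoch)) NULL
                                else as.integer(iterPerEpoch),
                 batchSize = as.integer(batchSize), baseLr = baseLr,
                 decayStart = as.integer(decayStart), seed = as.integer(seed),
                 patchSize = as.integer(patchSize), weights = weights,
                 checkpointEvery = as.integer(checkpointEvery),
                 checkpointDir = checkpointDir),
            class = "trainConfig")
}

#' Learning rate at a given epoch
#'
#' The base learning rate is held fixed for epochs up to
#' \code{decayStart - 1}, then decays linearly to 0 at the final epoch. With
#' the defaults (0.0002, 80 epochs, decay from 41): 0.0002 at epoch 10,
#' 0.0001 at epoch 60, 0 at epoch 80.
#'
#' @param epoch epoch index in \code{0..epochs}.
#' @param cfg a [trainConfig()].
#' @return numeric(1) learning rate.
#' @export
lrAtEpoch <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs)
    stopContract("epoch %s outside 0..%d", format(epoch), cfg$epochs)
  if (epoch <= cfg$decayStart - 1L) return(cfg$baseLr)
  cfg$baseLr * (cfg$epochs - epoch) / (cfg$epochs - cfg$decayStart + 1L)
}

oneHot <- function(class, n) {
  y <- numeric(n); y[class] <- 1; y
}

# Gradient of a batch-mean L1 term, d/dy mean|y - ref|
l1Grad <- function(y, ref) sign(y - ref) / length(y)

# Forward/backward helpers threading the shared latent stacks.
encFwd <- function(bundle, x, domain) {
  stem <- if (domain == "s") bundle@ES else bundle@ET
  c1 <- netForward(stem, x)
  c2 <- netForward(bundle@ESh, c1$out)
  list(c1 = c1, c2 = c2, out = c2$out)
}

decFwd <- function(bundle, z, domain) {
  head <- if (domain == "s") bundle@US else bundle@UT
  c1 <- netForward(bundle@USh, z)
  c2 <- netForward(head, c1$out)
  list(c1 = c1, c2 = c2, out = c2$out)
}

decBwd <- function(bundle, fw, gy, domain) {
  head <- if (domain == "s") bundle@US else bundle@UT
  bHead <- netBackward(head, fw$c2$cache, gy)
  bSh <- netBackward(bundle@USh, fw$c1$cache, bHead$gin)
  list(gHead = bHead$grads, gSh = bSh$grads, gz = bSh$gin)
}

encBwd <- function(bundle, fw, gz, domain, needInput = FALSE) {
  stem <- if (domain == "s") bundle@ES else bundle@ET
  bSh <- netBackward(bundle@ESh, fw$c2$cache, gz)
  bStem <- netBackward(stem, fw$c1$cache, bSh$gin, needInput)
  list(gStem = bStem$grads, gSh = bSh$grads, gin = bStem$gin)
}

# Discriminator update on one batch; returns new bundle/state and CEd.
discStep <- function(bundle, stDS, stDT, batch, lr) {
  B <- length(batch$s)
  N <- bundle@N; fake <- N + 1L
  gDS <- NULL; gDT <- NULL
  CEd <- 0
  for (b in seq_len(B)) {
    s <- batch$s[[b]]; t <- batch$t[[b]]; k <- batch$k[b]
    tf <- decFwd(bundle, encFwd(bundle, s, "s")$out, "t")$out
    sf <- decFwd(bundle, encFwd(bundle, t, "t")$out, "s")$out
    terms <- list(list(x = t, net = "DT", class = k),
                  list(x = s, net = "DS", class = k),
                  list(x = tf, net = "DT", class = fake),
                  list(x = sf, net = "DS", class = fake))
    for (tm in terms) {
      net <- slot(bundle, tm$net)
      fw <- netForward(net, tm$x)
      pmap <- softmaxMap(fw$out)
      CEd <- CEd + mapCrossEntropy(pmap, tm$class) / B
      dlogits <- mapCEGrad(pmap, tm$class) / B
      bw <- netBackward(net, fw$cache, dlogits, needInput = FALSE)
      if (tm$net == "DS") gDS <- addGrads(gDS, bw$grads)
      else gDT <- addGrads(gDT, bw$grads)
    }
  }
  uS <- adamStep(bundle@DS, gDS, stDS, lr)
  uT <- adamStep(bundle@DT, gDT, stDT, lr)
  bundle@DS <- uS$net; bundle@DT <- uT$net
  list(bundle = bundle, stDS = uS$state, stDT = uT$state, CEd = CEd)
}

# Generator-objective gradients on one batch. Parameter gradients accumulate
# into six groups: the two domain stems, the shared encoder tail, the shared
# decoder entry, and the two decoder heads.
genGrads <- function(bundle, batch, w) {
  B <- length(batch$s)
  N <- bundle@N
  gES <- NULL; gET <- NULL; gESh <- NULL; gUSh <- NULL
  gUS <- NULL; gUT <- NULL
  CEg <- 0; Lrec <- 0; Lcyc <- 0
  for (b in seq_len(B)) {
    s <- batch$s[[b]]; t <- batch$t[[b]]; k <- batch$k[b]
    eS <- encFwd(bundle, s, "s");    zs <- eS$out
    dTf <- decFwd(bundle, zs, "t");  tf <- dTf$out
    dSr <- decFwd(bundle, zs, "s");  sr <- dSr$out
    eT <- encFwd(bundle, t, "t");    zt <- eT$out
    dSf <- decFwd(bundle, zt, "s");  sf <- dSf$out
    dTr <- decFwd(bundle, zt, "t");  tr <- dTr$out
    eTf <- encFwd(bundle, tf, "t");  zt2 <- eTf$out
    dSc <- decFwd(bundle, zt2, "s"); scyc <- dSc$out
    eSf <- encFwd(bundle, sf, "s");  zs2 <- eSf$out
    dTc <- decFwd(bundle, zs2, "t"); tcyc <- dTc$out
    cDT <- netForward(bundle@DT, tf); pT <- softmaxMap(cDT$out)
    cDS <- netForward(bundle@DS, sf); pS <- softmaxMap(cDS$out)

    Lrec <- Lrec + (mean(abs(s - sr)) + mean(abs(t - tr))) / B
    Lcyc <- Lcyc + (mean(abs(s - scyc)) + mean(abs(t - tcyc))) / B
    CEg <- CEg + (mapCrossEntropy(pT, k) + mapCrossEntropy(pS, k)) / B

    # gradient seeds (all scaled by 1/B for the batch mean)
    gsr <- w$lambda2 * l1Grad(sr, s) / B
    gtr <- w$lambda2 * l1Grad(tr, t) / B
    gscyc <- w$lambda1 * l1Grad(scyc, s) / B
    gtcyc <- w$lambda1 * l1Grad(tcyc, t) / B
    gtfAdv <- netBackward(bundle@DT, cDT$cache, mapCEGrad(pT, k) / B)$gin
    gsfAdv <- netBackward(bundle@DS, cDS$cache, mapCEGrad(pS, k) / B)$gin

    # cycle tails
    bTc <- decBwd(bundle, dTc, gtcyc, "t")
    gUT <- addGrads(gUT, bTc$gHead); gUSh <- addGrads(gUSh, bTc$gSh)
    bSf2 <- encBwd(bundle, eSf, bTc$gz, "s", needInput = TRUE)
    gES <- addGrads(gES, bSf2$gStem); gESh <- addGrads(gESh, bSf2$gSh)
    gsf <- gsfAdv + bSf2$gin
    bSc <- decBwd(bundle, dSc, gscyc, "s")
    gUS <- addGrads(gUS, bSc$gHead); gUSh <- addGrads(gUSh, bSc$gSh)
    bTf2 <- encBwd(bundle, eTf, bSc$gz, "t", needInput = TRUE)
    gET <- addGrads(gET, bTf2$gStem); gESh <- addGrads(gESh, bTf2$gSh)
    gtf <- gtfAdv + bTf2$gin
    # fake and reconstruction paths
    bTf <- decBwd(bundle, dTf, gtf, "t")
    gUT <- addGrads(gUT, bTf$gHead); gUSh <- addGrads(gUSh, bTf$gSh)
    bSf <- decBwd(bundle, dSf, gsf, "s")
    gUS <- addGrads(gUS, bSf$gHead); gUSh <- addGrads(gUSh, bSf$gSh)
    bSr <- decBwd(bundle, dSr, gsr, "s")
    gUS <- addGrads(gUS, bSr$gHead); gUSh <- addGrads(gUSh, bSr$gSh)
    bTr <- decBwd(bundle, dTr, gtr, "t")
    gUT <- addGrads(gUT, bTr$gHead); gUSh <- addGrads(gUSh, bTr$gSh)
    # encoders collect from both decode paths of their latent
    bS <- encBwd(bundle, eS, bTf$gz + bSr$gz, "s")
    gES <- addGrads(gES, bS$gStem); gESh <- addGrads(gESh, bS$gSh)
    bT <- encBwd(bundle, eT, bSf$gz + bTr$gz, "t")
    gET <- addGrads(gET, bT$gStem); gESh <- addGrads(gESh, bT$gSh)
  }
  list(gES = gES, gET = gET, gESh = gESh, gUSh = gUSh, gUS = gUS, gUT = gUT,
       CEg = CEg, Lrec = Lrec, Lcyc = Lcyc)
}

# Generator update: one Adam step on the genGrads gradients.
genStep <- function(bundle, states, batch, lr, w) {
  g <- genGrads(bundle, batch, w)
  gES <- g$gES; gET <- g$gET; gESh <- g$gESh; gUSh <- g$gUSh
  gUS <- g$gUS; gUT <- g$gUT
  CEg <- g$CEg; Lrec <- g$Lrec; Lcyc <- g$Lcyc
  uES <- adamStep(bundle@ES, gES, states$ES, lr)
  uET <- adamStep(bundle@ET, gET, states$ET, lr)
  uESh <- adamStep(bundle@ESh, gESh, states$ESh, lr)
  uUSh <- adamStep(bundle@USh, gUSh, states$USh, lr)
  uUS <- adamStep(bundle@US, gUS, states$US, lr)
  uUT <- adamStep(bundle@UT, gUT, states$UT, lr)
  bundle@ES <- uES$net; bundle@ET <- uET$net
  bundle@ESh <- uESh$net; bundle@USh <- uUSh$net
  bundle@US <- uUS$net; bundle@UT <- uUT$net
  list(bundle = bundle,
       states = list(ES = uES$state, ET = uET$state, ESh = uESh$state,
                     USh = uUSh$state, US = uUS$state, UT = uUT$state),
       CEg = CEg, Lrec = Lrec, Lcyc = Lcyc)
}

drawBatch <- function(pairs, dists, grid, patchSize, batchSize) {
  s <- vector("list", batchSize); t <- vector("list", batchSize)
  k <- integer(batchSize)
  for (b in seq_len(batchSize)) {
    p <- if (length(pairs) == 1L) 1L else sample.int(length(pairs), 1L)
    draw <- samplePatchPair(sourceImage(pairs[[p]]), targetImage(pairs[[p]]),
                            grid, dists[[p]], patchSize)
    s[[b]] <- draw$source; t[[b]] <- draw$target; k[b] <- draw$region
  }
  list(s = s, t = t, k = k)
}

checkFinite <- function(value, term, epoch, iter) {
  if (!is.finite(value))
    stop(sprintf(
      "non-finite %s (%g) at epoch %d iteration %d; aborting training",
      term, value, epoch, iter), call. = FALSE)
}

#' Train the translation model
#'
#' Alternating adversarial optimisation: each iteration draws a batch of
#' source/target patch pairs through the global sampling rule, performs one
#' discriminator update minimising \eqn{L_d = CE_d} and then one generator
#' update minimising \eqn{L_g = CE_g + \lambda_1 L_{cycle} + \lambda_2
#' L_{rec}}, both with Adam (beta 0.5/0.999) at the scheduled learning rate.
#' Sampling distributions are computed once per image pair at the start,
#' since the scores depend only on the data. The run is deterministic given
#' \code{cfg$seed}.
#'
#' @param pairs an [ImagePair-class] or list of them, all conforming to the
#'   grid geometry.
#' @param grid a [RegionGrid-class] built from the selected tolerance.
#' @param cfg a [trainConfig()].
#' @param bundle optionally, a pre-built [NetworkBundle-class] (e.g. from a
#'   checkpoint); by default networks are built and initialised from the seed.
#' @param resumeFrom path of a checkpoint file to resume from; overrides
#'   \code{bundle} and continues the interrupted trajectory exactly.
#' @param verbose print one structured log line per 100 iterations.
#' @return list with \code{bundle} (trained [NetworkBundle-class]) and
#'   \code{history} (data.frame of per-iteration losses and learning rate).
#' @export
trainModel <- function(pairs, grid, cfg, bundle = NULL, resumeFrom = NULL,
                       verbose = FALSE) {
  if (!is.list(pairs)) pairs <- list(pairs)
  if (!all(vapply(pairs, is, logical(1), class2 = "ImagePair")))
    stopContract("pairs must be ImagePair objects")
  for (p in pairs)
    if (any(dim(sourceImage(p))[1:2] != grid@imageShape))
      stopContract("image pair does not conform to the grid geometry")
  N <- nRegions(grid)
  w <- cfg$weights
  iterPerEpoch <- cfg$iterPerEpoch
  if (is.null(iterPerEpoch))
    iterPerEpoch <- sum(vapply(pairs, function(p)
      ceiling(prod(dim(sourceImage(p))[1:2]) / cfg$patchSize^2), numeric(1)))

  startEpoch <- 1L
  history <- list()
  if (!is.null(resumeFrom)) {
    ck <- loadCheckpoint(resumeFrom)
    bundle <- ck$bundle
    states <- ck$states
    startEpoch <- ck$epoch + 1L
    history <- ck$history
    assign(".Random.seed", ck$rngState, envir = globalenv())
    dists <- ck$dists
  } else {
    set.seed(cfg$seed)
    if (is.null(bundle)) {
      cs <- dim(sourceImage(pairs[[1]]))[3]
      ct <- dim(targetImage(pairs[[1]]))[3]
      bundle <- buildNetworks(cs, ct, N, preset = "tiny")
    }
    if (bundle@N != N)
      stopContract("bundle was built for N = %d but grid has N = %d",
                   bundle@N, N)
    states <- list(ES = adamInit(bundle@ES), ET = adamInit(bundle@ET),
                   ESh = adamInit(bundle@ESh), USh = adamInit(bundle@USh),
                   US = adamInit(bundle@US), UT = adamInit(bundle@UT),
                   DS = adamInit(bundle@DS), DT = adamInit(bundle@DT))
    # degenerate scores (all-zero Q, e.g. perfectly anti-correlated stains)
    # fall back to uniform sampling as the error instructs
    dists <- lapply(pairs, function(p)
      tryCatch(
        computeSamplingDistribution(sourceImage(p), targetImage(p), grid),
        regiongan_degenerate_error = function(e)
          uniformSamplingDistribution(sourceImage(p), grid)))
  }

  for (epoch in seq.int(startEpoch, cfg$epochs)) {
    lr <- lrAtEpoch(epoch, cfg)
    for (iter in seq_len(iterPerEpoch)) {
      batch <- drawBatch(pairs, dists, grid, cfg$patchSize, cfg$batchSize)
      d <- discStep(bundle, states$DS, states$DT, batch, lr)
      bundle <- d$bundle; states$DS <- d$stDS; states$DT <- d$stDT
      g <- genStep(bundle, states, batch, lr, w)
      bundle <- g$bundle
      states[c("ES", "ET", "ESh", "USh", "US", "UT")] <- g$states
      losses <- totalLosses(g$CEg, d$CEd, g$Lcyc, g$Lrec, w)
      for (nm in c("CEd", "CEg", "Lcyc", "Lrec"))
        checkFinite(switch(nm, CEd = d$CEd, CEg = g$CEg, Lcyc = g$Lcyc,
                           Lrec = g$Lrec), nm, epoch, iter)
      history[[length(history) + 1L]] <- data.frame(
        epoch = epoch, iter = iter, Lg = losses[["Lg"]], Ld = losses[["Ld"]],
        CEg = g$CEg, CEd = d$CEd, Lcycle = g$Lcyc, Lrec = g$Lrec, lr = lr)
      if (verbose && (iter %% 100L == 0L))
        message(sprintf(
          "epoch %d iter %d Lg %.4f Ld %.4f CEg %.4f CEd %.4f Lcyc %.4f Lrec %.4f lr %g",
          epoch, iter, losses[["Lg"]], losses[["Ld"]], g$CEg, d$CEd,
          g$Lcyc, g$Lrec, lr))
    }
    if (cfg$checkpointEvery > 0L && !is.null(cfg$checkpointDir) &&
        (epoch %% cfg$checkpointEvery == 0L)) {
      saveCheckpoint(file.path(cfg$checkpointDir,
                               sprintf("checkpoint_epoch%03d.rds", epoch)),
                     bundle, states, cfg, epoch, history, dists)
    }
  }
  list(bundle = bundle, history = do.call(rbind, history))
}

#' Save / load a training checkpoint
#'
#' A checkpoint stores all six networks, the optimiser states, the training
#' configuration, the epoch reached, the loss history, the sampling
#' distributions and the RNG state, so that a resumed run reproduces the
#' uninterrupted trajectory exactly. A format version is recorded.
#'
#' @param path file path (.rds).
#' @param bundle,states,cfg,epoch,history,dists checkpoint contents.
#' @return \code{saveCheckpoint}: the path, invisibly.
#' @export
saveCheckpoint <- function(path, bundle, states, cfg, epoch, history, dists) {
  saveRDS(list(format = 1L,
               version = as.character(utils::packageVersion("RegionGAN")),
               bundle = bundle, states = states, cfg = cfg, epoch = epoch,
               history = history, dists = dists,
               rngState = get(".Random.seed", envir = globalenv())),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint}: the checkpoint contents as a list.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format) || ck$format != 1L)
    stopContract("unsupported checkpoint format")
  ck
}

#' Pixelwise-supervised L1 baseline trainer
#'
#' A deliberately minimal supervised ablation used for validation: only the
#' source encoder and target decoder are trained, with the per-pixel L1 loss
#' between \code{UT(ES(s))} and the target patch cropped at the same position,
#' i.e. assuming the pair is pixelwise registered. Optimiser, schedule, batch
#' size and patch size follow the same configuration as [trainModel()], so the
#' comparison isolates the effect of the learning principle, not the budget.
#'
#' @inheritParams trainModel
#' @return list with \code{bundle} and \code{history}.
#' @export
trainL1Baseline <- function(pairs, grid, cfg, bundle = NULL) {
  if (!is.list(pairs)) pairs <- list(pairs)
  set.seed(cfg$seed)
  if (is.null(bundle)) {
    cs <- dim(sourceImage(pairs[[1]]))[3]
    ct <- dim(targetImage(pairs[[1]]))[3]
    bundle <- buildNetworks(cs, ct, nRegions(grid), preset = "tiny")
  }
  states <- list(ES = adamInit(bundle@ES), ESh = adamInit(bundle@ESh),
                 USh = adamInit(bundle@USh), UT = adamInit(bundle@UT))
  iterPerEpoch <- cfg$iterPerEpoch
  if (is.null(iterPerEpoch))
    iterPerEpoch <- sum(vapply(pairs, function(p)
      ceiling(prod(dim(sourceImage(p))[1:2]) / cfg$patchSize^2), numeric(1)))
  ps <- cfg$patchSize
  history <- list()
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lrAtEpoch(epoch, cfg)
    for (iter in seq_len(iterPerEpoch)) {
      gES <- NULL; gESh <- NULL; gUSh <- NULL; gUT <- NULL; loss <- 0
      for (b in seq_len(cfg$batchSize)) {
        p <- if (length(pairs) == 1L) 1L else sample.int(length(pairs), 1L)
        src <- sourceImage(pairs[[p]]); tgt <- targetImage(pairs[[p]])
        d <- dim(src)
        r0 <- sample.int(d[1] - ps + 1L, 1L) - 1L
        c0 <- sample.int(d[2] - ps + 1L, 1L) - 1L
        s <- src[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), , drop = FALSE]
        t <- tgt[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), , drop = FALSE]
        eS <- encFwd(bundle, s, "s")
        dT <- decFwd(bundle, eS$out, "t")
        loss <- loss + mean(abs(dT$out - t)) / cfg$batchSize
        gy <- l1Grad(dT$out, t) / cfg$batchSize
        bT <- decBwd(bundle, dT, gy, "t")
        gUT <- addGrads(gUT, bT$gHead); gUSh <- addGrads(gUSh, bT$gSh)
        bS <- encBwd(bundle, eS, bT$gz, "s")
        gES <- addGrads(gES, bS$gStem); gESh <- addGrads(gESh, bS$gSh)
      }
      uES <- adamStep(bundle@ES, gES, states$ES, lr)
      uESh <- adamStep(bundle@ESh, gESh, states$ESh, lr)
      uUSh <- adamStep(bundle@USh, gUSh, states$USh, lr)
      uUT <- adamStep(bundle@UT, gUT, states$UT, lr)
      bundle@ES <- uES$net; states$ES <- uES$state
      bundle@ESh <- uESh$net; states$ESh <- uESh$state
      bundle@USh <- uUSh$net; states$USh <- uUSh$state
      bundle@UT <- uUT$net; states$UT <- uUT$state
      history[[length(history) + 1L]] <-
        data.frame(epoch = epoch, iter = iter, L1 = loss, lr = lr)
    }
  }
  list(bundle = bundle, history = do.call(rbind, history))
}
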