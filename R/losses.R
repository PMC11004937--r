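# The four-term training objective. All losses are evaluated per patch with
# per-pixel means (the summed form of the printed equations is recovered by
# multiplying by the pixel count), which keeps the default loss weights
# meaningful across patch sizes.

asBatch <- function(x) {
  if (is.list(x)) lapply(x, asImageArray, what = "patch")
  else list(asImageArray(x, "patch"))
}

ceEps <- 1e-12

crossEntropy <- function(p, class) -log(max(p[class], ceEps))

#' Loss weights
#'
#' Weights of the generator objective \eqn{L_g = CE_g + \lambda_1 L_{cycle} +
#' \lambda_2 L_{rec}}. Defaults \eqn{\lambda_1 = \lambda_2 = 10}. A third
#' weight \eqn{\lambda_3 = 0.01} is accepted for configuration compatibility
#' but enters no loss term.
#'
#' @param lambda1 cycle-consistency weight (>= 0).
#' @param lambda2 reconstruction weight (>= 0).
#' @param lambda3 accepted but unused.
#' @return list of class \code{lossWeights}.
#' @export
lossWeights <- function(lambda1 = 10, lambda2 = 10, lambda3 = 0.01) {
  if (lambda1 < 0 || lambda2 < 0)
    stopContract("loss weights must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "lossWeights")
}

#' Reconstruction loss
#'
#' Least-absolute-deviation autoencoding error: the per-pixel mean of
#' \eqn{|S - U_S(E_S(S))|} plus that of \eqn{|T - U_T(E_T(T))|}, each averaged
#' over the batch. Identity generators give exactly 0.
#'
#' @param bundle a [NetworkBundle-class].
#' @param s,t source and target patches (arrays or lists of arrays).
#' @return nonnegative numeric(1).
#' @export
reconstructionLoss <- function(bundle, s, t) {
  s <- asBatch(s); t <- asBatch(t)
  ls <- mean(vapply(s, function(x)
    mean(abs(x - applyDomainAutoencoder(bundle, x, "source"))), numeric(1)))
  lt <- mean(vapply(t, function(x)
    mean(abs(x - applyDomainAutoencoder(bundle, x, "target"))), numeric(1)))
  ls + lt
}

applyDomainAutoencoder <- function(bundle, x, domain) {
  p <- padToEven(x)
  stem <- if (domain == "source") bundle@ES else bundle@ET
  head <- if (domain == "source") bundle@US else bundle@UT
  z <- netForward(bundle@ESh, netForward(stem, p$x)$out)$out
  y <- netForward(head, netForward(bundle@USh, z)$out)$out
  y[seq_len(p$size[1]), seq_len(p$size[2]), , drop = FALSE]
}

#' Cycle-consistency loss
#'
#' Sum of the forward round trip \eqn{|S - U_S(E_T(U_T(E_S(S))))|} and the
#' backward round trip \eqn{|T - U_T(E_S(U_S(E_T(T))))|}, per-pixel means
#' averaged over the batch.
#'
#' @inheritParams reconstructionLoss
#' @return nonnegative numeric(1).
#' @export
cycleLoss <- function(bundle, s, t) {
  s <- asBatch(s); t <- asBatch(t)
  fwd <- mean(vapply(s, function(x)
    mean(abs(x - applyGenerator(bundle, applyGenerator(bundle, x, "st"),
                                "ts"))), numeric(1)))
  bwd <- mean(vapply(t, function(x)
    mean(abs(x - applyGenerator(bundle, applyGenerator(bundle, x, "ts"),
                                "st"))), numeric(1)))
  fwd + bwd
}

#' Adversarial cross-entropy terms
#'
#' The discriminators classify patches into N + 1 classes: the region index of
#' a real patch, or the single combined fake class (index N + 1) for generated
#' patches. The discriminator loss is
#' \deqn{CE_d = CE(D_T(T), y) + CE(D_S(S), y) + CE(D_T(U_T(E_S(S))), fake) +
#'   CE(D_S(U_S(E_T(T))), fake)}
#' and the generator loss is
#' \deqn{CE_g = CE(D_T(U_T(E_S(S))), y_S) + CE(D_S(U_S(E_T(T))), y_T),}
#' i.e. the generators are rewarded when their outputs are classified as the
#' real class of the region the input came from. Each term is a batch mean of
#' per-patch cross-entropies; a patch's cross-entropy is the mean over the
#' discriminator's spatial logit map of the per-location cross-entropy,
#' computed from log-probabilities with a floor of 1e-12. Gradient separation (fake-path terms detached from the generators in
#' \eqn{CE_d}; discriminator parameters frozen in \eqn{CE_g}) is honoured by
#' the training loop.
#'
#' @param bundle a [NetworkBundle-class].
#' @param s,t source and target patches (arrays or lists).
#' @param sLabels,tLabels 1-based region labels in 1..N for each patch.
#' @return named numeric(2): \code{CEg}, \code{CEd}.
#' @export
adversarialCE <- function(bundle, s, sLabels, t, tLabels) {
  s <- asBatch(s); t <- asBatch(t)
  N <- bundle@N
  fake <- N + 1L
  sLabels <- as.integer(sLabels); tLabels <- as.integer(tLabels)
  if (any(sLabels < 1L | sLabels > N) || any(tLabels < 1L | tLabels > N))
    stopContract("region labels must lie in 1..N = 1..%d", N)
  fakeT <- lapply(s, function(x) applyGenerator(bundle, x, "st"))
  fakeS <- lapply(t, function(x) applyGenerator(bundle, x, "ts"))
  ceOn <- function(patches, domain, classes) {
    mean(vapply(seq_along(patches), function(i) {
      net <- if (domain == "source") bundle@DS else bundle@DT
      pmap <- softmaxMap(netForward(net, patches[[i]])$out)
      mapCrossEntropy(pmap, classes[i])
    }, numeric(1)))
  }
  CEd <- ceOn(t, "target", tLabels) + ceOn(s, "source", sLabels) +
    ceOn(fakeT, "target", rep(fake, length(fakeT))) +
    ceOn(fakeS, "source", rep(fake, length(fakeS)))
  CEg <- ceOn(fakeT, "target", sLabels) + ceOn(fakeS, "source", tLabels)
  c(CEg = CEg, CEd = CEd)
}

#' Combine loss terms into the generator and discriminator objectives
#'
#' \eqn{L_g = CE_g + \lambda_1 L_{cycle} + \lambda_2 L_{rec}} and
#' \eqn{L_d = CE_d}.
#'
#' @param CEg,CEd,Lcycle,Lrec finite loss components.
#' @param w a [lossWeights()] list.
#' @return named numeric(2): \code{Lg}, \code{Ld}.
#' @export
totalLosses <- function(CEg, CEd, Lcycle, Lrec, w = lossWeights()) {
  vals <- c(CEg, CEd, Lcycle, Lrec)
  if (!all(is.finite(vals)))
    stopContract("loss components must be finite")
  c(Lg = CEg + w$lambda1 * Lcycle + w$lambda2 * Lrec, Ld = CEd)
}
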