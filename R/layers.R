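# Minimal CNN engine used by the translation networks.
#
# A network is a list(layers = list(...)); feature maps are (H, W, C) arrays.
# Layer types: conv (im2col convolution + pointwise activation), residual
# (x + conv2(relu(conv1(x))) followed by ReLU), upsample2 (nearest x2), gap
# (global average pooling to a vector), dense (fully connected, optionally
# softmax). Activation derivatives are recovered from the stored outputs, so
# each cache keeps only the layer input and output.

actForward <- function(z, act) {
  switch(act,
         linear = z,
         relu = pmax(z, 0),
         lrelu = 0.2 * z + 0.8 * pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         stopContract("unknown activation '%s'", act))
}

# derivative of the activation expressed through its output a
actPrimeFromOut <- function(a, act) {
  switch(act,
         linear = array(1, dim(a)),
         relu = (a > 0) * 1,
         lrelu = 0.2 + 0.8 * (a > 0),
         sigmoid = a * (1 - a),
         stopContract("unknown activation '%s'", act))
}

convLayer <- function(cin, cout, k = 3L, stride = 1L, act = "relu") {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer((k - 1L) %/% 2L),
       act = act,
       W = matrix(0, k * k * cin, cout), b = numeric(cout))
}

residualLayer <- function(ch, k = 3L) {
  list(type = "residual",
       conv1 = convLayer(ch, ch, k, 1L, "relu"),
       conv2 = convLayer(ch, ch, k, 1L, "linear"))
}

denseLayer <- function(din, dout, act = "linear") {
  list(type = "dense", din = din, dout = dout, act = act,
       W = matrix(0, din, dout), b = numeric(dout))
}

convForward <- function(layer, x) {
  z <- conv_fwd(x, layer$W, layer$b, layer$k, layer$k, layer$stride,
                layer$pad)
  a <- actForward(z, layer$act)
  list(out = a, cache = list(x = x, a = a))
}

convBackward <- function(layer, cache, gy, needInput = TRUE) {
  gz <- gy * actPrimeFromOut(cache$a, layer$act)
  g <- conv_bwd(cache$x, layer$W, layer$k, layer$k, layer$stride, layer$pad,
                gz, needInput)
  list(gx = g$gx, grads = list(gW = g$gW, gb = g$gb))
}

layerForward <- function(layer, x) {
  switch(layer$type,
    conv = convForward(layer, x),
    residual = {
      r1 <- convForward(layer$conv1, x)
      r2 <- convForward(layer$conv2, r1$out)
      out <- pmax(x + r2$out, 0)
      list(out = out, cache = list(c1 = r1$cache, c2 = r2$cache, a = out))
    },
    upsample2 = list(out = upsample2_fwd(x), cache = NULL),
    gap = list(out = apply(x, 3, mean), cache = dim(x)),
    dense = {
      z <- drop(crossprod(layer$W, as.numeric(x))) + layer$b
      a <- if (layer$act == "softmax") {
        e <- exp(z - max(z)); e / sum(e)
      } else actForward(z, layer$act)
      list(out = a, cache = list(x = as.numeric(x), xdim = dim(x), a = a))
    },
    stopContract("unknown layer type '%s'", layer$type))
}

# For a softmax dense layer, gy must already be the gradient with respect to
# the logits (cross-entropy callers pass p - y).
layerBackward <- function(layer, cache, gy, needInput = TRUE) {
  switch(layer$type,
    conv = convBackward(layer, cache, gy, needInput),
    residual = {
      gz <- gy * (cache$a > 0)
      b2 <- convBackward(layer$conv2, cache$c2, gz)
      b1 <- convBackward(layer$conv1, cache$c1, b2$gx)
      list(gx = gz + b1$gx, grads = list(conv1 = b1$grads, conv2 = b2$grads))
    },
    upsample2 = list(gx = upsample2_bwd(gy), grads = NULL),
    gap = {
      d <- cache
      gx <- array(rep(gy, each = d[1] * d[2]) / (d[1] * d[2]), d)
      list(gx = gx, grads = NULL)
    },
    dense = {
      gz <- if (layer$act == "softmax") gy else
        gy * actPrimeFromOut(cache$a, layer$act)
      gW <- outer(cache$x, gz)
      gx <- drop(layer$W %*% gz)
      if (!is.null(cache$xdim)) gx <- array(gx, cache$xdim)
      list(gx = gx, grads = list(gW = gW, gb = gz))
    },
    stopContract("unknown layer type '%s'", layer$type))
}

netForward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layerForward(net$layers[[i]], x)
    caches[i] <- list(r$cache)   # single-bracket: keep NULL caches in place
    x <- r$out
  }
  list(out = x, cache = caches)
}

netBackward <- function(net, caches, gout, needInput = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layerBackward(net$layers[[i]], caches[[i]], gout,
                       needInput || i > 1L)
    grads[i] <- list(r$grads)    # keep NULL grads in place
    gout <- r$gx
  }
  list(gin = gout, grads = grads)
}

# Per-location softmax over the channel dimension of an (h, w, K) logit map.
softmaxMap <- function(L) {
  mx <- apply(L, c(1, 2), max)
  e <- exp(L - as.vector(mx))
  e / as.vector(apply(e, c(1, 2), sum))
}

# Mean over locations of the cross-entropy toward `class`, and the matching
# logit-map gradient.
mapCrossEntropy <- function(pmap, class) {
  -mean(log(pmax(pmap[, , class], 1e-12)))
}

mapCEGrad <- function(pmap, class) {
  g <- pmap
  g[, , class] <- g[, , class] - 1
  g / (dim(pmap)[1] * dim(pmap)[2])
}

# ---- parameter bookkeeping ------------------------------------------------

zeroGradsLike <- function(net) {
  lapply(net$layers, function(l) {
    switch(l$type,
      conv = list(gW = array(0, dim(l$W)), gb = numeric(length(l$b))),
      residual = list(
        conv1 = list(gW = array(0, dim(l$conv1$W)),
                     gb = numeric(length(l$conv1$b))),
        conv2 = list(gW = array(0, dim(l$conv2$W)),
                     gb = numeric(length(l$conv2$b)))),
      dense = list(gW = array(0, dim(l$W)), gb = numeric(length(l$b))),
      NULL)
  })
}

addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    if (!is.null(a[[i]]$gW)) {
      a[[i]]$gW <- a[[i]]$gW + b[[i]]$gW
      a[[i]]$gb <- a[[i]]$gb + b[[i]]$gb
    } else {
      a[[i]]$conv1$gW <- a[[i]]$conv1$gW + b[[i]]$conv1$gW
      a[[i]]$conv1$gb <- a[[i]]$conv1$gb + b[[i]]$conv1$gb
      a[[i]]$conv2$gW <- a[[i]]$conv2$gW + b[[i]]$conv2$gW
      a[[i]]$conv2$gb <- a[[i]]$conv2$gb + b[[i]]$conv2$gb
    }
  }
  a
}

scaleGrads <- function(g, s) {
  rapply(g, function(x) x * s, how = "replace")
}

netParameterCount <- function(net) {
  sum(vapply(net$layers, function(l) {
    switch(l$type,
      conv = length(l$W) + length(l$b),
      residual = length(l$conv1$W) + length(l$conv1$b) +
                 length(l$conv2$W) + length(l$conv2$b),
      dense = length(l$W) + length(l$b),
      0L)
  }, numeric(1)))
}

bundleParameterCount <- function(bundle) {
  sum(vapply(list(bundle@ES, bundle@ET, bundle@ESh, bundle@USh,
                  bundle@US, bundle@UT, bundle@DS, bundle@DT),
             netParameterCount, numeric(1)))
}

# ---- Adam -----------------------------------------------------------------

adamInit <- function(net) {
  list(t = 0L, m = zeroGradsLike(net), v = zeroGradsLike(net))
}

# One Adam step; returns list(net, state). beta = (0.5, 0.999), the standard
# choice for this family of adversarial models.
adamStep <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (is.null(grads[[i]])) next
    if (l$type == "residual") {
      for (cn in c("conv1", "conv2")) {
        uW <- upd(l[[cn]]$W, grads[[i]][[cn]]$gW,
                  state$m[[i]][[cn]]$gW, state$v[[i]][[cn]]$gW)
        ub <- upd(l[[cn]]$b, grads[[i]][[cn]]$gb,
                  state$m[[i]][[cn]]$gb, state$v[[i]][[cn]]$gb)
        l[[cn]]$W <- uW$w; state$m[[i]][[cn]]$gW <- uW$m
        state$v[[i]][[cn]]$gW <- uW$v
        l[[cn]]$b <- ub$w; state$m[[i]][[cn]]$gb <- ub$m
        state$v[[i]][[cn]]$gb <- ub$v
      }
    } else {
      uW <- upd(l$W, grads[[i]]$gW, state$m[[i]]$gW, state$v[[i]]$gW)
      ub <- upd(l$b, grads[[i]]$gb, state$m[[i]]$gb, state$v[[i]]$gb)
      l$W <- uW$w; state$m[[i]]$gW <- uW$m; state$v[[i]]$gW <- uW$v
      l$b <- ub$w; state$m[[i]]$gb <- ub$m; state$v[[i]]$gb <- ub$v
    }
    net$layers[[i]] <- l
  }
  list(net = net, state = state)
}

# ---- weight initialisation ------------------------------------------------

# Kaiming (He) fan-in initialisation preserving forward variance; biases 0.
kaimingFill <- function(layer) {
  fanIn <- nrow(layer$W)
  layer$W[] <- stats::rnorm(length(layer$W), 0, sqrt(2 / fanIn))
  layer$b[] <- 0
  layer
}

normalFill <- function(layer, sd = 0.02) {
  layer$W[] <- stats::rnorm(length(layer$W), 0, sd)
  layer$b[] <- 0
  layer
}

initNetWeights <- function(net, scheme = c("kaiming", "normal"), sd = 0.02) {
  scheme <- match.arg(scheme)
  fill <- if (scheme == "kaiming") kaimingFill else
    function(l) normalFill(l, sd)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "residual") {
      l$conv1 <- fill(l$conv1)
      l$conv2 <- fill(l$conv2)
    } else if (l$type %in% c("conv", "dense")) {
      l <- fill(l)
    }
    net$layers[[i]] <- l
  }
  net
}
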