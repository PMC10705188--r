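# ------------------------------------------------------------------------
# Compact volumetric neural-network engine.
#
# Activations are stored as arrays of shape (nVox, channels, batch) where
# nVox flattens the spatial grid column-major. Convolutions are computed as
# im2col gathers followed by BLAS matrix products; transposed convolutions
# and gradient scatters reuse the same geometry through a precomputed
# sparse scatter operator. Everything is deterministic given the R RNG at
# construction/training time.
# ------------------------------------------------------------------------

# Gather geometry for a convolution mapping an input grid `inDim` to an
# output grid under kernel `k`, stride `s` and lo/hi zero padding.
convGeom <- function(inDim, k, stride, padLo, padHi) {
  inDim <- as.integer(rep(inDim, length.out = 3L))
  k     <- as.integer(rep(k, length.out = 3L))
  s     <- as.integer(rep(stride, length.out = 3L))
  padLo <- as.integer(rep(padLo, length.out = 3L))
  padHi <- as.integer(rep(padHi, length.out = 3L))
  outDim <- (inDim + padLo + padHi - k) %/% s + 1L
  if (any(outDim < 1L))
    stop("convolution geometry collapses: input ",
         paste(inDim, collapse = "x"), " with kernel ",
         paste(k, collapse = "x"), call. = FALSE)
  padDim <- inDim + padLo + padHi
  nOut <- prod(outDim)
  kk <- prod(k)
  # output voxel start corners in padded coordinates
  oi <- (seq_len(outDim[1]) - 1L) * s[1] + 1L
  oj <- (seq_len(outDim[2]) - 1L) * s[2] + 1L
  ok <- (seq_len(outDim[3]) - 1L) * s[3] + 1L
  corner <- as.matrix(expand.grid(i = oi, j = oj, k = ok))
  taps <- as.matrix(expand.grid(a = 0:(k[1] - 1L), b = 0:(k[2] - 1L),
                                c = 0:(k[3] - 1L)))
  idx <- matrix(0L, nrow = nOut, ncol = kk)
  for (t in seq_len(kk)) {
    ii <- corner[, 1] + taps[t, 1]
    jj <- corner[, 2] + taps[t, 2]
    kkk <- corner[, 3] + taps[t, 3]
    idx[, t] <- ii + (jj - 1L) * padDim[1] + (kkk - 1L) * padDim[1] * padDim[2]
  }
  # linear indices (in the padded grid) of the original voxels
  gi <- seq_len(inDim[1]) + padLo[1]
  gj <- seq_len(inDim[2]) + padLo[2]
  gk <- seq_len(inDim[3]) + padLo[3]
  g <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  inner <- g[, 1] + (g[, 2] - 1L) * padDim[1] + (g[, 3] - 1L) * padDim[1] * padDim[2]
  idxVec <- as.vector(idx)
  # sparse scatter operator: the adjoint of the im2col gather
  scatter <- Matrix::sparseMatrix(i = idxVec, j = seq_along(idxVec), x = 1,
                                  dims = c(prod(padDim), nOut * kk))
  list(inDim = inDim, outDim = outDim, padDim = padDim, k = k, stride = s,
       nIn = prod(inDim), nOut = nOut, nPad = prod(padDim), kk = kk,
       idx = idx, idxVec = idxVec, inner = inner, scatter = scatter)
}

# batch item b of an activation array as a (nVox x ch) matrix
sliceBatch <- function(x, b) {
  m <- x[, , b, drop = FALSE]
  dim(m) <- dim(x)[1:2]
  m
}

# im2col for one batch item: x (nVox x ch) -> (nOut x kk*ch)
im2col <- function(geom, x) {
  ch <- ncol(x)
  xp <- matrix(0, geom$nPad, ch)
  xp[geom$inner, ] <- x
  m <- xp[geom$idxVec, , drop = FALSE]            # (nOut*kk) x ch
  dim(m) <- c(geom$nOut, geom$kk * ch)
  m
}

# scatter-add of a column matrix (nOut x kk*ch) back onto the (unpadded)
# input grid: the adjoint of im2col.
col2im <- function(geom, dcol) {
  ch <- ncol(dcol) / geom$kk
  dim(dcol) <- c(geom$nOut * geom$kk, ch)
  dxp <- as.matrix(geom$scatter %*% dcol)
  dxp[geom$inner, , drop = FALSE]
}

applyActivation <- function(y, act) {
  switch(act,
         linear  = y,
         relu    = { y[y < 0] <- 0; y },
         tanh    = tanh(y),
         sigmoid = 1 / (1 + exp(-y)))
}

# derivative expressed through the activation output
activationGrad <- function(dy, y, act) {
  switch(act,
         linear  = dy,
         relu    = dy * (y > 0),
         tanh    = dy * (1 - y * y),
         sigmoid = dy * y * (1 - y))
}

initWeight <- function(nrow, ncol, fanIn, act) {
  sdv <- if (identical(act, "relu")) sqrt(2 / fanIn) else sqrt(1 / fanIn)
  matrix(rnorm(nrow * ncol, sd = sdv), nrow, ncol)
}

# ---- layer constructors --------------------------------------------------

makeConv3d <- function(inDim, inCh, outCh, k = 3L, stride = 1L,
                       padLo = NULL, padHi = NULL, activation = "relu") {
  k <- as.integer(rep(k, length.out = 3L))
  if (is.null(padLo)) {                       # 'same'-style defaults
    if (all(k == 3L) && all(stride == 1L)) { padLo <- padHi <- c(1L, 1L, 1L) }
    else if (all(k == 3L) && all(stride == 2L)) { padLo <- padHi <- c(1L, 1L, 1L) }
    else if (all(k == 2L) && all(stride == 1L)) { padLo <- c(0L, 0L, 0L); padHi <- c(1L, 1L, 1L) }
    else { padLo <- padHi <- c(0L, 0L, 0L) }
  }
  geom <- convGeom(inDim, k, stride, padLo, padHi)
  list(type = "conv3d", geom = geom, inCh = inCh, outCh = outCh,
       activation = activation,
       params = list(W = initWeight(geom$kk * inCh, outCh, geom$kk * inCh,
                                    activation),
                     b = numeric(outCh)))
}

# transposed conv, kernel 3, stride 2: smallDim -> 2*smallDim
makeConvT3d <- function(smallDim, inCh, outCh, activation = "relu") {
  smallDim <- as.integer(rep(smallDim, length.out = 3L))
  bigDim <- smallDim * 2L
  geom <- convGeom(bigDim, 3L, 2L, 1L, 1L)    # big -> small gather geometry
  stopifnot(all(geom$outDim == smallDim))
  list(type = "convt3d", geom = geom, inCh = inCh, outCh = outCh,
       activation = activation, bigDim = bigDim,
       params = list(W = initWeight(geom$kk * outCh, inCh, geom$kk * inCh,
                                    activation),
                     b = numeric(outCh)))
}

makePool3d <- function(inDim, ch) {
  geom <- convGeom(inDim, 2L, 2L, 0L, 0L)
  list(type = "pool3d", geom = geom, ch = ch, params = list())
}

makeBatchNorm <- function(ch, eps = 1e-5, momentum = 0.9) {
  list(type = "batchnorm", ch = ch, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       runMean = numeric(ch), runVar = rep(1, ch))
}

makeFlatten <- function(nVox, ch) {
  list(type = "flatten", nVox = nVox, ch = ch, params = list())
}

makeDense <- function(nIn, nOut, activation = "linear") {
  list(type = "dense", nIn = nIn, nOut = nOut, activation = activation,
       params = list(W = initWeight(nIn, nOut, nIn, activation),
                     b = numeric(nOut)))
}

makeDropout <- function(rate) {
  list(type = "dropout", rate = rate, params = list())
}

makeGlobalAvgPool <- function(ch) {
  list(type = "gap", ch = ch, params = list())
}

# ---- forward / backward --------------------------------------------------

layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv3d = {
      B <- dim(x)[3]
      g <- layer$geom
      cols <- vector("list", B)
      preact <- array(0, c(g$nOut, layer$outCh, B))
      bm <- matrix(layer$params$b, g$nOut, layer$outCh, byrow = TRUE)
      for (b in seq_len(B)) {
        cb <- im2col(g, sliceBatch(x, b))
        cols[[b]] <- cb
        preact[, , b] <- cb %*% layer$params$W + bm
      }
      y <- applyActivation(preact, layer$activation)
      list(y = y, cache = list(cols = cols, y = y), layer = layer)
    },
    convt3d = {
      B <- dim(x)[3]
      g <- layer$geom
      preact <- array(0, c(g$nIn, layer$outCh, B))  # nIn = big grid
      bm <- matrix(layer$params$b, g$nIn, layer$outCh, byrow = TRUE)
      for (b in seq_len(B)) {
        xb <- sliceBatch(x, b)
        col <- xb %*% t(layer$params$W)             # nSmall x kk*outCh
        preact[, , b] <- col2im(g, col) + bm
      }
      y <- applyActivation(preact, layer$activation)
      list(y = y, cache = list(x = x, y = y), layer = layer)
    },
    pool3d = {
      B <- dim(x)[3]
      g <- layer$geom
      y <- array(0, c(g$nOut, layer$ch, B))
      src <- array(0L, c(g$nOut, layer$ch, B))
      for (b in seq_len(B)) for (c in seq_len(layer$ch)) {
        m <- matrix(x[, c, b][g$idxVec], g$nOut, g$kk)
        am <- max.col(m, ties.method = "first")
        sel <- cbind(seq_len(g$nOut), am)
        y[, c, b] <- m[sel]
        src[, c, b] <- matrix(g$idxVec, g$nOut, g$kk)[sel]
      }
      list(y = y, cache = list(src = src, inShape = dim(x)), layer = layer)
    },
    batchnorm = {
      B <- dim(x)[3]
      n <- dim(x)[1]
      xm <- matrix(aperm(x, c(1, 3, 2)), n * B, layer$ch)  # (vox*batch) x ch
      if (training) {
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        layer$runMean <- layer$momentum * layer$runMean + (1 - layer$momentum) * mu
        layer$runVar  <- layer$momentum * layer$runVar  + (1 - layer$momentum) * va
      } else {
        mu <- layer$runMean
        va <- layer$runVar
      }
      istd <- 1 / sqrt(va + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
      ym <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                  layer$params$beta, `+`)
      y <- aperm(array(ym, c(n, B, layer$ch)), c(1, 3, 2))
      list(y = y,
           cache = list(xhat = xhat, istd = istd, n = n, B = B,
                        training = training),
           layer = layer)
    },
    flatten = {
      B <- dim(x)[3]
      y <- matrix(0, B, layer$nVox * layer$ch)
      for (b in seq_len(B)) y[b, ] <- as.vector(x[, , b])
      list(y = y, cache = list(B = B), layer = layer)
    },
    gap = {
      B <- dim(x)[3]
      y <- matrix(0, B, layer$ch)
      for (b in seq_len(B)) y[b, ] <- colMeans(sliceBatch(x, b))
      list(y = y, cache = list(nVox = dim(x)[1]), layer = layer)
    },
    dense = {
      preact <- x %*% layer$params$W +
        matrix(layer$params$b, nrow(x), layer$nOut, byrow = TRUE)
      y <- applyActivation(preact, layer$activation)
      list(y = y, cache = list(x = x, y = y), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (matrix(runif(length(x)), nrow(x)) >= layer$rate) /
          (1 - layer$rate)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else list(y = x, cache = list(mask = NULL), layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv3d = {
      B <- dim(dy)[3]
      g <- layer$geom
      dpre <- activationGrad(dy, cache$y, layer$activation)
      dW <- matrix(0, nrow(layer$params$W), ncol(layer$params$W))
      db <- numeric(layer$outCh)
      dx <- array(0, c(g$nIn, layer$inCh, B))
      for (b in seq_len(B)) {
        d <- sliceBatch(dpre, b)
        dW <- dW + crossprod(cache$cols[[b]], d)
        db <- db + colSums(d)
        dx[, , b] <- col2im(g, d %*% t(layer$params$W))
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    convt3d = {
      B <- dim(dy)[3]
      g <- layer$geom
      dpre <- activationGrad(dy, cache$y, layer$activation)
      dW <- matrix(0, nrow(layer$params$W), ncol(layer$params$W))
      db <- numeric(layer$outCh)
      dx <- array(0, c(g$nOut, layer$inCh, B))
      for (b in seq_len(B)) {
        d <- sliceBatch(dpre, b)
        colDY <- im2col(g, d)                     # nSmall x kk*outCh
        dx[, , b] <- colDY %*% layer$params$W
        xb <- sliceBatch(cache$x, b)
        dW <- dW + crossprod(colDY, xb)
        db <- db + colSums(d)
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    pool3d = {
      B <- dim(dy)[3]
      dx <- array(0, cache$inShape)
      for (b in seq_len(B)) for (c in seq_len(layer$ch)) {
        v <- numeric(cache$inShape[1])
        v[cache$src[, c, b]] <- dy[, c, b]
        dx[, c, b] <- v
      }
      list(dx = dx, grads = list())
    },
    batchnorm = {
      n <- cache$n; B <- cache$B
      dym <- matrix(aperm(dy, c(1, 3, 2)), n * B, layer$ch)
      N <- n * B
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      if (cache$training) {
        g <- layer$params$gamma
        dxhat <- sweep(dym, 2, g, `*`)
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
        dxm <- sweep(t1 - t2, 2, cache$istd, `*`)
      } else {
        dxm <- sweep(sweep(dym, 2, layer$params$gamma, `*`), 2, cache$istd, `*`)
      }
      dx <- aperm(array(dxm, c(n, B, layer$ch)), c(1, 3, 2))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    flatten = {
      B <- cache$B
      dx <- array(0, c(layer$nVox, layer$ch, B))
      for (b in seq_len(B)) dx[, , b] <- array(dy[b, ], c(layer$nVox, layer$ch))
      list(dx = dx, grads = list())
    },
    gap = {
      B <- nrow(dy)
      dx <- array(0, c(cache$nVox, layer$ch, B))
      for (b in seq_len(B))
        dx[, , b] <- matrix(dy[b, ] / cache$nVox, cache$nVox, layer$ch,
                            byrow = TRUE)
      list(dx = dx, grads = list())
    },
    dense = {
      dpre <- activationGrad(dy, cache$y, layer$activation)
      list(dx = dpre %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dpre), b = colSums(dpre)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    })
}

# ---- sequential networks -------------------------------------------------

seqForward <- function(net, x, training = FALSE, keepActs = FALSE) {
  caches <- vector("list", length(net$layers))
  acts <- if (keepActs) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layerForward(net$layers[[i]], x, training)
    x <- fw$y
    caches[[i]] <- fw$cache
    net$layers[[i]] <- fw$layer
    if (keepActs) acts[[i]] <- x
  }
  list(out = x, caches = caches, net = net, acts = acts)
}

seqBackward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dy <- dout
  for (i in rev(seq_along(net$layers))) {
    bw <- layerBackward(net$layers[[i]], caches[[i]], dy)
    dy <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dy, grads = grads)
}

# ---- parameter utilities -------------------------------------------------

netParamCount <- function(net) {
  sum(vapply(net$layers, function(l) sum(vapply(l$params, length, 1L)), 1))
}

adamInit <- function(net) {
  lapply(net$layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adamStep <- function(net, grads, state, lr, t, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# stack a list of same-shape cubes into an activation array (nVox, 1, B)
stackCubes <- function(cubes) {
  n <- prod(dim(cubes[[1]]))
  x <- array(0, c(n, 1L, length(cubes)))
  for (b in seq_along(cubes)) x[, 1L, b] <- as.vector(cubes[[b]])
  x
}

# split an activation array (nVox, 1, B) back into cubes of dimension `d`
unstackCubes <- function(x, d) {
  lapply(seq_len(dim(x)[3]), function(b) array(x[, 1L, b], d))
}
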