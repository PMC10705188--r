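#' @import methods
#' @importFrom stats rnorm runif quantile sd cov median
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage index; kept below 2^31.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow when
# derived seeds are chained.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9176) %%
               2147483629)
}

stopifnot3d <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3D array, got dimensions: ",
         paste(dim(x), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

# Zero-pad a 3D array by `pad` voxels on each side of each axis
# (pad is a 3x2 matrix of lo/hi pads, or a length-3 vector for symmetric pads).
padArray3d <- function(x, pad, value = 0) {
  if (is.null(dim(pad))) pad <- cbind(pad, pad)
  d <- dim(x)
  out <- array(value, d + pad[, 1L] + pad[, 2L])
  out[pad[1L, 1L] + seq_len(d[1L]),
      pad[2L, 1L] + seq_len(d[2L]),
      pad[3L, 1L] + seq_len(d[3L])] <- x
  out
}

# Separable Gaussian smoothing of a 3D array (reflection padding).
# sigma in voxels; sigma = 0 returns the input unchanged.
gaussianSmooth3d <- function(x, sigma) {
  stopifnot3d(x)
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- outer(seq_len(n), -r:r, "+")
    idx[idx < 1L] <- 1L - idx[idx < 1L]           # reflect
    idx[idx > n] <- 2L * n - idx[idx > n]
    idx[idx < 1L] <- 1L; idx[idx > n] <- n        # guard tiny axes
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = n)         # axis-first flattening
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_len(2L * r + 1L)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) x <- smooth1(x, ax)
  x
}

# Largest 6-connected component of a logical 3D mask (vectorized flood fill).
largestComponent6 <- function(mask) {
  stopifnot3d(mask, "mask")
  mask <- mask != 0
  if (!any(mask)) return(mask)
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else        { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  remaining <- mask
  best <- NULL
  bestSize <- -1L
  while (any(remaining)) {
    seedIdx <- which(remaining)[1L]
    comp <- array(FALSE, d)
    comp[seedIdx] <- TRUE
    repeat {
      grown <- comp
      for (ax in 1:3) for (by in c(-1L, 1L))
        grown <- grown | shift(comp, ax, by)
      grown <- grown & remaining
      if (identical(grown, comp)) break
      comp <- grown
    }
    sz <- sum(comp)
    if (sz > bestSize) { best <- comp; bestSize <- sz }
    remaining <- remaining & !comp
  }
  best
}

# 6-neighbourhood binary erosion / dilation of a logical 3D mask.
erode6 <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  out <- mask
  pad <- padArray3d(mask + 0, c(1L, 1L, 1L), value = 0)
  ctr <- list(1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]))
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    off <- ctr
    off[[ax]] <- off[[ax]] + by
    out <- out & (pad[off[[1]], off[[2]], off[[3]]] > 0)
  }
  out
}

dilate6 <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  out <- mask
  pad <- padArray3d(mask + 0, c(1L, 1L, 1L), value = 0)
  ctr <- list(1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]))
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    off <- ctr
    off[[ax]] <- off[[ax]] + by
    out <- out | (pad[off[[1]], off[[2]], off[[3]]] > 0)
  }
  out
}

# Trilinear sampling of a 3D array at fractional voxel coordinates (1-based).
# Coordinates outside the grid return `fill`.
sampleTrilinear <- function(x, ci, cj, ck, fill = 0) {
  d <- dim(x)
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  fi <- ci - i0;  fj <- cj - j0;  fk <- ck - k0
  out <- numeric(length(ci))
  inside <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
  out[!inside] <- fill
  if (any(inside)) {
    # clamp corner indices so voxels exactly on the far face stay valid
    gi0 <- pmin(pmax(i0[inside], 1), d[1]); gi1 <- pmin(gi0 + 1, d[1])
    gj0 <- pmin(pmax(j0[inside], 1), d[2]); gj1 <- pmin(gj0 + 1, d[2])
    gk0 <- pmin(pmax(k0[inside], 1), d[3]); gk1 <- pmin(gk0 + 1, d[3])
    wi <- fi[inside]; wj <- fj[inside]; wk <- fk[inside]
    at <- function(ii, jj, kk) x[cbind(ii, jj, kk)]
    c00 <- at(gi0, gj0, gk0) * (1 - wi) + at(gi1, gj0, gk0) * wi
    c10 <- at(gi0, gj1, gk0) * (1 - wi) + at(gi1, gj1, gk0) * wi
    c01 <- at(gi0, gj0, gk1) * (1 - wi) + at(gi1, gj0, gk1) * wi
    c11 <- at(gi0, gj1, gk1) * (1 - wi) + at(gi1, gj1, gk1) * wi
    c0 <- c00 * (1 - wj) + c10 * wj
    c1 <- c01 * (1 - wj) + c11 * wj
    out[inside] <- c0 * (1 - wk) + c1 * wk
  }
  out
}

# Nearest-neighbour sampling companion to sampleTrilinear.
sampleNearest <- function(x, ci, cj, ck, fill = 0) {
  d <- dim(x)
  ri <- round(ci); rj <- round(cj); rk <- round(ck)
  inside <- ri >= 1 & ri <= d[1] & rj >= 1 & rj <= d[2] & rk >= 1 & rk <= d[3]
  out <- rep(fill, length(ci))
  if (any(inside))
    out[inside] <- x[cbind(ri[inside], rj[inside], rk[inside])]
  out
}

# Rotate a 3D cube about one axis through its centre by `angleDeg` degrees,
# trilinear interpolation (nearest for `nearest = TRUE`), out-of-field `fill`.
rotateCube <- function(x, axis, angleDeg, fill = -1, nearest = FALSE) {
  stopifnot3d(x)
  if (angleDeg %% 360 == 0) return(x)
  d <- dim(x)
  th <- angleDeg * pi / 180
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  u <- g$i - ctr[1]; v <- g$j - ctr[2]; w <- g$k - ctr[3]
  # inverse mapping: sample source at R^{-1} (rotate by -th in the plane
  # perpendicular to `axis`)
  cs <- cos(th); sn <- sin(th)
  if (axis == 1L) {
    sv <- cs * v + sn * w; sw <- -sn * v + cs * w; su <- u
  } else if (axis == 2L) {
    su <- cs * u - sn * w; sw <- sn * u + cs * w; sv <- v
  } else {
    su <- cs * u + sn * v; sv <- -sn * u + cs * v; sw <- w
  }
  ci <- su + ctr[1]; cj <- sv + ctr[2]; ck <- sw + ctr[3]
  vals <- if (nearest) sampleNearest(x, ci, cj, ck, fill)
          else sampleTrilinear(x, ci, cj, ck, fill)
  array(vals, d)
}

# Otsu threshold of a numeric array, computed on a 256-bin histogram over
# `range` via EBImage. Returns the threshold on the original intensity scale.
otsuThreshold <- function(x, range = c(-1, 1)) {
  v <- (as.numeric(x) - range[1]) / diff(range)
  v[v < 0] <- 0; v[v > 1] <- 1
  img <- EBImage::Image(matrix(v, nrow = 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  range[1] + th * diff(range)
}

# Center-slice extraction on a named anatomical plane. Axes follow the
# radiological storage convention used throughout the package:
# axis 1 = left-right (x), axis 2 = anterior-posterior (y),
# axis 3 = inferior-superior (z). Sagittal fixes x, coronal fixes y,
# axial fixes z.
centerSlice <- function(vol, plane = c("axial", "sagittal", "coronal")) {
  stopifnot3d(vol)
  plane <- match.arg(plane)
  d <- dim(vol)
  mid <- function(n) (n + 1L) %/% 2L
  switch(plane,
         sagittal = vol[mid(d[1]), , ],
         coronal  = vol[, mid(d[2]), ],
         axial    = vol[, , mid(d[3])])
}
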