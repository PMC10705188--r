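# ------------------------------------------------------------------------
# Tumor-into-tissue blending. Three methods: copy-paste (I), seamless
# gradient-domain blending (II, iterative Poisson-style optimization), and
# style/texture refinement on top of the seamless result (III). Both
# optimization stages run natively in 3D (3D gradients, 3D Gram features)
# to preserve inter-slice coherence.
# ------------------------------------------------------------------------

#' Build a blending request
#'
#' @param tumor tumor cube (3D array or single-patch [PatchSet-class]),
#'   normalized intensities.
#' @param pancreas pancreas cube enclosing the insertion site.
#' @param offset 1-based voxel origin of the tumor cube inside the pancreas
#'   cube; default centers the tumor.
#' @param method `"I"` (copy-paste), `"II"` (seamless), `"III"`
#'   (seamless + style refinement).
#' @param maskThreshold threshold for tumor-object extraction, in (-1, 1);
#'   `NULL` picks Otsu's threshold on the tumor histogram (logged on the
#'   result).
#' @param iterations optimization iterations for methods II/III.
#' @param stepSize gradient-descent step (adapted downward on an increase).
#' @param weights named list of loss weights: `gradient`, `style`,
#'   `content`, `tv`.
#' @param extractor 3D feature extractor for the style stage.
#' @param seed seed for any stochastic choices.
#' @return a validated list of class `BlendRequest`.
#' @export
blendRequest <- function(tumor, pancreas, offset = NULL,
                         method = c("I", "II", "III"),
                         maskThreshold = NULL, iterations = 200L,
                         stepSize = 0.1,
                         weights = list(gradient = 1, style = 1e4,
                                        content = 1, tv = 1e-3),
                         extractor = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is(tumor, "PatchSet")) tumor <- patches(tumor)[[1]]
  if (is(pancreas, "PatchSet")) pancreas <- patches(pancreas)[[1]]
  stopifnot3d(tumor, "tumor"); stopifnot3d(pancreas, "pancreas")
  td <- dim(tumor); pd <- dim(pancreas)
  if (is.null(offset)) offset <- (pd - td) %/% 2L + 1L
  offset <- as.integer(rep(offset, length.out = 3L))
  if (any(offset < 1L) || any(offset + td - 1L > pd))
    stop("tumor cube does not fit inside the pancreas cube at this offset",
         call. = FALSE)
  if (!is.null(maskThreshold) &&
      (maskThreshold <= -1 || maskThreshold >= 1))
    stop("maskThreshold must lie in (-1, 1)", call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  w <- utils::modifyList(list(gradient = 1, style = 1e4, content = 1,
                              tv = 1e-3), as.list(weights))
  structure(list(tumor = tumor, pancreas = pancreas, offset = offset,
                 method = method, maskThreshold = maskThreshold,
                 iterations = as.integer(iterations), stepSize = stepSize,
                 weights = w, extractor = extractor,
                 seed = as.integer(seed)),
            class = "BlendRequest")
}

#' Extract the tumor object mask by thresholding
#'
#' Voxels strictly above the threshold, restricted to the largest
#' 6-connected component. With `erode = TRUE` the mask is additionally
#' eroded by one voxel, the form used as the optimization region of the
#' seamless/style stages (the un-eroded rim supplies Dirichlet boundary
#' values).
#'
#' @param tumor normalized tumor cube (3D array).
#' @param maskThreshold threshold in (-1, 1); `NULL` for Otsu's threshold.
#' @param erode also erode by one voxel.
#' @return A [MaskVolume-class] with attribute `threshold`.
#' @export
extractTumorMask <- function(tumor, maskThreshold = NULL, erode = FALSE) {
  if (is(tumor, "PatchSet")) tumor <- patches(tumor)[[1]]
  stopifnot3d(tumor, "tumor")
  if (is.null(maskThreshold)) maskThreshold <- otsuThreshold(tumor)
  raw <- tumor > maskThreshold
  if (!any(raw))
    stop("threshold ", signif(maskThreshold, 4),
         " is above the tumor maximum: empty mask", call. = FALSE)
  comp <- largestComponent6(raw)
  if (erode) comp <- erode6(comp)
  out <- MaskVolume(comp, label = "tumor")
  attr(out, "threshold") <- maskThreshold
  out
}

# place a tumor-cube mask into pancreas coordinates
placeMask <- function(maskCube, pd, offset) {
  out <- array(FALSE, pd)
  td <- dim(maskCube)
  out[offset[1]:(offset[1] + td[1] - 1L),
      offset[2]:(offset[2] + td[2] - 1L),
      offset[3]:(offset[3] + td[3] - 1L)] <- maskCube != 0
  out
}

blendResult <- function(v, losses = NULL, threshold = NULL) {
  out <- CTVolume(v, spacing = 1, intensityDomain = "normalized")
  attr(out, "losses") <- losses
  attr(out, "maskThreshold") <- threshold
  out
}

#' Blend I: copy-paste
#'
#' Inside the placed tumor mask the output takes the tumor voxels; outside
#' it is bit-identical to the pancreas input.
#'
#' @param req a [blendRequest()] (any `method`; the field is not enforced
#'   so the stages can reuse it).
#' @return A normalized [CTVolume-class] with attributes `losses` (NULL)
#'   and `maskThreshold`.
#' @export
blendCopyPaste <- function(req) {
  stopifnot(inherits(req, "BlendRequest"))
  m <- extractTumorMask(req$tumor, req$maskThreshold)
  big <- placeMask(voxels(m) != 0, dim(req$pancreas), req$offset)
  out <- req$pancreas
  td <- dim(req$tumor)
  tPlaced <- array(0, dim(req$pancreas))
  tPlaced[req$offset[1]:(req$offset[1] + td[1] - 1L),
          req$offset[2]:(req$offset[2] + td[2] - 1L),
          req$offset[3]:(req$offset[3] + td[3] - 1L)] <- req$tumor
  out[big] <- tPlaced[big]
  blendResult(out, threshold = attr(m, "threshold"))
}

# gradient-matching loss and its gradient w.r.t. x, over a subgrid.
# target supplies the desired forward differences. Returns list(loss, grad).
gradMatchLoss <- function(x, target) {
  d <- dim(x)
  loss <- 0
  grad <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    idxA <- idxB <- lapply(d, seq_len)
    idxA[[ax]] <- 1:(n - 1L); idxB[[ax]] <- 2:n
    rx <- x[idxB[[1]], idxB[[2]], idxB[[3]]] -
      x[idxA[[1]], idxA[[2]], idxA[[3]]]
    rt <- target[idxB[[1]], idxB[[2]], idxB[[3]]] -
      target[idxA[[1]], idxA[[2]], idxA[[3]]]
    r <- rx - rt
    loss <- loss + sum(r^2)
    gB <- array(0, d); gA <- array(0, d)
    gB[idxB[[1]], idxB[[2]], idxB[[3]]] <- 2 * r
    gA[idxA[[1]], idxA[[2]], idxA[[3]]] <- -2 * r
    grad <- grad + gB + gA
  }
  list(loss = loss, grad = grad)
}

# total-variation (squared differences) loss and gradient
tvLoss <- function(x) gradMatchLoss(x, array(0, dim(x)))

#' Blend II: seamless gradient-domain blending
#'
#' Iteratively minimizes a 3D gradient-matching loss: inside the (eroded)
#' tumor mask the blend's spatial gradients are pulled toward the tumor's
#' gradient field while the mask rim is held at the pancreas values
#' (Dirichlet constraint); outside the mask the output equals the pancreas
#' input voxel-for-voxel. Gradient descent with an adaptive step; aborts if
#' the loss turns non-finite.
#'
#' @param req a [blendRequest()] with `iterations >= 1`.
#' @return A normalized [CTVolume-class]; `attr(,"losses")` holds the loss
#'   per iteration (element 1 = initial loss).
#' @export
blendSeamless <- function(req) {
  stopifnot(inherits(req, "BlendRequest"))
  if (req$iterations < 1L) stop("need iterations >= 1", call. = FALSE)
  m <- extractTumorMask(req$tumor, req$maskThreshold)
  inner <- erode6(voxels(m) != 0)
  if (!any(inner)) inner <- voxels(m) != 0   # mask too thin to erode
  pd <- dim(req$pancreas)
  td <- dim(req$tumor)
  sel <- list(req$offset[1]:(req$offset[1] + td[1] - 1L),
              req$offset[2]:(req$offset[2] + td[2] - 1L),
              req$offset[3]:(req$offset[3] + td[3] - 1L))
  # work on the tumor-sized subvolume of the output
  sub <- req$pancreas[sel[[1]], sel[[2]], sel[[3]]]
  sub[inner] <- req$tumor[inner]             # copy-paste initialization
  opt <- which(inner)
  step <- req$stepSize
  losses <- numeric(req$iterations + 1L)
  gm <- gradMatchLoss(sub, req$tumor)
  losses[1] <- gm$loss
  for (it in seq_len(req$iterations)) {
    if (!is.finite(gm$loss))
      stop("non-finite blending loss at iteration ", it, call. = FALSE)
    prop <- sub
    prop[opt] <- sub[opt] - step * gm$grad[opt]
    gmProp <- gradMatchLoss(prop, req$tumor)
    if (gmProp$loss <= gm$loss) {
      sub <- prop; gm <- gmProp
    } else {
      step <- step / 2                       # backtrack on an increase
    }
    losses[it + 1L] <- gm$loss
  }
  out <- req$pancreas
  sub[sub < -1] <- -1; sub[sub > 1] <- 1
  outSub <- out[sel[[1]], sel[[2]], sel[[3]]]
  outSub[inner] <- sub[inner]
  out[sel[[1]], sel[[2]], sel[[3]]] <- outSub
  blendResult(out, losses = losses, threshold = attr(m, "threshold"))
}

# style (Gram) + content loss over extractor activations; returns loss and
# gradient w.r.t. the input volume. Uses the first three conv blocks.
styleContentGrad <- function(net, x, gramTargets, contentTarget, wStyle,
                             wContent) {
  fw <- seqForward(net, stackCubes(list(x)), training = FALSE,
                   keepActs = TRUE)
  layerIds <- seq_along(net$layers)
  convIds <- grep("^conv", names(net$layers))
  a3id <- convIds[3]
  loss <- 0
  dacts <- vector("list", length(net$layers))
  for (li in convIds) {
    A <- fw$acts[[li]][, , 1, drop = TRUE]
    nv <- nrow(A)
    G <- crossprod(A) / nv
    tgt <- gramTargets[[match(li, convIds)]]
    diff <- G - tgt
    loss <- loss + wStyle * mean(diff^2)
    dA <- (4 / (nv * length(G))) * wStyle * (A %*% diff)
    dacts[[li]] <- dA
  }
  A3 <- fw$acts[[a3id]][, , 1, drop = TRUE]
  cdiff <- A3 - contentTarget
  loss <- loss + wContent * mean(cdiff^2)
  dacts[[a3id]] <- dacts[[a3id]] + wContent * 2 * cdiff / length(cdiff)
  # manual reverse pass accumulating injected gradients
  dy <- NULL
  for (li in rev(layerIds)) {
    if (!is.null(dacts[[li]])) {
      inj <- array(dacts[[li]], c(dim(dacts[[li]]), 1L))
      dy <- if (is.null(dy)) inj else dy + inj
    }
    if (is.null(dy)) next
    bw <- layerBackward(net$layers[[li]], fw$caches[[li]], dy)
    dy <- bw$dx
  }
  list(loss = loss, grad = array(dy[, 1, 1], dim(x)))
}

#' Blend III: seamless blending plus style/texture refinement
#'
#' Runs the seamless stage, then refines the inserted region under a
#' weighted sum of content loss (activation distance to the stage-1
#' result), style loss (Gram-matrix distance to the pancreas background),
#' gradient-matching loss and total-variation loss, with features from the
#' seeded untrained volumetric extractor. Outside the mask the output
#' equals the pancreas input.
#'
#' @param req a [blendRequest()].
#' @return A normalized [CTVolume-class]; `attr(,"losses")` holds the
#'   stage-2 total loss per iteration.
#' @export
blendStylized <- function(req) {
  stopifnot(inherits(req, "BlendRequest"))
  stage1 <- blendSeamless(req)
  pd <- dim(req$pancreas)
  if (any(pd < 16L))
    stop("pancreas cube must be >= 16 per side for the feature extractor",
         call. = FALSE)
  extractor <- req$extractor %||% buildFeatureExtractor()
  # truncated net: conv/pool blocks 1-3 (style + content features)
  full <- extractorNet(extractor, pd)
  net <- list(kind = "seq", layers = full$layers[1:6])
  m <- extractTumorMask(req$tumor, req$maskThreshold)
  inner <- erode6(voxels(m) != 0)
  if (!any(inner)) inner <- voxels(m) != 0
  big <- placeMask(inner, pd, req$offset)
  opt <- which(big)
  x1 <- voxels(stage1)
  # targets: style Grams from the pancreas background, content from stage 1
  fwP <- seqForward(net, stackCubes(list(req$pancreas)), training = FALSE,
                    keepActs = TRUE)
  convIds <- grep("^conv", names(net$layers))
  gramTargets <- lapply(convIds, function(li) {
    A <- fwP$acts[[li]][, , 1, drop = TRUE]
    crossprod(A) / nrow(A)
  })
  fwC <- seqForward(net, stackCubes(list(x1)), training = FALSE,
                    keepActs = TRUE)
  contentTarget <- fwC$acts[[convIds[3]]][, , 1, drop = TRUE]
  tumorPlaced <- array(0, pd)
  td <- dim(req$tumor)
  tumorPlaced[req$offset[1]:(req$offset[1] + td[1] - 1L),
              req$offset[2]:(req$offset[2] + td[2] - 1L),
              req$offset[3]:(req$offset[3] + td[3] - 1L)] <- req$tumor
  w <- req$weights
  totalLoss <- function(x) {
    sc <- styleContentGrad(net, x, gramTargets, contentTarget,
                           w$style, w$content)
    gm <- gradMatchLoss(x, tumorPlaced)
    tv <- tvLoss(x)
    list(loss = sc$loss + w$gradient * gm$loss + w$tv * tv$loss,
         grad = sc$grad + w$gradient * gm$grad + w$tv * tv$grad)
  }
  x <- x1
  step <- req$stepSize
  cur <- totalLoss(x)
  losses <- numeric(req$iterations + 1L)
  losses[1] <- cur$loss
  for (it in seq_len(req$iterations)) {
    if (!is.finite(cur$loss))
      stop("non-finite blending loss at iteration ", it, call. = FALSE)
    prop <- x
    prop[opt] <- x[opt] - step * cur$grad[opt]
    nxt <- totalLoss(prop)
    if (nxt$loss <= cur$loss) { x <- prop; cur <- nxt }
    else step <- step / 2
    losses[it + 1L] <- cur$loss
  }
  x[x < -1] <- -1; x[x > 1] <- 1
  out <- req$pancreas
  out[big] <- x[big]
  blendResult(out, losses = losses, threshold = attr(m, "threshold"))
}

#' Dispatch a blending request to its method
#'
#' @param req a [blendRequest()].
#' @return A normalized [CTVolume-class]; see the individual methods.
#' @export
blendVolumes <- function(req) {
  stopifnot(inherits(req, "BlendRequest"))
  switch(req$method,
         I = blendCopyPaste(req),
         II = blendSeamless(req),
         III = blendStylized(req))
}
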