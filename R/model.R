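# Multi-scale patch network: construction, forward pass and gradients.
#
# Layout conventions: feature maps are arrays dim (H, W, C, N) (N = patches
# in flight); convolutions are 'same'-padded stride-1 and computed as
# im2col %*% kernel-matrix; batch norm operates on the (H*W*N) x C matrix
# view; module order is conv -> ReLU -> batch norm -> 2x2 max pool.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9
SIGMOID_EPS <- 1e-7

#' Number of patches per image for a spec
#'
#' @param spec a [ModelSpec-class].
#' @return integer vector, patches per scale (row-major tiling), so
#'   \code{sum(patchCounts(spec))} is the patch total per image.
#' @export
patchCounts <- function(spec) as.integer((spec@scales %/% spec@patch)^2)

#' Length of the concatenated per-image embedding
#'
#' @param spec a [ModelSpec-class].
#' @return total patches times the final filter count.
#' @export
embeddingLength <- function(spec) {
  as.integer(sum(patchCounts(spec)) * spec@filters[length(spec@filters)])
}

#' Build the image pyramid for the scales of a spec
#'
#' The input must already have side >= the largest scale (images are
#' resized at load time); the largest scale is returned unresampled when
#' the sides match, all other scales by exact block averaging.
#'
#' @param image a [WellImage-class] or H x W x C array.
#' @param spec a [ModelSpec-class].
#' @return list of channel-last arrays, one per scale, largest first.
#' @export
downsampleImage <- function(image, spec) {
  arr <- if (is(image, "WellImage")) image@data else image
  if (dim(arr)[1] < max(spec@scales))
    stop("image side ", dim(arr)[1], " is smaller than the largest scale ",
         max(spec@scales))
  if (dim(arr)[1] != max(spec@scales))
    arr <- resizeToSide(arr, max(spec@scales))
  lapply(as.integer(spec@scales), function(s) resizeToSide(arr, s))
}

#' Tile an image into non-overlapping patches
#'
#' Row-major tiling: patches are ordered along the first grid row, then
#' the second, and so on. This ordering is part of the embedding contract.
#'
#' @param arr H x W x C array with \code{patch} dividing the side.
#' @param patch patch side.
#' @return array of dim (patch, patch, C, nPatches).
#' @export
patchify <- function(arr, patch) {
  d <- dim(arr)
  if (d[1] %% patch != 0 || d[2] %% patch != 0)
    stop("patch size ", patch, " does not divide image side ", d[1])
  gr <- d[1] %/% patch
  gc <- d[2] %/% patch
  out <- array(0, c(patch, patch, d[3], gr * gc))
  p <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    p <- p + 1L
    out[, , , p] <- arr[((i - 1) * patch + 1):(i * patch),
                        ((j - 1) * patch + 1):(j * patch), , drop = FALSE]
  }
  out
}

#' Reassemble patches into an image (inverse of [patchify()])
#'
#' @param patches array from [patchify()].
#' @param side original image side.
#' @return H x W x C array.
#' @export
unpatchify <- function(patches, side) {
  patch <- dim(patches)[1]
  gr <- side %/% patch
  out <- array(0, c(side, side, dim(patches)[3]))
  p <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gr)) {
    p <- p + 1L
    out[((i - 1) * patch + 1):(i * patch),
        ((j - 1) * patch + 1):(j * patch), ] <- patches[, , , p]
  }
  out
}

# ---- weights ---------------------------------------------------------------

extractorKeys <- function(spec) {
  if (spec@shareAcrossScales) return("shared")
  keys <- character(0)
  for (si in seq_along(spec@scales)) {
    if (spec@shareWithinScale) {
      keys <- c(keys, sprintf("scale%d", spec@scales[si]))
    } else {
      keys <- c(keys, sprintf("scale%d.patch%d", spec@scales[si],
                              seq_len(patchCounts(spec)[si])))
    }
  }
  keys
}

newExtractor <- function(spec, nChannels = 3L) {
  k <- spec@kernel
  cin <- nChannels
  mods <- vector("list", length(spec@filters))
  for (m in seq_along(spec@filters)) {
    f <- spec@filters[m]
    fanIn <- k * k * cin
    mods[[m]] <- list(
      W = matrix(rnorm(fanIn * f, 0, sqrt(2 / fanIn)), fanIn, f),
      b = numeric(f),
      gamma = rep(1, f), beta = numeric(f),
      rm = numeric(f), rv = rep(1, f), bnN = 0L)
    cin <- f
  }
  mods
}

#' Initialise network weights for a spec
#'
#' Variance-scaling (He) initialisation for convolutional and fully
#' connected weights, unit scale / zero shift for batch norm; fully
#' seed-controlled.
#'
#' @param spec a [ModelSpec-class].
#' @param seed integer seed.
#' @return a [DCNNModel-class] with untrained weights.
#' @export
initializeModel <- function(spec, seed = 1L) {
  validObject(spec)
  weights <- withSeed(seed, {
    ext <- lapply(extractorKeys(spec), function(k) newExtractor(spec))
    names(ext) <- extractorKeys(spec)
    dIn <- embeddingLength(spec)
    fc <- list()
    for (w in spec@fcWidths) {
      fc[[length(fc) + 1L]] <- list(
        W = matrix(rnorm(dIn * w, 0, sqrt(2 / dIn)), dIn, w),
        b = numeric(w))
      dIn <- w
    }
    nOut <- if (spec@head == "activation") 1L else spec@nGenes
    list(ext = ext, fc = fc,
         head = list(W = matrix(rnorm(dIn * nOut, 0, sqrt(1 / dIn)),
                                dIn, nOut),
                     b = numeric(nOut)))
  })
  new("DCNNModel", spec = spec, weights = weights,
      specHash = objectHash(spec), history = data.frame())
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: convolution kernels and biases, batch
#' norm scale/shift (running statistics are buffers, not parameters),
#' fully connected weights and biases, and the output head.
#'
#' @param spec a [ModelSpec-class].
#' @return integer parameter count.
#' @examples
#' countParameters(modelSpec())
#' @export
countParameters <- function(spec) {
  k <- spec@kernel
  perExtractor <- 0L
  cin <- 3L
  for (f in spec@filters) {
    perExtractor <- perExtractor + k * k * cin * f + f + 2L * f
    cin <- f
  }
  nExt <- length(extractorKeys(spec))
  dIn <- embeddingLength(spec)
  fc <- 0L
  for (w in spec@fcWidths) {
    fc <- fc + dIn * w + w
    dIn <- w
  }
  nOut <- if (spec@head == "activation") 1L else spec@nGenes
  as.integer(nExt * perExtractor + fc + dIn * nOut + nOut)
}

# ---- low-level layers ------------------------------------------------------
#
# Feature maps travel through the extractor as (H*W*N) x C matrices with
# row index r = h + H*w + H*W*n (items stacked in contiguous row blocks).
# This keeps convolution (im2col + GEMM), batch norm, pooling and global
# average pooling in one memory layout with no transposes; the fused
# kernels in src/ do the per-element work in place.

# Matrix (H*W*N) x F -> array (H, W, F, N); used at API boundaries only.
matToArray <- function(M, H, W, N) {
  f <- ncol(M)
  tmp <- array(M, c(H * W, N, f))
  tmp <- aperm(tmp, c(1, 3, 2))
  dim(tmp) <- c(H, W, f, N)
  tmp
}

# array (H, W, F, N) -> matrix (H*W*N) x F
arrayToMat <- function(A) {
  d <- dim(A)
  tmp <- A
  dim(tmp) <- c(d[1] * d[2], d[3], d[4])
  tmp <- aperm(tmp, c(1, 3, 2))
  matrix(tmp, d[1] * d[2] * d[4], d[3])
}

# item chunk bounds keeping each im2col buffer under ~240 MB
convChunks <- function(H, W, C, N, k) {
  perItem <- H * W * k * k * C
  chunk <- max(1L, as.integer(3e7 %/% perItem))
  starts <- seq(1L, N, by = chunk)
  lapply(starts, function(s) c(s, min(N, s + chunk - 1L)))
}

# Shallow wide layers are bandwidth-bound: below this input-channel
# count (and for 3x3 kernels) the direct blocked convolution kernel is
# used instead of materialising im2col buffers.
DIRECT_CONV_MAX_C <- 4L

# 'same' convolution of the matrix-layout batch: (H*W*N) x Cin times the
# (k*k*Cin) x F kernel matrix, chunked over items.
convForwardMat <- function(Xm, H, W, N, Kmat, k) {
  if (k == 3L && ncol(Xm) <= DIRECT_CONV_MAX_C)
    return(cpp_conv3_fwd(Xm, H, W, N, as.vector(t(Kmat)), ncol(Kmat)))
  out <- matrix(0, nrow(Xm), ncol(Kmat))
  for (ch in convChunks(H, W, ncol(Xm), N, k)) {
    cols <- cpp_im2col_mat(Xm, H, W, N, k, ch[1] - 1L, ch[2] - 1L)
    out[((ch[1] - 1L) * H * W + 1L):(ch[2] * H * W), ] <- cols %*% Kmat
  }
  out
}

# Gradients of the convolution; dX is skipped when computeDX is FALSE
# (the first module's input is the raw image, nothing propagates below).
convBackwardMat <- function(Xm, H, W, N, Kmat, dA, k, computeDX = TRUE) {
  if (!computeDX && k == 3L && ncol(Xm) <= DIRECT_CONV_MAX_C)
    return(list(dX = NULL, dK = cpp_conv3_dk(Xm, dA, H, W, N),
                db = colSums(dA)))
  dX <- if (computeDX) matrix(0, nrow(Xm), ncol(Xm)) else NULL
  dK <- matrix(0, nrow(Kmat), ncol(Kmat))
  tK <- t(Kmat)
  for (ch in convChunks(H, W, ncol(Xm), N, k)) {
    rows <- ((ch[1] - 1L) * H * W + 1L):(ch[2] * H * W)
    cols <- cpp_im2col_mat(Xm, H, W, N, k, ch[1] - 1L, ch[2] - 1L)
    dAc <- dA[rows, , drop = FALSE]
    dK <- dK + crossprod(cols, dAc)
    if (computeDX)
      dX[rows, ] <- cpp_col2im_mat(dAc %*% tK, H, W, ncol(Xm),
                                   ch[2] - ch[1] + 1L, k)
  }
  list(dX = dX, dK = dK, db = colSums(dA))
}

# Engine selection: the single-precision C++ extractor halves memory
# traffic and is the default; the double-precision R path below computes
# the same quantities and serves as the reference implementation
# (options(pathscore.engine = "double") switches, as the tests do when
# they compare the two).
useFloatEngine <- function(spec) {
  identical(getOption("pathscore.engine", "float"), "float") &&
    spec@kernel == 3L && spec@pool == 2L
}

# Forward pass of one extractor over a patch batch in matrix layout
# ((p*p*N) x C). Returns the pooled output matrix, a cache for the
# backward pass, and modules with updated batch-norm running statistics.
extractorForward <- function(mods, Xm, side, N, spec, training) {
  if (useFloatEngine(spec)) {
    fw <- cpp_ext_forward(mods, Xm, side, N, training)
    newMods <- mods
    if (training) {
      for (m in seq_along(mods)) {
        st <- fw$stats[[m]]
        mom <- if ((mods[[m]]$bnN %||% 0L) == 0L) 0 else BN_MOMENTUM
        newMods[[m]]$rm <- mom * mods[[m]]$rm + (1 - mom) * st$mean
        newMods[[m]]$rv <- mom * mods[[m]]$rv + (1 - mom) * st$var
        newMods[[m]]$bnN <- (mods[[m]]$bnN %||% 0L) + 1L
      }
    }
    return(list(out = fw$out, cache = list(ptr = fw$cache),
                mods = newMods))
  }
  extractorForwardR(mods, Xm, side, N, spec, training)
}

extractorForwardR <- function(mods, Xm, side, N, spec, training) {
  cache <- vector("list", length(mods))
  newMods <- mods
  H <- side
  for (m in seq_along(mods)) {
    A <- convForwardMat(Xm, H, H, N, mods[[m]]$W, spec@kernel)
    cpp_bias_relu(A, mods[[m]]$b)            # in place; A is now post-ReLU
    if (training) {
      mv <- cpp_col_meanvar(A)
      mu <- mv$mean
      invstd <- 1 / sqrt(mv$var + BN_EPS)
      # the first batch initialises the running statistics outright: the
      # (0, 1) defaults are arbitrary and an EMA from them would need many
      # batches to reach the true activation scale
      mom <- if ((mods[[m]]$bnN %||% 0L) == 0L) 0 else BN_MOMENTUM
      newMods[[m]]$rm <- mom * mods[[m]]$rm + (1 - mom) * mv$mean
      newMods[[m]]$rv <- mom * mods[[m]]$rv + (1 - mom) * mv$var
      newMods[[m]]$bnN <- (mods[[m]]$bnN %||% 0L) + 1L
    } else {
      mu <- mods[[m]]$rm
      invstd <- 1 / sqrt(mods[[m]]$rv + BN_EPS)
    }
    Y <- cpp_bn_apply(A, mu, invstd, mods[[m]]$gamma, mods[[m]]$beta)
    mp <- cpp_maxpool_mat(Y, H, H, N)
    cache[[m]] <- list(X = Xm, Ar = A, mu = mu, invstd = invstd,
                       idx = mp$idx, side = H)
    Xm <- mp$out
    H <- H %/% 2L
  }
  list(out = Xm, cache = cache, mods = newMods)
}

# Backward pass through one extractor; dOut matches the pooled output
# matrix. Returns per-module gradients (W, b, gamma, beta).
extractorBackward <- function(mods, cache, dOut, N, spec) {
  if (!is.null(cache$ptr))
    return(cpp_ext_backward(mods, cache$ptr, dOut))
  extractorBackwardR(mods, cache, dOut, N, spec)
}

extractorBackwardR <- function(mods, cache, dOut, N, spec) {
  grads <- vector("list", length(mods))
  for (m in rev(seq_along(mods))) {
    cc <- cache[[m]]
    H <- cc$side
    dY <- cpp_maxpool_mat_bwd(dOut, cc$idx, H * H * N)
    bnb <- cpp_bn_bwd(dY, cc$Ar, cc$mu, cc$invstd, mods[[m]]$gamma)
    dA <- bnb$dX
    cpp_relu_bwd(dA, cc$Ar)                  # in place
    cb <- convBackwardMat(cc$X, H, H, N, mods[[m]]$W, dA, spec@kernel,
                          computeDX = m > 1L)
    grads[[m]] <- list(W = cb$dK, b = cb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    dOut <- cb$dX
  }
  grads
}

#' Apply the feature extractor to a single patch
#'
#' Runs one patch through the stack of conv/ReLU/batch-norm/max-pool
#' modules in inference mode (frozen batch statistics), yielding the
#' per-patch feature block — 8 x 8 x 64 for the default spec.
#'
#' @param model a [DCNNModel-class].
#' @param patch a (patch, patch, 3) array.
#' @param scale which scale's extractor to use (defaults to the smallest).
#' @return feature block array (h, h, channels).
#' @export
extractFeatures <- function(model, patch, scale = min(model@spec@scales)) {
  spec <- model@spec
  if (dim(patch)[1] != spec@patch)
    stop("patch side must equal spec patch size ", spec@patch)
  key <- extractorKeyFor(spec, scale)
  Xm <- matrix(patch, dim(patch)[1] * dim(patch)[2], dim(patch)[3])
  fw <- extractorForward(model@weights$ext[[key]], Xm, dim(patch)[1], 1L,
                         spec, training = FALSE)
  h <- spec@patch %/% spec@pool^length(spec@filters)
  array(fw$out, c(h, h, ncol(fw$out)))
}

extractorKeyFor <- function(spec, scale, patchIndex = 1L) {
  if (spec@shareAcrossScales) return("shared")
  if (spec@shareWithinScale) return(sprintf("scale%d", scale))
  sprintf("scale%d.patch%d", scale, patchIndex)
}

#' Global average pooling of a feature block
#'
#' @param block (h, h, c) or (h, h, c, n) array.
#' @return length-c vector (or n x c matrix): per-channel spatial means.
#' @examples
#' globalAveragePool(array(c(1, 2, 3, 4), c(2, 2, 1)))
#' @export
globalAveragePool <- function(block) {
  d <- dim(block)
  if (length(d) == 3L) {
    colMeans(matrix(block, d[1] * d[2], d[3]))
  } else {
    tmp <- block
    dim(tmp) <- c(d[1] * d[2], d[3], d[4])
    t(colMeans(tmp))  # n x c
  }
}

# per-patch pooled vectors V ((N*P) x F, patch-major items) -> per-image
# embedding matrix (N x P*F).
pooledToEmbedding <- function(V, P, N) {
  f <- ncol(V)
  A <- array(t(V), c(f, P, N))
  t(matrix(A, f * P, N))
}

# inverse reshape for the backward pass: dE block (N x P*F) -> dV
embeddingToDV <- function(dE, P, N) {
  f <- ncol(dE) %/% P
  A <- array(t(dE), c(f, P, N))
  t(matrix(A, f, P * N))                   # (N*P) x F
}

#' Concatenate per-patch pooled vectors into one embedding
#'
#' Scale-major, then row-major patch order; concatenation order is part of
#' the model contract (permuting patches changes the embedding).
#'
#' @param vectors list over scales of (nPatches x c) matrices (or plain
#'   vectors for single-patch scales).
#' @return one numeric embedding vector.
#' @export
embedPatches <- function(vectors) {
  unlist(lapply(vectors, function(v) {
    if (is.matrix(v)) as.vector(t(v)) else as.vector(v)
  }), use.names = FALSE)
}

# ---- full network ----------------------------------------------------------

sigmoidClip <- function(z) {
  pmin(1 - SIGMOID_EPS, pmax(SIGMOID_EPS, 1 / (1 + exp(-z))))
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward through the whole network for a batch.
# scaleBatches: list over scales of ((p*p*N*P_s) x 3) matrix-layout patch
# stacks, image-major patch order within each scale. Returns outputs plus
# a cache when training = TRUE (dropout masks are drawn from the current
# RNG stream).
networkForward <- function(weights, spec, scaleBatches, N, training) {
  P <- patchCounts(spec)
  h <- spec@patch %/% spec@pool^length(spec@filters)
  extCache <- vector("list", length(spec@scales))
  newWeights <- weights
  E <- NULL
  for (si in seq_along(spec@scales)) {
    key <- extractorKeyFor(spec, spec@scales[si])
    fw <- extractorForward(weights$ext[[key]], scaleBatches[[si]],
                           spec@patch, N * P[si], spec, training)
    if (training) newWeights$ext[[key]] <- fw$mods
    extCache[[si]] <- fw$cache
    V <- cpp_block_rowmeans(fw$out, h * h)   # (N*P_s) x F
    Es <- pooledToEmbedding(V, P[si], N)
    E <- if (is.null(E)) Es else cbind(E, Es)
  }
  fcCache <- list()
  X <- E
  masks <- list()
  nfc <- length(weights$fc)
  for (i in seq_len(nfc)) {
    Z <- sweep(X %*% weights$fc[[i]]$W, 2L, weights$fc[[i]]$b, "+")
    Hd <- pmax(Z, 0)
    mask <- NULL
    if (training && spec@dropout > 0 && i < nfc) {
      mask <- matrix(rbinom(length(Hd), 1L, 1 - spec@dropout) /
                       (1 - spec@dropout), nrow(Hd), ncol(Hd))
      Hd <- Hd * mask
    }
    fcCache[[i]] <- list(X = X, Z = Z, mask = mask)
    X <- Hd
  }
  Zh <- sweep(X %*% weights$head$W, 2L, weights$head$b, "+")
  out <- if (spec@head == "activation") {
    as.vector(sigmoidClip(Zh))
  } else {
    softmaxRows(Zh)
  }
  list(out = out, E = E, extCache = extCache, fcCache = fcCache,
       headIn = X, Zh = Zh, weights = newWeights)
}

# Backward pass; labels: numeric 0/1 vector (activation head) or 1-based
# class indices (gene head). Gradient of the mean loss over the batch.
networkBackward <- function(weights, spec, fw, labels, N) {
  grads <- list(ext = list(), fc = list(), head = list())
  if (spec@head == "activation") {
    dZh <- matrix((fw$out - labels) / N, ncol = 1L)
  } else {
    Ph <- softmaxRows(fw$Zh)
    Y <- matrix(0, nrow(Ph), ncol(Ph))
    Y[cbind(seq_len(nrow(Ph)), labels)] <- 1
    dZh <- (Ph - Y) / N
  }
  grads$head <- list(W = crossprod(fw$headIn, dZh), b = colSums(dZh))
  dX <- dZh %*% t(weights$head$W)
  for (i in rev(seq_along(weights$fc))) {
    cc <- fw$fcCache[[i]]
    if (!is.null(cc$mask)) dX <- dX * cc$mask
    dZ <- dX * (cc$Z > 0)
    grads$fc[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
    dX <- dZ %*% t(weights$fc[[i]]$W)
  }
  # split dE back into the per-scale blocks
  P <- patchCounts(spec)
  f <- spec@filters[length(spec@filters)]
  h <- spec@patch %/% spec@pool^length(spec@filters)
  off <- 0L
  for (si in seq_along(spec@scales)) {
    cols <- off + seq_len(P[si] * f)
    off <- off + P[si] * f
    dV <- embeddingToDV(dX[, cols, drop = FALSE], P[si], N)
    dPooled <- cpp_block_rowmeans_bwd(dV, h * h)
    key <- extractorKeyFor(spec, spec@scales[si])
    eg <- extractorBackward(weights$ext[[key]], fw$extCache[[si]], dPooled,
                            N * P[si], spec)
    if (is.null(grads$ext[[key]])) {
      grads$ext[[key]] <- eg
    } else {
      for (m in seq_along(eg)) for (nm in names(eg[[m]]))
        grads$ext[[key]][[m]][[nm]] <- grads$ext[[key]][[m]][[nm]] +
          eg[[m]][[nm]]
    }
  }
  grads
}

# Assemble per-scale patch batches (matrix layout) for a list of image
# pyramids from imagePyramid(); items are stacked as contiguous row
# blocks in image order.
assembleScaleBatches <- function(pyramids, spec) {
  lapply(seq_along(spec@scales), function(si)
    do.call(rbind, lapply(pyramids, `[[`, si)))
}

# Build the patch pyramid of one image in matrix layout: one
# ((p*p*P_s) x 3) matrix per scale, patches in row-major tile order.
imagePyramid <- function(image, spec) {
  lapply(downsampleImage(image, spec), function(arr)
    arrayToMat(patchify(arr, spec@patch)))
}

#' Run the network on images
#'
#' Inference-mode forward pass (dropout disabled, batch norm using frozen
#' running statistics): deterministic given fixed weights.
#'
#' @param model a [DCNNModel-class].
#' @param images a [WellImage-class], a list of them, or a list of
#'   channel-last arrays.
#' @return for the activation head, a numeric vector of scores strictly
#'   inside (0, 1); for the gene head, an n x nGenes matrix of class
#'   probabilities (rows sum to 1).
#' @export
forwardPass <- function(model, images) {
  if (is(images, "WellImage") || (is.array(images) &&
                                  length(dim(images)) == 3L))
    images <- list(images)
  spec <- model@spec
  pyr <- lapply(images, imagePyramid, spec = spec)
  sb <- assembleScaleBatches(pyr, spec)
  fw <- networkForward(model@weights, spec, sb, length(images),
                       training = FALSE)
  fw$out
}

#' Classification losses
#'
#' Mean loss over a batch: binary cross-entropy for the sigmoid activation
#' head, categorical cross-entropy for the softmax gene head. Predictions
#' are clipped away from 0 and 1 by a small epsilon.
#'
#' @param outputs numeric scores (activation head) or a probability matrix
#'   (gene head).
#' @param labels 0/1 vector, or 1-based class indices / one-hot matrix.
#' @param head "activation" or "gene".
#' @return non-negative scalar mean loss.
#' @examples
#' modelLoss(c(0.5), 1, "activation")  # ln 2
#' modelLoss(matrix(1/7, 1, 7), 1, "gene")  # ln 7
#' @export
modelLoss <- function(outputs, labels, head = c("activation", "gene")) {
  head <- match.arg(head)
  if (head == "activation") {
    p <- pmin(1 - SIGMOID_EPS, pmax(SIGMOID_EPS, outputs))
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  } else {
    P <- outputs
    P[] <- pmin(1 - SIGMOID_EPS, pmax(SIGMOID_EPS, outputs))
    if (is.matrix(labels)) labels <- max.col(labels, ties.method = "first")
    -mean(log(P[cbind(seq_len(nrow(P)), labels)]))
  }
}
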