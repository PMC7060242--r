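# Architecture contracts: shapes, patch arithmetic, parameter count,
# forward-pass ranges, losses and end-to-end gradients.

ns <- asNamespace("pathscore")

test_that("invalid specs are rejected at construction", {
  expect_error(modelSpec(scales = c(256L, 512L)), "decreasing")
  expect_error(modelSpec(scales = c(512L, 256L), patch = 100L), "divide")
  expect_error(modelSpec(patch = 16L), "divisible by pool")
  expect_error(modelSpec(dropout = 1), "dropout")
  expect_error(modelSpec(head = "both"), "head")
})

test_that("default architecture matches the reference geometry", {
  spec <- modelSpec()
  expect_identical(spec@scales, c(1024L, 512L, 256L))
  expect_identical(patchCounts(spec), c(16L, 4L, 1L))
  expect_identical(sum(patchCounts(spec)), 21L)
  expect_identical(embeddingLength(spec), 1344L)
  # shape chain through the five pools
  sides <- 256 / 2^(0:5)
  expect_identical(sides, c(256, 128, 64, 32, 16, 8))
})

test_that("downsampling yields the three scales and preserves constants", {
  spec <- modelSpec()
  img <- array(0.25, c(1024, 1024, 3))
  pyr <- downsampleImage(img, spec)
  expect_identical(vapply(pyr, function(p) dim(p)[1], 1), c(1024, 512, 256))
  for (p in pyr) expect_true(all(p == 0.25))
  # the largest scale is returned unresampled
  img2 <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  expect_identical(downsampleImage(img2, spec)[[1]], img2)
  expect_error(downsampleImage(array(0, c(512, 512, 3)), spec), "smaller")
})

test_that("patchify tiles row-major and unpatchify inverts it", {
  img <- array(seq_len(16 * 16 * 3) / 800, c(16, 16, 3))
  p <- patchify(img, 8L)
  expect_identical(dim(p), c(8L, 8L, 3L, 4L))
  # row-major: second patch is the top-right block
  expect_identical(p[, , , 2], img[1:8, 9:16, ])
  expect_identical(unpatchify(p, 16L), img)
  expect_identical(dim(patchify(img, 16L))[4], 1L)  # whole image, one patch
  expect_error(patchify(img, 5L), "divide")
})

test_that("feature extraction produces the documented block shapes", {
  spec <- modelSpec(scales = 256L, patch = 256L)
  m <- initializeModel(spec, seed = 1)
  block <- extractFeatures(m, array(runif(256 * 256 * 3), c(256, 256, 3)))
  expect_identical(dim(block), c(8L, 8L, 64L))
  # per-module channel counts follow the filter schedule (double-
  # precision reference path, whose cache exposes the activations)
  X <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  sp2 <- tinySpec()
  w <- initializeModel(sp2, seed = 1)@weights$ext$scale16
  fw <- ns$extractorForwardR(w, ns$arrayToMat(X), 16L, 2L, sp2,
                             training = FALSE)
  expect_identical(ncol(fw$cache[[1]]$Ar), 2L)
  expect_identical(ncol(fw$cache[[2]]$Ar), 3L)
  # all-zero patch with zero biases and BN shift stays zero
  spec0 <- modelSpec(scales = 256L, patch = 256L)
  m0 <- initializeModel(spec0, seed = 2)
  z <- extractFeatures(m0, array(0, c(256, 256, 3)))
  expect_true(all(z == 0))
})

test_that("global average pooling averages each channel", {
  expect_equal(globalAveragePool(array(c(1, 2, 3, 4), c(2, 2, 1))), 2.5)
  blk <- array(0, c(8, 8, 64))
  blk[, , 5] <- 7
  v <- globalAveragePool(blk)
  expect_length(v, 64)
  expect_equal(v[5], 7)
  expect_equal(sum(v[-5]), 0)
})

test_that("embedding length and ordering follow the contract", {
  spec <- modelSpec()
  expect_identical(embeddingLength(spec), 21L * 64L)
  single <- modelSpec(scales = 256L, patch = 256L)
  expect_identical(embeddingLength(single), 64L)
  # concatenation is order-sensitive
  v1 <- matrix(1:8, 2, 4, byrow = TRUE)
  e12 <- embedPatches(list(v1))
  e21 <- embedPatches(list(v1[2:1, ]))
  expect_false(identical(e12, e21))
  expect_identical(sort(e12), sort(e21))
})

test_that("forward pass respects head ranges and is deterministic", {
  spec <- tinySpec()
  m <- initializeModel(spec, seed = 3)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  s1 <- forwardPass(m, img)
  s2 <- forwardPass(m, img)
  expect_identical(s1, s2)
  expect_true(s1 > 0 && s1 < 1)
  g <- initializeModel(tinySpec(head = "gene"), seed = 3)
  p <- forwardPass(g, img)
  expect_equal(rowSums(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # equal logits split the softmax evenly
  expect_equal(ns$softmaxRows(matrix(2, 1, 7)), matrix(1 / 7, 1, 7))
})

test_that("parameter count equals the actual number of trainable scalars
           and stays under a million", {
  for (spec in list(modelSpec(), tinySpec(),
                    modelSpec(head = "gene"),
                    modelSpec(scales = 256L, patch = 256L))) {
    m <- initializeModel(spec, seed = 1)
    counted <- 0L
    for (ext in m@weights$ext) for (mod in ext)
      counted <- counted + length(mod$W) + length(mod$b) +
        length(mod$gamma) + length(mod$beta)
    for (fc in m@weights$fc) counted <- counted + length(fc$W) +
        length(fc$b)
    counted <- counted + length(m@weights$head$W) + length(m@weights$head$b)
    expect_identical(countParameters(spec), counted)
  }
  expect_lt(countParameters(modelSpec()), 1e6)
  # widening the FC trunk strictly increases the count
  expect_gt(countParameters(modelSpec(fcWidths = c(200L, 200L, 200L))),
            countParameters(modelSpec()))
})

test_that("losses take their closed-form values", {
  expect_equal(modelLoss(c(1 - 1e-7, 1e-7), c(1, 0), "activation"), 0,
               tolerance = 1e-6)
  expect_equal(modelLoss(0.5, 1, "activation"), log(2))
  expect_equal(modelLoss(matrix(1 / 7, 1, 7), 1, "gene"), log(7))
  P <- matrix(c(0.7, 0.2, 0.1), 1)
  expect_equal(modelLoss(P, 1, "gene"), -log(0.7))
  expect_gte(modelLoss(matrix(runif(21), 3), sample(7, 3, TRUE), "gene"), 0)
})

test_that("the single-precision engine agrees with the double-precision
           reference on outputs and gradients", {
  spec <- tinySpec()
  set.seed(30)
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  m <- initializeModel(spec, seed = 6)
  pyr <- lapply(imgs, ns$imagePyramid, spec = spec)
  sb <- ns$assembleScaleBatches(pyr, spec)
  y <- c(0, 1, 1, 0)
  fwF <- ns$networkForward(m@weights, spec, sb, 4, training = TRUE)
  grF <- ns$networkBackward(m@weights, spec, fwF, y, 4)
  withr::local_options(pathscore.engine = "double")
  fwD <- ns$networkForward(m@weights, spec, sb, 4, training = TRUE)
  grD <- ns$networkBackward(m@weights, spec, fwD, y, 4)
  expect_equal(fwF$out, fwD$out, tolerance = 1e-5)
  relerr <- function(a, b) max(abs(a - b) / pmax(1e-4, abs(b)))
  expect_lt(relerr(grF$head$W, grD$head$W), 1e-4)
  expect_lt(relerr(grF$ext$scale16[[1]]$W, grD$ext$scale16[[1]]$W), 1e-3)
  expect_lt(relerr(grF$ext$scale16[[2]]$W, grD$ext$scale16[[2]]$W), 1e-3)
  expect_lt(relerr(grF$ext$scale8[[2]]$gamma,
                   grD$ext$scale8[[2]]$gamma), 1e-3)
})

test_that("analytic gradients match finite differences end to end", {
  withr::local_options(pathscore.engine = "double")
  spec <- tinySpec()
  set.seed(31)
  N <- 3
  imgs <- lapply(1:N, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labels <- c(0, 1, 1)
  m <- initializeModel(spec, seed = 4)
  pyr <- lapply(imgs, ns$imagePyramid, spec = spec)
  sb <- ns$assembleScaleBatches(pyr, spec)
  lossAt <- function(w) {
    fw <- ns$networkForward(w, spec, sb, N, training = TRUE)
    modelLoss(fw$out, labels, "activation")
  }
  fw <- ns$networkForward(m@weights, spec, sb, N, training = TRUE)
  gr <- ns$networkBackward(m@weights, spec, fw, labels, N)
  setNested <- function(W, path, i, v) {
    if (length(path) == 1) {
      W[[path[[1]]]][i] <- v
      return(W)
    }
    W[[path[[1]]]] <- setNested(W[[path[[1]]]], path[-1], i, v)
    W
  }
  paths <- list(list("head", "W"), list("fc", 1L, "W"),
                list("ext", "scale16", 1L, "W"),
                list("ext", "scale16", 2L, "gamma"),
                list("ext", "scale8", 1L, "b"),
                list("ext", "scale8", 2L, "beta"))
  for (path in paths) {
    w <- m@weights
    g <- gr
    for (p in path) {
      w <- w[[p]]
      g <- g[[p]]
    }
    for (i in sample(length(w), min(3, length(w)))) {
      eps <- 1e-6
      num <- (lossAt(setNested(m@weights, path, i, w[i] + eps)) -
                lossAt(setNested(m@weights, path, i, w[i] - eps))) /
        (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
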