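# Low-level compute kernels against naive reference implementations.

ns <- asNamespace("pathscore")

test_that("im2col + GEMM convolution matches direct convolution", {
  set.seed(11)
  for (dims in list(c(6, 6, 2, 3), c(8, 8, 3, 1), c(4, 4, 1, 5))) {
    x <- array(rnorm(prod(dims)), dims)
    K <- array(rnorm(3 * 3 * dims[3] * 4), c(3, 3, dims[3], 4))
    Xm <- ns$arrayToMat(x)
    got <- ns$convForwardMat(Xm, dims[1], dims[2], dims[4],
                             matrix(K, 9 * dims[3], 4), 3L)
    gotA <- ns$matToArray(got, dims[1], dims[2], dims[4])
    expect_equal(gotA, naiveConv(x, K), tolerance = 1e-12)
    # the chunked matrix-layout path agrees with the plain array kernel
    cols <- ns$cpp_im2col(x, dims[1], dims[2], dims[3], dims[4], 3L)
    expect_equal(got, cols %*% matrix(K, 9 * dims[3], 4),
                 tolerance = 1e-12)
  }
})

test_that("matrix-layout col2im is the adjoint of matrix-layout im2col", {
  set.seed(15)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  Xm <- ns$arrayToMat(x)
  cols <- ns$cpp_im2col_mat(Xm, 6L, 6L, 3L, 3L, 0L, 2L)
  cmat <- matrix(rnorm(length(cols)), nrow(cols))
  lhs <- sum(cols * cmat)
  rhs <- sum(Xm * ns$cpp_col2im_mat(cmat, 6L, 6L, 2L, 3L, 3L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("fused bias+ReLU, batch-norm and pooling kernels match their
           plain-R counterparts", {
  set.seed(16)
  A <- matrix(rnorm(32 * 3), 32, 3)
  b <- rnorm(3)
  ref <- pmax(sweep(A, 2, b, "+"), 0)
  ns$cpp_bias_relu(A, b)
  expect_equal(A, ref)
  mv <- ns$cpp_col_meanvar(A)
  expect_equal(mv$mean, colMeans(A))
  expect_equal(mv$var, colMeans(A^2) - colMeans(A)^2, tolerance = 1e-12)
  gamma <- runif(3, 0.5, 2); beta <- rnorm(3)
  invstd <- 1 / sqrt(mv$var + 1e-5)
  Y <- ns$cpp_bn_apply(A, mv$mean, invstd, gamma, beta)
  refY <- sweep(sweep(sweep(sweep(A, 2, mv$mean), 2, invstd, "*"),
                      2, gamma, "*"), 2, beta, "+")
  expect_equal(Y, refY, tolerance = 1e-12)
  # matrix-layout pooling agrees with the array kernel
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  mpA <- ns$cpp_maxpool(x, 8L, 8L, 2L, 2L)
  mpM <- ns$cpp_maxpool_mat(ns$arrayToMat(x), 8L, 8L, 2L)
  expect_equal(ns$arrayToMat(array(mpA$out, c(4, 4, 2, 2))), mpM$out)
  # block row-means = global average pooling per item block
  P <- matrix(rnorm(4 * 6 * 2), 24, 2)
  V <- ns$cpp_block_rowmeans(P, 4L)
  expect_equal(V[1, ], colMeans(P[1:4, ]))
  expect_equal(V[6, ], colMeans(P[21:24, ]))
  dV <- matrix(rnorm(12), 6, 2)
  dP <- ns$cpp_block_rowmeans_bwd(dV, 4L)
  expect_equal(colSums(dP), colSums(dV))
  expect_equal(dP[1:4, 1], rep(dV[1, 1] / 4, 4))
})

test_that("col2im is the adjoint of im2col", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  cols <- ns$cpp_im2col(x, 6L, 6L, 2L, 2L, 3L)
  cmat <- matrix(rnorm(length(cols)), nrow(cols))
  lhs <- sum(cols * cmat)
  rhs <- sum(as.vector(x) * ns$cpp_col2im(cmat, 6L, 6L, 2L, 2L, 3L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("max pooling matches blockwise maxima and routes gradients to
           the argmax", {
  set.seed(13)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  mp <- ns$cpp_maxpool(x, 8L, 8L, 2L, 2L)
  out <- array(mp$out, c(4, 4, 2, 2))
  for (n in 1:2) for (c in 1:2) for (w in 1:4) for (h in 1:4)
    expect_equal(out[h, w, c, n],
                 max(x[(2 * h - 1):(2 * h), (2 * w - 1):(2 * w), c, n]))
  dout <- rnorm(length(mp$out))
  dx <- ns$cpp_maxpool_bwd(dout, mp$idx, length(x))
  expect_equal(sum(dx), sum(dout))         # gradient mass conserved
  expect_equal(sum(dx != 0), length(dout)) # exactly one recipient per window
  expect_true(all(as.vector(x)[mp$idx] == mp$out))
})

test_that("disc rasteriser paints the right area and the annulus is
           disjoint from its disc", {
  img <- numeric(200 * 200)
  n <- ns$cpp_add_disc(img, 200L, 200L, 100, 100, 15, 2)
  expect_equal(n, pi * 15^2, tolerance = 0.02)
  expect_equal(sum(img), 2 * n)
  ring <- numeric(200 * 200)
  ns$cpp_add_annulus(ring, 200L, 200L, 100, 100, 15, 30, 1)
  expect_equal(sum(img * ring), 0)
  # border clipping: fewer pixels but no error
  edge <- numeric(50 * 50)
  nEdge <- ns$cpp_add_disc(edge, 50L, 50L, 2, 2, 10, 1)
  expect_lt(nEdge, pi * 100)
  expect_equal(sum(edge), nEdge)
})

test_that("batch norm backward matches finite differences", {
  set.seed(14)
  Xm <- matrix(rnorm(40), 10, 4)
  gamma <- runif(4, 0.5, 1.5)
  beta <- rnorm(4)
  dY <- matrix(rnorm(40), 10, 4)
  bnTrain <- function(X) {
    mv <- ns$cpp_col_meanvar(X)
    invstd <- 1 / sqrt(mv$var + 1e-5)
    list(out = ns$cpp_bn_apply(X, mv$mean, invstd, gamma, beta),
         mu = mv$mean, invstd = invstd)
  }
  fw <- bnTrain(Xm)
  bw <- ns$cpp_bn_bwd(dY, Xm, fw$mu, fw$invstd, gamma)
  lossAt <- function(X) sum(bnTrain(X)$out * dY)
  eps <- 1e-6
  for (i in sample(length(Xm), 6)) {
    Xp <- Xm; Xp[i] <- Xp[i] + eps
    Xl <- Xm; Xl[i] <- Xl[i] - eps
    expect_equal(bw$dX[i], (lossAt(Xp) - lossAt(Xl)) / (2 * eps),
                 tolerance = 1e-4)
  }
  expect_equal(bw$dbeta, colSums(dY))
})
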