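# Synthetic assay simulator: layout statistics, rendering physics,
# dose model, and experiment generation.

test_that("layout draws honour the configured cell-count distribution", {
  # zero-variance draw gives exactly the mean every seed
  p <- simParams(fovSize = 128L, meanCells = 10, sdCells = 0)
  for (s in 1:5)
    expect_identical(nrow(sampleLayout(p, s)@cellCenters), 10L)
  # zero transfection rate gives zero transfected cells
  p0 <- tinySimParams(transfectionRate = 0)
  expect_identical(sum(sampleLayout(p0, 1)@transfected), 0L)
  # determinism
  t1 <- sampleLayout(tinySimParams(), 42)
  t2 <- sampleLayout(tinySimParams(), 42)
  expect_identical(t1@cellCenters, t2@cellCenters)
  expect_identical(t1@transfected, t2@transfected)
})

test_that("layout respects the field bounds and overlap ceiling", {
  p <- smallSimParams()
  tr <- sampleLayout(p, 3)
  r <- tr@nucleusRadius
  expect_true(all(tr@cellCenters >= r & tr@cellCenters <= 256 - r + 1))
  expect_true(all(r >= 6 & r <= 12))
  # at low density every placement must satisfy the lens-area overlap
  # ceiling (checked against the independent R overlap formula)
  ns <- asNamespace("pathscore")
  sparse <- simParams(fovSize = 512L, meanCells = 40, sdCells = 0)
  trs <- sampleLayout(sparse, 8)
  cc <- trs@cellCenters
  rr <- trs@nucleusRadius
  for (i in seq_len(nrow(cc) - 1)) {
    j <- (i + 1):nrow(cc)
    d <- sqrt((cc[j, 1] - cc[i, 1])^2 + (cc[j, 2] - cc[i, 2])^2)
    expect_true(all(ns$discOverlapFraction(d, rr[i], rr[j]) <= 0.3 + 1e-9))
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simParams(transfectionRate = 1.2), "transfectionRate")
  expect_error(simParams(meanCells = 0), "meanCells")
  expect_error(simParams(cytoplasmRadiusFactor = 0.9), "cytoplasm")
  expect_error(renderWell(sampleLayout(tinySimParams(), 1), 1.5,
                          tinySimParams(), 1), "alpha")
})

test_that("dose-to-activation follows the Hill form", {
  m <- doseModel(alpha0 = 0.8, ic50 = 10, hill = 1.5, floor = 0)
  expect_equal(doseToActivation(m, 0), 0.8)        # Hill at zero
  expect_equal(doseToActivation(m, 10), 0.4)       # midpoint
  expect_equal(doseToActivation(m, 1e9), 0, tolerance = 1e-6) # asymptote
  mf <- doseModel(alpha0 = 0.9, ic50 = 5, floor = 0.2)
  expect_equal(doseToActivation(mf, 1e9), 0.2, tolerance = 1e-5)
  # non-increasing without rebound, and bounded by [floor, alpha0]
  conc <- c(0, 10^seq(-2, 4, length.out = 30))
  a <- doseToActivation(mf, conc)
  expect_true(all(diff(a) <= 1e-12))
  expect_true(all(a >= 0.2 - 1e-9 & a <= 0.9 + 1e-9))
  # rebound raises the high-dose tail above the floor
  mr <- doseModel(alpha0 = 0.9, ic50 = 5, floor = 0.05, reboundAmp = 0.3,
                  reboundConc = 1000)
  ar <- doseToActivation(mr, conc)
  expect_gt(ar[length(ar)], doseToActivation(mf, 1e4))
  expect_error(doseToActivation(m, -1), ">= 0")
})

test_that("rendering is monotone in activation and conserves per-cell
           reporter signal", {
  # sparse layout so cells do not overlap and per-cell sums are separable
  p <- simParams(fovSize = 256L, meanCells = 6, sdCells = 0,
                 nucleusRadiusRange = c(6, 8), shotNoise = FALSE,
                 readNoiseSd = 0, transfectionRate = 1)
  tr <- sampleLayout(p, 5)
  hi <- renderWell(tr, 1, p, seed = 9)
  lo <- renderWell(tr, 0, p, seed = 9)
  nucRatio <- function(w, t) {
    nucMask <- getChannel(w$image, "nuclear") > 0.001
    rep_ <- getChannel(w$image, "reporter")
    mean(rep_[nucMask]) / mean(rep_[!nucMask & rep_ > 0])
  }
  expect_gt(nucRatio(hi, tr), nucRatio(lo, tr))
  expect_true(all(hi$truth@nuclearFraction >= lo$truth@nuclearFraction))
  # conservation: total reporter signal is independent of alpha (noise off)
  sHi <- sum(getChannel(hi$image, "reporter"))
  sLo <- sum(getChannel(lo$image, "reporter"))
  expect_equal(sHi, sLo, tolerance = 0.01)
  mid <- renderWell(tr, 0.5, p, seed = 9)
  expect_equal(sum(getChannel(mid$image, "reporter")), sLo,
               tolerance = 0.01)
})

test_that("reporter appears only in transfected cells", {
  p <- simParams(fovSize = 256L, meanCells = 8, sdCells = 0,
                 nucleusRadiusRange = c(6, 8), shotNoise = FALSE,
                 readNoiseSd = 0, transfectionRate = 0.5)
  tr <- sampleLayout(p, 2)
  w <- renderWell(tr, 0.7, p, seed = 3)
  rep_ <- getChannel(w$image, "reporter")
  mrk <- getChannel(w$image, "marker")
  expect_true(all((rep_ > 0) <= (mrk >= 0) ))
  if (any(!tr@transfected)) {
    i <- which(!tr@transfected)[1]
    cy <- tr@cellCenters[i, 1]; cx <- tr@cellCenters[i, 2]
    expect_identical(rep_[round(cy), round(cx)], 0)
    expect_true(is.na(w$truth@nuclearFraction[i]))
  }
})

test_that("generateExperiment writes the declared wells, plates and
           manifest and is bit-deterministic", {
  d1 <- file.path(tempdir(), "exp1")
  d2 <- file.path(tempdir(), "exp2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  design <- data.frame(gene = "KRAS", variant = c("WT", "G12D"),
                       annotation_class = c("WT", "activating"),
                       alpha = c(0.05, 0.9), n_wells = 4L)
  ds1 <- generateExperiment(design, tinySimParams(), seed = 5, outDir = d1,
                            plateSize = 4L)
  m1 <- manifest(ds1)
  expect_identical(nrow(m1), 8L)
  expect_identical(length(unique(m1$plate_id)), 2L)
  expect_identical(sort(table(m1$variant)), sort(table(c(rep("WT", 4),
                                                         rep("G12D", 4)))))
  expect_true(all(file.exists(imagePaths(ds1))))
  expect_true("truth_alpha" %in% names(m1))
  generateExperiment(design, tinySimParams(), seed = 5, outDir = d2,
                     plateSize = 4L)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("simulated wells at default density match the emulated dataset
           statistics (reduced replicate count)", {
  # a compact version of the calibration run: the acceptance suite
  # re-measures this over 50 full wells
  p <- simParams()
  counts <- vapply(1:8, function(s)
    nrow(sampleLayout(p, s)@cellCenters), 1L)
  expect_equal(mean(counts), 3543, tolerance = 0.15)
  frac <- vapply(1:8, function(s) {
    tr <- sampleLayout(p, s)
    mean(tr@transfected)
  }, 1)
  expect_equal(mean(frac), 0.12, tolerance = 0.25)
})

test_that("the intensity-ratio oracle separates low from high activation
           wells perfectly at modest well counts", {
  p <- smallSimParams()
  ratios <- function(alpha, seeds) vapply(seeds, function(s) {
    tr <- sampleLayout(p, s)
    oracleRatio(renderWell(tr, alpha, p, seed = s + 500)$image)$ratio
  }, 1)
  lo <- ratios(0.05, 1:6)
  hi <- ratios(0.9, 7:12)
  expect_true(all(is.finite(c(lo, hi))))
  expect_equal(bruteForceAuc(c(lo, hi), rep(c(0, 1), each = 6)), 1)
})
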