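#' Create simulation parameters
#'
#' Constructor for [SimParams-class] with defaults matching the assay
#' statistics the simulator emulates: a 1024 x 1024 FOV with on average
#' 3543 +/- 767 nuclei of which ~12% are transfected, a Poisson + Gaussian
#' (shot + read) sCMOS-style noise model, and a graded mapping from latent
#' activation to the per-cell nuclear fraction of the reporter.
#'
#' @param fovSize pixels per side of the field of view.
#' @param meanCells,sdCells mean and sd of the truncated-normal nuclei count.
#' @param transfectionRate Bernoulli probability a cell is transfected.
#' @param nucleusRadiusRange uniform range of nucleus radii, pixels.
#' @param cytoplasmRadiusFactor cytoplasm outer radius / nucleus radius.
#' @param channelGains named photon budgets, see [SimParams-class].
#' @param reporterBrightnessSdLog lognormal sd of per-cell reporter totals.
#' @param nuclearFractionBase,nuclearFractionGain,nuclearFractionJitterSd
#'   parameters of the activation-to-nuclear-fraction mapping.
#' @param shotNoise apply Poisson shot noise.
#' @param readNoiseSd Gaussian read noise sigma, camera counts.
#' @param bitDepth output integer depth.
#' @param maxOverlap maximum tolerated nucleus disc overlap fraction.
#' @return a validated [SimParams-class] object.
#' @examples
#' p <- simParams(fovSize = 256L, meanCells = 60, sdCells = 10)
#' p
#' @export
simParams <- function(fovSize = 1024L,
                      meanCells = 3543,
                      sdCells = 767,
                      transfectionRate = 0.12,
                      nucleusRadiusRange = c(6, 12),
                      cytoplasmRadiusFactor = 2.0,
                      channelGains = c(nuclear = 600, marker = 200,
                                       reporter = 120000),
                      reporterBrightnessSdLog = 0.25,
                      nuclearFractionBase = 0.15,
                      nuclearFractionGain = 0.7,
                      nuclearFractionJitterSd = 0.05,
                      shotNoise = TRUE,
                      readNoiseSd = 3,
                      bitDepth = 16L,
                      maxOverlap = 0.3) {
  new("SimParams",
      fovSize = as.integer(fovSize), meanCells = meanCells,
      sdCells = sdCells, transfectionRate = transfectionRate,
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      cytoplasmRadiusFactor = cytoplasmRadiusFactor,
      channelGains = channelGains,
      reporterBrightnessSdLog = reporterBrightnessSdLog,
      nuclearFractionBase = nuclearFractionBase,
      nuclearFractionGain = nuclearFractionGain,
      nuclearFractionJitterSd = nuclearFractionJitterSd,
      shotNoise = shotNoise, readNoiseSd = readNoiseSd,
      bitDepth = as.integer(bitDepth), maxOverlap = maxOverlap)
}

#' Create a dose-to-activation model
#'
#' @param alpha0 activation at zero drug.
#' @param ic50 half-effect concentration (nM).
#' @param hill Hill slope.
#' @param floor activation at saturating drug.
#' @param reboundAmp amplitude of the optional high-dose rebound (0 = off).
#' @param reboundConc half-maximal concentration of the rebound bump.
#' @return a validated [DoseModel-class].
#' @examples
#' doseModel(alpha0 = 0.9, ic50 = 10)
#' @export
doseModel <- function(alpha0 = 0.9, ic50 = 10, hill = 1, floor = 0.05,
                      reboundAmp = 0, reboundConc = 1000) {
  new("DoseModel", alpha0 = alpha0, ic50 = ic50, hill = hill, floor = floor,
      reboundAmp = reboundAmp, reboundConc = reboundConc)
}

#' Create a model architecture specification
#'
#' Defaults give the reference multi-scale architecture: three
#' resolution paths (1024, 512, 256), 256 x 256 patches, five
#' conv(3x3)/ReLU/batch-norm/max-pool(2x2) modules with filter schedule
#' (4, 8, 16, 32, 64), global average pooling to a 64-vector per patch,
#' three 100-wide fully connected layers with 20% dropout between them, and
#' a single sigmoid output unit (or a 7-way softmax gene head).
#'
#' @param scales strictly decreasing image sides.
#' @param patch patch side.
#' @param filters per-module output channel counts.
#' @param kernel convolution kernel side.
#' @param pool max-pool window.
#' @param fcWidths fully connected layer widths.
#' @param dropout dropout fraction between FC layers.
#' @param head "activation" or "gene".
#' @param nGenes gene count for the softmax head.
#' @param shareWithinScale share the extractor across patches of one scale.
#' @param shareAcrossScales share one extractor across all scales.
#' @return a validated [ModelSpec-class].
#' @examples
#' spec <- modelSpec()
#' countParameters(spec)
#' @export
modelSpec <- function(scales = c(1024L, 512L, 256L), patch = 256L,
                      filters = c(4L, 8L, 16L, 32L, 64L), kernel = 3L,
                      pool = 2L, fcWidths = c(100L, 100L, 100L),
                      dropout = 0.20, head = "activation", nGenes = 7L,
                      shareWithinScale = TRUE, shareAcrossScales = FALSE) {
  new("ModelSpec",
      scales = as.integer(scales), patch = as.integer(patch),
      filters = as.integer(filters), kernel = as.integer(kernel),
      pool = as.integer(pool), fcWidths = as.integer(fcWidths),
      dropout = dropout, head = head, nGenes = as.integer(nGenes),
      shareWithinScale = shareWithinScale,
      shareAcrossScales = shareAcrossScales)
}

#' Create a training configuration
#'
#' Defaults follow the reference training recipe (batch size 32, Adam with
#' learning rate 1e-4); the stopping rule (early stopping on validation
#' loss, patience 5, at most 50 epochs) is this package's choice.
#'
#' @param batchSize images per gradient step.
#' @param learningRate Adam step size.
#' @param maxEpochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @param augment random flips / right-angle rotations of training patches.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 32L, learningRate = 1e-4,
                        maxEpochs = 50L, patience = 5L, seed = 1L,
                        augment = FALSE) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), seed = as.integer(seed),
      augment = augment)
}

#' Create a split specification
#'
#' @param fractions train/validation/test fractions (sum to 1).
#' @param seed integer seed for the plate assignment.
#' @return a validated [SplitSpec-class].
#' @export
splitSpec <- function(fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  new("SplitSpec", fractions = fractions, unit = "plate",
      seed = as.integer(seed))
}

#' Construct a well-image dataset from a manifest
#'
#' @param manifest data.frame or path to a manifest CSV.
#' @param root image root directory; defaults to the manifest's directory
#'   when a path is given.
#' @param channelRoles channel order of the stored images.
#' @return a [WellDataset-class].
#' @export
wellDataset <- function(manifest, root = ".",
                        channelRoles = c("nuclear", "marker", "reporter")) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("manifest file not found: ", manifest)
    if (missing(root)) root <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  new("WellDataset", manifest = manifest, root = root,
      channelRoles = channelRoles)
}

#' @describeIn wellDataset number of images in the dataset.
#' @param x a \code{WellDataset}.
#' @export
setMethod("length", "WellDataset", function(x) nrow(x@manifest))

#' Accessors for WellDataset
#'
#' @param x a [WellDataset-class].
#' @return \code{manifest()} returns the manifest data.frame;
#'   \code{imagePaths()} the absolute image paths; \code{plateIds()} the
#'   per-image plate identifiers.
#' @export
manifest <- function(x) x@manifest

#' @rdname manifest
#' @export
imagePaths <- function(x) file.path(x@root, x@manifest$image_path)

#' @rdname manifest
#' @export
plateIds <- function(x) as.character(x@manifest$plate_id)

#' Accessors for WellImage
#'
#' @param x a [WellImage-class].
#' @return \code{imageData()} returns the H x W x 3 array,
#'   \code{channelRoles()} the channel role names, \code{getChannel()} one
#'   channel matrix selected by role.
#' @export
imageData <- function(x) x@data

#' @rdname imageData
#' @export
channelRoles <- function(x) x@channelRoles

#' @rdname imageData
#' @param role one of the entries of \code{channelRoles(x)}.
#' @export
getChannel <- function(x, role) {
  i <- match(role, x@channelRoles)
  if (is.na(i)) stop("no channel with role '", role, "'")
  x@data[, , i]
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@fovSize, "x", object@fovSize, "FOV;",
      sprintf("%.0f +/- %.0f cells;", object@meanCells, object@sdCells),
      sprintf("%.1f%% transfected\n", 100 * object@transfectionRate))
})

setMethod("show", "WellTruth", function(object) {
  cat("WellTruth:", nrow(object@cellCenters), "cells,",
      sum(object@transfected), "transfected; alpha =",
      format(object@activation, digits = 3), "\n")
})

setMethod("show", "WellImage", function(object) {
  d <- dim(object@data)
  cat("WellImage:", d[1], "x", d[2], "px; channels:",
      paste(object@channelRoles, collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: scales (", paste(object@scales, collapse = ", "),
      "), patch ", object@patch, ", filters (",
      paste(object@filters, collapse = ", "), "), head '", object@head,
      "'\n  patches/image: ", sum((object@scales %/% object@patch)^2),
      "; embedding length: ", embeddingLength(object),
      "; parameters: ", countParameters(object), "\n", sep = "")
})

setMethod("show", "WellDataset", function(object) {
  m <- object@manifest
  cat("WellDataset:", nrow(m), "images,",
      length(unique(m$plate_id)), "plates,",
      length(unique(paste(m$gene, m$variant))), "variants\n")
})

setMethod("show", "DCNNModel", function(object) {
  cat("DCNNModel (head '", object@spec@head, "'), ",
      countParameters(object@spec), " parameters; ",
      if (nrow(object@history)) paste0("trained ", nrow(object@history),
                                       " epochs") else "untrained",
      "\n", sep = "")
})
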