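#' @useDynLib pathscore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rlnorm sd t.test cor median mad
#' @importFrom utils read.csv write.csv head
NULL

#' Simulation parameters for the synthetic translocation assay
#'
#' Describes one field of view (FOV) of a well from the reporter assay:
#' cell density, transfection rate, cell geometry, per-channel photon
#' budgets, the mapping from latent pathway activation to the nuclear
#' fraction of the reporter, and the camera noise model. Defaults are
#' calibrated to the assay statistics the simulator emulates:
#' 3543 +/- 767 nuclei per 1024x1024 FOV, of which ~12% are transfected.
#'
#' @slot fovSize integer, pixels per side of the square FOV.
#' @slot meanCells expected number of nuclei per FOV.
#' @slot sdCells standard deviation of the nuclei count (truncated at 1).
#' @slot transfectionRate probability that a cell carries the construct.
#' @slot nucleusRadiusRange min/max nucleus radius in pixels (uniform draw).
#' @slot cytoplasmRadiusFactor cytoplasm outer radius as a multiple (>1) of
#'   the nucleus radius.
#' @slot channelGains named numeric: \code{nuclear} and \code{marker} are
#'   expected photon counts per pixel inside the respective structure;
#'   \code{reporter} is the expected \emph{total} photon budget of one
#'   cell's reporter pool (so translocation redistributes, never adds,
#'   signal).
#' @slot reporterBrightnessSdLog log-sd of the per-cell lognormal
#'   expression variability of the reporter pool.
#' @slot nuclearFractionBase,nuclearFractionGain,nuclearFractionJitterSd
#'   per-cell reporter nuclear fraction is
#'   \code{clip(base + gain * alpha + N(0, jitter), 0, 1)}.
#' @slot shotNoise logical, apply Poisson shot noise to expected counts.
#' @slot readNoiseSd Gaussian read noise sigma in camera counts.
#' @slot bitDepth output integer depth (pixels quantised to 2^bitDepth - 1).
#' @slot maxOverlap maximum tolerated pairwise disc overlap (fraction of the
#'   smaller nucleus) during placement; heavier overlaps are rejected.
#'
#' @seealso [simParams()], [sampleLayout()], [renderWell()]
#' @export
setClass("SimParams", representation(
  fovSize = "integer",
  meanCells = "numeric",
  sdCells = "numeric",
  transfectionRate = "numeric",
  nucleusRadiusRange = "numeric",
  cytoplasmRadiusFactor = "numeric",
  channelGains = "numeric",
  reporterBrightnessSdLog = "numeric",
  nuclearFractionBase = "numeric",
  nuclearFractionGain = "numeric",
  nuclearFractionJitterSd = "numeric",
  shotNoise = "logical",
  readNoiseSd = "numeric",
  bitDepth = "integer",
  maxOverlap = "numeric"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@fovSize) != 1L || object@fovSize < 32L ||
      object@fovSize %% 2L != 0L)
    msg <- c(msg, "fovSize must be a single even integer >= 32")
  if (object@meanCells <= 0) msg <- c(msg, "meanCells must be > 0")
  if (object@sdCells < 0) msg <- c(msg, "sdCells must be >= 0")
  if (object@transfectionRate < 0 || object@transfectionRate > 1)
    msg <- c(msg, "transfectionRate must be in [0, 1]")
  if (length(object@nucleusRadiusRange) != 2L ||
      any(object@nucleusRadiusRange <= 0) ||
      diff(object@nucleusRadiusRange) < 0)
    msg <- c(msg, "nucleusRadiusRange must be increasing positive pair")
  if (object@cytoplasmRadiusFactor <= 1)
    msg <- c(msg, "cytoplasmRadiusFactor must be > 1")
  if (!all(c("nuclear", "marker", "reporter") %in% names(object@channelGains)))
    msg <- c(msg, "channelGains must name nuclear, marker and reporter")
  if (object@bitDepth < 8L || object@bitDepth > 16L)
    msg <- c(msg, "bitDepth must be between 8 and 16")
  if (object@maxOverlap < 0 || object@maxOverlap > 1)
    msg <- c(msg, "maxOverlap must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth for one simulated well
#'
#' Geometry and latent state of one simulated FOV: nucleus centres and
#' radii, per-cell transfection flags, and (after rendering) the latent
#' activation level and per-cell nuclear fraction of the reporter.
#'
#' @slot cellCenters n x 2 matrix of (y, x) nucleus centres in pixels.
#' @slot nucleusRadius numeric vector of nucleus radii.
#' @slot transfected logical vector, construct-positive cells.
#' @slot activation latent pathway activation alpha in [0, 1]
#'   (NA until rendered).
#' @slot nuclearFraction per-cell nuclear fraction of the reporter pool
#'   (length 0 until rendered; entries for non-transfected cells are NA).
#' @slot fovSize integer FOV side used to generate the layout.
#' @export
setClass("WellTruth", representation(
  cellCenters = "matrix",
  nucleusRadius = "numeric",
  transfected = "logical",
  activation = "numeric",
  nuclearFraction = "numeric",
  fovSize = "integer"
))

setValidity("WellTruth", function(object) {
  n <- nrow(object@cellCenters)
  msg <- character()
  if (ncol(object@cellCenters) != 2L) msg <- c(msg, "cellCenters must be n x 2")
  if (length(object@nucleusRadius) != n || length(object@transfected) != n)
    msg <- c(msg, "per-cell slots must have one entry per cell")
  if (length(object@nuclearFraction) &&
      any(!is.na(object@nuclearFraction) &
          (object@nuclearFraction < 0 | object@nuclearFraction > 1)))
    msg <- c(msg, "nuclearFraction must lie in [0, 1]")
  if (!is.na(object@activation) &&
      (object@activation < 0 || object@activation > 1))
    msg <- c(msg, "activation must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hill-type dose to activation model used by the simulator
#'
#' Maps a drug concentration to the latent activation level of a simulated
#' variant: a four-parameter decreasing Hill curve with an optional
#' high-dose "rebound" bump emulating off-target re-activation.
#'
#' @slot alpha0 activation at zero drug.
#' @slot ic50 half-effect concentration (same units as the dose grid, nM).
#' @slot hill Hill slope (> 0).
#' @slot floor minimal activation at saturating drug.
#' @slot reboundAmp amplitude of the optional high-dose bump (0 disables).
#' @slot reboundConc concentration of half-maximal rebound.
#' @seealso [doseToActivation()]
#' @export
setClass("DoseModel", representation(
  alpha0 = "numeric", ic50 = "numeric", hill = "numeric",
  floor = "numeric", reboundAmp = "numeric", reboundConc = "numeric"
))

setValidity("DoseModel", function(object) {
  msg <- character()
  if (object@alpha0 < 0 || object@alpha0 > 1) msg <- c(msg, "alpha0 in [0,1]")
  if (object@floor < 0 || object@floor > object@alpha0)
    msg <- c(msg, "floor must lie in [0, alpha0]")
  if (object@ic50 <= 0) msg <- c(msg, "ic50 must be > 0")
  if (object@hill <= 0) msg <- c(msg, "hill must be > 0")
  if (object@reboundAmp < 0) msg <- c(msg, "reboundAmp must be >= 0")
  if (object@reboundConc <= 0) msg <- c(msg, "reboundConc must be > 0")
  if (length(msg)) msg else TRUE
})

#' One field of view as a three-channel intensity raster
#'
#' Intensities are stored channel-last as an H x W x 3 array of doubles in
#' [0, 1] (camera counts divided by 2^bitDepth - 1). The channel order is
#' fixed by \code{channelRoles}; the default order is nuclear stain,
#' transfection marker, pathway reporter.
#'
#' @slot data H x W x 3 numeric array in [0, 1].
#' @slot channelRoles character(3), roles in channel order.
#' @slot path source file, or "" for in-memory images.
#' @export
setClass("WellImage", representation(
  data = "array", channelRoles = "character", path = "character"
))

setValidity("WellImage", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "data must be an H x W x 3 array")
  if (length(object@channelRoles) != 3L)
    msg <- c(msg, "channelRoles must have length 3")
  if (length(msg)) msg else TRUE
})

#' Architecture of the multi-scale patch network
#'
#' Hyperparameters of the multi-scale convolutional classifier: an image is
#' resampled to each entry of \code{scales}, tiled into
#' \code{patch} x \code{patch} patches, every patch is passed through a
#' stack of conv/ReLU/batch-norm/max-pool modules, globally average-pooled
#' to one feature vector per patch, and all vectors are concatenated into
#' one embedding that feeds the fully connected trunk and the output head.
#'
#' @slot scales strictly decreasing integer sides, e.g. c(1024, 512, 256).
#' @slot patch patch side; must divide every scale.
#' @slot filters output channels of the successive feature-extraction
#'   modules (their number sets the module count).
#' @slot kernel convolution kernel side (odd; size-preserving padding).
#' @slot pool max-pooling window (stride = window).
#' @slot fcWidths widths of the fully connected layers.
#' @slot dropout dropout fraction between fully connected layers.
#' @slot head "activation" (single sigmoid unit) or "gene"
#'   (\code{nGenes}-way softmax).
#' @slot nGenes number of genes for the softmax head.
#' @slot shareWithinScale share the feature extractor across the patches of
#'   one scale (one extractor per scale).
#' @slot shareAcrossScales share one feature extractor across all scales.
#' @export
setClass("ModelSpec", representation(
  scales = "integer", patch = "integer", filters = "integer",
  kernel = "integer", pool = "integer", fcWidths = "integer",
  dropout = "numeric", head = "character", nGenes = "integer",
  shareWithinScale = "logical", shareAcrossScales = "logical"
))

setValidity("ModelSpec", function(object) {
  msg <- character()
  s <- object@scales
  if (!length(s) || any(diff(s) >= 0))
    msg <- c(msg, "scales must be strictly decreasing")
  if (any(s %% object@patch != 0))
    msg <- c(msg, "patch must divide every scale")
  if (length(s) > 1 && any(max(s) %% s != 0))
    msg <- c(msg, "every scale must divide the largest scale")
  shrink <- object@pool^length(object@filters)
  if (object@patch %% shrink != 0)
    msg <- c(msg, sprintf(
      "patch (%d) must be divisible by pool^nModules (%d)",
      object@patch, shrink))
  if (object@kernel %% 2L != 1L) msg <- c(msg, "kernel must be odd")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (!object@head %in% c("activation", "gene"))
    msg <- c(msg, "head must be 'activation' or 'gene'")
  if (object@head == "gene" && object@nGenes < 2L)
    msg <- c(msg, "gene head needs nGenes >= 2")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' @slot batchSize images per optimisation step.
#' @slot learningRate Adam step size.
#' @slot maxEpochs upper bound on epochs.
#' @slot patience early-stopping patience on validation loss, in epochs.
#' @slot seed integer seed controlling initialisation, shuffling and dropout.
#' @slot augment apply random flips / 90-degree rotations to training
#'   patches (off by default).
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", learningRate = "numeric", maxEpochs = "integer",
  patience = "integer", seed = "integer", augment = "logical"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Plate-stratified split specification
#'
#' @slot fractions train/validation/test image fractions, summing to 1.
#' @slot unit stratification unit; only "plate" is supported: all images
#'   of a plate stay in one split so performance is measured across
#'   experimental batches.
#' @slot seed integer seed for the randomised plate assignment.
#' @export
setClass("SplitSpec", representation(
  fractions = "numeric", unit = "character", seed = "integer"
))

setValidity("SplitSpec", function(object) {
  msg <- character()
  f <- object@fractions
  if (length(f) != 3L || any(f <= 0) || abs(sum(f) - 1) > 1e-8)
    msg <- c(msg, "fractions must be 3 positive numbers summing to 1")
  if (!identical(object@unit, "plate"))
    msg <- c(msg, "only unit = 'plate' is supported")
  if (length(msg)) msg else TRUE
})

#' A well-image dataset: manifest plus image root
#'
#' @slot manifest data.frame with one row per image; required columns are
#'   image_path, plate_id, well_id, gene, variant, annotation_class; drug,
#'   concentration_nM and truth_alpha (synthetic ground truth) are optional.
#' @slot root directory that image_path entries are relative to.
#' @slot channelRoles channel order of the images on disk.
#' @export
setClass("WellDataset", representation(
  manifest = "data.frame", root = "character", channelRoles = "character"
))

setValidity("WellDataset", function(object) {
  req <- c("image_path", "plate_id", "well_id", "gene", "variant",
           "annotation_class")
  miss <- setdiff(req, names(object@manifest))
  if (length(miss))
    return(paste("manifest lacks columns:", paste(miss, collapse = ", ")))
  if (any(!nzchar(as.character(object@manifest$plate_id))))
    return("plate_id entries must be non-empty")
  TRUE
})

#' A trained (or initialised) multi-scale network
#'
#' @slot spec the [ModelSpec-class] the weights were built for.
#' @slot weights nested list of parameter arrays.
#' @slot specHash hash tying the weights to their spec, so that checkpoint /
#'   spec mismatches are detectable at load time.
#' @slot history per-epoch training metrics (empty before training).
#' @export
setClass("DCNNModel", representation(
  spec = "ModelSpec", weights = "list", specHash = "character",
  history = "data.frame"
))
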