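#' Sample the cell layout of one synthetic well
#'
#' Draws the geometry of one field of view: the nuclei count comes from a
#' normal distribution truncated at 1, each cell is flagged transfected
#' i.i.d. with the configured rate, nucleus radii are uniform in the
#' configured range, and centres are placed uniformly with rejection of
#' placements that overlap an existing nucleus by more than
#' \code{maxOverlap} of the smaller disc (a bounded number of attempts per
#' cell keeps dense fields feasible).
#'
#' @param params a [SimParams-class].
#' @param seed integer seed; the layout is fully determined by
#'   (params, seed).
#' @return a [WellTruth-class] with geometry filled in and activation NA
#'   (set later by [renderWell()]).
#' @examples
#' truth <- sampleLayout(simParams(fovSize = 256L, meanCells = 40,
#'                                 sdCells = 5), seed = 1)
#' truth
#' @export
sampleLayout <- function(params, seed) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  withSeed(seed, {
    n <- if (params@sdCells == 0) {
      max(1L, as.integer(round(params@meanCells)))
    } else {
      repeat {
        draw <- round(rnorm(1, params@meanCells, params@sdCells))
        if (draw >= 1) break
      }
      as.integer(draw)
    }
    transfected <- rbinom(n, 1L, params@transfectionRate) == 1L
    radii <- runif(n, params@nucleusRadiusRange[1],
                   params@nucleusRadiusRange[2])
    centers <- cpp_place_nuclei(radii, params@fovSize, params@maxOverlap,
                                40L)
    colnames(centers) <- c("y", "x")
    new("WellTruth", cellCenters = centers, nucleusRadius = radii,
        transfected = transfected, activation = NA_real_,
        nuclearFraction = numeric(0), fovSize = params@fovSize)
  })
}

# Uniform placement with a spatial hash; a candidate is rejected when any
# neighbour's nucleus disc would overlap the smaller of the two discs by
# more than maxOverlap (lens-area criterion). After maxTries rejected
# draws the last candidate is kept, which keeps very dense fields feasible
# while still discouraging heavy stacking.
placeNuclei <- function(n, radii, fov, maxOverlap, maxTries = 40L) {
  rmax <- max(radii)
  bin <- max(2 * rmax, 1)
  nbins <- max(1L, as.integer(ceiling(fov / bin)))
  grid <- vector("list", nbins * nbins)
  ys <- numeric(n)
  xs <- numeric(n)
  binOf <- function(y, x) {
    by <- min(nbins, max(1L, as.integer(ceiling(y / bin))))
    bx <- min(nbins, max(1L, as.integer(ceiling(x / bin))))
    c(by, bx)
  }
  for (i in seq_len(n)) {
    r <- radii[i]
    lo <- r + 1
    hi <- fov - r
    if (hi <= lo) { lo <- fov / 2; hi <- fov / 2 }
    for (try in seq_len(maxTries)) {
      y <- runif(1, lo, hi)
      x <- runif(1, lo, hi)
      b <- binOf(y, x)
      nb <- integer(0)
      for (dy in -1:1) for (dx in -1:1) {
        by <- b[1] + dy; bx <- b[2] + dx
        if (by >= 1 && by <= nbins && bx >= 1 && bx <= nbins)
          nb <- c(nb, grid[[(bx - 1L) * nbins + by]])
      }
      ok <- TRUE
      if (length(nb)) {
        d <- sqrt((ys[nb] - y)^2 + (xs[nb] - x)^2)
        ov <- discOverlapFraction(d, r, radii[nb])
        ok <- all(ov <= maxOverlap)
      }
      if (ok || try == maxTries) {
        ys[i] <- y; xs[i] <- x
        key <- (b[2] - 1L) * nbins + b[1]
        grid[[key]] <- c(grid[[key]], i)
        break
      }
    }
  }
  cbind(y = ys, x = xs)
}

# Fraction of the smaller disc covered by the lens-shaped intersection of
# two discs at centre distance d (vectorised over d and r2).
discOverlapFraction <- function(d, r1, r2) {
  rs <- pmin(r1, r2)
  rl <- pmax(r1, r2)
  out <- numeric(length(d))
  out[d >= r1 + r2] <- 0
  inside <- d <= rl - rs
  out[inside] <- 1
  mid <- d < r1 + r2 & !inside
  if (any(mid)) {
    dm <- d[mid]; a <- rs[mid]; b <- rl[mid]
    d1 <- (dm^2 - a^2 + b^2) / (2 * dm)
    d2 <- dm - d1
    lens <- b^2 * acos(pmin(1, pmax(-1, d1 / b))) -
      d1 * sqrt(pmax(0, b^2 - d1^2)) +
      a^2 * acos(pmin(1, pmax(-1, d2 / a))) -
      d2 * sqrt(pmax(0, a^2 - d2^2))
    out[mid] <- lens / (pi * a^2)
  }
  out
}

#' Map a drug concentration to a latent activation level
#'
#' Decreasing four-parameter Hill curve with an optional high-dose rebound
#' bump: \code{alpha(c) = floor + (alpha0 - floor) / (1 + (c/ic50)^hill) +
#' reboundAmp / (1 + (reboundConc/c)^hill)}, clipped to [0, 1]. With
#' \code{reboundAmp = 0} the curve is non-increasing in concentration and
#' bounded by \code{[floor, alpha0]}.
#'
#' @param model a [DoseModel-class].
#' @param conc concentration(s) >= 0, same units as \code{ic50} (nM).
#' @return activation level(s) in [0, 1].
#' @examples
#' m <- doseModel(alpha0 = 0.8, ic50 = 10, floor = 0)
#' doseToActivation(m, c(0, 10, 1e6))
#' @export
doseToActivation <- function(model, conc) {
  stopifnot(is(model, "DoseModel"))
  validObject(model)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  base <- model@floor +
    (model@alpha0 - model@floor) / (1 + (conc / model@ic50)^model@hill)
  reb <- ifelse(conc > 0,
                model@reboundAmp / (1 + (model@reboundConc / conc)^model@hill),
                0)
  clip01(base + reb)
}

#' Render one synthetic well image
#'
#' Paints the three channels of a field of view from its layout and a
#' latent activation level alpha. The nuclear-stain channel carries a disc
#' per nucleus for every cell; the transfection-marker channel carries
#' whole-cell discs for transfected cells only; the reporter channel exists
#' only in transfected cells and splits each cell's fixed photon budget
#' between the nuclear disc and the cytoplasmic annulus according to the
#' per-cell nuclear fraction \code{clip(base + gain * alpha + jitter, 0,
#' 1)} — translocation redistributes signal, it never adds any. Poisson
#' shot noise and Gaussian read noise are then applied and the raster is
#' quantised to \code{bitDepth} bits.
#'
#' @param truth a [WellTruth-class] from [sampleLayout()].
#' @param alpha latent activation level in [0, 1].
#' @param params the [SimParams-class] used for the layout.
#' @param seed integer seed for per-cell jitter, brightness and noise.
#' @return a list with \code{image} (a [WellImage-class]) and \code{truth}
#'   (the input truth with activation and per-cell nuclear fractions
#'   filled in).
#' @examples
#' p <- simParams(fovSize = 128L, meanCells = 15, sdCells = 2)
#' tr <- sampleLayout(p, seed = 1)
#' well <- renderWell(tr, alpha = 0.9, p, seed = 2)
#' well$image
#' @export
renderWell <- function(truth, alpha, params, seed) {
  stopifnot(is(truth, "WellTruth"), is(params, "SimParams"))
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  withSeed(seed, {
    H <- params@fovSize
    n <- nrow(truth@cellCenters)
    gains <- params@channelGains
    nuclear <- numeric(H * H)
    marker <- numeric(H * H)
    reporter <- numeric(H * H)
    nucFrac <- rep(NA_real_, n)
    # draw per-cell randomness for all cells so the RNG stream (and hence
    # every later draw) is independent of which cells are transfected
    jitter <- rnorm(n, 0, params@nuclearFractionJitterSd)
    brightness <- rlnorm(n, log(gains[["reporter"]]),
                         params@reporterBrightnessSdLog)
    for (i in seq_len(n)) {
      cy <- truth@cellCenters[i, 1]
      cx <- truth@cellCenters[i, 2]
      r <- truth@nucleusRadius[i]
      rc <- r * params@cytoplasmRadiusFactor
      cpp_add_disc(nuclear, H, H, cy, cx, r, gains[["nuclear"]])
      if (truth@transfected[i]) {
        f <- clip01(params@nuclearFractionBase +
                      params@nuclearFractionGain * alpha + jitter[i])
        nucFrac[i] <- f
        cpp_add_disc(marker, H, H, cy, cx, rc, gains[["marker"]])
        nNuc <- cpp_add_disc(reporter, H, H, cy, cx, r, 0)
        nAnn <- cpp_add_annulus(reporter, H, H, cy, cx, r, rc, 0)
        if (nNuc > 0)
          cpp_add_disc(reporter, H, H, cy, cx, r, f * brightness[i] / nNuc)
        if (nAnn > 0)
          cpp_add_annulus(reporter, H, H, cy, cx, r, rc,
                          (1 - f) * brightness[i] / nAnn)
      }
    }
    maxCount <- 2^params@bitDepth - 1
    quantise <- function(x) {
      if (params@shotNoise) x <- rpois(length(x), x)
      if (params@readNoiseSd > 0) x <- x + rnorm(length(x), 0,
                                                 params@readNoiseSd)
      matrix(pmin(maxCount, pmax(0, round(x))) / maxCount, H, H)
    }
    img <- array(c(quantise(nuclear), quantise(marker), quantise(reporter)),
                 dim = c(H, H, 3))
    truth@activation <- alpha
    truth@nuclearFraction <- nucFrac
    list(image = new("WellImage", data = img,
                     channelRoles = c("nuclear", "marker", "reporter"),
                     path = ""),
         truth = truth)
  })
}

#' Build a dose-series design block
#'
#' Expands one (variant, drug) combination over a concentration grid into
#' design rows for [generateExperiment()], using a [DoseModel-class] to set
#' the ground-truth activation at each dose.
#'
#' @param gene,variant,annotationClass labels for the manifest.
#' @param model a [DoseModel-class].
#' @param drug drug name.
#' @param concentrations dose grid in nM (0 allowed).
#' @param nWellsPerConc wells per concentration.
#' @return a design data.frame, one row per concentration.
#' @export
doseDesign <- function(gene, variant, annotationClass, model, drug,
                       concentrations, nWellsPerConc = 4L) {
  data.frame(gene = gene, variant = variant,
             annotation_class = annotationClass,
             drug = drug, concentration_nM = concentrations,
             alpha = doseToActivation(model, concentrations),
             n_wells = as.integer(nWellsPerConc),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic experiment: images plus manifest
#'
#' Renders every well of a design, writes one multi-page 16-bit TIFF per
#' well (page order nuclear, marker, reporter) and a manifest CSV. Wells
#' are randomly interleaved (seeded) before being grouped into plates of
#' \code{plateSize}, so each simulated plate mixes conditions the way a
#' real assay plate does and plate-stratified splits remain informative.
#' The ground-truth activation is stored in a \code{truth_alpha} column
#' that exists only for synthetic data.
#'
#' @param design data.frame with columns gene, variant, annotation_class,
#'   alpha, n_wells and optionally drug, concentration_nM. See
#'   [doseDesign()] for dose series.
#' @param params a [SimParams-class].
#' @param seed integer seed; identical (design, params, seed) yield
#'   bit-identical images and manifest.
#' @param outDir output directory (created if needed); images go to
#'   \code{outDir/images}, the manifest to \code{outDir/manifest.csv}.
#' @param plateSize wells per simulated plate.
#' @return a [WellDataset-class] for the generated manifest, invisibly.
#' @examples
#' d <- data.frame(gene = "KRAS", variant = c("WT", "G12D"),
#'                 annotation_class = c("WT", "activating"),
#'                 alpha = c(0.05, 0.9), n_wells = 2L)
#' p <- simParams(fovSize = 128L, meanCells = 15, sdCells = 2)
#' ds <- generateExperiment(d, p, seed = 1, outDir = tempfile())
#' ds
#' @export
generateExperiment <- function(design, params, seed, outDir,
                               plateSize = 16L) {
  stopifnot(is.data.frame(design), nrow(design) > 0)
  req <- c("gene", "variant", "annotation_class", "alpha", "n_wells")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (!"drug" %in% names(design)) design$drug <- NA_character_
  if (!"concentration_nM" %in% names(design))
    design$concentration_nM <- NA_real_
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)

  wells <- design[rep(seq_len(nrow(design)), design$n_wells), , drop = FALSE]
  nw <- nrow(wells)
  ord <- withSeed(deriveSeed(seed, 0L), sample.int(nw))
  wells <- wells[ord, , drop = FALSE]
  plate <- (seq_len(nw) - 1L) %/% plateSize + 1L
  wells$plate_id <- sprintf("P%03d", plate)
  wells$well_id <- sprintf("W%02d", (seq_len(nw) - 1L) %% plateSize + 1L)
  wells$image_path <- file.path("images",
                                sprintf("well_%04d.tif", seq_len(nw)))
  for (i in seq_len(nw)) {
    wseed <- deriveSeed(seed, i)
    truth <- sampleLayout(params, wseed)
    out <- renderWell(truth, wells$alpha[i], params,
                      deriveSeed(seed, i + nw))
    writeWellImage(out$image, file.path(outDir, wells$image_path[i]))
  }
  man <- data.frame(
    image_path = wells$image_path, plate_id = wells$plate_id,
    well_id = wells$well_id, gene = wells$gene, variant = wells$variant,
    annotation_class = wells$annotation_class, drug = wells$drug,
    concentration_nM = wells$concentration_nM,
    truth_alpha = wells$alpha, stringsAsFactors = FALSE)
  rownames(man) <- NULL
  write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(wellDataset(man, root = outDir))
}
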