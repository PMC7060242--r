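#' Write a well image as a multi-page 16-bit TIFF
#'
#' Pages are written in channel order (default nuclear, marker, reporter).
#' Intensities in [0, 1] are stored as unsigned 16-bit samples, so a
#' write/read round trip is exact up to integer quantisation.
#'
#' @param image a [WellImage-class].
#' @param path output file path (directories are created).
#' @return \code{path}, invisibly.
#' @export
writeWellImage <- function(image, path) {
  stopifnot(is(image, "WellImage"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(image@data)[3]),
                  function(i) image@data[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Load a well image from TIFF
#'
#' Accepts a 3-page greyscale TIFF (one page per channel) or a single-page
#' RGB TIFF. Intensities are returned as doubles in [0, 1], scaled by the
#' file's bit depth (a constant 16-bit page of 65535 loads as constant
#' 1.0). Channel roles are attached from \code{channelRoles} in page /
#' plane order.
#'
#' @param path TIFF file path.
#' @param channelRoles roles to attach, in channel order.
#' @return a [WellImage-class].
#' @export
loadWellImage <- function(path,
                          channelRoles = c("nuclear", "marker", "reporter")) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (length(pages) == 1L) {
    p <- pages[[1]]
    if (length(dim(p)) == 3L && dim(p)[3] >= 3L) {
      # RGB(A) single page; drop any alpha plane
      pages <- lapply(1:3, function(i) p[, , i])
    } else {
      stop("image '", path, "' has 1 channel; expected 3")
    }
  }
  if (length(pages) != 3L)
    stop("image '", path, "' has ", length(pages),
         " channels; expected 3")
  if (!all(vapply(pages, function(p) length(dim(p)) == 2L ||
                  is.null(dim(p)), TRUE)))
    stop("image '", path, "' has non-greyscale pages; expected 3 planes")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], 3))
  new("WellImage", data = arr, channelRoles = channelRoles, path = path)
}

#' Split a dataset by plate into train / validation / test
#'
#' Plates are atomic: all images of one plate land in the same split, so
#' that held-out performance is measured across experimental batches
#' rather than within them. Plates are assigned greedily (largest plate
#' first, seeded shuffle breaking ties) to whichever split currently has
#' the largest image deficit relative to its target fraction; the
#' resulting partition is disjoint and exhaustive and, for equal-size
#' plates at exactly divisible fractions, exact.
#'
#' @param dataset a [WellDataset-class].
#' @param spec a [SplitSpec-class].
#' @return named list of three [WellDataset-class] objects
#'   (\code{train}, \code{val}, \code{test}).
#' @examples
#' m <- data.frame(image_path = sprintf("w%d.tif", 1:10),
#'                 plate_id = sprintf("P%d", rep(1:5, each = 2)),
#'                 well_id = "W01", gene = "KRAS", variant = "WT",
#'                 annotation_class = "WT")
#' sp <- splitByPlate(wellDataset(m), splitSpec(seed = 1))
#' vapply(sp, length, 1L)
#' @export
splitByPlate <- function(dataset, spec = splitSpec()) {
  stopifnot(is(dataset, "WellDataset"), is(spec, "SplitSpec"))
  validObject(spec)
  man <- dataset@manifest
  plates <- table(as.character(man$plate_id))
  if (length(plates) < 3L)
    stop("plate-stratified split needs at least 3 plates; got ",
         length(plates))
  assign <- assignPlates(as.integer(plates), names(plates),
                         spec@fractions, spec@seed)
  out <- lapply(c(train = "train", val = "val", test = "test"),
                function(s) {
                  keep <- as.character(man$plate_id) %in%
                    names(assign)[assign == s]
                  new("WellDataset", manifest = man[keep, , drop = FALSE],
                      root = dataset@root,
                      channelRoles = dataset@channelRoles)
                })
  out
}

# Greedy largest-first assignment of plates (sizes = image counts) to the
# three splits, maximising the remaining image deficit of each split.
assignPlates <- function(sizes, plateNames, fractions, seed) {
  total <- sum(sizes)
  target <- fractions * total
  ord <- withSeed(seed, sample.int(length(sizes)))
  ord <- ord[order(sizes[ord], decreasing = TRUE)]  # stable: shuffled ties
  got <- c(train = 0, val = 0, test = 0)
  splits <- c("train", "val", "test")
  assign <- character(length(sizes))
  for (i in ord) {
    deficit <- target - got
    pick <- splits[which.max(deficit)]
    assign[i] <- pick
    got[pick] <- got[pick] + sizes[i]
  }
  names(assign) <- plateNames
  assign
}

#' Write a split as a manifest CSV with a split column
#'
#' @param splits the list returned by [splitByPlate()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSplit <- function(splits, path) {
  man <- do.call(rbind, lapply(names(splits), function(s) {
    m <- splits[[s]]@manifest
    if (nrow(m)) m$split <- s
    m
  }))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a split manifest back into the three datasets
#'
#' @param path CSV written by [writeSplit()].
#' @param root image root directory (defaults to the CSV's directory).
#' @param channelRoles channel order of the stored images.
#' @return named list of train / val / test [WellDataset-class] objects.
#' @export
readSplit <- function(path, root = dirname(path),
                      channelRoles = c("nuclear", "marker", "reporter")) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  if (!"split" %in% names(man)) stop("no 'split' column in ", path)
  lapply(c(train = "train", val = "val", test = "test"), function(s)
    new("WellDataset", manifest = man[man$split == s, , drop = FALSE],
        root = root, channelRoles = channelRoles))
}

# Resize a channel-last array to side `side`: exact block averaging when
# the ratio is an integer (area interpolation), EBImage bilinear otherwise.
resizeToSide <- function(arr, side) {
  h <- dim(arr)[1]
  if (h == side) return(arr)
  if (h %% side == 0) {
    f <- h %/% side
    out <- array(0, c(side, side, dim(arr)[3]))
    for (c in seq_len(dim(arr)[3])) out[, , c] <- blockMean(arr[, , c], f)
    out
  } else {
    as.array(EBImage::resize(EBImage::Image(arr, colormode = "Color"),
                             w = side, h = side))
  }
}

# Exact f x f block mean of a square matrix (area downsampling).
blockMean <- function(m, f) {
  h <- nrow(m) %/% f
  w <- ncol(m) %/% f
  s1 <- colMeans(array(m, c(f, h, ncol(m))))          # h x W
  t(colMeans(array(t(s1), c(f, w, h))))               # h x w
}
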