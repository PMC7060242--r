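# Performance surfaces (ROC/AUC, accuracy, confusion matrices) and an
# independent, non-learned nuclear-translocation oracle used to validate
# the simulator and benchmark the network.

#' Empirical ROC curve and AUC
#'
#' AUC by the trapezoidal rule over the empirical ROC, sweeping the
#' distinct score values as thresholds; tied scores contribute half, which
#' makes the result identical to the rank (Mann-Whitney) statistic and to
#' exhaustive pairwise comparison with 1/2 credit for ties.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1, logical, or a two-level factor where
#'   the second level is positive).
#' @return list with \code{auc} and \code{curve} (data.frame of fpr, tpr
#'   points from (0,0) to (1,1)).
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
rocAuc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) != 2L)
    stop("both classes must be present to compute a ROC curve")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # collapse threshold steps at tied scores
  newThr <- c(TRUE, diff(ss) != 0)
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  keep <- c(which(c(newThr[-1], TRUE)))
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) +
                                  curve$tpr[-1]) / 2)
  list(auc = auc, curve = curve)
}

#' Binary confusion matrix at a score threshold
#'
#' Predictions are "active" when the score strictly exceeds the threshold
#' (default: the sigmoid midpoint 0.5).
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = active).
#' @param threshold decision threshold.
#' @return 2 x 2 integer matrix (rows = truth, columns = prediction).
#' @export
confusionBinary <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  m <- matrix(0L, 2, 2, dimnames = list(truth = c("inactive", "active"),
                                        predicted = c("inactive", "active")))
  for (i in seq_along(y)) m[y[i] + 1L, pred[i] + 1L] <-
      m[y[i] + 1L, pred[i] + 1L] + 1L
  m
}

#' Multi-class confusion matrix from class probabilities
#'
#' Predictions by row-wise argmax; ties are broken towards the lowest
#' class index (deterministic and reported here so it is part of the
#' contract). Returns counts and row percentages (each true class sums
#' to 100).
#'
#' @param probs n x k probability matrix (or an integer vector of
#'   predicted classes).
#' @param labels true class indices (1-based) or factor.
#' @param classes optional class names.
#' @return list with \code{counts} and \code{percent} matrices.
#' @export
confusionMulti <- function(probs, labels, classes = NULL) {
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  pred <- if (is.matrix(probs)) max.col(probs, ties.method = "first")
  else as.integer(probs)
  k <- max(y, pred, if (is.matrix(probs)) ncol(probs) else 0L)
  if (is.null(classes)) classes <- if (is.factor(labels) &&
                                       nlevels(labels) == k)
    levels(labels) else as.character(seq_len(k))
  counts <- matrix(0L, k, k, dimnames = list(truth = classes,
                                             predicted = classes))
  for (i in seq_along(y)) counts[y[i], pred[i]] <- counts[y[i], pred[i]] + 1L
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, percent = percent)
}

#' Per-gene evaluation report
#'
#' For each gene: AUC of wildtype vs mutant separation and accuracy at the
#' 0.5 cutoff, plus unweighted means across genes and the pooled binary
#' confusion matrix. Mean AUC / accuracy recompute exactly from the
#' per-gene values.
#'
#' @param scores per-image activation scores.
#' @param man manifest rows aligned with \code{scores}; images with
#'   annotation_class "WT" are negatives, everything else positive.
#' @return list with \code{perGene} data.frame (gene, auc, accuracy, n),
#'   \code{meanAuc}, \code{meanAccuracy}, \code{confusion}.
#' @export
evalReport <- function(scores, man) {
  y <- as.integer(as.character(man$annotation_class) != "WT")
  genes <- sort(unique(as.character(man$gene)))
  rows <- lapply(genes, function(g) {
    i <- man$gene == g
    if (length(unique(y[i])) < 2L) return(NULL)
    data.frame(gene = g, auc = rocAuc(scores[i], y[i])$auc,
               accuracy = mean((scores[i] > 0.5) == (y[i] == 1)),
               n = sum(i), stringsAsFactors = FALSE)
  })
  perGene <- do.call(rbind, rows)
  if (is.null(perGene)) stop("no gene has both WT and mutant images")
  list(perGene = perGene,
       meanAuc = mean(perGene$auc),
       meanAccuracy = mean(perGene$accuracy),
       confusion = confusionBinary(scores, y))
}

# Exhaustive 1-D Otsu: the threshold maximising between-class variance.
otsuSplit1d <- function(x) {
  v <- sort(x)
  n <- length(v)
  if (n < 2L || v[n] - v[1] <= 0)
    return(list(thr = NA_real_, loMean = NA_real_, hiMean = NA_real_))
  cs <- cumsum(v)
  i <- seq_len(n - 1L)
  m0 <- cs[i] / i
  m1 <- (cs[n] - cs[i]) / (n - i)
  bc <- (i / n) * (1 - i / n) * (m1 - m0)^2
  k <- which.max(bc)
  list(thr = (v[k] + v[k + 1L]) / 2, loMean = m0[k], hiMean = m1[k])
}

#' Classical translocation oracle for one well
#'
#' An independent, non-learned readout of the translocation phenotype used
#' to validate the simulator and cross-check the network: nuclei are
#' segmented from the nuclear channel (Otsu threshold, hole filling,
#' distance-map watershed to split touching nuclei), transfected cells are
#' gated by a one-dimensional Otsu split of the nucleus-mean marker
#' intensities (with a separation floor that declares marker-free wells
#' empty), and the statistic is the median over transfected
#' cells of mean reporter intensity inside the nucleus divided by mean
#' reporter intensity in the surrounding cytoplasmic annulus.
#'
#' A well in which no transfected cell is detected yields an explicit
#' empty-well result (\code{empty = TRUE}, ratio NA), never a number.
#'
#' @param image a [WellImage-class] with declared channel roles.
#' @param markerSeparationFloor minimum separation (in normalised
#'   intensity units) between the marker-negative and marker-positive
#'   nucleus populations; below it the well is declared empty. The
#'   default corresponds to 20 camera counts at 16 bit, far above read
#'   noise and far below any real marker signal.
#' @param annulusFactor annulus outer radius as a multiple of the
#'   equivalent nucleus radius.
#' @return list with \code{ratio} (median nuclear:cytoplasmic reporter
#'   ratio), \code{nCells} (transfected cells used), \code{nNuclei}
#'   (segmented nuclei) and \code{empty}.
#' @export
oracleRatio <- function(image, markerSeparationFloor = 20 / 65535,
                        annulusFactor = 2) {
  stopifnot(is(image, "WellImage"))
  nuc <- getChannel(image, "nuclear")
  mrk <- getChannel(image, "marker")
  rep_ <- getChannel(image, "reporter")
  thr <- EBImage::otsu(EBImage::Image(nuc), range = c(0, 1))
  mask <- EBImage::fillHull(nuc > thr)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  nNuc <- max(labels)
  if (nNuc == 0L)
    return(list(ratio = NA_real_, nCells = 0L, nNuclei = 0L, empty = TRUE))
  labv <- as.integer(labels)
  inNuc <- labv > 0L
  # gate transfected nuclei by a 1-D Otsu split of the nucleus-mean
  # marker intensities: marker-positive nuclei form a well-separated
  # upper mode, and (unlike a pixel-background rule) the split is
  # unaffected by how much of the field the whole-cell marker discs
  # cover. A separation floor guards the no-transfection case.
  nucMarker <- tapply(mrk[inNuc], labv[inNuc], mean)
  split <- otsuSplit1d(as.numeric(nucMarker))
  if (is.na(split$thr) ||
      (split$hiMean - split$loMean) < markerSeparationFloor)
    return(list(ratio = NA_real_, nCells = 0L, nNuclei = nNuc,
                empty = TRUE))
  transfected <- as.integer(names(nucMarker))[nucMarker > split$thr]
  if (!length(transfected))
    return(list(ratio = NA_real_, nCells = 0L, nNuclei = nNuc,
                empty = TRUE))
  # annulus: pixels within annulusFactor * r_eq of a nucleus, assigned to
  # the nearest nucleus by seeded propagation, excluding all nuclei
  areas <- tabulate(labv[inNuc], nbins = nNuc)
  rEq <- sqrt(mean(areas) / pi)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(
    (annulusFactor - 1) * rEq)) + 1L, shape = "disc")
  territory <- EBImage::propagate(EBImage::Image(rep_), labels,
                                  mask = EBImage::dilate(mask, brush))
  terv <- as.integer(territory)
  ratios <- vapply(transfected, function(l) {
    nucMean <- mean(rep_[labv == l])
    ringPix <- rep_[terv == l & labv == 0L]
    if (!length(ringPix)) return(NA_real_)
    ringMean <- mean(ringPix)
    if (ringMean <= 0) return(NA_real_)
    nucMean / ringMean
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios))
    return(list(ratio = NA_real_, nCells = 0L, nNuclei = nNuc,
                empty = TRUE))
  list(ratio = median(ratios), nCells = length(ratios), nNuclei = nNuc,
       empty = FALSE)
}
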