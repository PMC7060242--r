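# Dose-response series: mean network output per drug concentration with
# SEM error bars, potency ordering, and high-dose rebound detection.

#' Build dose-response series from per-image scores
#'
#' Groups scores by (gene, variant, drug, concentration) and reports the
#' mean score, the standard error of the mean and the image count per
#' concentration, sorted by ascending dose (a zero-dose group, when
#' present, leads the series). Restricted to a single concentration the
#' means equal those of [summarizeVariants()].
#'
#' @param scores per-image activation scores aligned with \code{man}.
#' @param man manifest data.frame with gene, variant, drug and
#'   concentration_nM columns.
#' @return data.frame with columns gene, variant, drug, concentration_nM,
#'   mean_score, sem, n_images; one row per dose point.
#' @export
buildDoseSeries <- function(scores, man) {
  keep <- !is.na(man$drug) & nzchar(as.character(man$drug)) &
    !is.na(man$concentration_nM)
  if (!any(keep)) stop("no drug-treated wells in the manifest")
  man <- man[keep, , drop = FALSE]
  scores <- scores[keep]
  key <- paste(man$gene, man$variant, man$drug, man$concentration_nM,
               sep = "\r")
  idx <- split(seq_along(scores), key)
  rows <- lapply(idx, function(i) {
    data.frame(gene = as.character(man$gene[i[1]]),
               variant = as.character(man$variant[i[1]]),
               drug = as.character(man$drug[i[1]]),
               concentration_nM = man$concentration_nM[i[1]],
               mean_score = mean(scores[i]),
               sem = semOf(scores[i]),
               n_images = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$variant, out$drug, out$concentration_nM), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order two dose series by potency
#'
#' Purely descriptive comparison (no curve fitting): for each series, the
#' lowest concentration at which the mean score drops below a threshold —
#' by default halfway between the series' zero-dose (or lowest-dose) mean
#' and its minimum — and which series reaches its threshold at the lower
#' concentration. Equal crossing concentrations are reported as a tie.
#'
#' @param seriesA,seriesB single-series data.frames (one (variant, drug)
#'   each) as returned by [buildDoseSeries()].
#' @param threshold optional fixed score threshold applied to both series;
#'   by default each series uses its own halfway threshold.
#' @return list with per-series crossing concentrations and thresholds,
#'   and \code{morePotent} ("A", "B" or "tie").
#' @export
comparePotency <- function(seriesA, seriesB, threshold = NULL) {
  crossing <- function(s) {
    s <- s[order(s$concentration_nM), , drop = FALSE]
    thr <- threshold %||%
      ((s$mean_score[1] + min(s$mean_score)) / 2)
    below <- which(s$mean_score < thr)
    list(threshold = thr,
         concentration = if (length(below))
           s$concentration_nM[min(below)] else NA_real_)
  }
  a <- crossing(seriesA)
  b <- crossing(seriesB)
  morePotent <- if (is.na(a$concentration) && is.na(b$concentration)) {
    "tie"
  } else if (is.na(b$concentration) ||
             (!is.na(a$concentration) &&
              a$concentration < b$concentration)) {
    "A"
  } else if (is.na(a$concentration) ||
             b$concentration < a$concentration) {
    "B"
  } else {
    "tie"
  }
  list(A = a, B = b, morePotent = morePotent)
}

#' Detect a high-dose rebound in a dose series
#'
#' Flags a local minimum followed by a later rise that exceeds twice the
#' combined standard error of the two points (so noise-level fluctuations
#' are not flagged), and reports the concentration of the minimum. At
#' least four concentrations are required.
#'
#' @param series a single-series data.frame from [buildDoseSeries()].
#' @return list with \code{rebound} (logical), \code{minConcentration}
#'   (dose of the minimum preceding the rise, or NA) and \code{rise}
#'   (score increase from the minimum to the later maximum).
#' @export
detectRebound <- function(series) {
  s <- series[order(series$concentration_nM), , drop = FALSE]
  if (nrow(s) < 4L) stop("rebound detection needs >= 4 concentrations")
  m <- s$mean_score
  sem <- s$sem
  i <- which.min(m)  # first occurrence of the global minimum
  if (i < nrow(s)) {
    later <- (i + 1L):nrow(s)
    rise <- m[later] - m[i]
    gate <- 2 * sqrt(sem[later]^2 + sem[i]^2)
    if (any(rise > gate)) {
      return(list(rebound = TRUE, minConcentration = s$concentration_nM[i],
                  rise = max(rise)))
    }
  }
  list(rebound = FALSE, minConcentration = NA_real_, rise = 0)
}
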