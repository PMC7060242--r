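# Per-image scores, per-variant summaries, the 0.5 activity call, and the
# variant-vs-wildtype comparison.

#' Score every image of a dataset
#'
#' Deterministic inference-mode forward pass over all images, in batches.
#'
#' @param model a trained [DCNNModel-class] (activation head for scalar
#'   scores; gene head yields a probability matrix).
#' @param dataset a [WellDataset-class], or a list of [WellImage-class]
#'   objects.
#' @param batchSize images per forward batch.
#' @return numeric scores in (0, 1) (activation head) or an
#'   n x nGenes probability matrix (gene head), in dataset order.
#' @export
scoreImages <- function(model, dataset, batchSize = 16L) {
  imgs <- if (is(dataset, "WellDataset")) {
    paths <- imagePaths(dataset)
    function(i) loadWellImage(paths[i], dataset@channelRoles)
  } else {
    function(i) dataset[[i]]
  }
  n <- if (is(dataset, "WellDataset")) length(dataset) else length(dataset)
  if (n == 0L) stop("no images to score")
  spec <- model@spec
  out <- NULL
  for (s in seq(1L, n, by = batchSize)) {
    e <- min(n, s + batchSize - 1L)
    batch <- lapply(s:e, imgs)
    res <- forwardPass(model, batch)
    out <- if (spec@head == "activation") c(out, res) else rbind(out, res)
  }
  out
}

#' Summarise per-image scores by variant
#'
#' Averages the network's prediction values over all images of each
#' (gene, variant), reports the standard error of the mean, and calls a
#' variant \emph{active} when its mean score is strictly above the sigmoid
#' midpoint of 0.5 (a mean of exactly 0.5 is inactive).
#'
#' @param scores per-image scores aligned with \code{man}.
#' @param man manifest data.frame with gene, variant and annotation_class
#'   columns (e.g. \code{manifest(dataset)}).
#' @return data.frame with one row per variant: gene, variant,
#'   annotation_class, n_images, mean_score, sem, call.
#' @examples
#' man <- data.frame(gene = "BRAF", variant = "V600E",
#'                   annotation_class = "activating")[rep(1, 3), ]
#' summarizeVariants(c(0.8, 0.9, 1.0), man)
#' @export
summarizeVariants <- function(scores, man) {
  if (length(scores) == 0L) stop("no scores to summarise")
  if (length(scores) != nrow(man))
    stop("scores and manifest rows differ in length")
  key <- paste(man$gene, man$variant, sep = "\r")
  idx <- split(seq_along(scores), key)
  rows <- lapply(idx, function(i) {
    s <- scores[i]
    data.frame(gene = as.character(man$gene[i[1]]),
               variant = as.character(man$variant[i[1]]),
               annotation_class = as.character(man$annotation_class[i[1]]),
               n_images = length(s),
               mean_score = mean(s),
               sem = semOf(s),
               call = if (mean(s) > 0.5) "active" else "inactive",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$variant), , drop = FALSE]
}

#' Tabulate active calls per annotation class and gene
#'
#' For each (annotation_class, gene) present in the summaries: the number
#' of variants called active, the total, and the percentage, plus one
#' grand-total row per class. Classes with no variants are simply absent
#' from the table.
#'
#' @param summaries output of [summarizeVariants()].
#' @return data.frame with columns annotation_class, gene, n_active,
#'   n_total, percent_active.
#' @export
classBreakdown <- function(summaries) {
  rows <- list()
  for (cls in unique(summaries$annotation_class)) {
    sub <- summaries[summaries$annotation_class == cls, , drop = FALSE]
    for (g in unique(sub$gene)) {
      gs <- sub[sub$gene == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        annotation_class = cls, gene = g,
        n_active = sum(gs$call == "active"), n_total = nrow(gs),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      annotation_class = cls, gene = "Total",
      n_active = sum(sub$call == "active"), n_total = nrow(sub),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$percent_active <- 100 * out$n_active / out$n_total
  rownames(out) <- NULL
  out
}

#' Map variant names to protein positions
#'
#' Parses HGVS-like protein notation tolerantly: missense ("V654A",
#' "p.V600E"), deletions ("V152del"), anchored multi-residue forms
#' ("W557_558Del", "G12_G13_Del_Ins_DC"). The reported position is the
#' first (anchor) residue number. Unparseable names are returned in a
#' rejects table with a reason, never dropped silently.
#'
#' @param summaries output of [summarizeVariants()] (needs variant,
#'   mean_score, annotation_class columns).
#' @return list with \code{profile} (position, variant, mean_score,
#'   annotation_class, call; sorted by position) and \code{rejected}
#'   (variant, reason).
#' @examples
#' s <- data.frame(gene = "cKIT",
#'                 variant = c("V654A", "W557_558Del", "odd-name"),
#'                 annotation_class = "VUS", n_images = 1,
#'                 mean_score = c(0.8, 0.9, 0.5), sem = 0,
#'                 call = c("active", "active", "inactive"))
#' positionProfile(s)
#' @export
positionProfile <- function(summaries) {
  v <- as.character(summaries$variant)
  m <- regmatches(v, regexpr("[0-9]+", v))
  has <- grepl("[0-9]", v)
  wtLike <- toupper(v) %in% c("WT", "WILDTYPE", "WILD-TYPE")
  keep <- has & !wtLike
  pos <- rep(NA_integer_, length(v))
  pos[has] <- as.integer(regmatches(v, regexpr("[0-9]+", v)))
  profile <- data.frame(
    position = pos[keep], variant = v[keep],
    mean_score = summaries$mean_score[keep],
    annotation_class = summaries$annotation_class[keep],
    call = summaries$call[keep], stringsAsFactors = FALSE)
  profile <- profile[order(profile$position), , drop = FALSE]
  rownames(profile) <- NULL
  rejReason <- ifelse(wtLike[!keep], "wildtype reference, no position",
                      "no residue number found in name")
  rejected <- data.frame(variant = v[!keep], reason = rejReason,
                         stringsAsFactors = FALSE)
  list(profile = profile, rejected = rejected)
}

#' Compare a variant's image scores to wildtype
#'
#' Two-sample t test on per-image activation scores, Welch by default
#' (set \code{pooled = TRUE} for the classical equal-variance test).
#' Groups whose scores are all identical have no estimable variance and
#' raise an explicit degenerate-input error.
#'
#' @param variantScores,wtScores per-image scores, at least 2 each.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list with statistic, df, p.value, and the two group means.
#' @export
compareToWT <- function(variantScores, wtScores, pooled = FALSE) {
  if (length(variantScores) < 2L || length(wtScores) < 2L)
    stop("need at least 2 scores per group")
  if (sd(variantScores) == 0 && sd(wtScores) == 0)
    stop("degenerate input: both groups are constant, variance is zero")
  tt <- t.test(variantScores, wtScores, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       mean_variant = mean(variantScores), mean_wt = mean(wtScores))
}
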